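# DAPC-style population structure: PCA of allele frequencies, a-score PC
# selection, k-means cluster search with BIC, and linear discriminant
# analysis with membership probabilities.

#' PCA of the allele-frequency matrix
#'
#' Column-centred (optionally unit-scaled) frequencies decomposed by
#' singular values; percent variance per component is the eigenvalue
#' fraction.
#'
#' @param freqs imputed `afm` or a plain matrix.
#' @param n_components number of components to return.
#' @param scale unit-scale columns before decomposition (default FALSE:
#'   centre only).
#' @return list with `scores` (populations x components), `loadings`,
#'   `pct_variance` (all components), `sdev`.
#' @export
pca_frequencies <- function(freqs, n_components = NULL, scale = FALSE) {
  vals <- if (inherits(freqs, "afm")) freqs$values else freqs
  assert_that(!anyNA(vals), "PCA requires a complete matrix")
  maxc <- min(nrow(vals) - 1L, ncol(vals))
  n_components <- n_components %||% maxc
  assert_that(n_components >= 1 && n_components <= maxc,
              "n_components out of range")
  if (scale) {
    keep <- apply(vals, 2, stats::sd) > 0
    vals <- vals[, keep, drop = FALSE]
  }
  pc <- stats::prcomp(vals, center = TRUE, scale. = scale)
  pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
       pct_variance = pct, sdev = pc$sdev)
}

#' k-means cluster search with BIC
#'
#' Runs seeded k-means (25 restarts, 300 iterations) on retained PC scores
#' for K = 1..Kmax and scores each solution with the Gaussian-profile BIC
#' for k-means, BIC(K) = n log(WSS_K / n) + K log(n). K = 1 uses the total
#' centred sum of squares.
#'
#' @param scores populations x PCs score matrix.
#' @param k_max largest K to try (must be < number of populations).
#' @param seed RNG seed.
#' @param nstart,iter_max k-means control.
#' @return list with `bic_by_k`, `chosen_k` (argmin BIC), `assignments`
#'   (for chosen_k) and `wss_by_k`.
#' @export
find_clusters <- function(scores, k_max = 20L, seed = 1L, nstart = 25L,
                          iter_max = 300L) {
  n <- nrow(scores)
  assert_that(k_max < n, "k_max must be smaller than the number of populations")
  set.seed(seed)
  wss <- numeric(k_max)
  assign_list <- vector("list", k_max)
  tot <- sum(scale(scores, scale = FALSE)^2)
  wss[1] <- tot
  assign_list[[1]] <- rep(1L, n)
  for (k in 2:k_max) {
    km <- stats::kmeans(scores, centers = k, nstart = nstart,
                        iter.max = iter_max)
    wss[k] <- km$tot.withinss
    assign_list[[k]] <- km$cluster
  }
  bic <- n * log(wss / n) + seq_len(k_max) * log(n)
  chosen <- which.min(bic)
  list(bic_by_k = bic, wss_by_k = wss, chosen_k = chosen,
       assignments = stats::setNames(assign_list[[chosen]], rownames(scores)))
}

#' Discriminant analysis of principal components
#'
#' Linear discriminant analysis on retained PC scores: discriminant axes
#' are eigenvectors of W^-1 B (within / between class scatter); membership
#' probabilities are normal-density posteriors with equal priors from
#' Mahalanobis distances under the pooled within-class covariance. A ridge
#' is added to W when it is singular (e.g. single-member clusters).
#'
#' @param scores populations x PCs matrix.
#' @param assignments cluster labels per population.
#' @param n_pcs number of leading PCs to use (default all supplied).
#' @return list of class `dapc_fit`: `memberships` (rows sum to 1),
#'   `assignments` (argmax, ties to the lowest cluster index),
#'   `discriminant_scores`, `axes`, `n_axes`, `input_assignments`.
#' @export
dapc <- function(scores, assignments, n_pcs = ncol(scores)) {
  assert_that(n_pcs >= 1 && n_pcs <= ncol(scores), "n_pcs out of range")
  X <- scores[, seq_len(n_pcs), drop = FALSE]
  grp <- align_groups(assignments, rownames(X))
  grp <- factor(grp)
  K <- nlevels(grp)
  assert_that(K >= 2, "need at least two clusters")
  n <- nrow(X)

  mu <- apply(X, 2, function(c) tapply(c, grp, mean))
  mu <- matrix(mu, nrow = K)           # K x p class means
  gm <- colMeans(X)
  # pooled within-class scatter (covariance form)
  W <- matrix(0, n_pcs, n_pcs)
  for (k in seq_len(K)) {
    sel <- grp == levels(grp)[k]
    Xc <- sweep(X[sel, , drop = FALSE], 2, mu[k, ])
    W <- W + crossprod(Xc)
  }
  W <- W / max(n - K, 1)
  if (rcond_sym(W) < 1e-10) W <- W + diag(1e-6 * mean(diag(W)) + 1e-12, n_pcs)
  B <- matrix(0, n_pcs, n_pcs)
  for (k in seq_len(K)) {
    nk <- sum(grp == levels(grp)[k])
    dk <- mu[k, ] - gm
    B <- B + nk * tcrossprod(dk)
  }
  B <- B / n
  M <- solve(W, B)
  ei <- eigen(M)
  n_axes <- min(K - 1L, n_pcs)
  axes <- Re(ei$vectors[, seq_len(n_axes), drop = FALSE])
  ds <- X %*% axes
  rownames(ds) <- rownames(X)

  # posterior memberships: equal priors, pooled covariance W
  Winv <- solve(W)
  d2 <- sapply(seq_len(K), function(k) {
    Xc <- sweep(X, 2, mu[k, ])
    rowSums((Xc %*% Winv) * Xc)
  })
  logp <- -0.5 * d2
  logp <- logp - apply(logp, 1, max)
  post <- exp(logp)
  post <- post / rowSums(post)
  colnames(post) <- levels(grp)
  rownames(post) <- rownames(X)
  hard <- apply(post, 1, function(r) which(r == max(r))[1])  # tie -> lowest index
  structure(list(memberships = post,
                 assignments = stats::setNames(levels(grp)[hard], rownames(X)),
                 discriminant_scores = ds, axes = axes, n_axes = n_axes,
                 input_assignments = grp),
            class = "dapc_fit")
}

rcond_sym <- function(M) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

#' a-score selection of the number of PCs
#'
#' For each candidate PC count, the a-score is the observed proportion of
#' populations correctly reassigned to their cluster by the discriminant
#' step minus the mean reassignment proportion over label permutations
#' (which corrects for the overfitting that grows with PC count).
#'
#' @param scores populations x PCs matrix (at least max(candidates) cols).
#' @param groups cluster labels.
#' @param candidates PC counts to evaluate.
#' @param n_permutations permutations per candidate (default 10).
#' @param seed RNG seed.
#' @return list with `ascore` (named by candidate count), `optimal`
#'   (candidate maximising the a-score) and `observed`, `null_mean`.
#' @export
select_pcs_ascore <- function(scores, groups, candidates,
                              n_permutations = 10L, seed = 1L) {
  n <- nrow(scores)
  assert_that(all(candidates >= 1) && all(candidates < n),
              "candidate PC counts must be in [1, n_pops)")
  assert_that(max(candidates) <= ncol(scores), "not enough score columns")
  grp <- align_groups(groups, rownames(scores))
  set.seed(seed)
  obs <- null_mean <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    np <- candidates[i]
    fit <- dapc(scores, grp, n_pcs = np)
    obs[i] <- mean(fit$assignments == as.character(grp))
    reassign <- numeric(n_permutations)
    for (b in seq_len(n_permutations)) {
      pg <- sample(as.character(grp))
      names(pg) <- rownames(scores)
      pfit <- dapc(scores, pg, n_pcs = np)
      reassign[b] <- mean(pfit$assignments == pg)
    }
    null_mean[i] <- mean(reassign)
  }
  ascore <- obs - null_mean
  names(ascore) <- names(obs) <- names(null_mean) <- as.character(candidates)
  list(ascore = ascore, optimal = candidates[which.max(ascore)],
       observed = obs, null_mean = null_mean)
}

#' Full clustering pipeline for an allele-frequency matrix
#'
#' PCA, BIC-based k-means cluster number search, then DAPC memberships.
#' Mirrors the judgment call of overriding the BIC choice with a
#' `chosen_k` when geography or prior knowledge argues for it.
#'
#' @param freqs imputed `afm`.
#' @param n_pcs PCs retained for the discriminant step (typically few,
#'   chosen by a-score). The K search itself runs on all PCs: restricting
#'   the cluster-number search to a handful of axes lets k-means overfit
#'   small clusters and pushes the BIC minimum past the true K.
#' @param k_max largest K tried.
#' @param chosen_k optional override of the BIC-selected K.
#' @param seed RNG seed.
#' @return list of class `clustering_result`.
#' @export
cluster_populations <- function(freqs, n_pcs = 7L, k_max = 20L,
                                chosen_k = NULL, seed = 1L) {
  pc <- pca_frequencies(freqs)
  fc <- find_clusters(pc$scores, k_max = k_max, seed = seed)
  k <- chosen_k %||% fc$chosen_k
  if (k < 2L) k <- 2L
  set.seed(seed)
  km <- stats::kmeans(pc$scores, centers = k, nstart = 25L, iter.max = 300L)
  fit <- dapc(pc$scores, stats::setNames(km$cluster, rownames(pc$scores)),
              n_pcs = n_pcs)
  structure(list(pca = pc, bic_by_k = fc$bic_by_k, chosen_k = k,
                 bic_k = fc$chosen_k, dapc = fit,
                 assignments = fit$assignments,
                 memberships = fit$memberships),
            class = "clustering_result")
}
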