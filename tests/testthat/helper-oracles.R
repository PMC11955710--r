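# Independent oracles and small fixtures shared across test files. Each
# oracle is a deliberately naive re-implementation, kept separate from the
# package code paths it checks.

tiny_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_clusters = 3L, pops_per_cluster = c(5L, 5L, 5L),
             n_loci = 80L, n_adaptive = 6L, n_bioclim = 8L,
             design = list(locations = "Lincoln", years = 2L,
                           seasons = c("spring", "summer"), reps = 2L,
                           n_rows = 4L, n_cols = 4L),
             ...)
}

# Hudson-type FST between two frequency vectors (true frequencies):
# 1 - mean within-het / mean between-het
hudson_fst <- function(p1, p2) {
  hw <- p1 * (1 - p1) + p2 * (1 - p2)
  hb <- p1 * (1 - p2) + p2 * (1 - p1)
  1 - sum(hw) / sum(hb)
}

# naive O(n^2 L) Modified Rogers Distance
naive_mrd <- function(vals) {
  n <- nrow(vals)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (l in seq_len(ncol(vals))) {
      p <- c(vals[i, l], vals[j, l]); q <- 1 - p
      s <- s + (p[1] - p[2])^2 + (q[1] - q[2])^2
    }
    d[i, j] <- sqrt(s / (2 * ncol(vals)))
  }
  dimnames(d) <- list(rownames(vals), rownames(vals))
  d
}

# element-wise VanRaden G
naive_gmatrix <- function(vals) {
  pbar <- colMeans(vals)
  Z <- 2 * vals - 1
  Zc <- sweep(Z, 2, colMeans(Z))
  den <- 2 * sum(pbar * (1 - pbar))
  n <- nrow(vals)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    G[i, j] <- sum(Zc[i, ] * Zc[j, ]) / den
  G
}

# recursive numerator relationship (memoised on a full matrix)
naive_amatrix <- function(ped) {
  ids <- ped$id
  n <- length(ids)
  sire <- match(ped$sire, ids)
  dam <- match(ped$dam, ids)
  A <- matrix(NA_real_, n, n)
  a <- function(i, j) {
    if (!is.na(A[i, j])) return(A[i, j])
    val <- if (i == j) {
      1 + if (!is.na(sire[i]) && !is.na(dam[i])) 0.5 * a(sire[i], dam[i]) else 0
    } else {
      k <- max(i, j); m <- min(i, j)    # k is the later individual
      0.5 * ((if (!is.na(sire[k])) a(m, sire[k]) else 0) +
               (if (!is.na(dam[k])) a(m, dam[k]) else 0))
    }
    A[i, j] <<- A[j, i] <<- val
    val
  }
  for (i in seq_len(n)) for (j in seq_len(i)) a(i, j)
  dimnames(A) <- list(ids, ids)
  A
}

# naive RDA: explicit regression then eigendecomposition of the fitted
# cross-product
naive_rda <- function(Y, X) {
  Xs <- scale(X)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  B <- solve(crossprod(Xs), crossprod(Xs, Yc))
  Fit <- Xs %*% B
  ev <- eigen(crossprod(Fit), symmetric = TRUE)
  list(eig_fraction = ev$values[ev$values > 1e-10] / sum(Yc^2),
       constrained_proportion = sum(Fit^2) / sum(Yc^2))
}

# dense-V restricted log-likelihood for y = Xb + sum Z_i u_i + e
dense_logreml <- function(y, X, Zs, Ks, s2, s2e) {
  n <- length(y)
  V <- diag(s2e, n)
  for (i in seq_along(Zs)) {
    K <- Ks[[i]] %||% diag(ncol(Zs[[i]]))
    V <- V + s2[i] * (Zs[[i]] %*% K %*% t(Zs[[i]]))
  }
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtVX, t(X) %*% Vi)
  -0.5 * (determinant(V)$modulus + determinant(XtVX)$modulus +
            as.numeric(t(y) %*% P %*% y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# agreement between two labelings up to permutation (greedy best-match)
label_agreement <- function(a, b) {
  tab <- table(a, b)
  sum(apply(tab, 2, max)) / length(a)
}
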