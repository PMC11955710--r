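# REML variance components for the multi-environment trial mixed model,
# with a genomic covariance for the population term: average-information
# updates with EM fallback, boundary handling by fixing components at zero,
# GBLUPs, likelihood-ratio tests and narrow-sense heritability.
#
# Model: y = X beta + sum_i Z_i u_i + e,  u_i ~ N(0, K_i s2_i),
# e ~ N(0, I s2_e). The restricted likelihood is evaluated through the
# mixed-model equations: -2 logREML = (n-p) log s2_e + sum_i q_i log s2_i
# + sum_i log|K_i| + log|C| + y'Py, with C the MME coefficient matrix and
# y'Py = (y'y - bhat'X'y - uhat'Z'y)/s2_e.

#' Fit a Gaussian mixed model by AI-REML
#'
#' @param data data.frame of plot records; all design variables are treated
#'   as factors.
#' @param response name of the trait column.
#' @param fixed character vector of fixed-effect terms (e.g.
#'   `c("location", "year", "season")`); terms with fewer than two observed
#'   levels are dropped automatically (a single-site analysis simply has no
#'   location effect). `":"` builds factor interactions.
#' @param random character vector of random terms (e.g.
#'   `c("population", "population:season")`).
#' @param kmat named list mapping a random term to its covariance matrix
#'   (a `relationship_matrix` or plain matrix with level names); terms not
#'   listed use the identity.
#' @param tol convergence tolerance on the change in logREML.
#' @param max_iter iteration cap.
#' @param verbose print the iteration trace.
#' @return object of class `lmm_fit`: `estimates` (term, sigma2, se,
#'   boundary), `loglik`, `converged`, `gblup` (named list per K-term),
#'   `n`, `rank_x`, `gradient_norm`, `beta`.
#' @export
fit_lmm <- function(data, response, fixed = character(),
                    random = "population", kmat = list(),
                    tol = 1e-6, max_iter = 200L, verbose = FALSE) {
  data <- as.data.frame(data)
  y <- data[[response]]
  assert_that(is.numeric(y) && !anyNA(y), "response must be numeric and complete")
  n <- length(y)

  X <- build_fixed_matrix(data, fixed)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  p <- ncol(X)

  terms <- lapply(random, function(tm) make_random_term(data, tm, kmat))
  names(terms) <- random
  # drop terms confounded with the residual (one level per observation and
  # identity covariance cannot be separated from e)
  ok <- vapply(terms, function(t) t$q < n || !is.null(t$K), logical(1))
  if (!all(ok)) {
    warning("dropping non-identifiable random term(s): ",
            paste(random[!ok], collapse = ", "))
    terms <- terms[ok]
  }
  nt <- length(terms)
  assert_that(nt >= 1, "need at least one random term")

  Zs <- lapply(terms, `[[`, "Z")
  Z <- do.call(cbind, Zs)
  qs <- vapply(terms, `[[`, integer(1), "q")
  u_index <- split(seq_len(sum(qs)), rep(seq_len(nt), qs))

  # constant cross-products (C is modest here: dense factorizations win)
  XtX <- crossprod(X); XtZ <- as.matrix(crossprod(X, Z))
  ZtZ <- as.matrix(Matrix::crossprod(Z))
  Xty <- crossprod(X, y); Zty <- as.vector(Matrix::crossprod(Z, y))
  yty <- sum(y^2)
  Cbase <- rbind(cbind(XtX, XtZ), cbind(t(XtZ), ZtZ))
  uidx_all <- p + seq_len(sum(qs))
  logdetK <- sum(vapply(terms, `[[`, numeric(1), "logdetK"))

  vy <- stats::var(y)
  theta <- rep(vy / (nt + 1), nt + 1)      # components then residual
  names(theta) <- c(names(terms), "residual")
  lower <- 1e-8 * vy
  boundary <- rep(FALSE, nt)

  ll_old <- -Inf; ll <- NA_real_; converged <- FALSE
  AI <- NULL; sol <- NULL; Cchol <- NULL; trKC <- NULL; uqf <- NULL

  for (iter in seq_len(max_iter)) {
    s2 <- theta[seq_len(nt)]; s2e <- theta[nt + 1L]
    D <- as.matrix(Matrix::bdiag(lapply(seq_len(nt),
                                        function(i) terms[[i]]$Kinv / s2[i])))
    C <- Cbase / s2e
    C[uidx_all, uidx_all] <- C[uidx_all, uidx_all] + D
    Cchol <- tryCatch(chol(C), error = function(e)
      chol(C + diag(1e-8 * mean(diag(C)), nrow(C))))
    rhs <- c(Xty / s2e, Zty / s2e)
    sol <- backsolve(Cchol, forwardsolve(t(Cchol), rhs))
    beta <- sol[seq_len(p)]
    u <- sol[-seq_len(p)]
    Cinv <- chol2inv(Cchol)
    logdetC <- 2 * sum(log(diag(Cchol)))
    yPy <- (yty - sum(beta * Xty) - sum(u * Zty)) / s2e
    # -2 logREML = log|R| + log|G| + log|C| + y'Py with R = I s2e, so the
    # residual determinant term carries n (not n - p); the MME coefficient
    # matrix C absorbs log|X'V^-1 X|
    ll <- -0.5 * (n * log(s2e) + sum(qs * log(s2)) + logdetK +
                    logdetC + yPy)
    if (verbose) message(sprintf("iter %d logREML %.6f  theta: %s", iter, ll,
                                 paste(signif(theta, 4), collapse = " ")))

    # per-term quadratic forms and traces
    uqf <- numeric(nt); trKC <- numeric(nt)
    for (i in seq_len(nt)) {
      ui <- u[u_index[[i]]]
      blk <- Cinv[p + u_index[[i]], p + u_index[[i]], drop = FALSE]
      Kinv <- terms[[i]]$Kinv
      uqf[i] <- as.numeric(ui %*% (Kinv %*% ui))
      trKC[i] <- sum(Kinv * blk)          # tr(Kinv %*% blk), both symmetric
    }

    if (abs(ll - ll_old) < tol && iter > 2) { converged <- TRUE; break }
    ll_old <- ll

    # EM update (always available as fallback)
    em <- theta
    em[seq_len(nt)] <- (uqf + trKC) / qs
    resid <- y - as.vector(X %*% beta) - as.vector(Z %*% u)
    em[nt + 1L] <- (yty - sum(beta * Xty) - sum(u * Zty)) / (n - p)

    proposal <- em
    if (iter > 2) {
      ai_step <- tryCatch({
        gr <- reml_gradient(qs, s2, s2e, uqf, trKC, n, p, resid)
        Fm <- matrix(0, n, nt + 1L)
        for (i in seq_len(nt)) Fm[, i] <- as.vector(Zs[[i]] %*% u[u_index[[i]]]) / s2[i]
        Fm[, nt + 1L] <- resid / s2e
        rhsF <- rbind(crossprod(X, Fm) / s2e,
                      as.matrix(Matrix::crossprod(Z, Fm)) / s2e)
        solF <- backsolve(Cchol, forwardsolve(t(Cchol), rhsF))
        PF <- (Fm - X %*% solF[seq_len(p), , drop = FALSE] -
                 as.matrix(Z %*% solF[-seq_len(p), , drop = FALSE])) / s2e
        AI <- 0.5 * crossprod(Fm, PF)
        free <- c(!boundary, TRUE)
        step <- rep(0, nt + 1L)
        step[free] <- solve(AI[free, free, drop = FALSE], gr[free])
        cand <- theta + step
        # halve the step while it leaves the parameter space
        h <- 0
        while (any(cand[c(!boundary, TRUE)] <= 0) && h < 10) {
          step <- step / 2; cand <- theta + step; h <- h + 1
        }
        if (any(cand <= 0)) NULL else cand
      }, error = function(e) NULL)
      if (!is.null(ai_step)) proposal <- ai_step
    }
    proposal[seq_len(nt)][boundary] <- lower
    hit <- proposal[seq_len(nt)] < lower
    proposal[seq_len(nt)][hit] <- lower
    boundary <- boundary | (hit & theta[seq_len(nt)] <= lower * 1.0001)
    proposal[nt + 1L] <- max(proposal[nt + 1L], lower)
    theta <- proposal
  }

  s2 <- theta[seq_len(nt)]; s2e <- theta[nt + 1L]
  resid <- y - as.vector(X %*% sol[seq_len(p)]) -
    as.vector(Z %*% sol[-seq_len(p)])
  gr <- reml_gradient(qs, s2, s2e, uqf, trKC, n, p, resid)

  # standard errors from the inverse AI (observed information approximation)
  se <- rep(NA_real_, nt + 1L)
  if (!is.null(AI)) {
    Vinv <- tryCatch(solve(AI), error = function(e) NULL)
    if (!is.null(Vinv)) se <- sqrt(pmax(diag(Vinv), 0))
  }

  u <- sol[-seq_len(p)]
  gblup <- list()
  for (i in seq_len(nt)) {
    if (!is.null(terms[[i]]$K))
      gblup[[names(terms)[i]]] <-
        stats::setNames(u[u_index[[i]]], terms[[i]]$levels)
  }
  est <- data.frame(term = c(names(terms), "residual"),
                    sigma2 = ifelse(c(boundary, FALSE), 0, unname(theta)),
                    se = unname(se),
                    boundary = c(boundary, FALSE),
                    stringsAsFactors = FALSE)
  structure(list(estimates = est, loglik = as.numeric(ll),
                 theta = unname(theta), converged = converged,
                 gblup = gblup, n = n, rank_x = p,
                 gradient_norm = sqrt(sum(gr[c(!boundary, TRUE)]^2)),
                 beta = stats::setNames(sol[seq_len(p)], colnames(X)),
                 random = names(terms), response = response,
                 iterations = iter),
            class = "lmm_fit")
}

reml_gradient <- function(qs, s2, s2e, uqf, trKC, n, p, resid) {
  nt <- length(qs)
  gr <- numeric(nt + 1L)
  trP_terms <- qs - trKC / s2          # s2_i * tr(P Z_i K_i Z_i')
  for (i in seq_len(nt)) {
    trPZKZ <- trP_terms[i] / s2[i]
    gr[i] <- -0.5 * (trPZKZ - uqf[i] / s2[i]^2)
  }
  trP <- (n - p - sum(trP_terms)) / s2e
  yPPy <- sum(resid^2) / s2e^2
  gr[nt + 1L] <- -0.5 * (trP - yPPy)
  gr
}

build_fixed_matrix <- function(data, fixed) {
  keep <- character(0)
  for (tm in fixed) {
    vars <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (all(vapply(vars, function(v)
      length(unique(data[[v]])) >= 2L, logical(1))))
      keep <- c(keep, tm)
  }
  if (!length(keep)) return(matrix(1, nrow(data), 1,
                                   dimnames = list(NULL, "(Intercept)")))
  for (v in unique(unlist(strsplit(keep, ":"))))
    data[[v]] <- factor(data[[v]])
  stats::model.matrix(stats::as.formula(paste("~", paste(keep, collapse = " + "))),
                      data = data)
}

make_random_term <- function(data, term, kmat) {
  vars <- strsplit(term, ":", fixed = TRUE)[[1]]
  f <- if (length(vars) == 1L) factor(data[[vars]])
       else do.call(interaction,
                    c(lapply(vars, function(v) data[[v]]),
                      list(sep = ":", drop = TRUE)))
  levs <- levels(f)
  K <- kmat[[term]]
  if (!is.null(K)) {
    if (inherits(K, "relationship_matrix")) K <- K$values
    assert_that(all(levs %in% rownames(K)),
                paste0("covariance for '", term, "' must cover all levels"))
    K <- K[levs, levs, drop = FALSE]
    K <- (K + t(K)) / 2
    ch <- tryCatch(chol(K), error = function(e)
      chol(K + diag(1e-6 * mean(diag(K)), nrow(K))))
    Kinv <- chol2inv(ch)
    logdetK <- 2 * sum(log(diag(ch)))
  } else {
    Kinv <- Matrix::Diagonal(length(levs))
    logdetK <- 0
  }
  Z <- Matrix::sparse.model.matrix(~ 0 + f)
  colnames(Z) <- levs
  list(Z = Z, q = length(levs), K = K, Kinv = Kinv, logdetK = logdetK,
       levels = levs)
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %s: logREML %.3f (%s, %d iters, |grad| %.2e)\n",
              x$response, x$loglik,
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$gradient_norm))
  print(x$estimates, row.names = FALSE)
  invisible(x)
}

#' Likelihood-ratio test for one variance component
#'
#' The reduced model must nest the full model by removing exactly one
#' random term. The statistic 2 (logREML_full - logREML_reduced) is
#' referred to the boundary mixture 0.5 chi2_0 + 0.5 chi2_1.
#'
#' @param fit_full,fit_reduced `lmm_fit` objects.
#' @return list with `statistic`, `p_value`, `stars`, `term`.
#' @export
lrt_component <- function(fit_full, fit_reduced) {
  dropped <- setdiff(fit_full$random, fit_reduced$random)
  assert_that(length(dropped) == 1L &&
                all(fit_reduced$random %in% fit_full$random),
              "reduced model must remove exactly one random term from the full model")
  stat <- max(2 * (fit_full$loglik - fit_reduced$loglik), 0)
  p <- 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, p_value = p, stars = p_stars(p), term = dropped)
}

#' @rdname lrt_component
#' @param p p-value(s).
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Narrow-sense heritability on a population-mean basis
#'
#' h2 = s2_p / (s2_p + s2_pb/n_r + s2_ps/n_s + s2_py/n_y + s2_pl/n_l +
#' s2_e / (n_r n_s n_y n_l)). Absent interaction terms enter as 0 with
#' divisor 1; the residual divisor is the product of the effective
#' replicate / season / year / location counts of the analysis at hand.
#'
#' @param sigma_p additive (population) variance.
#' @param sigma_e residual variance.
#' @param sigma_pb,sigma_ps,sigma_py,sigma_pl interaction variances
#'   (population x replicate / season / year / location).
#' @param n_r,n_s,n_y,n_l effective numbers of replicates, seasons, years,
#'   locations.
#' @return heritability in \[0, 1\].
#' @export
heritability <- function(sigma_p, sigma_e, sigma_pb = 0, sigma_ps = 0,
                         sigma_py = 0, sigma_pl = 0,
                         n_r = 1L, n_s = 1L, n_y = 1L, n_l = 1L) {
  v <- c(sigma_p, sigma_e, sigma_pb, sigma_ps, sigma_py, sigma_pl)
  assert_that(all(is.finite(v)) && all(v >= 0), "variances must be >= 0")
  assert_that(all(c(n_r, n_s, n_y, n_l) >= 1), "divisors must be >= 1")
  denom <- sigma_p + sigma_pb / n_r + sigma_ps / n_s + sigma_py / n_y +
    sigma_pl / n_l + sigma_e / (n_r * n_s * n_y * n_l)
  assert_that(denom > 0, "all variance components are zero")
  sigma_p / denom
}

#' Standardized GBLUP matrix and its PCA
#'
#' Binds per-trait population GBLUPs into a population x trait matrix,
#' z-scores each trait, and (for `trait_pca`) ordinates the populations.
#'
#' @param fits named list of `lmm_fit` objects (one per trait), each with a
#'   G-covariance population term.
#' @param term name of the population random term (default "population").
#' @return `gblup_matrix`: population x trait matrix of standardized
#'   GBLUPs; traits with zero variance are dropped with a warning.
#' @export
gblup_matrix <- function(fits, term = "population") {
  assert_that(all(vapply(fits, function(f) f$converged, logical(1))),
              "all fits must have converged")
  cols <- lapply(fits, function(f) f$gblup[[term]])
  pops <- names(cols[[1]])
  m <- sapply(cols, function(v) v[pops])
  rownames(m) <- pops
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance trait(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  scale(m)
}

#' @rdname gblup_matrix
#' @param m standardized GBLUP matrix.
#' @export
trait_pca <- function(m) {
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  list(scores = pc$x, loadings = pc$rotation,
       pct_variance = 100 * pc$sdev^2 / sum(pc$sdev^2))
}
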