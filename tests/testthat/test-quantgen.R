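# AI-REML variance components, LRT, heritability, GBLUP PCA.

test_that("balanced one-way fit equals closed-form ANOVA estimators", {
  set.seed(42)
  np <- 92; m <- 24
  pop <- rep(sprintf("P%02d", 1:np), each = m)
  u <- rnorm(np)
  y <- 10 + u[as.integer(factor(pop))] + rnorm(np * m, sd = sqrt(2))
  d <- data.frame(population = pop, y = y)
  fit <- fit_lmm(d, "y", random = "population")
  expect_true(fit$converged)

  gm <- tapply(y, pop, mean)
  msb <- m * var(gm)
  mse <- sum((y - ave(y, pop))^2) / (np * m - np)
  expect_equal(fit$estimates$sigma2[1], (msb - mse) / m, tolerance = 1e-4)
  expect_equal(fit$estimates$sigma2[2], mse, tolerance = 1e-4)
  expect_lt(fit$gradient_norm, 1e-4)
})

test_that("logREML and its gradient agree with the dense-V oracle", {
  set.seed(7)
  n <- 60
  pop <- factor(rep(sprintf("P%d", 1:12), each = 5))
  blk <- factor(rep(1:5, times = 12))
  K <- crossprod(matrix(rnorm(144), 12, 12)) / 12 + diag(12) * 0.5
  dimnames(K) <- list(levels(pop), levels(pop))
  u <- as.vector(t(chol(K)) %*% rnorm(12))
  y <- 2 + u[as.integer(pop)] + rnorm(5)[as.integer(blk)] * 0.7 + rnorm(n)
  d <- data.frame(population = pop, block = blk, y = y)
  fit <- fit_lmm(d, "y", random = c("population", "block"),
                 kmat = list(population = K))
  expect_true(fit$converged)
  expect_lt(fit$gradient_norm, 1e-4)

  s2 <- fit$theta[1:2]          # raw values (boundary kept at its floor)
  s2e <- fit$theta[3]
  X <- matrix(1, n, 1)
  Zp <- model.matrix(~ 0 + pop); Zb <- model.matrix(~ 0 + blk)
  ll_dense <- dense_logreml(y, X, list(Zp, Zb), list(K, NULL), s2, s2e)
  expect_equal(fit$loglik, as.numeric(ll_dense), tolerance = 1e-6)

  # numerical gradient of the dense oracle is ~0 at the fitted optimum
  num_grad <- vapply(1:3, function(k) {
    h <- 1e-5
    th <- c(s2, s2e)
    up <- th; up[k] <- up[k] + h
    dn <- th; dn[k] <- dn[k] - h
    (dense_logreml(y, X, list(Zp, Zb), list(K, NULL), up[1:2], up[3]) -
       dense_logreml(y, X, list(Zp, Zb), list(K, NULL), dn[1:2], dn[3])) / (2 * h)
  }, numeric(1))
  free <- c(!fit$estimates$boundary[1:2], TRUE)   # boundary gradients are not zero
  expect_lt(max(abs(num_grad[free])), 1e-3)
})

test_that("fit matches lme4 on an identity-covariance model", {
  skip_if_not_installed("lme4")
  set.seed(15)
  d <- expand.grid(population = sprintf("P%d", 1:30),
                   season = c("sp", "su", "au"), rep = 1:4)
  u <- rnorm(30); ps <- rnorm(90) * 0.8
  d$y <- 3 + u[as.integer(d$population)] +
    ps[as.integer(interaction(d$population, d$season))] + rnorm(nrow(d))
  fit <- fit_lmm(d, "y", fixed = "season",
                 random = c("population", "population:season"))
  lf <- lme4::lmer(y ~ season + (1 | population) + (1 | population:season),
                   data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  lme4_est <- vc$vcov[match(c("population", "population:season", "Residual"),
                            vc$grp)]
  expect_equal(fit$estimates$sigma2, lme4_est, tolerance = 1e-4)
})

test_that("a zero-variance component is driven to the boundary", {
  set.seed(8)
  d <- data.frame(population = rep(sprintf("P%d", 1:40), each = 6))
  d$y <- rnorm(240)            # no population signal at all
  fit <- fit_lmm(d, "y", random = "population")
  expect_lt(fit$estimates$sigma2[1], 0.05)
  expect_equal(fit$estimates$sigma2[2], var(d$y), tolerance = 0.05)
})

test_that("GBLUPs shrink with vanishing signal and centre near zero", {
  set.seed(91)
  np <- 25
  K <- diag(np); dimnames(K) <- list(sprintf("P%d", 1:np), sprintf("P%d", 1:np))
  d <- data.frame(population = rep(rownames(K), each = 8))
  u <- rnorm(np, sd = 2)
  d$y_strong <- u[as.integer(factor(d$population))] + rnorm(200, sd = 0.5)
  d$y_null <- rnorm(200)
  f1 <- fit_lmm(d, "y_strong", random = "population",
                kmat = list(population = K))
  f0 <- fit_lmm(d, "y_null", random = "population",
                kmat = list(population = K))
  g1 <- f1$gblup$population; g0 <- f0$gblup$population
  expect_gt(sd(g1), 5 * sd(g0))
  expect_lt(abs(mean(g1)), 0.1)
  expect_gt(cor(g1, u), 0.9)
})

test_that("LRT uses the boundary mixture and maps stars correctly", {
  f <- list(loglik = -100, random = c("a", "b"))
  r <- list(loglik = -100, random = "a")
  class(f) <- class(r) <- "lmm_fit"
  out <- lrt_component(f, r)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 0.5)
  expect_equal(out$term, "b")
  expect_error(lrt_component(r, f), "exactly one")

  expect_equal(p_stars(c(0.0005, 0.005, 0.03, 0.3)),
               c("***", "**", "*", "ns"))

  # 2*delta logREML against the half-half mixture
  f2 <- list(loglik = -95, random = c("a", "b"))
  class(f2) <- "lmm_fit"
  out2 <- lrt_component(f2, r)
  expect_equal(out2$statistic, 10)
  expect_equal(out2$p_value, 0.5 * pchisq(10, 1, lower.tail = FALSE))
})

test_that("LRT has power for a strong simulated interaction", {
  # sigma2_ps = 1 against sigma2_e = 1: p < 0.001 in nearly all seeds
  hits <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    d <- expand.grid(population = sprintf("P%d", 1:30),
                     season = c("sp", "su", "au"), rep = 1:4)
    ps <- rnorm(90)
    d$y <- ps[as.integer(interaction(d$population, d$season))] + rnorm(360)
    full <- fit_lmm(d, "y", fixed = "season",
                    random = c("population", "population:season"))
    red <- fit_lmm(d, "y", fixed = "season", random = "population")
    lrt_component(full, red)$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("heritability follows its algebra and the published magnitude", {
  # sigma_p = sigma_e with residual divisor d: h2 = d / (d + 1)
  for (d in c(1, 6, 48))
    expect_equal(heritability(sigma_p = 2, sigma_e = 2,
                              n_r = d, n_s = 1, n_y = 1, n_l = 1),
                 d / (d + 1))
  expect_equal(heritability(sigma_p = 3, sigma_e = 0), 1)
  expect_error(heritability(0, 0), "zero")
  expect_error(heritability(-1, 1), ">= 0")

  # single-site across-years biomass magnitudes: within 0.06 of 0.81 under
  # the documented divisor convention (2 reps x 3 seasons x 3 years x 1 loc)
  h2 <- heritability(sigma_p = 1.12, sigma_e = 1.8, sigma_ps = 0.24,
                     sigma_py = 0.19, n_r = 2, n_s = 3, n_y = 3, n_l = 1)
  expect_lt(abs(h2 - 0.81), 0.06)

  # monotone: increasing in sigma_p, decreasing in each nuisance component
  base <- heritability(1, 1, 0.1, 0.1, 0.1, 0.1, 2, 3, 3, 2)
  expect_gt(heritability(1.5, 1, 0.1, 0.1, 0.1, 0.1, 2, 3, 3, 2), base)
  expect_lt(heritability(1, 1.5, 0.1, 0.1, 0.1, 0.1, 2, 3, 3, 2), base)
  expect_lt(heritability(1, 1, 0.5, 0.1, 0.1, 0.1, 2, 3, 3, 2), base)
  expect_lt(heritability(1, 1, 0.1, 0.5, 0.1, 0.1, 2, 3, 3, 2), base)
  expect_lt(heritability(1, 1, 0.1, 0.1, 0.5, 0.1, 2, 3, 3, 2), base)
  expect_lt(heritability(1, 1, 0.1, 0.1, 0.1, 0.5, 2, 3, 3, 2), base)
})

test_that("GBLUP matrix PCA matches the eigen oracle and edge cases", {
  set.seed(77)
  np <- 30
  K <- diag(np); dimnames(K) <- list(sprintf("P%d", 1:np), sprintf("P%d", 1:np))
  mk_fit <- function(vals) {
    structure(list(converged = TRUE,
                   gblup = list(population = setNames(vals, rownames(K)))),
              class = "lmm_fit")
  }
  u1 <- rnorm(np)
  fits <- list(t1 = mk_fit(u1), t2 = mk_fit(2 * u1 + 5))   # perfectly correlated
  m <- gblup_matrix(fits)
  expect_equal(unname(colMeans(m)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(m, 2, sd)), c(1, 1))
  pc <- trait_pca(m)
  expect_gt(pc$pct_variance[1], 99.999)

  # 8-trait fixture with known covariance: percent variance matches the
  # covariance eigenvalues
  set.seed(3)
  S <- crossprod(matrix(rnorm(64), 8, 8)) / 8 + diag(8)
  Xm <- matrix(rnorm(np * 8), np, 8) %*% chol(S)
  fits8 <- lapply(seq_len(8), function(j) mk_fit(Xm[, j]))
  names(fits8) <- paste0("t", 1:8)
  m8 <- gblup_matrix(fits8)
  pc8 <- trait_pca(m8)
  ev <- eigen(cov(m8), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(pc8$pct_variance, 100 * ev / sum(ev), tolerance = 1e-8)

  # zero-variance trait dropped with a warning
  fits0 <- list(t1 = mk_fit(u1), t2 = mk_fit(rep(1, np)))
  expect_warning(m0 <- gblup_matrix(fits0), "zero-variance")
  expect_equal(ncol(m0), 1L)
})
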