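# Collinearity pruning, RDA, candidate detection, predictor assignment,
# cluster chi-square, nearest-gene annotation.

test_that("prune_collinear implements the stated drop rule", {
  set.seed(51)
  n <- 60
  base <- matrix(rnorm(n * 4), n, 4)
  m <- cbind(base, base[, 2] + rnorm(n, sd = 0.1))   # duplicate-ish of var 2
  colnames(m) <- paste0("Bio", 1:5)
  kept <- prune_collinear(m, threshold = 0.8)
  # exactly one of the correlated pair dropped, others all retained
  expect_equal(length(kept), 4)
  expect_true(sum(c("Bio2", "Bio5") %in% kept) == 1)
  expect_true(all(c("Bio1", "Bio3", "Bio4") %in% kept))

  # mutually independent variables: all retained
  m0 <- base
  colnames(m0) <- paste0("Bio", 1:4)
  expect_equal(prune_collinear(m0, threshold = 0.8), colnames(m0))

  # oracle: independent re-implementation of the iterative rule on a
  # 19-variable table with planted links
  set.seed(52)
  core <- matrix(rnorm(n * 7), n, 7)
  full <- core
  for (j in 8:19) full <- cbind(full, core[, ((j - 8) %% 7) + 1] +
                                  rnorm(n, sd = 0.3))
  colnames(full) <- paste0("Bio", 1:19)
  oracle <- (function(mm, thr = 0.8) {
    vars <- colnames(mm)
    repeat {
      cc <- abs(cor(mm[, vars, drop = FALSE])); diag(cc) <- 0
      if (length(vars) < 2 || max(cc) < thr) return(vars)
      w <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      i <- w[1]; j <- w[2]
      mi <- mean(cc[i, -c(i, j)]); mj <- mean(cc[j, -c(i, j)])
      drop <- if (isTRUE(mi > mj)) i else if (isTRUE(mj > mi)) j else max(i, j)
      vars <- vars[-drop]
    }
  })(full)
  expect_identical(prune_collinear(full, threshold = 0.8), oracle)

  # constant variable dropped first with a warning
  cm <- cbind(base, const = rep(1, n))
  colnames(cm) <- paste0("Bio", 1:5)
  expect_warning(kc <- prune_collinear(cm), "zero-variance")
  expect_false("Bio5" %in% kc)
})

test_that("rda_fit matches the naive oracle and vegan", {
  set.seed(61)
  Y <- matrix(rnorm(10 * 20), 10, 20,
              dimnames = list(paste0("P", 1:10), paste0("f", 1:20)))
  X <- matrix(rnorm(10 * 3), 10, 3, dimnames = list(NULL, paste0("Bio", 1:3)))
  r <- rda_fit(Y, X)
  o <- naive_rda(Y, X)
  expect_equal(r$eig_fraction, o$eig_fraction, tolerance = 1e-8)
  expect_equal(r$constrained_proportion, o$constrained_proportion,
               tolerance = 1e-10)

  skip_if_not_installed("vegan")
  v <- vegan::rda(Y ~ ., data = as.data.frame(scale(X)))
  expect_equal(unname(r$eig_fraction),
               unname(v$CCA$eig / v$tot.chi), tolerance = 1e-8)

  # exactly linear response: constrained proportion = 1
  B <- matrix(rnorm(60), 3, 20)
  rl <- rda_fit(scale(X) %*% B, X)
  expect_equal(rl$constrained_proportion, 1, tolerance = 1e-10)

  # axis orthogonality of site scores
  cp <- crossprod(r$site_scores)
  expect_lt(max(abs(cp - diag(diag(cp)))), 1e-8)

  # independent response at large n: constrained proportion near q/(n-1)
  set.seed(62)
  Yn <- matrix(rnorm(500 * 40), 500, 40)
  Xn <- matrix(rnorm(500 * 5), 500, 5, dimnames = list(NULL, paste0("B", 1:5)))
  rn <- rda_fit(Yn, Xn)
  expect_lt(abs(rn$constrained_proportion - 5 / 499), 0.01)

  # rank-deficient predictors error names the aliased variable
  Xr <- cbind(X, Bio4 = X[, 1] * 2)
  expect_error(rda_fit(Y, Xr), "Bio4")
})

test_that("detect_candidates flags tail loci at the expected null rate", {
  # null: standard normal loadings -> expected flags ~ 4509 * 3 * 0.0027
  set.seed(71)
  fake <- structure(list(
    loadings = matrix(rnorm(4509 * 3), 4509, 3,
                      dimnames = list(sprintf("s%04d", 1:4509), NULL)),
    axes_used = 3L), class = "rda_result")
  got <- detect_candidates(fake, n_axes = 3, sd_mult = 3)
  lambda <- 4509 * 3 * 2 * pnorm(-3)
  expect_gt(nrow(got), qpois(0.001, lambda))
  expect_lt(nrow(got), qpois(0.999, lambda) + 10)

  # a planted 10-SD locus is flagged on its axis
  fake$loadings[1, 2] <- 10
  got2 <- detect_candidates(fake, n_axes = 3, sd_mult = 3)
  expect_true("s0001" %in% got2$locus)
  expect_equal(got2$axis[got2$locus == "s0001"], 2L)
  expect_error(detect_candidates(fake, n_axes = 5), "exceeds")
})

test_that("assign_predictor picks the strongest variable with BH control", {
  set.seed(81)
  n <- 92
  bio <- data.frame(population = sprintf("P%03d", 1:n),
                    Bio1 = rnorm(n), Bio2 = rnorm(n), Bio3 = rnorm(n))
  vals <- matrix(runif(n * 4, 0.2, 0.8), n, 4,
                 dimnames = list(bio$population, paste0("L", 1:4)))
  vals[, 1] <- plogis(2 * scale(bio$Bio3)[, 1])     # monotone in Bio3
  cand <- data.frame(locus = paste0("L", 1:4), axis = 1L, loading = 0.1)
  out <- assign_predictor(cand, afm(vals, provenance = "imputed"), bio)
  expect_equal(out$variable[1], "Bio3")
  expect_lt(out$p_value[1], 1e-6)
  # q >= p and BH monotone in the ranked p-values
  expect_true(all(out$q_value >= out$p_value - 1e-15))
  o <- order(out$p_value)
  expect_true(all(diff(out$q_value[o]) >= -1e-15))

  # identical predictors: deterministic tie-break to the lower Bio index
  bio2 <- bio; bio2$Bio2 <- bio2$Bio1
  vals2 <- vals
  vals2[, 2] <- plogis(scale(bio2$Bio1)[, 1])
  out2 <- assign_predictor(cand[2, , drop = FALSE],
                           afm(vals2, provenance = "imputed"), bio2)
  expect_equal(out2$variable, "Bio1")
})

test_that("chisq_cluster_association computes the independence test", {
  # hand-checked 2x2 contingency: (10,30)/(30,10) -> chi-square = 20
  tab <- rbind(c(10, 30), c(30, 10))
  expect_equal(unname(suppressWarnings(
    chisq.test(tab, correct = FALSE))$statistic), 20)

  # wire the same table through the module: 2 clusters x 1 pop, pool 20,
  # frequencies 10/40 and 30/40
  vals <- matrix(c(0.25, 0.75), 2, 1,
                 dimnames = list(c("P1", "P2"), "L1"))
  out <- chisq_cluster_association(
    data.frame(locus = "L1"), afm(vals, provenance = "imputed"),
    clusters = setNames(1:2, c("P1", "P2")), pool_size = 20)
  expect_equal(out$chisq, 20)

  # identical frequencies across clusters: statistic ~ 0, p ~ 1
  v0 <- matrix(0.4, 6, 2, dimnames = list(paste0("P", 1:6), c("a", "b")))
  out0 <- chisq_cluster_association(
    data.frame(locus = c("a", "b")), afm(v0, provenance = "imputed"),
    clusters = setNames(rep(1:2, each = 3), paste0("P", 1:6)))
  expect_lt(max(out0$chisq), 1e-10)
  expect_gt(min(out0$chisq_p), 0.999)

  # planted cluster-differentiated locus reaches q < 0.05 in >= 9/10 seeds
  hits <- vapply(1:10, function(s) {
    set.seed(200 + s)
    n <- 30
    cl <- setNames(rep(1:3, each = 10), sprintf("P%02d", 1:n))
    v <- matrix(runif(n * 5, 0.3, 0.7), n, 5,
                dimnames = list(names(cl), paste0("L", 1:5)))
    v[cl == 1, 1] <- runif(10, 0.05, 0.15)
    v[cl == 3, 1] <- runif(10, 0.85, 0.95)
    out <- chisq_cluster_association(data.frame(locus = paste0("L", 1:5)),
                                     afm(v, provenance = "imputed"), cl)
    out$chisq_q[1] < 0.05
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("nearest_gene applies the 3 kb window with strand awareness", {
  genes <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                      start = c(4000L, 20000L, 1000L),
                      end = c(6000L, 25000L, 2000L),
                      strand = c("+", "-", "+"),
                      gene_id = c("g1", "g2", "g3"))
  loci <- data.frame(
    locus = c("inside", "down2999", "gone3001", "up2999", "minus_up",
              "between", "nochrom"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr1", "chrX"),
    pos = c(5000L, 8999L, 9001L, 1001L, 27500L, 17500L, 100L))
  out <- nearest_gene(data.frame(locus = loci$locus), loci, genes)
  expect_equal(out$relation,
               c("within", "downstream", "none", "upstream", "upstream",
                 "downstream", "none"))
  expect_equal(out$gene, c("g1", "g1", NA, "g1", "g2", "g2", NA))
  expect_equal(out$distance, c(0, 2999, NA, 2999, 2500, 2500, NA))

  # between two genes: the nearer one wins (brute-force scan agrees)
  loci2 <- data.frame(locus = "x", chrom = "chr1", pos = 6000L + 1000L)
  o2 <- nearest_gene(data.frame(locus = "x"), loci2, genes)
  d_all <- pmax(0, genes$start - 7000L, 7000L - genes$end)
  expect_equal(o2$gene, genes$gene_id[which.min(replace(d_all, genes$chrom !=
                                                          "chr1", Inf))])
  # strand-naive mode flips the minus-strand relation
  o3 <- nearest_gene(data.frame(locus = "minus_up"), loci, genes,
                     strand_aware = FALSE)
  expect_equal(o3$relation, "downstream")
})

test_that("gea_scan is enriched for planted loci over background", {
  cfg <- sim_config(seed = 99, n_loci = 1200, n_adaptive = 30)
  f <- simulate_population_frequencies(cfg)
  ba <- simulate_bioclim_and_adaptive(f, cfg)
  pg <- simulate_pedigree_and_gff(cfg)
  scan <- gea_scan(ba$freqs, ba$bioclim, attr(f, "cluster"), genes = pg$genes)
  expect_gt(nrow(scan$candidates), 0)
  planted <- ba$adaptive$locus
  flagged <- scan$candidates$locus
  a <- sum(planted %in% flagged)
  b <- length(planted) - a
  cc <- length(flagged) - a
  dd <- cfg$n_loci - length(planted) - cc
  odds <- (a / max(b, 0.5)) / (cc / dd)
  expect_gt(odds, 10)
  expect_true(all(c("variable", "r", "p_value", "q_value", "chisq_q",
                    "gene", "relation", "distance") %in%
                    names(scan$candidates)))
})
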