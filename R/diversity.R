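# Between-population distance, within-group diversity, differentiation,
# gene flow and hierarchical AMOVA.

#' Modified Rogers Distance
#'
#' For populations x and y over L biallelic loci,
#' MRD(x, y) = sqrt( (1/(2L)) * sum_l \[ (p_xl - p_yl)^2 + (q_xl - q_yl)^2 \] )
#'           = sqrt( (1/L) * sum_l (p_xl - p_yl)^2 ),
#' bounded in \[0, 1\].
#'
#' @param freqs imputed `afm` (no missing values).
#' @return symmetric distance matrix with zero diagonal, population ids as
#'   dimnames.
#' @export
modified_rogers_distance <- function(freqs) {
  vals <- if (inherits(freqs, "afm")) freqs$values else freqs
  assert_that(!anyNA(vals), "MRD requires an imputed (complete) matrix")
  d <- as.matrix(stats::dist(vals)) / sqrt(ncol(vals))
  dimnames(d) <- list(rownames(vals), rownames(vals))
  d
}

#' Expected heterozygosity (gene diversity)
#'
#' Per-population He = mean over loci of 2 p (1 - p); for biallelic loci
#' bounded by 0.5. Optional cluster assignment adds per-cluster summaries.
#'
#' @param freqs imputed `afm`.
#' @param groups optional cluster assignment (vector named by population or
#'   aligned with rows).
#' @return list with `per_population` (named numeric) and, when groups are
#'   given, `per_cluster` (data.frame cluster, mean, min, max, n).
#' @export
expected_heterozygosity <- function(freqs, groups = NULL) {
  vals <- if (inherits(freqs, "afm")) freqs$values else freqs
  assert_that(!anyNA(vals), "He requires a complete matrix")
  he <- rowMeans(2 * vals * (1 - vals))
  out <- list(per_population = he)
  if (!is.null(groups)) {
    groups <- align_groups(groups, names(he))
    assert_that(all(table(groups) >= 1), "empty group")
    agg <- data.frame(
      cluster = sort(unique(groups)),
      mean = as.numeric(tapply(he, groups, mean)),
      min = as.numeric(tapply(he, groups, min)),
      max = as.numeric(tapply(he, groups, max)),
      n = as.integer(table(groups)))
    out$per_cluster <- agg
  }
  out
}

align_groups <- function(groups, ids) {
  if (!is.null(names(groups))) {
    assert_that(all(ids %in% names(groups)), "groups must cover all populations")
    groups <- groups[ids]
  } else {
    assert_that(length(groups) == length(ids),
                "groups must align with populations")
  }
  groups
}

#' Pairwise cluster FST (Nei-type, ratio of sums)
#'
#' For each cluster pair, FST = sum_l (HT_l - HS_l) / sum_l HT_l where HS_l
#' is the mean within-population heterozygosity 2p(1-p) across the member
#' populations of the two clusters and HT_l = 2 pbar (1 - pbar) with pbar
#' their mean frequency. Values are clipped to \[0, 1\]; a pair with HT = 0
#' at all loci is defined as FST = 0.
#'
#' @param freqs imputed `afm`.
#' @param groups cluster assignment.
#' @return list with `fst` (symmetric matrix), `nm` (gene-flow matrix,
#'   `NA` on the diagonal), `fst_class` and `nm_class` (label matrices).
#' @export
pairwise_fst <- function(freqs, groups) {
  vals <- if (inherits(freqs, "afm")) freqs$values else freqs
  groups <- align_groups(groups, rownames(vals))
  cl <- sort(unique(groups))
  assert_that(length(cl) >= 2, "need at least two groups")
  K <- length(cl)
  fst <- matrix(0, K, K, dimnames = list(cl, cl))
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    sel <- groups %in% c(cl[a], cl[b])
    p <- vals[sel, , drop = FALSE]
    hs <- colMeans(2 * p * (1 - p))
    pb <- colMeans(p)
    ht <- 2 * pb * (1 - pb)
    denom <- sum(ht)
    f <- if (denom > 0) sum(ht - hs) / denom else 0
    fst[a, b] <- fst[b, a] <- min(max(f, 0), 1)
  }
  nm <- matrix(NA_real_, K, K, dimnames = list(cl, cl))
  off <- which(upper.tri(fst) | lower.tri(fst))
  nm[off] <- vapply(fst[off], function(f) if (f > 0) gene_flow(f) else Inf,
                    numeric(1))
  fst_class <- matrix(NA_character_, K, K, dimnames = list(cl, cl))
  fst_class[off] <- classify_differentiation(fst[off])
  nm_class <- matrix(NA_character_, K, K, dimnames = list(cl, cl))
  nm_class[off] <- classify_gene_flow(pmin(nm[off], .Machine$double.xmax))
  list(fst = fst, nm = nm, fst_class = fst_class, nm_class = nm_class)
}

#' Gene flow from the fixation index
#'
#' Island-model equivalent number of migrants: Nm = (1 - FST) / (4 FST).
#'
#' @param fst fixation index in (0, 1\] (vectorised).
#' @export
gene_flow <- function(fst) {
  assert_that(all(is.finite(fst)) && all(fst > 0) && all(fst <= 1),
              "fst must lie in (0, 1]")
  (1 - fst) / (4 * fst)
}

#' Classify differentiation and gene-flow levels
#'
#' Differentiation bins (lower-inclusive, half-open): little \[0, 0.05),
#' moderate \[0.05, 0.15), great \[0.15, 0.25), and "very great" above 0.25
#' (an extension beyond the published bins, flagged in the label).
#' Gene-flow grades: low \[0, 0.25), medium \[0.25, 1), high >= 1.
#'
#' @param fst,nm non-negative values (vectorised).
#' @return character labels.
#' @export
classify_differentiation <- function(fst) {
  assert_that(all(fst >= 0), "fst must be non-negative")
  cut(fst, breaks = c(0, 0.05, 0.15, 0.25, Inf), right = FALSE,
      labels = c("little", "moderate", "great", "very great"),
      include.lowest = TRUE) |> as.character()
}

#' @rdname classify_differentiation
#' @export
classify_gene_flow <- function(nm) {
  assert_that(all(nm >= 0), "nm must be non-negative")
  cut(nm, breaks = c(0, 0.25, 1, Inf), right = FALSE,
      labels = c("low", "medium", "high"), include.lowest = TRUE) |>
    as.character()
}

#' Hierarchical AMOVA on a distance matrix
#'
#' Distance-based analysis of molecular variance with populations as units
#' nested in countries nested in clusters. Sums of squares come from
#' squared distances (SS of a group = sum of squared pairwise distances /
#' group size); variance components use the standard unbalanced
#' nested-design coefficients; significance by permutation (populations
#' permuted among clusters for the top level, among countries within
#' cluster for the middle level, and freely for Phi_ST).
#'
#' @param dist_mat symmetric distance matrix with population dimnames.
#' @param clusters cluster assignment per population.
#' @param countries optional country assignment (nested in clusters: each
#'   (cluster, country) pair forms a subgroup). When omitted a two-level
#'   AMOVA (clusters / populations) is returned.
#' @param n_perm permutations for p-values (default 999).
#' @param seed RNG seed for the permutations.
#' @return data.frame with one row per stratum: df, SS, MS, variance
#'   component, percent variance, Phi statistic and permutation p-value.
#' @export
amova <- function(dist_mat, clusters, countries = NULL, n_perm = 999,
                  seed = 1L) {
  ids <- rownames(dist_mat)
  clusters <- as.character(align_groups(clusters, ids))
  d2 <- dist_mat^2
  N <- length(ids)

  if (is.null(countries)) {
    res <- amova_two_level(d2, clusters)
  } else {
    countries <- as.character(align_groups(countries, ids))
    res <- amova_three_level(d2, clusters, countries)
  }

  # permutation p-values
  set.seed(seed)
  obs_phi <- res$phi
  exceed <- rep(0L, length(obs_phi))
  for (b in seq_len(n_perm)) {
    perm_cl <- sample(clusters)
    if (is.null(countries)) {
      pr <- amova_two_level(d2, perm_cl)
      exceed[1] <- exceed[1] + (pr$phi[1] >= obs_phi[1])
      exceed[2] <- exceed[2] + (pr$phi[2] >= obs_phi[2])
    } else {
      # top level: permute populations among clusters (countries follow)
      o <- sample(N)
      pr_top <- amova_three_level(d2, clusters[o], countries[o])
      exceed[1] <- exceed[1] + (pr_top$phi[1] >= obs_phi[1])
      # middle: permute populations among countries within their cluster
      perm_co <- countries
      for (g in unique(clusters)) {
        sel <- which(clusters == g)
        perm_co[sel] <- countries[sel][sample(length(sel))]
      }
      pr_mid <- amova_three_level(d2, clusters, perm_co)
      exceed[2] <- exceed[2] + (pr_mid$phi[2] >= obs_phi[2])
      # bottom: free permutation (Phi_ST analogue)
      pr_bot <- amova_three_level(d2, clusters[o], countries[o])
      exceed[3] <- exceed[3] + (pr_bot$phi[3] >= obs_phi[3])
    }
  }
  res$table$p_value <- NA_real_
  k <- length(obs_phi)
  res$table$p_value[seq_len(k)] <- (exceed + 1) / (n_perm + 1)
  res$table
}

ss_within <- function(d2, groups) {
  s <- 0
  for (g in unique(groups)) {
    sel <- groups == g
    n <- sum(sel)
    s <- s + sum(d2[sel, sel]) / (2 * n)
  }
  s
}

amova_two_level <- function(d2, clusters) {
  N <- nrow(d2)
  G <- length(unique(clusters))
  ss_tot <- sum(d2) / (2 * N)
  ss_wg <- ss_within(d2, clusters)
  ss_ag <- ss_tot - ss_wg
  df_ag <- G - 1
  df_wg <- N - G
  ms_ag <- ss_ag / df_ag
  ms_wg <- ss_wg / df_wg
  ng <- table(clusters)
  n0 <- (N - sum(ng^2) / N) / (G - 1)
  sig_w <- ms_wg
  sig_a <- max((ms_ag - ms_wg) / n0, 0)
  tot <- sig_a + sig_w
  phi <- c(sig_a / tot, sig_a / tot)
  tab <- data.frame(
    stratum = c("among_clusters", "within_clusters", "total"),
    df = c(df_ag, df_wg, N - 1),
    SS = c(ss_ag, ss_wg, ss_tot),
    MS = c(ms_ag, ms_wg, ss_tot / (N - 1)),
    variance = c(sig_a, sig_w, tot),
    pct_variance = c(100 * sig_a / tot, 100 * sig_w / tot, 100),
    phi = c(phi[1], NA, NA))
  list(table = tab, phi = phi[1:2])
}

amova_three_level <- function(d2, clusters, countries) {
  N <- nrow(d2)
  cg <- paste(clusters, countries, sep = "/")   # enforce nesting
  G <- length(unique(clusters))
  C <- length(unique(cg))
  ss_tot <- sum(d2) / (2 * N)
  ss_within_cl <- ss_within(d2, clusters)
  ss_within_co <- ss_within(d2, cg)
  ss_among_cl <- ss_tot - ss_within_cl
  ss_among_co <- ss_within_cl - ss_within_co
  df_cl <- G - 1
  df_co <- C - G
  df_pop <- N - C
  ms_cl <- ss_among_cl / df_cl
  ms_co <- ss_among_co / df_co
  ms_pop <- ss_within_co / df_pop

  # unbalanced nested-design coefficients (units have weight 1)
  n_gc <- table(cg)                       # pops per (cluster, country)
  n_g <- table(clusters)                  # pops per cluster
  cl_of_cg <- sub("/.*$", "", names(n_gc))
  A <- sum(n_gc^2 / n_g[cl_of_cg])
  n1 <- (N - A) / df_co
  n2 <- (A - sum(n_gc^2) / N) / df_cl
  n3 <- (N - sum(n_g^2) / N) / df_cl

  sig_c <- ms_pop
  sig_b <- max((ms_co - ms_pop) / n1, 0)
  sig_a <- max((ms_cl - ms_pop - n2 * sig_b) / n3, 0)
  tot <- sig_a + sig_b + sig_c
  phi_ct <- sig_a / tot
  phi_sc <- if (sig_b + sig_c > 0) sig_b / (sig_b + sig_c) else 0
  phi_st <- (sig_a + sig_b) / tot
  tab <- data.frame(
    stratum = c("among_clusters", "among_countries_within",
                "among_populations_within", "total"),
    df = c(df_cl, df_co, df_pop, N - 1),
    SS = c(ss_among_cl, ss_among_co, ss_within_co, ss_tot),
    MS = c(ms_cl, ms_co, ms_pop, ss_tot / (N - 1)),
    variance = c(sig_a, sig_b, sig_c, tot),
    pct_variance = c(100 * sig_a / tot, 100 * sig_b / tot,
                     100 * sig_c / tot, 100),
    phi = c(phi_ct, phi_sc, phi_st, NA))
  list(table = tab, phi = c(phi_ct, phi_sc, phi_st))
}
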