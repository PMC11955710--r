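#' Simulation configuration
#'
#' Describes the world the synthetic-data generator emulates: a germplasm
#' collection of ~92 populations falling into ~7 drift-structured clusters,
#' genotyped as 30-individual DNA bulks with 4 technical sequencing
#' replicates at ~4,509 biallelic loci, with bioclimatic descriptors of the
#' collection sites, a planted subset of environment-associated loci, and
#' multi-environment plot phenotypes generated from the mixed model the
#' quantitative-genetics module fits.
#'
#' @param seed integer master seed; all generator randomness derives from it.
#' @param n_clusters number of genetic clusters.
#' @param pops_per_cluster integer vector of cluster sizes (defaults mirror
#'   the seven-cluster collection: 6, 27, 12, 12, 8, 19, 8 populations).
#' @param n_loci number of biallelic loci.
#' @param cluster_fst Balding-Nichols drift parameter F per cluster, in (0,1).
#' @param within_sd within-cluster (among-population) perturbation SD on the
#'   frequency scale. The default 0.12 keeps the majority of molecular
#'   variance among populations rather than among clusters (the pattern the
#'   hierarchical AMOVA of such collections shows) while leaving the seven
#'   clusters cleanly recoverable; it also gives the genomic relationship
#'   matrix enough within-cluster rank for population variance components
#'   to be well-conditioned.
#' @param pool_size individuals pooled per bulk.
#' @param n_tech_reps technical sequencing replicates per bulk.
#' @param mean_depth mean Poisson read depth per locus per replicate.
#' @param missing_rate per-(population, locus) dropout probability (all
#'   replicates at zero depth), exercising the coverage filter.
#' @param n_bioclim number of bioclimatic variables (Bio1..Bio_n).
#' @param n_adaptive number of loci whose frequencies are driven by a
#'   bioclimatic variable.
#' @param adaptive_slope logit-scale effect per SD of the driver variable.
#' @param trait_config named list per trait of variance components
#'   (`sigma_p`, `sigma_ps`, `sigma_py`, `sigma_pl`, `sigma_b`, `sigma_row`,
#'   `sigma_col`, `sigma_e`) on the trait scale.
#' @param design list with `locations`, `years`, `seasons`, `reps`,
#'   `n_rows`, `n_cols` describing the balanced row-column trial layout.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_clusters = 7L,
                       pops_per_cluster = c(6L, 27L, 12L, 12L, 8L, 19L, 8L),
                       n_loci = 4509L,
                       cluster_fst = 0.06,
                       within_sd = 0.12,
                       pool_size = 30L,
                       n_tech_reps = 4L,
                       mean_depth = 20,
                       missing_rate = 0.02,
                       n_bioclim = 19L,
                       n_adaptive = 60L,
                       adaptive_slope = 1.5,
                       trait_config = default_trait_config(),
                       design = list(locations = c("Lincoln", "PalmerstonNorth"),
                                     years = 3L, seasons = c("spring", "summer", "autumn"),
                                     reps = 2L, n_rows = 8L, n_cols = 12L)) {
  cfg <- list(seed = as.integer(seed), n_clusters = as.integer(n_clusters),
              pops_per_cluster = as.integer(pops_per_cluster),
              n_loci = as.integer(n_loci), cluster_fst = cluster_fst,
              within_sd = within_sd, pool_size = as.integer(pool_size),
              n_tech_reps = as.integer(n_tech_reps), mean_depth = mean_depth,
              missing_rate = missing_rate, n_bioclim = as.integer(n_bioclim),
              n_adaptive = as.integer(n_adaptive), adaptive_slope = adaptive_slope,
              trait_config = trait_config, design = design)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  num_ok <- function(x) all(is.finite(x))
  assert_that(num_ok(cfg$cluster_fst) && all(cfg$cluster_fst > 0) &&
                all(cfg$cluster_fst < 1),
              "cluster_fst must lie in (0, 1)")
  assert_that(length(cfg$pops_per_cluster) == cfg$n_clusters,
              "pops_per_cluster must have n_clusters entries")
  assert_that(all(cfg$pops_per_cluster >= 1L), "each cluster needs >= 1 population")
  assert_that(num_ok(cfg$mean_depth) && cfg$mean_depth > 0, "mean_depth must be > 0")
  assert_that(cfg$pool_size >= 1L && cfg$n_tech_reps >= 1L,
              "pool_size and n_tech_reps must be >= 1")
  assert_that(cfg$missing_rate >= 0 && cfg$missing_rate < 1,
              "missing_rate must be in [0, 1)")
  assert_that(cfg$n_adaptive <= cfg$n_loci, "n_adaptive cannot exceed n_loci")
  assert_that(cfg$within_sd >= 0 && num_ok(cfg$within_sd), "within_sd must be >= 0")
  for (tc in cfg$trait_config) {
    v <- unlist(tc)
    assert_that(num_ok(v) && all(v >= 0), "trait variance components must be >= 0 and finite")
  }
  invisible(cfg)
}

#' Default trait generating variances
#'
#' Three traits at the magnitudes of the study's single-site (Lincoln)
#' across-year analyses: biomass (score), growth habit (score) and leaf size
#' (score). Components not reported there (replicate, row, column) default
#' to small positive values so the design terms are exercised.
#'
#' @export
default_trait_config <- function() {
  list(
    biomass      = list(sigma_p = 1.12, sigma_ps = 0.24, sigma_py = 0.19,
                        sigma_pl = 0.26, sigma_b = 0.05, sigma_row = 0.05,
                        sigma_col = 0.05, sigma_e = 1.80),
    growth_habit = list(sigma_p = 0.20, sigma_ps = 0.02, sigma_py = 0.02,
                        sigma_pl = 0.03, sigma_b = 0.01, sigma_row = 0.01,
                        sigma_col = 0.01, sigma_e = 0.29),
    leaf_size    = list(sigma_p = 0.40, sigma_ps = 0.06, sigma_py = 0.03,
                        sigma_pl = 0.02, sigma_b = 0.01, sigma_row = 0.01,
                        sigma_col = 0.01, sigma_e = 0.42)
  )
}
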