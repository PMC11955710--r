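#' Simulate drift-structured population allele frequencies
#'
#' Balding-Nichols model: per locus an ancestral frequency is drawn
#' Uniform(0.05, 0.95); each cluster draws its frequency from
#' Beta(p(1-F)/F, (1-p)(1-F)/F) with F the cluster drift parameter, so the
#' expected Hudson FST between clusters is close to F; populations perturb
#' their cluster frequency by independent Gaussian noise on the frequency
#' scale, clipped to \[0, 1\].
#'
#' @param config a [sim_config()].
#' @return an `afm` of true frequencies with attributes `cluster`
#'   (integer cluster id per population) and `ancestral` (per-locus p).
#' @export
simulate_population_frequencies <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "freqs"))
  L <- config$n_loci
  n_pop <- sum(config$pops_per_cluster)
  Fst <- rep_len(config$cluster_fst, config$n_clusters)
  anc <- runif(L, 0.05, 0.95)

  cl_freq <- matrix(NA_real_, config$n_clusters, L)
  for (k in seq_len(config$n_clusters)) {
    Fk <- Fst[k]
    cl_freq[k, ] <- rbeta(L, anc * (1 - Fk) / Fk, (1 - anc) * (1 - Fk) / Fk)
  }
  cluster_of <- rep(seq_len(config$n_clusters), times = config$pops_per_cluster)
  vals <- cl_freq[cluster_of, , drop = FALSE] +
    matrix(rnorm(n_pop * L, sd = config$within_sd), n_pop, L)
  vals <- pmin(pmax(vals, 0), 1)
  rownames(vals) <- sprintf("POP%03d", seq_len(n_pop))

  # loci spread over 7 chromosomes at fixed spacing
  chrom <- sprintf("chr%d", 1L + (seq_len(L) - 1L) %% 7L)
  pos <- integer(L)
  for (cc in unique(chrom)) pos[chrom == cc] <- seq_len(sum(chrom == cc)) * 1500L
  loci <- data.frame(locus = sprintf("snp%05d", seq_len(L)),
                     chrom = chrom, pos = pos, ref = "A", alt = "T",
                     stringsAsFactors = FALSE)
  ord <- order(loci$chrom, loci$pos)
  loci <- loci[ord, ]; vals <- vals[, ord, drop = FALSE]
  colnames(vals) <- loci$locus
  out <- afm(vals, loci, provenance = "true")
  attr(out, "cluster") <- stats::setNames(cluster_of, rownames(vals))
  attr(out, "ancestral") <- anc[ord]
  attr(out, "cluster_freq") <- cl_freq[, ord, drop = FALSE]
  out
}

#' Simulate pooled sequencing read counts
#'
#' Each bulk pools `pool_size` diploid individuals: the realised bulk allele
#' frequency is Binomial(2 * pool_size, p) / (2 * pool_size). Each technical
#' replicate then draws a Poisson depth and Binomial alt reads at the bulk
#' frequency. Optional dropout zeroes all replicates of a (population,
#' locus) cell to emulate missing GBS calls.
#'
#' @param true_freqs `afm` of true population frequencies.
#' @param config a [sim_config()].
#' @return a `data.table` with columns population, locus, replicate,
#'   alt_count, ref_count (the pool count table).
#' @export
simulate_pool_counts <- function(true_freqs, config) {
  validate_sim_config(config)
  p <- true_freqs$values
  assert_that(all(p >= 0 & p <= 1), "true frequencies must lie in [0, 1]")
  set.seed(stage_seed(config$seed, "counts"))
  n_pop <- nrow(p); L <- ncol(p); R <- config$n_tech_reps
  n2 <- 2L * config$pool_size

  bulk <- matrix(rbinom(n_pop * L, n2, p) / n2, n_pop, L)
  drop <- matrix(runif(n_pop * L) < config$missing_rate, n_pop, L)

  cells <- n_pop * L
  reps <- lapply(seq_len(R), function(r) {
    depth <- rpois(cells, config$mean_depth)
    depth[as.vector(drop)] <- 0L
    alt <- rbinom(cells, depth, as.vector(bulk))
    data.table::data.table(
      population = rep(rownames(p), times = L),
      locus = rep(colnames(p), each = n_pop),
      replicate = r, alt_count = alt, ref_count = depth - alt)
  })
  out <- data.table::rbindlist(reps)
  data.table::setkey(out, population, locus, replicate)
  out[]
}

#' Simulate bioclimatic variables and plant adaptive loci
#'
#' Bioclim variables get cluster-level means plus population noise so that
#' climate is correlated with the genetic geography. A stated set of
#' variable pairs is made collinear (|r| >= 0.85) to exercise pruning.
#' For each adaptive locus, the population frequencies are overwritten as
#' inverse-logit(intercept + slope * z(driver variable)), producing strong
#' frequency-environment correlation.
#'
#' @param true_freqs `afm` from [simulate_population_frequencies()].
#' @param config a [sim_config()].
#' @return list with `bioclim` (data.frame population x Bio1..Bio_n),
#'   `adaptive` (data.frame locus, driver variable), and `freqs` (the
#'   modified `afm`).
#' @export
simulate_bioclim_and_adaptive <- function(true_freqs, config) {
  validate_sim_config(config)
  assert_that(config$n_adaptive <= config$n_loci, "n_adaptive cannot exceed n_loci")
  set.seed(stage_seed(config$seed, "bioclim"))
  cluster_of <- attr(true_freqs, "cluster")
  n_pop <- nrow(true_freqs$values)
  B <- config$n_bioclim

  # independent core variables with a decaying gradient spectrum: the
  # study's constrained ordination concentrates in the leading axes (RDA1+2
  # explain two thirds of the climate-aligned variation), so the first
  # three cores carry markedly stronger cluster-level separation
  n_base <- min(max(4L, 7L), B)
  core_sd <- c(3, 3, 3, rep(1, max(n_base - 3L, 0)))[seq_len(n_base)]
  base <- sapply(seq_len(n_base), function(j) {
    mu <- rnorm(config$n_clusters, sd = core_sd[j])
    mu[cluster_of] + rnorm(n_pop, sd = 1)
  })
  bio <- matrix(NA_real_, n_pop, B)
  bio[, seq_len(min(n_base, B))] <- base[, seq_len(min(n_base, B))]
  # remaining variables are collinear copies of a base variable (r >= 0.85)
  if (B > n_base) {
    for (j in (n_base + 1L):B) {
      src <- ((j - n_base - 1L) %% n_base) + 1L
      bio[, j] <- base[, src] + rnorm(n_pop, sd = 0.25 * stats::sd(base[, src]))
    }
  }
  colnames(bio) <- sprintf("Bio%d", seq_len(B))
  bioclim <- data.frame(population = rownames(true_freqs$values), bio,
                        stringsAsFactors = FALSE)

  # plant adaptive loci; drivers are drawn from the three dominant core
  # variables at the proportions of the study's candidate split across its
  # three associated variables (69 : 9 : 44)
  vals <- true_freqs$values
  adaptive_idx <- sort(sample.int(config$n_loci, config$n_adaptive))
  n_driver <- min(3L, n_base)
  drivers <- sprintf("Bio%d", sample.int(n_driver, config$n_adaptive,
                                         replace = TRUE,
                                         prob = c(69, 9, 44)[seq_len(n_driver)]))
  anc <- attr(true_freqs, "ancestral")
  for (i in seq_along(adaptive_idx)) {
    l <- adaptive_idx[i]
    z <- scale(bio[, drivers[i]])[, 1]
    # environmental cline added on the logit scale on top of the locus's
    # drift background, so slope 0 leaves the locus exactly as generated
    eta <- qlogis(pmin(pmax(vals[, l], 0.02), 0.98)) +
      config$adaptive_slope * z
    vals[, l] <- plogis(eta)
  }
  freqs <- afm(vals, true_freqs$loci, provenance = "true")
  attr(freqs, "cluster") <- cluster_of
  attr(freqs, "ancestral") <- anc
  list(bioclim = bioclim,
       adaptive = data.frame(locus = colnames(vals)[adaptive_idx],
                             driver = drivers, stringsAsFactors = FALSE),
       freqs = freqs)
}

#' Simulate plot-level phenotypes from the trial mixed model
#'
#' Generates a complete balanced row-column layout (locations x years x
#' seasons x replicates, populations randomised to row-column cells within
#' replicate) and draws each trait from the generating mixed model:
#' population effects MVN(0, G sigma2_p), independent Gaussian interaction
#' effects (population x season / year / location), design effects
#' (replicate, row, column), fixed year/location/season effects, and a
#' Gaussian residual.
#'
#' @param G population x population relationship matrix (symmetric PSD
#'   within 1e-8) whose row names are the population ids.
#' @param config a [sim_config()].
#' @return `data.table` with columns population, location, year, season,
#'   replicate, row, column and one column per trait; attribute `truth`
#'   carries the generating effects.
#' @export
simulate_phenotypes <- function(G, config) {
  validate_sim_config(config)
  assert_that(is.matrix(G) && nrow(G) == ncol(G), "G must be square")
  assert_that(max(abs(G - t(G))) < 1e-8, "G must be symmetric within 1e-8")
  G <- (G + t(G)) / 2
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  assert_that(min(ev) > -1e-8 * max(abs(ev)), "G must be positive semi-definite")
  pops <- rownames(G) %||% sprintf("POP%03d", seq_len(nrow(G)))

  set.seed(stage_seed(config$seed, "phenotypes"))
  d <- config$design
  layout <- data.table::CJ(population = pops,
                           location = d$locations,
                           year = sprintf("Y%d", seq_len(d$years)),
                           season = d$seasons,
                           replicate = sprintf("R%d", seq_len(d$reps)))
  # randomise populations to row-column cells within each rep block
  layout[, cell := {
    n <- .N
    idx <- sample.int(n)
    idx
  }, by = .(location, year, season, replicate)]
  layout[, row := sprintf("row%02d", 1L + (cell - 1L) %/% d$n_cols)]
  layout[, column := sprintf("col%02d", 1L + (cell - 1L) %% d$n_cols)]
  layout[, cell := NULL]

  # matrix square root of G for correlated population effects
  es <- eigen(G, symmetric = TRUE)
  Lh <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), nrow(G))

  truth <- list()
  for (trait in names(config$trait_config)) {
    tc <- config$trait_config[[trait]]
    u_p <- as.vector(Lh %*% rnorm(nrow(G))) * sqrt(tc$sigma_p)
    names(u_p) <- pops
    eff <- function(keys, s2) {
      u <- rnorm(length(keys)) * sqrt(s2)
      stats::setNames(u, keys)
    }
    ps <- eff(unique(layout[, paste(population, season)]), tc$sigma_ps)
    py <- eff(unique(layout[, paste(population, year)]), tc$sigma_py)
    pl <- eff(unique(layout[, paste(population, location)]), tc$sigma_pl)
    bk <- eff(unique(layout[, paste(location, year, season, replicate)]), tc$sigma_b)
    rw <- eff(unique(layout[, paste(location, year, season, replicate, row)]),
              tc$sigma_row)
    cl <- eff(unique(layout[, paste(location, year, season, replicate, column)]),
              tc$sigma_col)
    fx_year <- stats::setNames(seq_len(d$years) * 0.5, sprintf("Y%d", seq_len(d$years)))
    fx_loc <- stats::setNames(seq_along(d$locations) * 0.8, d$locations)
    fx_sea <- stats::setNames(seq_along(d$seasons) * 0.3, d$seasons)
    y <- 5 + fx_year[layout$year] + fx_loc[layout$location] + fx_sea[layout$season] +
      u_p[layout$population] +
      ps[layout[, paste(population, season)]] +
      py[layout[, paste(population, year)]] +
      pl[layout[, paste(population, location)]] +
      bk[layout[, paste(location, year, season, replicate)]] +
      rw[layout[, paste(location, year, season, replicate, row)]] +
      cl[layout[, paste(location, year, season, replicate, column)]] +
      rnorm(nrow(layout)) * sqrt(tc$sigma_e)
    layout[, (trait) := as.numeric(y)]
    truth[[trait]] <- list(u_p = u_p)
  }
  out <- layout[]
  data.table::setattr(out, "truth", truth)
  out
}

#' Simulate a pedigree and gene models
#'
#' Pedigree: all populations as founders plus an optional small crossed
#' cohort (two F1s and a selfed individual) so the numerator-relationship
#' recursion is exercised. Gene models: GFF3-style gene records positioned
#' so that fixture SNPs fall within genes, at 2,999 / 3,001 bp flanks, and
#' intergenic.
#'
#' @param config a [sim_config()].
#' @param crossed include the small crossed cohort (default TRUE).
#' @return list with `pedigree` (data.frame id, sire, dam) and `genes`
#'   (data.frame chrom, start, end, strand, gene_id).
#' @export
simulate_pedigree_and_gff <- function(config, crossed = TRUE) {
  validate_sim_config(config)
  n_pop <- sum(config$pops_per_cluster)
  ids <- sprintf("POP%03d", seq_len(n_pop))
  ped <- data.frame(id = ids, sire = NA_character_, dam = NA_character_,
                    stringsAsFactors = FALSE)
  if (crossed) {
    ped <- rbind(ped, data.frame(
      id = c("X001", "X002", "S001"),
      sire = c(ids[1], ids[1], "X001"),
      dam = c(ids[2], ids[3], "X001"),
      stringsAsFactors = FALSE))
  }
  genes <- data.frame(
    chrom = c("chr1", "chr1", "chr2", "chr3"),
    start = c(4000L, 20000L, 10000L, 50000L),
    end   = c(6000L, 25000L, 12000L, 55000L),
    strand = c("+", "-", "+", "+"),
    gene_id = c("gene001", "gene002", "gene003", "gene004"),
    stringsAsFactors = FALSE)
  list(pedigree = ped, genes = genes)
}
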