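# Pooled allele-frequency estimation: replicate merging, AAF, the three SNP
# filters, and mean imputation.

#' Alternative allele frequency from pooled read counts
#'
#' AAF = Alt / (Alt + Ref); zero total depth yields `NA` (an absent
#' observation, deliberately distinct from frequency 0).
#'
#' @param alt_count,ref_count non-negative integer read counts (vectorised).
#' @return numeric vector of frequencies in \[0, 1\] with `NA` at zero depth.
#' @export
compute_aaf <- function(alt_count, ref_count) {
  assert_that(all(alt_count >= 0, na.rm = TRUE) && all(ref_count >= 0, na.rm = TRUE),
              "read counts must be non-negative")
  tot <- alt_count + ref_count
  ifelse(tot > 0, alt_count / tot, NA_real_)
}

#' Merge technical replicates by summing read counts
#'
#' Count addition (not averaging of per-replicate frequencies): the merged
#' AAF is the depth-weighted mean of replicate AAFs.
#'
#' @param counts pool count table with columns population, locus, replicate,
#'   alt_count, ref_count.
#' @return `data.table` with one row per (population, locus) and summed
#'   counts.
#' @export
merge_replicates <- function(counts) {
  counts <- data.table::as.data.table(counts)
  if (anyDuplicated(counts[, .(population, locus, replicate)]) > 0L)
    stop("duplicate (population, locus, replicate) keys", call. = FALSE)
  merged <- counts[, .(alt_count = sum(alt_count), ref_count = sum(ref_count)),
                   by = .(population, locus)]
  data.table::setkey(merged, population, locus)
  merged[]
}

#' Pool count table to raw allele-frequency matrix
#'
#' @param merged merged count table (one row per population x locus).
#' @param loci locus metadata data.frame (locus, chrom, pos, ref, alt).
#' @return an `afm` with provenance `"raw"`.
#' @export
counts_to_afm <- function(merged, loci) {
  merged <- data.table::as.data.table(merged)
  merged[, aaf := compute_aaf(alt_count, ref_count)]
  wide <- data.table::dcast(merged, population ~ locus, value.var = "aaf")
  pops <- wide$population
  vals <- as.matrix(wide[, -1])
  rownames(vals) <- pops
  loci <- loci[order(loci$chrom, loci$pos), , drop = FALSE]
  vals <- vals[, loci$locus, drop = FALSE]
  afm(vals, loci, provenance = "raw")
}

#' SNP filter specification
#'
#' The three retention rules applied to a raw frequency matrix: a locus is
#' kept iff (a) it is non-missing in more than `min_sample_coverage` of
#' populations (strict >), (b) its AAF lies strictly inside
#' `per_pop_af_bounds` in at least `min_pops_in_bounds` populations, and
#' (c) its mean AAF over non-missing populations lies strictly inside
#' `mean_af_bounds`.
#'
#' @param min_sample_coverage fraction of populations, default 0.95.
#' @param per_pop_af_bounds open interval, default c(0.05, 0.95).
#' @param min_pops_in_bounds default 10.
#' @param mean_af_bounds open interval, default c(0.05, 0.95).
#' @export
filter_spec <- function(min_sample_coverage = 0.95,
                        per_pop_af_bounds = c(0.05, 0.95),
                        min_pops_in_bounds = 10L,
                        mean_af_bounds = c(0.05, 0.95)) {
  assert_that(min_sample_coverage >= 0 && min_sample_coverage <= 1,
              "min_sample_coverage must be in [0, 1]")
  assert_that(per_pop_af_bounds[1] < per_pop_af_bounds[2] &&
                mean_af_bounds[1] < mean_af_bounds[2],
              "AF bounds must be ordered")
  structure(list(min_sample_coverage = min_sample_coverage,
                 per_pop_af_bounds = per_pop_af_bounds,
                 min_pops_in_bounds = as.integer(min_pops_in_bounds),
                 mean_af_bounds = mean_af_bounds),
            class = "filter_spec")
}

#' Filter SNPs on coverage and frequency rules
#'
#' @param freqs raw `afm`.
#' @param spec a [filter_spec()].
#' @return filtered `afm` (original locus order preserved) with attribute
#'   `filter_report`: per-rule pass counts and the retained total.
#' @export
filter_snps <- function(freqs, spec = filter_spec()) {
  vals <- freqs$values
  assert_that(ncol(vals) > 0 && nrow(vals) > 0, "empty frequency matrix")
  n_pop <- nrow(vals)
  nonmiss <- colSums(!is.na(vals))
  rule_cov <- nonmiss / n_pop > spec$min_sample_coverage
  inb <- vals > spec$per_pop_af_bounds[1] & vals < spec$per_pop_af_bounds[2]
  rule_pop <- colSums(inb, na.rm = TRUE) >= spec$min_pops_in_bounds
  mu <- colMeans(vals, na.rm = TRUE)
  rule_mean <- !is.na(mu) & mu > spec$mean_af_bounds[1] & mu < spec$mean_af_bounds[2]
  keep <- rule_cov & rule_pop & rule_mean
  out <- afm(vals[, keep, drop = FALSE], freqs$loci[keep, , drop = FALSE],
             provenance = "filtered")
  attr(out, "filter_report") <- data.frame(
    rule = c("coverage", "per_pop_bounds", "mean_bounds", "retained"),
    n_pass = c(sum(rule_cov), sum(rule_pop), sum(rule_mean), sum(keep)),
    n_total = ncol(vals))
  for (a in c("cluster", "ancestral", "cluster_freq")) {
    v <- attr(freqs, a)
    if (!is.null(v)) {
      attr(out, a) <- switch(a, ancestral = v[keep],
                             cluster_freq = v[, keep, drop = FALSE], v)
    }
  }
  out
}

#' Impute missing frequencies by the per-locus mean
#'
#' Each missing cell is replaced by the mean AAF over non-missing
#' populations at that locus; non-missing cells are untouched, so per-locus
#' means are preserved.
#'
#' @param freqs filtered `afm`.
#' @return `afm` with provenance `"imputed"` and no missing cells.
#' @export
impute_missing <- function(freqs) {
  vals <- freqs$values
  mu <- colMeans(vals, na.rm = TRUE)
  if (anyNA(mu))
    stop("locus missing in all populations; filter before imputing", call. = FALSE)
  idx <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(idx)) vals[idx] <- mu[idx[, 2]]
  out <- afm(vals, freqs$loci, provenance = "imputed")
  for (a in c("cluster", "ancestral", "cluster_freq"))
    if (!is.null(attr(freqs, a))) attr(out, a) <- attr(freqs, a)
  out
}

#' Read pooled allele depths from a VCF
#'
#' Parses a VCF 4.2 with per-sample AD (ref, alt) via `VariantAnnotation`.
#' Sample columns named `<population>_rep<k>` are split into population and
#' replicate. Multi-allelic sites are skipped with a warning; the study's
#' pipeline analyses biallelic SNPs only.
#'
#' @param path VCF file.
#' @return pool count table (`data.table`) plus attribute `loci`.
#' @export
read_pool_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  nalt <- lengths(VariantAnnotation::alt(vcf))
  if (any(nalt != 1L)) {
    warning(sum(nalt != 1L), " multi-allelic site(s) skipped")
    vcf <- vcf[nalt == 1L]
  }
  ad <- VariantAnnotation::geno(vcf)$AD
  rr <- SummarizedExperiment::rowRanges(vcf)
  loci <- data.frame(
    locus = names(rr),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = vapply(rr$ALT, function(a) as.character(a)[1], ""),
    stringsAsFactors = FALSE)
  samples <- colnames(ad)
  pop <- sub("_rep[0-9]+$", "", samples)
  repl <- as.integer(sub("^.*_rep", "", samples))
  refc <- vapply(seq_along(samples), function(j)
    vapply(ad[, j], `[`, numeric(1), 1L), numeric(nrow(ad)))
  altc <- vapply(seq_along(samples), function(j)
    vapply(ad[, j], `[`, numeric(1), 2L), numeric(nrow(ad)))
  out <- data.table::data.table(
    population = rep(pop, each = nrow(ad)),
    locus = rep(loci$locus, times = length(samples)),
    replicate = rep(repl, each = nrow(ad)),
    ref_count = as.integer(as.vector(refc)),
    alt_count = as.integer(as.vector(altc)))
  data.table::setkey(out, population, locus, replicate)
  data.table::setattr(out, "loci", loci)
  out[]
}

#' Read a pool count table from TSV
#'
#' @param path TSV with columns population, locus, replicate, alt_count,
#'   ref_count.
#' @export
read_pool_counts <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  need <- c("population", "locus", "replicate", "alt_count", "ref_count")
  assert_that(all(need %in% names(dt)),
              paste("count table needs columns:", paste(need, collapse = ", ")))
  data.table::setkey(dt, population, locus, replicate)
  dt[]
}
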