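# Redundancy-analysis landscape genomics: predictor pruning, constrained
# ordination, candidate-SNP detection, association assignment with FDR,
# cluster chi-square tests, and nearest-gene annotation.

#' Prune collinear bioclimatic variables
#'
#' Iteratively, while any pair of retained variables has |Pearson r| >=
#' `threshold`, the member of the worst (highest |r|) pair with the larger
#' mean absolute correlation to all other remaining variables is dropped
#' (ties broken toward the higher Bio index). Zero-variance variables are
#' dropped first with a warning. Deterministic.
#'
#' @param bioclim data.frame with a `population` column and Bio columns, or
#'   a plain numeric matrix.
#' @param threshold correlation threshold, default 0.8.
#' @return character vector of retained variable names (original order).
#' @export
prune_collinear <- function(bioclim, threshold = 0.8) {
  m <- bioclim_matrix(bioclim)
  assert_that(ncol(m) >= 2, "need at least two variables")
  constant <- apply(m, 2, stats::sd) == 0
  if (any(constant)) {
    warning("dropping zero-variance variable(s): ",
            paste(colnames(m)[constant], collapse = ", "))
    m <- m[, !constant, drop = FALSE]
  }
  vars <- colnames(m)
  cc <- abs(stats::cor(m))
  diag(cc) <- 0
  while (length(vars) > 1 && max(cc) >= threshold) {
    worst <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    i <- worst[1]; j <- worst[2]
    mean_i <- mean(cc[i, -c(i, j)])
    mean_j <- mean(cc[j, -c(i, j)])
    drop_idx <- if (isTRUE(mean_i > mean_j)) i
                else if (isTRUE(mean_j > mean_i)) j
                else max(i, j)            # tie: higher Bio index goes
    vars <- vars[-drop_idx]
    cc <- cc[-drop_idx, -drop_idx, drop = FALSE]
    if (length(vars) < 2) break
  }
  vars
}

bioclim_matrix <- function(bioclim) {
  if (is.matrix(bioclim)) return(bioclim)
  cols <- setdiff(names(bioclim), "population")
  m <- as.matrix(bioclim[, cols, drop = FALSE])
  if ("population" %in% names(bioclim)) rownames(m) <- bioclim$population
  m
}

#' Redundancy analysis (constrained ordination)
#'
#' Predictors are z-scored and the response centred (unit-scaled too for
#' trait responses); the multivariate least-squares fitted values are
#' decomposed by SVD. Constrained eigenvalue fractions are squared singular
#' values over the total response inertia; response loadings are the
#' right-singular vectors (unit norm per axis); site scores are the
#' population coordinates on the constrained axes.
#'
#' @param response populations x features numeric matrix (SNP frequencies
#'   or trait values).
#' @param predictors data.frame/matrix of explanatory variables (aligned
#'   rows).
#' @param scale_response z-score the response columns (use for traits;
#'   leave FALSE for allele frequencies).
#' @return object of class `rda_result`: `eig_fraction` (per constrained
#'   axis, as fraction of total inertia), `constrained_proportion`,
#'   `site_scores`, `loadings`, `biplot_scores`, `axes_used`.
#' @export
rda_fit <- function(response, predictors, scale_response = FALSE) {
  Y <- as.matrix(response)
  X <- bioclim_matrix(predictors)
  assert_that(nrow(Y) == nrow(X), "response and predictors must align")
  assert_that(nrow(Y) > ncol(X), "need more populations than predictors")
  assert_that(!anyNA(Y) && !anyNA(X), "missing values not allowed")
  X <- scale(X)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[-seq_len(qrx$rank)]]
    stop("rank-deficient predictors; aliased: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  Yc <- scale(Y, center = TRUE, scale = scale_response)
  if (scale_response) Yc[, attr(Yc, "scaled:scale") == 0] <- 0
  fitted <- qr.fitted(qrx, Yc)
  sv <- svd(fitted)
  total_inertia <- sum(Yc^2)
  pos <- sv$d^2 / total_inertia > 1e-12
  axes_used <- sum(pos)
  d <- sv$d[pos]
  site <- sv$u[, pos, drop = FALSE] %*% diag(d, axes_used)
  rownames(site) <- rownames(Y)
  load <- sv$v[, pos, drop = FALSE]
  rownames(load) <- colnames(Y)
  colnames(site) <- colnames(load) <- sprintf("RDA%d", seq_len(axes_used))
  biplot <- stats::cor(X, site)
  structure(list(eig_fraction = d^2 / total_inertia,
                 constrained_proportion = sum(d^2) / total_inertia,
                 site_scores = site, loadings = load,
                 biplot_scores = biplot, axes_used = axes_used,
                 total_inertia = total_inertia),
            class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("<rda_result> %d constrained axes, %.1f%% of inertia (RDA1 %.1f%%)\n",
              x$axes_used, 100 * x$constrained_proportion,
              100 * x$eig_fraction[1]))
  invisible(x)
}

#' Detect candidate loci from RDA loadings
#'
#' Per axis 1..`n_axes`, loci whose loading lies more than `sd_mult`
#' standard deviations from the mean loading are flagged; the candidate set
#' is the union over axes and each candidate is tagged with the axis of
#' maximal exceedance (in SD units).
#'
#' @param rda `rda_result` computed on a SNP response.
#' @param n_axes axes to scan (default 3).
#' @param sd_mult threshold multiplier (default 3).
#' @return data.frame locus, axis, loading (sorted by locus order).
#' @export
detect_candidates <- function(rda, n_axes = 3L, sd_mult = 3) {
  assert_that(n_axes <= rda$axes_used, "n_axes exceeds available axes")
  L <- rda$loadings
  z <- sapply(seq_len(n_axes), function(a)
    abs(L[, a] - mean(L[, a])) / stats::sd(L[, a]))
  flagged <- z > sd_mult
  any_flag <- rowSums(flagged) > 0
  if (!any(any_flag))
    return(data.frame(locus = character(0), axis = integer(0),
                      loading = numeric(0)))
  best_axis <- apply(z[any_flag, , drop = FALSE], 1, which.max)
  data.frame(locus = rownames(L)[any_flag],
             axis = as.integer(best_axis),
             loading = L[cbind(which(any_flag), best_axis)],
             stringsAsFactors = FALSE)
}

#' Assign the most strongly correlated predictor to each candidate
#'
#' Per candidate SNP, Pearson correlation of its allele frequency against
#' each retained bioclim variable; assignment to the argmax |r| (ties to
#' the lower Bio index), two-sided correlation-test p-values and
#' Benjamini-Hochberg q-values across the candidate set.
#'
#' @param candidates data.frame from [detect_candidates()].
#' @param freqs imputed `afm`.
#' @param bioclim bioclim table restricted to the retained variables (plus
#'   the `population` column).
#' @return candidate table extended with variable, r, p_value, q_value.
#' @export
assign_predictor <- function(candidates, freqs, bioclim) {
  assert_that(nrow(candidates) > 0, "no candidates to assign")
  vals <- if (inherits(freqs, "afm")) freqs$values else freqs
  m <- bioclim_matrix(bioclim)
  if (!is.null(rownames(m)) && !is.null(rownames(vals)))
    m <- m[rownames(vals), , drop = FALSE]
  vars <- colnames(m)
  res <- lapply(candidates$locus, function(l) {
    x <- vals[, l]
    assert_that(stats::sd(x) > 0, paste("zero-variance locus", l))
    rs <- apply(m, 2, function(v) stats::cor(x, v))
    best <- which(abs(rs) == max(abs(rs)))[1]   # ties -> lower Bio index
    ct <- stats::cor.test(x, m[, best])
    data.frame(variable = vars[best], r = unname(rs[best]),
               p_value = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- cbind(candidates, do.call(rbind, res))
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Chi-square test of SNP frequency x cluster independence
#'
#' Per candidate, a cluster x allele contingency table is built from
#' rounded allele counts (2 * pool_size * AAF summed over member
#' populations) and tested for independence without continuity correction;
#' q-values by Benjamini-Hochberg across candidates. Tables with more than
#' 20% of expected cells below 1 are flagged low-reliability.
#'
#' @param candidates candidate data.frame (needs a `locus` column).
#' @param freqs imputed `afm`.
#' @param clusters cluster assignment per population.
#' @param pool_size individuals per bulk (default 30).
#' @return candidate table extended with chisq, chisq_p, chisq_q,
#'   low_reliability.
#' @export
chisq_cluster_association <- function(candidates, freqs, clusters,
                                      pool_size = 30L) {
  vals <- if (inherits(freqs, "afm")) freqs$values else freqs
  clusters <- align_groups(clusters, rownames(vals))
  cl <- sort(unique(clusters))
  assert_that(length(cl) >= 2, "need at least two clusters")
  stat <- p <- numeric(nrow(candidates))
  lowrel <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    x <- vals[, candidates$locus[i]]
    alt <- vapply(cl, function(g)
      round(sum(2 * pool_size * x[clusters == g])), numeric(1))
    tot <- vapply(cl, function(g)
      2 * pool_size * sum(clusters == g), numeric(1))
    tab <- cbind(alt = alt, ref = tot - alt)
    suppressWarnings(ct <- stats::chisq.test(tab, correct = FALSE))
    stat[i] <- unname(ct$statistic)
    p[i] <- ct$p.value
    lowrel[i] <- mean(ct$expected < 1) > 0.2
  }
  out <- candidates
  out$chisq <- stat
  out$chisq_p <- p
  out$chisq_q <- stats::p.adjust(p, method = "BH")
  out$low_reliability <- lowrel
  out
}

#' Nearest-gene annotation within a flanking window
#'
#' A SNP inside \[gene start, gene end\] is "within" (distance 0);
#' otherwise the nearest gene on the same chromosome whose nearer boundary
#' lies within `window` bp is assigned, with the relation upstream /
#' downstream defined relative to gene strand (5' flank = upstream) unless
#' `strand_aware = FALSE`. Ties go to the smaller distance, then the lower
#' gene start. SNPs on chromosomes absent from the annotation get no gene.
#'
#' @param candidates data.frame with a `locus` column.
#' @param loci locus metadata (locus, chrom, pos).
#' @param genes gene models: data.frame (chrom, start, end, strand,
#'   gene_id) or a GFF3 file path read via [read_gene_models()].
#' @param window flank size in bp (default 3000).
#' @param strand_aware use gene strand for upstream/downstream (default
#'   TRUE).
#' @return candidate table extended with gene, relation (within / upstream
#'   / downstream / none), distance.
#' @export
nearest_gene <- function(candidates, loci, genes, window = 3000L,
                         strand_aware = TRUE) {
  if (is.character(genes) && length(genes) == 1L) genes <- read_gene_models(genes)
  gene <- rel <- rep(NA_character_, nrow(candidates))
  dist <- rep(NA_real_, nrow(candidates))
  li <- loci[match(candidates$locus, loci$locus), ]
  for (i in seq_len(nrow(candidates))) {
    g <- genes[genes$chrom == li$chrom[i], , drop = FALSE]
    if (!nrow(g)) { rel[i] <- "none"; next }
    pos <- li$pos[i]
    d <- pmax(0, g$start - pos, pos - g$end)
    inside <- pos >= g$start & pos <= g$end
    d[inside] <- 0
    ok <- d <= window
    if (!any(ok)) { rel[i] <- "none"; next }
    cand <- which(ok)
    cand <- cand[order(d[cand], g$start[cand])]
    j <- cand[1]
    gene[i] <- g$gene_id[j]
    dist[i] <- d[j]
    if (inside[j]) {
      rel[i] <- "within"
    } else {
      before <- pos < g$start[j]
      plus <- !strand_aware || g$strand[j] != "-"
      rel[i] <- if (before == plus) "upstream" else "downstream"
    }
  }
  out <- candidates
  out$gene <- gene
  out$relation <- rel
  out$distance <- dist
  out
}

#' Read gene models from GFF3
#'
#' Imports via `rtracklayer` and keeps `type == "gene"` records as a plain
#' data.frame (chrom, start, end, strand, gene_id), 1-based inclusive.
#'
#' @param path GFF3 file.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  id <- gr$ID %||% gr$Name
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             gene_id = as.character(id),
             stringsAsFactors = FALSE)
}

#' Full genotype-environment association scan
#'
#' Convenience wrapper: prune predictors, run the SNP RDA, detect
#' candidates at the SD threshold, assign predictors with FDR, test
#' cluster association, and annotate nearest genes when gene models are
#' supplied.
#'
#' @param freqs imputed `afm`.
#' @param bioclim full bioclim table.
#' @param clusters cluster assignment.
#' @param genes optional gene models (data.frame or GFF3 path).
#' @param threshold collinearity threshold (default 0.8).
#' @param n_axes,sd_mult candidate detection settings.
#' @param pool_size bulk size for the chi-square counts.
#' @return list with `retained_variables`, `rda`, `candidates`.
#' @export
gea_scan <- function(freqs, bioclim, clusters, genes = NULL, threshold = 0.8,
                     n_axes = 3L, sd_mult = 3, pool_size = 30L) {
  retained <- prune_collinear(bioclim, threshold = threshold)
  keep <- c(intersect(names(bioclim), "population"), retained)
  bc <- bioclim[, keep, drop = FALSE]
  rda <- rda_fit(freqs$values, bc)
  cand <- detect_candidates(rda, n_axes = min(n_axes, rda$axes_used),
                            sd_mult = sd_mult)
  if (nrow(cand)) {
    cand <- assign_predictor(cand, freqs, bc)
    cand <- chisq_cluster_association(cand, freqs, clusters,
                                      pool_size = pool_size)
    if (!is.null(genes)) cand <- nearest_gene(cand, freqs$loci, genes)
  }
  list(retained_variables = retained, rda = rda, candidates = cand)
}
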