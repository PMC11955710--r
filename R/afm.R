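#' Allele-frequency matrix
#'
#' The central container of the pipeline: a populations x loci matrix of
#' alternative allele frequencies (AAF) in \[0, 1\], with `NA` marking
#' missing calls (zero sequencing depth). Locus metadata (chromosome,
#' 1-based position, ref/alt alleles) travels with the matrix, as does a
#' provenance flag recording how far through the frequency pipeline the
#' object has come.
#'
#' @param values numeric matrix, populations in rows, loci in columns.
#'   Row names are population ids, column names locus ids.
#' @param loci data.frame with one row per locus: columns `locus`, `chrom`,
#'   `pos` (1-based), `ref`, `alt`. Optional; a minimal frame is synthesised
#'   from column names when absent.
#' @param provenance one of `"true"`, `"raw"`, `"filtered"`, `"imputed"`.
#'
#' @return an object of class `afm`.
#' @export
afm <- function(values, loci = NULL, provenance = "raw") {
  assert_that(is.matrix(values) && is.numeric(values),
              "`values` must be a numeric matrix (populations x loci)")
  assert_that(nrow(values) > 0 && ncol(values) > 0, "empty frequency matrix")
  provenance <- match.arg(provenance, c("true", "raw", "filtered", "imputed"))
  rng <- range(values, na.rm = TRUE)
  assert_that(rng[1] >= 0 && rng[2] <= 1,
              "allele frequencies must lie in [0, 1]")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("POP%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("snp%05d", seq_len(ncol(values)))
  if (is.null(loci)) {
    loci <- data.frame(locus = colnames(values),
                       chrom = "chr1",
                       pos   = seq_len(ncol(values)),
                       ref   = "A", alt = "T",
                       stringsAsFactors = FALSE)
  }
  assert_that(nrow(loci) == ncol(values),
              "`loci` must have one row per matrix column")
  assert_that(all(c("locus", "chrom", "pos") %in% names(loci)),
              "`loci` needs columns locus, chrom, pos")
  # positions must be strictly increasing within each chromosome
  ok <- tapply(loci$pos, loci$chrom, function(p) all(diff(p) > 0))
  assert_that(all(unlist(ok)), "locus positions must strictly increase within chromosome")
  if (provenance == "imputed")
    assert_that(!anyNA(values), "an imputed matrix cannot contain missing values")
  structure(list(values = values, loci = loci, provenance = provenance),
            class = "afm")
}

#' @export
print.afm <- function(x, ...) {
  cat(sprintf("<afm> %d populations x %d loci (%s), %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$provenance,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.afm <- function(x) dim(x$values)

#' @rdname afm
#' @param x an `afm` object.
#' @export
populations <- function(x) rownames(x$values)

#' @rdname afm
#' @export
loci_info <- function(x) x$loci

#' Write / read a frequency matrix as TSV
#'
#' Loci as rows, populations as columns, preceded by the locus metadata
#' columns; the layout downstream stages and external tools read back.
#'
#' @param x an `afm` object.
#' @param path output file.
#' @export
write_afm_tsv <- function(x, path) {
  dt <- data.table::as.data.table(x$loci)
  dt <- cbind(dt, data.table::as.data.table(t(x$values)))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_afm_tsv
#' @param provenance provenance flag to stamp on the object read back.
#' @export
read_afm_tsv <- function(path, provenance = "raw") {
  dt <- data.table::fread(path, sep = "\t")
  meta_cols <- intersect(c("locus", "chrom", "pos", "ref", "alt"), names(dt))
  loci <- as.data.frame(dt[, meta_cols, with = FALSE])
  vals <- t(as.matrix(dt[, setdiff(names(dt), meta_cols), with = FALSE]))
  colnames(vals) <- loci$locus
  afm(vals, loci, provenance = provenance)
}
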