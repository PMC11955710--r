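# Genomic and pedigree relationship matrices.

#' VanRaden genomic relationship matrix from pooled frequencies
#'
#' Population dosages M = 2 * AAF in \[0, 2\] are recoded to Z = M - 1 in
#' \[-1, 1\], centred by locus means, and
#' G = Zc Zc' / (2 * sum_l pbar_l (1 - pbar_l)) with pbar_l the mean AAF
#' across populations (VanRaden method 1 adapted to population-level
#' dosages). Monomorphic loci (pbar in \{0, 1\}) are dropped with a warning.
#'
#' @param freqs imputed `afm`.
#' @param denom `"observed"` (mean observed frequencies, default) or
#'   `"half"` (reference 0.5 frequencies in the denominator).
#' @param ridge value added to the diagonal to guarantee invertibility in
#'   downstream mixed models (default 1e-8).
#' @return list of class `relationship_matrix` with `values`, `ids`,
#'   `kind = "genomic"`.
#' @export
build_gmatrix <- function(freqs, denom = c("observed", "half"), ridge = 1e-8) {
  denom <- match.arg(denom)
  vals <- if (inherits(freqs, "afm")) freqs$values else freqs
  assert_that(!anyNA(vals), "G-matrix requires a complete matrix")
  pbar <- colMeans(vals)
  mono <- pbar <= 0 | pbar >= 1
  if (any(mono)) {
    warning(sum(mono), " monomorphic locus/loci dropped from G")
    vals <- vals[, !mono, drop = FALSE]
    pbar <- pbar[!mono]
  }
  assert_that(ncol(vals) >= 2, "need >= 2 polymorphic loci")
  Z <- 2 * vals - 1
  Zc <- sweep(Z, 2, colMeans(Z))
  den <- if (denom == "observed") 2 * sum(pbar * (1 - pbar)) else 0.5 * ncol(vals)
  G <- tcrossprod(Zc) / den
  G <- (G + t(G)) / 2 + diag(ridge, nrow(G))
  structure(list(values = G, ids = rownames(vals), kind = "genomic"),
            class = "relationship_matrix")
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' A(i,i) = 1 + 0.5 A(sire_i, dam_i); A(i,j) = 0.5 \[A(j, sire_i) +
#' A(j, dam_i)\] with unknown parents contributing 0. Ids referenced as
#' parents without their own pedigree row become implicit founders (with a
#' message); cycles are rejected.
#'
#' @param ped data.frame with columns id, sire, dam (`NA`/`""`/`"0"` =
#'   unknown parent).
#' @return `relationship_matrix` of kind `"pedigree"` (diagonal 1 + F).
#' @export
build_amatrix <- function(ped) {
  ped <- normalize_pedigree(ped)
  ids <- ped$id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    A[i, i] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        a <- 0.5 * ((if (s > 0) A[j, s] else 0) + (if (d > 0) A[j, d] else 0))
        A[i, j] <- A[j, i] <- a
      }
    }
  }
  structure(list(values = A, ids = ids, kind = "pedigree"),
            class = "relationship_matrix")
}

#' Pedigree inbreeding coefficients
#'
#' F_i = 0.5 A(sire_i, dam_i); founders have F = 0.
#'
#' @param ped pedigree data.frame (id, sire, dam).
#' @return named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(ped) {
  A <- build_amatrix(ped)
  diag(A$values) - 1
}

# topological sort + implicit founders + cycle detection
normalize_pedigree <- function(ped) {
  assert_that(all(c("id", "sire", "dam") %in% names(ped)),
              "pedigree needs columns id, sire, dam")
  clean <- function(x) {
    x <- as.character(x)
    x[x %in% c("", "0", "NA", "unknown")] <- NA_character_
    x
  }
  ped <- data.frame(id = as.character(ped$id), sire = clean(ped$sire),
                    dam = clean(ped$dam), stringsAsFactors = FALSE)
  assert_that(!anyDuplicated(ped$id), "duplicate pedigree ids")
  parents <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$id)
  if (length(parents)) {
    message(length(parents), " parent id(s) without a pedigree row treated as founders")
    ped <- rbind(data.frame(id = parents, sire = NA_character_,
                            dam = NA_character_, stringsAsFactors = FALSE), ped)
  }
  # Kahn's algorithm: parents must precede offspring
  ordered <- character(0)
  placed <- character(0)
  remaining <- ped
  while (nrow(remaining)) {
    ready <- with(remaining, (is.na(sire) | sire %in% placed) &
                    (is.na(dam) | dam %in% placed))
    if (!any(ready)) stop("pedigree contains a cycle", call. = FALSE)
    ordered <- c(ordered, remaining$id[ready])
    placed <- ordered
    remaining <- remaining[!ready, , drop = FALSE]
  }
  ped[match(ordered, ped$id), , drop = FALSE]
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("<relationship_matrix> %s, %d ids, mean diag %.3f\n",
              x$kind, length(x$ids), mean(diag(x$values))))
  invisible(x)
}

#' Write / read a relationship matrix as TSV with an id header
#'
#' @param x a `relationship_matrix`.
#' @param path file path.
#' @export
write_relationship_tsv <- function(x, path) {
  dt <- data.table::data.table(id = x$ids)
  dt <- cbind(dt, data.table::as.data.table(x$values))
  data.table::setnames(dt, c("id", x$ids))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_relationship_tsv
#' @param kind `"genomic"` or `"pedigree"`.
#' @export
read_relationship_tsv <- function(path, kind = "genomic") {
  dt <- data.table::fread(path, sep = "\t")
  ids <- dt$id
  vals <- as.matrix(dt[, -1])
  dimnames(vals) <- list(ids, ids)
  structure(list(values = vals, ids = ids, kind = kind),
            class = "relationship_matrix")
}
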