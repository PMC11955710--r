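# Writers for the synthetic fixtures: plain-text standard formats that the
# ingestion side of the pipeline (and external tools) can read back.

#' Write a pool count table as a VCF 4.2 file
#'
#' One sample column per population x technical replicate (named
#' `<population>_rep<k>`), FORMAT fields AD (alt-first not used: AD is
#' ref,alt per VCF convention) and DP. Biallelic SNP records only.
#'
#' @param counts pool count table (population, locus, replicate, alt_count,
#'   ref_count) as from [simulate_pool_counts()].
#' @param loci locus metadata data.frame (locus, chrom, pos, ref, alt).
#' @param path output path (uncompressed `.vcf`).
#' @export
write_pool_vcf <- function(counts, loci, path) {
  counts <- data.table::as.data.table(counts)
  samples <- counts[, unique(paste0(population, "_rep", replicate))]
  counts[, sample := paste0(population, "_rep", replicate)]
  wide_ad <- data.table::dcast(counts, locus ~ sample,
                               value.var = c("ref_count", "alt_count"))
  data.table::setkey(wide_ad, locus)
  loci_dt <- data.table::as.data.table(loci)
  data.table::setkey(loci_dt, locus)
  wide_ad <- loci_dt[wide_ad]
  data.table::setorder(wide_ad, chrom, pos)

  hdr <- c("##fileformat=VCFv4.2",
           "##source=poolscape-simulate",
           paste0("##contig=<ID=", unique(loci$chrom), ">"),
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  fmt_cols <- vapply(samples, function(s) {
    rc <- wide_ad[[paste0("ref_count_", s)]]
    ac <- wide_ad[[paste0("alt_count_", s)]]
    paste0(rc, ",", ac, ":", rc + ac)
  }, character(nrow(wide_ad)))
  body <- paste(wide_ad$chrom, wide_ad$pos, wide_ad$locus, wide_ad$ref,
                wide_ad$alt, ".", "PASS", ".", "AD:DP",
                apply(fmt_cols, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' @param genes data.frame chrom, start, end, strand, gene_id.
#' @param path output path.
#' @export
write_genes_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand,
    type = "gene", ID = genes$gene_id, Name = genes$gene_id)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Generate and write the full synthetic fixture set
#'
#' Runs every generator under the config's seed and writes: pooled VCF and
#' TSV count table, true-frequency TSV, phenotype CSV, bioclim CSV,
#' pedigree CSV, GFF3 gene models and a JSON run manifest.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list of generated objects and file paths.
#' @export
simulate_study <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  freqs0 <- simulate_population_frequencies(config)
  ba <- simulate_bioclim_and_adaptive(freqs0, config)
  counts <- simulate_pool_counts(ba$freqs, config)
  G <- build_gmatrix(ba$freqs)
  phen <- simulate_phenotypes(G$values, config)
  pg <- simulate_pedigree_and_gff(config)

  paths <- list(
    vcf = file.path(out_dir, "pool_counts.vcf"),
    counts = file.path(out_dir, "pool_counts.tsv"),
    true_freqs = file.path(out_dir, "true_freqs.tsv"),
    phenotypes = file.path(out_dir, "phenotypes.csv"),
    bioclim = file.path(out_dir, "bioclim.csv"),
    pedigree = file.path(out_dir, "pedigree.csv"),
    gff = file.path(out_dir, "genes.gff3"),
    clusters = file.path(out_dir, "clusters.csv"),
    adaptive = file.path(out_dir, "adaptive_loci.csv"),
    manifest = file.path(out_dir, "manifest.json"))

  write_pool_vcf(counts, ba$freqs$loci, paths$vcf)
  data.table::fwrite(counts, paths$counts, sep = "\t")
  write_afm_tsv(ba$freqs, paths$true_freqs)
  data.table::fwrite(phen, paths$phenotypes)
  data.table::fwrite(ba$bioclim, paths$bioclim)
  data.table::fwrite(pg$pedigree, paths$pedigree)
  write_genes_gff3(pg$genes, paths$gff)
  data.table::fwrite(data.frame(population = populations(freqs0),
                                cluster = as.integer(attr(freqs0, "cluster"))),
                     paths$clusters)
  data.table::fwrite(ba$adaptive, paths$adaptive)

  manifest <- list(
    seed = config$seed,
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    n_populations = sum(config$pops_per_cluster),
    n_clusters = config$n_clusters,
    n_loci = config$n_loci,
    n_adaptive = config$n_adaptive,
    files = lapply(paths, basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(config = config, freqs = ba$freqs, bioclim = ba$bioclim,
                 adaptive = ba$adaptive, counts = counts, G = G,
                 phenotypes = phen, pedigree = pg$pedigree, genes = pg$genes,
                 paths = paths))
}
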