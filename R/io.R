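# TSV/JSON writers. Every tabular output carries '# key: value' header
# comments recording provenance (package version, config hash).

.write_tsv <- function(df, path, meta = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (length(meta))
    writeLines(paste0("# ", names(meta), ": ", unlist(meta)), con)
  close(con); on.exit()
  fwrite(as.data.frame(df), path, sep = "\t", append = length(meta) > 0,
         col.names = TRUE)
  invisible(path)
}

#' Write the TA-site table
#'
#' @param index A `tn_ta_index`.
#' @param path Output TSV path.
#' @param meta Optional named list written as `# key: value` header lines.
#' @return The path, invisibly.
#' @export
write_ta_sites <- function(index, path, meta = NULL) {
  .write_tsv(index[, .(replicon, pos, duplicated)], path, meta)
}

#' Write per-gene TA profiles (with exclusion flags if present)
#' @param profiles Output of [gene_ta_profile] or [apply_gene_filters].
#' @inheritParams write_ta_sites
#' @export
write_gene_ta_profile <- function(profiles, path, meta = NULL) {
  .write_tsv(profiles, path, meta)
}

#' Write heme-motif hits
#' @param hits Output of [scan_heme_motifs].
#' @inheritParams write_ta_sites
#' @export
write_motif_hits <- function(hits, path, meta = NULL) {
  .write_tsv(hits, path, meta)
}

#' Write a per-site insertion table
#' @param ins_table A `tn_insertion_table`.
#' @inheritParams write_ta_sites
#' @export
write_insertion_table <- function(ins_table, path, meta = NULL) {
  .write_tsv(ins_table$sites, path,
             c(meta, ins_table$totals))
}

#' Write per-gene counts
#' @param counts A `tn_gene_counts`.
#' @inheritParams write_ta_sites
#' @export
write_gene_counts <- function(counts, path, meta = NULL) {
  .write_tsv(counts, path, meta)
}

#' Write essentiality calls
#' @param calls A `tn_calls`.
#' @inheritParams write_ta_sites
#' @export
write_calls <- function(calls, path, meta = NULL) {
  .write_tsv(calls, path, meta)
}

#' Write accepted inserts as TSV
#' @param inserts data.table from [process_fastq].
#' @inheritParams write_ta_sites
#' @export
write_inserts <- function(inserts, path, meta = NULL) {
  .write_tsv(inserts, path, meta)
}

#' Write a genome as FASTA
#' @param genome A [tn_genome].
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "tn_genome"))
  dss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Write a gene table as GFF3
#'
#' Converts the package's 0-based half-open intervals back to GFF3 1-based
#' inclusive coordinates.
#'
#' @param genes Gene table (as from [load_annotation]).
#' @param path Output path.
#' @export
write_genes_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$replicon_id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$source <- "tnseqr"
  gr$ID <- genes$gene_id
  gr$product <- genes$product
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write an UpSet-style membership table
#' @param membership Output of [membership_matrix].
#' @inheritParams write_ta_sites
#' @export
write_membership <- function(membership, path, meta = NULL) {
  m <- membership
  m$genes <- vapply(m$genes, paste, character(1), collapse = ",")
  .write_tsv(m, path, meta)
}
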