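# Per-gene read tabulation under the first-95%-of-gene rule, gene exclusion
# filters, and RpK normalization to 10^7 uniquely mapped reads per library.

#' Assign gene exclusion categories from TA-site profiles
#'
#' Genes that cannot be scored are excluded, with precedence:
#' `no_ta` (no TA sites at all) > `no_ta_first95` (no TA sites outside the
#' last 5% of the gene) > `under_half_unique` (strictly fewer than half of
#' the gene's TA sites are unique; exactly half passes). All other genes are
#' `none`.
#'
#' @param profiles Output of [gene_ta_profile].
#' @return `profiles` with an `excluded` character column added.
#' @export
apply_gene_filters <- function(profiles) {
  stopifnot(all(c("gene_id", "n_ta_total", "n_ta_unique", "n_ta_first95")
                %in% names(profiles)))
  excluded <- rep("none", nrow(profiles))
  excluded[profiles$n_ta_unique < profiles$n_ta_total / 2] <-
    "under_half_unique"
  excluded[profiles$n_ta_first95 == 0L] <- "no_ta_first95"
  excluded[profiles$n_ta_total == 0L] <- "no_ta"
  profiles$excluded <- excluded
  profiles
}

#' Count insertion reads per gene
#'
#' Sums `reads_total` over unique (non-duplicated) TA sites whose
#' strand-aware offset lies within the first 95% of the gene length
#' (`offset < floor(0.95 * length)`); insertions in the last 5% of a gene
#' often fail to disrupt function and are omitted. A site inside two
#' overlapping genes contributes to both.
#'
#' @param ins_table A `tn_insertion_table` from [tally_insertions].
#' @param genes Gene table from [load_annotation].
#' @param index A `tn_ta_index` with `duplicated` flags filled in.
#' @return data.table with `gene_id` and `raw_reads` for every gene.
#' @export
count_gene_reads <- function(ins_table, genes, index) {
  stopifnot(inherits(ins_table, "tn_insertion_table"),
            inherits(index, "tn_ta_index"))
  if (anyNA(index$duplicated))
    stop("run mark_duplicated_sites() before count_gene_reads()")
  sites <- merge(ins_table$sites,
                 data.table(replicon = index$replicon, pos = index$pos,
                            dup = index$duplicated),
                 by = c("replicon", "pos"), all.x = TRUE)
  if (anyNA(sites$dup))
    stop("insertion table contains positions absent from the TA index")
  sites <- sites[dup == FALSE]
  gdt <- as.data.table(genes[, c("gene_id", "replicon_id", "start", "end",
                                 "strand")])
  hits <- sites[gdt, on = .(replicon = replicon_id, pos >= start, pos < end),
                .(gene_id = i.gene_id, strand = i.strand, gstart = i.start,
                  gend = i.end, site = x.pos, reads = x.reads_total),
                nomatch = NULL]
  if (nrow(hits)) {
    hits[, offset := ifelse(strand == "+", site - gstart,
                            (gend - 2L) - site)]
    counts <- hits[offset < floor(0.95 * (gend - gstart)),
                   .(raw_reads = sum(reads)), by = gene_id]
  } else {
    counts <- data.table(gene_id = character(), raw_reads = integer())
  }
  out <- merge(data.table(gene_id = genes$gene_id), counts,
               by = "gene_id", all.x = TRUE, sort = FALSE)
  out[is.na(raw_reads), raw_reads := 0L]
  out[match(genes$gene_id, out$gene_id)]
}

#' Normalize per-gene read counts
#'
#' Computes reads per kilobase of gene (RpK, over the full annotated length),
#' scales each library to 10^7 uniquely mapped reads
#' (`norm_rpk = rpk * 1e7 / total_unique_mapped`), and takes
#' `log2(norm_rpk)`, undefined (`NA`) for genes with zero reads and for
#' excluded genes.
#'
#' @param genes Gene table from [load_annotation].
#' @param raw Output of [count_gene_reads] (columns `gene_id`, `raw_reads`).
#' @param total_unique_mapped Library total of uniquely mapped reads; must be
#'   positive.
#' @param profiles Filtered profiles from [apply_gene_filters]; when
#'   supplied, the `excluded` column is carried through and excluded genes
#'   get no log2 value.
#' @return A `tn_gene_counts` data.frame: `gene_id`, `gene_length_bp`,
#'   `raw_reads`, `rpk`, `norm_rpk`, `log2_norm_rpk`, `excluded`.
#' @export
normalize_gene_counts <- function(genes, raw, total_unique_mapped,
                                  profiles = NULL) {
  if (!is.numeric(total_unique_mapped) || total_unique_mapped <= 0)
    stop("total_unique_mapped must be positive")
  dt <- data.table(gene_id = genes$gene_id,
                   gene_length_bp = genes$end - genes$start)
  dt <- merge(dt, as.data.table(raw), by = "gene_id", sort = FALSE)
  excluded <- rep("none", nrow(dt))
  if (!is.null(profiles)) {
    excluded <- profiles$excluded[match(dt$gene_id, profiles$gene_id)]
    excluded[is.na(excluded)] <- "none"
  }
  dt[, excluded := excluded]
  dt[, rpk := raw_reads / (gene_length_bp / 1000)]
  dt[, norm_rpk := rpk * (1e7 / total_unique_mapped)]
  dt[, log2_norm_rpk := fifelse(raw_reads > 0 & excluded == "none",
                                log2(norm_rpk), NA_real_)]
  out <- as.data.frame(dt[match(genes$gene_id, dt$gene_id)])
  class(out) <- c("tn_gene_counts", class(out))
  attr(out, "total_unique_mapped") <- total_unique_mapped
  out
}

#' Tabulate one replicate end to end
#'
#' Convenience wrapper: [count_gene_reads] then [normalize_gene_counts],
#' using the insertion table's own uniquely-mapped total.
#'
#' @inheritParams count_gene_reads
#' @param profiles Filtered profiles from [apply_gene_filters].
#' @return A `tn_gene_counts` data.frame.
#' @export
tabulate_genes <- function(ins_table, genes, index, profiles) {
  raw <- count_gene_reads(ins_table, genes, index)
  normalize_gene_counts(genes, raw, ins_table$totals$total_unique_mapped,
                        profiles)
}
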