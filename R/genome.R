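#' @import data.table
NULL

# Coordinate convention used throughout the package:
#  * TA sites are identified by the 0-based index of the T on the forward
#    strand (TA is its own reverse complement, so one position covers both
#    strands).
#  * Gene intervals are stored 0-based half-open [start, end); GFF3 input
#    (1-based inclusive) is converted at the boundary.

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Construct a genome object
#'
#' A genome is an ordered set of replicons (chromosome, plasmids), each a DNA
#' sequence over the alphabet A, C, G, T, N, with a topology used when
#' extracting k-mers near replicon ends (k-mers wrap on circular replicons).
#'
#' @param seqs Named character vector of replicon sequences (uppercased).
#' @param topology Character vector, one of `"circular"` or `"linear"` per
#'   replicon; recycled if length 1.
#' @return An object of class `tn_genome`.
#' @export
tn_genome <- function(seqs, topology = "circular") {
  if (length(seqs) == 0L) stop("genome must contain at least one replicon")
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("every replicon must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate replicon id: ", names(seqs)[duplicated(names(seqs))][1L])
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    off <- regmatches(seqs[bad][1L], regexpr("[^ACGTN]", seqs[bad][1L]))
    stop("replicon '", names(seqs)[bad][1L],
         "' contains non-ACGTN character '", off, "'")
  }
  if (any(nchar(seqs) == 0L)) stop("empty replicon sequence")
  topology <- rep_len(match.arg(topology, c("circular", "linear"),
                                several.ok = TRUE), length(seqs))
  names(topology) <- names(seqs)
  structure(list(seq = seqs, topology = topology), class = "tn_genome")
}

#' @export
print.tn_genome <- function(x, ...) {
  cat("tn_genome with", length(x$seq), "replicon(s):\n")
  for (id in names(x$seq))
    cat(sprintf("  %s: %s bp (%s)\n", id,
                format(nchar(x$seq[[id]]), big.mark = ","), x$topology[[id]]))
  invisible(x)
}

#' Load a genome from a FASTA file
#'
#' Reads a multi-record FASTA file into a [tn_genome] object, one replicon per
#' record (in file order). Sequences are uppercased; any character outside
#' A, C, G, T, N is an error naming the offending record.
#'
#' @param fasta_path Path to a FASTA file.
#' @inheritParams tn_genome
#' @return A `tn_genome`.
#' @export
load_genome <- function(fasta_path, topology = "circular") {
  if (!file.exists(fasta_path)) stop("file not found: ", fasta_path)
  recs <- tryCatch(Biostrings::readBStringSet(fasta_path),
                   error = function(e)
                     stop("malformed FASTA '", fasta_path, "': ",
                          conditionMessage(e), call. = FALSE))
  if (length(recs) == 0L) stop("empty FASTA file: ", fasta_path)
  ids <- sub("\\s.*$", "", names(recs))
  tn_genome(stats::setNames(as.character(recs), ids), topology = topology)
}

#' Load gene annotation from GFF3
#'
#' Imports `gene` features (falling back to `CDS` when no `gene` features are
#' present) and converts coordinates from GFF3 1-based inclusive to the
#' package's 0-based half-open convention.
#'
#' @param gff_path Path to a GFF3 file whose features carry an `ID` attribute.
#' @param genome The [tn_genome] the annotation refers to; features on unknown
#'   replicons or outside replicon bounds are an error.
#' @return A data.frame with columns `gene_id`, `replicon_id`, `start`, `end`
#'   (0-based half-open), `strand` (+/-), `product`.
#' @export
load_annotation <- function(gff_path, genome) {
  stopifnot(inherits(genome, "tn_genome"))
  gr <- rtracklayer::import(gff_path, format = "gff3")
  types <- as.character(gr$type)
  keep <- if (any(types == "gene")) types == "gene" else types == "CDS"
  gr <- gr[keep]
  if (length(gr) == 0L) stop("no gene/CDS features in ", gff_path)
  ids <- as.character(gr$ID)
  if (anyNA(ids) || any(ids == ""))
    stop("gene/CDS feature without an ID attribute in ", gff_path)
  if (anyDuplicated(ids))
    stop("duplicate gene ID: ", ids[duplicated(ids)][1L])
  rep_id <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(rep_id), names(genome$seq))
  if (length(unknown))
    stop("annotation references unknown replicon(s): ",
         paste(unknown, collapse = ", "))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  lens <- nchar(genome$seq)[rep_id]
  if (any(start0 < 0L | end0 > lens | start0 >= end0)) {
    bad <- which(start0 < 0L | end0 > lens | start0 >= end0)[1L]
    stop("gene '", ids[bad], "' has coordinates outside replicon '",
         rep_id[bad], "'")
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("gene feature without explicit +/- strand")
  product <- if (!is.null(gr$product)) as.character(gr$product)
             else rep(NA_character_, length(gr))
  data.frame(gene_id = ids, replicon_id = rep_id, start = start0, end = end0,
             strand = strand, product = product, stringsAsFactors = FALSE)
}

#' Basic per-replicon sequence statistics
#'
#' @param genome A [tn_genome].
#' @return data.frame with `replicon`, `length_bp`, `gc` (fraction of
#'   G+C among A/C/G/T calls; N excluded from the denominator) and
#'   `gc_percent`.
#' @export
genome_stats <- function(genome) {
  stopifnot(inherits(genome, "tn_genome"))
  dss <- Biostrings::DNAStringSet(unname(genome$seq))
  f <- Biostrings::letterFrequency(dss, letters = c("A", "C", "G", "T"))
  acgt <- rowSums(f)
  gc <- ifelse(acgt > 0, (f[, "C"] + f[, "G"]) / acgt, NA_real_)
  data.frame(replicon = names(genome$seq), length_bp = nchar(genome$seq),
             gc = gc, gc_percent = 100 * gc,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Extract, for each TA position, the k-mer starting at the T (fwd) and the
# reverse complement of the k bases ending at the A (rev). On circular
# replicons k-mers wrap around the origin; on linear replicons k-mers that
# do not fit are NA (undefined).
.site_kmers <- function(seq, pos0, k, topology) {
  n <- nchar(seq)
  if (topology == "circular" && n >= k) {
    ext <- paste0(substring(seq, n - k + 2L, n), seq, substring(seq, 1L, k))
    off <- k - 1L
    fwd <- substring(ext, off + pos0 + 1L, off + pos0 + k)
    revsrc <- substring(ext, off + pos0 + 3L - k, off + pos0 + 2L)
    rev <- .revcomp(revsrc)
  } else {
    fs <- pos0 + 1L; fe <- pos0 + k
    fwd <- ifelse(fe <= n, substring(seq, fs, fe), NA_character_)
    rs <- pos0 + 3L - k; re <- pos0 + 2L
    rev <- rep(NA_character_, length(pos0))
    ok <- rs >= 1L & re <= n
    if (any(ok)) rev[ok] <- .revcomp(substring(seq, rs[ok], re[ok]))
  }
  list(fwd = fwd, rev = rev)
}

#' Enumerate candidate transposon insertion (TA) sites
#'
#' The mariner/Himar1 transposon inserts exclusively at TA dinucleotides.
#' Every forward-strand TA position is a candidate site; because TA is
#' palindromic a single position covers both strands. For each site the
#' flanking k-mers used by duplicate detection and exact mapping are recorded:
#' the k-mer starting at the T (forward orientation) and the reverse
#' complement of the k bases ending at the A (reverse orientation).
#'
#' @param genome A [tn_genome].
#' @param kmer_len k-mer length; 14 matches the expected MmeI-liberated
#'   genomic insert size.
#' @return A `tn_ta_index`: a [data.table::data.table] with columns
#'   `replicon`, `pos` (0-based T index, strictly increasing per replicon),
#'   `fwd_kmer`, `rev_kmer` (NA when undefined at a linear replicon edge),
#'   and `duplicated` (NA until [mark_duplicated_sites] is run).
#' @export
enumerate_ta_sites <- function(genome, kmer_len = 14L) {
  stopifnot(inherits(genome, "tn_genome"), kmer_len >= 2L)
  out <- lapply(names(genome$seq), function(id) {
    s <- genome$seq[[id]]
    m <- Biostrings::matchPattern("TA", Biostrings::DNAString(s))
    pos0 <- BiocGenerics::start(m) - 1L
    km <- .site_kmers(s, pos0, as.integer(kmer_len), genome$topology[[id]])
    data.table(replicon = id, pos = pos0, fwd_kmer = km$fwd,
               rev_kmer = km$rev, duplicated = NA)
  })
  idx <- rbindlist(out)
  setattr(idx, "kmer_len", as.integer(kmer_len))
  setattr(idx, "class", c("tn_ta_index", class(idx)))
  idx[]
}

#' Flag TA sites whose k-mer context is not unique
#'
#' Short MmeI-liberated inserts can only be placed uniquely when the sequence
#' context of their TA site is unique in the genome. A site is flagged
#' `duplicated` when its forward or reverse k-mer occurs as the forward or
#' reverse k-mer of any *other* site, across all replicons. A k-mer that is
#' undefined (linear replicon edge) is treated as duplicated for that
#' orientation, since reads from that side cannot be placed.
#'
#' @param index A `tn_ta_index` from [enumerate_ta_sites].
#' @param both_orientations If `FALSE`, only forward k-mers are compared
#'   (reads recovered from a single transposon side).
#' @return The index with the `duplicated` column filled in.
#' @export
mark_duplicated_sites <- function(index, both_orientations = TRUE) {
  stopifnot(inherits(index, "tn_ta_index"))
  idx <- copy(index)
  uid <- seq_len(nrow(idx))
  if (both_orientations) {
    pool <- data.table(kmer = c(idx$fwd_kmer, idx$rev_kmer), uid = c(uid, uid))
  } else {
    pool <- data.table(kmer = idx$fwd_kmer, uid = uid)
  }
  pool <- pool[!is.na(kmer)]
  shared <- pool[, if (uniqueN(uid) > 1L) .(uid = unique(uid)), by = kmer]
  dup <- logical(nrow(idx))
  if (nrow(shared)) dup[unique(shared$uid)] <- TRUE
  # undefined k-mers cannot be proven unique
  dup <- dup | is.na(idx$fwd_kmer)
  if (both_orientations) dup <- dup | is.na(idx$rev_kmer)
  idx[, duplicated := dup]
  idx[]
}

#' Per-gene TA-site profile
#'
#' Counts, for every gene, the TA sites it contains (T position in
#' `[start, end)`), how many of those are unique (not flagged duplicated),
#' and how many fall within the first 95% of the gene length. The 95% cutoff
#' is strand-aware: the offset of a site at position `p` is `p - start` for
#' `+` genes and `(end - 2) - p` for `-` genes, and a site is within the
#' first 95% when `offset < floor(0.95 * gene length)`.
#'
#' @param genes Gene table from [load_annotation].
#' @param index A `tn_ta_index` with `duplicated` flags filled in.
#' @return data.frame with `gene_id`, `n_ta_total`, `n_ta_unique`,
#'   `n_ta_first95`, `n_ta_unique_first95`.
#' @export
gene_ta_profile <- function(genes, index) {
  stopifnot(inherits(index, "tn_ta_index"))
  if (anyNA(index$duplicated))
    stop("run mark_duplicated_sites() before gene_ta_profile()")
  gdt <- as.data.table(genes[, c("gene_id", "replicon_id", "start", "end",
                                 "strand")])
  sdt <- data.table(replicon = index$replicon, pos = index$pos,
                    dup = index$duplicated)
  hits <- sdt[gdt, on = .(replicon = replicon_id, pos >= start, pos < end),
              .(gene_id = i.gene_id, strand = i.strand, gstart = i.start,
                gend = i.end, site = x.pos, dup = x.dup),
              nomatch = NULL]
  if (nrow(hits)) {
    hits[, offset := ifelse(strand == "+", site - gstart,
                            (gend - 2L) - site)]
    hits[, first95 := offset < floor(0.95 * (gend - gstart))]
    prof <- hits[, .(n_ta_total = .N,
                     n_ta_unique = sum(!dup),
                     n_ta_first95 = sum(first95),
                     n_ta_unique_first95 = sum(first95 & !dup)),
                 by = gene_id]
  } else {
    prof <- data.table(gene_id = character(), n_ta_total = integer(),
                       n_ta_unique = integer(), n_ta_first95 = integer(),
                       n_ta_unique_first95 = integer())
  }
  out <- merge(data.table(gene_id = genes$gene_id), prof,
               by = "gene_id", all.x = TRUE, sort = FALSE)
  for (cl in setdiff(names(out), "gene_id"))
    set(out, which(is.na(out[[cl]])), cl, 0L)
  setDF(out)
  out[match(genes$gene_id, out$gene_id), , drop = FALSE]
}

#' Load protein sequences from a FASTA file
#'
#' @param fasta_path Amino-acid FASTA.
#' @return Named character vector of uppercased protein sequences.
#' @export
load_proteins <- function(fasta_path) {
  recs <- Biostrings::readBStringSet(fasta_path)
  stats::setNames(toupper(as.character(recs)), sub("\\s.*$", "", names(recs)))
}

#' Scan a proteome for c-type cytochrome heme-binding motifs
#'
#' Counts left-to-right non-overlapping matches of the CX(2-4)CH motif
#' (cysteine, 2 to 4 arbitrary residues, cysteine, histidine), the canonical
#' covalent heme attachment site of c-type cytochromes. At each scan position
#' the shortest spacer match is taken first.
#'
#' @param proteins Named character vector of amino-acid sequences (20-letter
#'   alphabet plus X and `*`).
#' @return data.frame with `protein_id` and `n_motifs`.
#' @export
scan_heme_motifs <- function(proteins) {
  if (length(proteins) && (is.null(names(proteins)) || anyNA(names(proteins))))
    stop("proteins must be a named character vector")
  seqs <- toupper(proteins)
  n <- vapply(seqs, function(s) {
    m <- gregexpr("C.{2,4}?CH", s, perl = TRUE)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }, integer(1), USE.NAMES = FALSE)
  data.frame(protein_id = names(proteins), n_motifs = n,
             row.names = NULL, stringsAsFactors = FALSE)
}
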