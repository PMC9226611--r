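# Exact unique placement of 14-18 bp genomic inserts. Because accepted
# inserts begin "TA", every exact genomic occurrence of an insert starts at a
# TA site (forward strand) or ends at one (reverse strand), so the search
# space is the per-site k-mer table rather than a general aligner.

#' Build an exact-match index over candidate insertion sites
#'
#' For every TA site and every insert length in `lengths`, records the
#' forward k-mer (starting at the T) and the reverse k-mer (reverse
#' complement of the k bases ending at the A), keyed for constant-time
#' lookup. K-mers wrap on circular replicons; k-mers that do not fit on a
#' linear replicon are omitted (reads from that side cannot be placed).
#'
#' @param genome A [tn_genome].
#' @param ta_index A `tn_ta_index` from [enumerate_ta_sites]; computed when
#'   `NULL`.
#' @param lengths Insert lengths supported by the index.
#' @return An object of class `tn_match_index`.
#' @export
build_index <- function(genome, ta_index = NULL, lengths = 14:18) {
  stopifnot(inherits(genome, "tn_genome"), all(lengths >= 2L))
  if (is.null(ta_index)) ta_index <- enumerate_ta_sites(genome)
  parts <- list()
  for (id in names(genome$seq)) {
    pos0 <- ta_index$pos[ta_index$replicon == id]
    if (length(pos0) == 0L) next
    s <- genome$seq[[id]]
    topo <- genome$topology[[id]]
    for (L in as.integer(lengths)) {
      km <- .site_kmers(s, pos0, L, topo)
      parts[[length(parts) + 1L]] <-
        data.table(kmer = km$fwd, replicon = id, site = pos0, strand = "+")
      parts[[length(parts) + 1L]] <-
        data.table(kmer = km$rev, replicon = id, site = pos0, strand = "-")
    }
  }
  kmers <- rbindlist(parts)[!is.na(kmer)]
  setkey(kmers, kmer)
  structure(list(genome = genome, lengths = as.integer(lengths),
                 kmers = kmers),
            class = "tn_match_index")
}

#' All exact occurrences of a query sequence, both strands
#'
#' General genome-wide lookup backing the mapper: returns every exact
#' occurrence of `query` on either strand (positions wrap on circular
#' replicons). For TA-initial queries of an indexed length the occurrence
#' list is read from the site k-mer table; other queries fall back to a
#' direct scan.
#'
#' @param index A `tn_match_index`.
#' @param query DNA string.
#' @return data.table with `replicon`, `start` (0-based forward-strand start
#'   of the occurrence), `strand`, and `site` (the TA position the occurrence
#'   is anchored to, `NA` for non-TA queries).
#' @export
lookup_kmer <- function(index, query) {
  stopifnot(inherits(index, "tn_match_index"))
  query <- toupper(query)
  L <- nchar(query)
  if (startsWith(query, "TA") && L %in% index$lengths) {
    hits <- index$kmers[.(query), on = "kmer", nomatch = NULL]
    return(data.table(replicon = hits$replicon,
                      start = ifelse(hits$strand == "+", hits$site,
                                     hits$site + 2L - L),
                      strand = hits$strand, site = hits$site))
  }
  out <- list()
  rcq <- .revcomp(query)
  for (id in names(index$genome$seq)) {
    s <- index$genome$seq[[id]]
    n <- nchar(s)
    circ <- index$genome$topology[[id]] == "circular" && n >= L
    subj <- if (circ) paste0(s, substring(s, 1L, L - 1L)) else s
    for (str in c("+", "-")) {
      pat <- if (str == "+") query else rcq
      m <- Biostrings::matchPattern(pat, Biostrings::DNAString(subj))
      st <- BiocGenerics::start(m) - 1L
      st <- st[st < n]   # deduplicate wrapped copies
      if (length(st))
        out[[length(out) + 1L]] <-
          data.table(replicon = id, start = st, strand = str,
                     site = NA_integer_)
    }
  }
  if (length(out)) rbindlist(out)
  else data.table(replicon = character(), start = integer(),
                  strand = character(), site = integer())
}

#' Map processed inserts by exact unique placement
#'
#' An insert maps when it has exactly one exact occurrence in the genome
#' across both strands; inserts with several occurrences are `multi`
#' (discarded from counts but tallied) and inserts with none are `unmapped`.
#' A reverse-strand hit reports the same TA site position as a forward hit,
#' so both recovery orientations of one insertion event collapse to one site.
#'
#' @param inserts data.table with `read_id` and `seq` (from [process_fastq]).
#' @param index A `tn_match_index`.
#' @return data.table with `read_id`, `seq`, `status`
#'   (`mapped`/`multi`/`unmapped`) and, for mapped reads, `replicon`, `site`
#'   (0-based TA position) and `strand`.
#' @export
map_inserts <- function(inserts, index) {
  stopifnot(inherits(index, "tn_match_index"))
  ins <- as.data.table(inserts)[, .(read_id, seq)]
  uq <- unique(ins$seq)
  if (any(!nchar(uq) %in% index$lengths))
    stop("insert length outside index lengths (",
         paste(index$lengths, collapse = ","), ")")
  occ <- index$kmers[.(uq), on = "kmer", nomatch = NULL]
  counts <- occ[, .N, by = kmer]
  lut <- data.table(seq = uq)
  lut <- merge(lut, counts, by.x = "seq", by.y = "kmer", all.x = TRUE)
  lut[is.na(N), N := 0L]
  lut[, status := fifelse(N == 0L, "unmapped",
                          fifelse(N == 1L, "mapped", "multi"))]
  uniq <- occ[occ$kmer %in% lut$seq[lut$status == "mapped"]]
  lut <- merge(lut, uniq[, .(seq = kmer, replicon, site, strand)],
               by = "seq", all.x = TRUE)
  out <- merge(ins, lut, by = "seq", all.x = TRUE, sort = FALSE)
  setcolorder(out, c("read_id", "seq", "status", "replicon", "site",
                     "strand"))
  out[, N := NULL]
  out[]
}

#' Single-insert mapping
#'
#' @param seq Insert sequence (must begin "TA").
#' @param index A `tn_match_index`.
#' @return list with `status` and, when mapped, `replicon`, `site`, `strand`.
#' @export
map_insert <- function(seq, index) {
  occ <- lookup_kmer(index, seq)
  if (nrow(occ) == 0L) return(list(status = "unmapped"))
  if (nrow(occ) > 1L) return(list(status = "multi"))
  list(status = "mapped", replicon = occ$replicon, site = occ$site,
       strand = occ$strand)
}

#' Tally uniquely mapped insertions per TA site
#'
#' @param mapped Output of [map_inserts].
#' @return A `tn_insertion_table`: list with `sites` (data.table of
#'   `replicon`, `pos`, `reads_fwd`, `reads_rev`, `reads_total`, sorted by
#'   position) and `totals` (`total_unique_mapped`, `total_multi`,
#'   `total_unmapped`, `n_sites`).
#' @export
tally_insertions <- function(mapped) {
  m <- as.data.table(mapped)
  ok <- m[status == "mapped"]
  if (nrow(ok)) {
    sites <- ok[, .(reads_fwd = sum(strand == "+"),
                    reads_rev = sum(strand == "-")),
                by = .(replicon, pos = site)]
    sites[, reads_total := reads_fwd + reads_rev]
    setkey(sites, replicon, pos)
  } else {
    sites <- data.table(replicon = character(), pos = integer(),
                        reads_fwd = integer(), reads_rev = integer(),
                        reads_total = integer())
  }
  structure(list(sites = sites[],
                 totals = list(total_unique_mapped = nrow(ok),
                               total_multi = sum(m$status == "multi"),
                               total_unmapped = sum(m$status == "unmapped"),
                               n_sites = nrow(sites))),
            class = "tn_insertion_table")
}

#' @export
print.tn_insertion_table <- function(x, ...) {
  cat("tn_insertion_table:", x$totals$total_unique_mapped,
      "uniquely mapped reads at", x$totals$n_sites, "sites (",
      x$totals$total_multi, "multi,", x$totals$total_unmapped,
      "unmapped )\n")
  invisible(x)
}
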