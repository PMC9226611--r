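# Junction-read processing: from raw forward reads with the layout
#   [revcomp(junction)][IR remnant][genomic insert starting TA][adapter][...]
# to 14-18 bp genomic inserts beginning "TA".

#' Read-processing configuration
#'
#' Parameters of the MmeI junction-read extraction. The defaults describe the
#' library chemistry: the Illumina adapter prefix, the transposon
#' inverted-repeat segment containing the MmeI recognition site (in transposon
#' orientation), and a 4-base inverted-repeat remnant separating the MmeI
#' site from genomic DNA. Both anchor sequences are configuration: real
#' libraries supply their own primer-derived values.
#'
#' @param adapter_seq Adapter sequence searched in the raw read (Hamming
#'   matching, up to `max_mismatches` mismatches).
#' @param junction_seq Inverted-repeat / MmeI recognition segment searched in
#'   the reverse-complemented read. The default is a Himar1-style
#'   inverted-repeat segment terminating in the MmeI recognition site
#'   (TCCGAC); it must be long enough that an approximate match with
#'   `max_mismatches` errors is vanishingly unlikely by chance.
#' @param ir_remnant_len Bases of transposon inverted repeat left between the
#'   MmeI site and genomic DNA; removed from the insert 5' end.
#' @param max_mismatches Maximum Hamming mismatches for both anchor matches.
#' @param min_insert_len,max_insert_len Accepted genomic insert length range
#'   (bp); MmeI digestion with end repair yields 14 bp inserts.
#' @param qual_threshold,qual_window Sliding-window quality truncation: the
#'   read is cut at the first window whose mean Phred score falls below the
#'   threshold (window 1 cuts before the first low-quality base).
#' @return A list of class `tn_processing_config`.
#' @export
processing_config <- function(adapter_seq = "AGATCGGAAGAGC",
                              junction_seq = "ACAGGTTGGATGATAAGTCCGAC",
                              ir_remnant_len = 4L,
                              max_mismatches = 2L,
                              min_insert_len = 14L,
                              max_insert_len = 18L,
                              qual_threshold = 20L,
                              qual_window = 1L) {
  stopifnot(nchar(adapter_seq) > 0L, nchar(junction_seq) > 0L,
            ir_remnant_len >= 0L, max_mismatches >= 0L,
            min_insert_len > 0L, min_insert_len <= max_insert_len,
            qual_window >= 1L)
  structure(list(adapter_seq = toupper(adapter_seq),
                 junction_seq = toupper(junction_seq),
                 ir_remnant_len = as.integer(ir_remnant_len),
                 max_mismatches = as.integer(max_mismatches),
                 min_insert_len = as.integer(min_insert_len),
                 max_insert_len = as.integer(max_insert_len),
                 qual_threshold = as.integer(qual_threshold),
                 qual_window = as.integer(qual_window)),
            class = "tn_processing_config")
}

#' Leftmost approximate (Hamming) match of a pattern in a sequence
#'
#' Scans every alignment where the full pattern fits and returns the 0-based
#' offset of the leftmost alignment with at most `max_mismatches` mismatches,
#' or `NA` if none exists. No indels are considered.
#'
#' @param seq,pattern Character scalars.
#' @param max_mismatches Maximum Hamming distance.
#' @return Integer 0-based offset, or `NA_integer_`.
#' @export
find_approx <- function(seq, pattern, max_mismatches = 0L) {
  stopifnot(nchar(pattern) > 0L)
  n <- nchar(seq); m <- nchar(pattern)
  if (m > n) return(NA_integer_)
  s <- utf8ToInt(seq); p <- utf8ToInt(pattern)
  for (i in 0:(n - m)) {
    if (sum(s[(i + 1L):(i + m)] != p) <= max_mismatches) return(i)
  }
  NA_integer_
}

#' Sliding-window quality truncation
#'
#' Truncates a read at the first window whose mean Phred quality falls below
#' the threshold (with window 1: immediately before the first base with
#' quality below the threshold). Qualities are Phred+33.
#'
#' @param seq,qual Character scalars of equal length.
#' @param config A [processing_config].
#' @return list with truncated `seq` and `qual`.
#' @export
quality_truncate <- function(seq, qual, config = processing_config()) {
  stopifnot(nchar(seq) == nchar(qual))
  n <- nchar(qual)
  if (n == 0L) return(list(seq = seq, qual = qual))
  q <- utf8ToInt(qual) - 33L
  w <- config$qual_window
  if (w == 1L) {
    bad <- which(q < config$qual_threshold)
  } else {
    nw <- n - w + 1L
    if (nw < 1L) return(list(seq = seq, qual = qual))
    cs <- c(0, cumsum(q))
    means <- (cs[(w + 1L):(n + 1L)] - cs[1:nw]) / w
    bad <- which(means < config$qual_threshold)
  }
  if (length(bad) == 0L) return(list(seq = seq, qual = qual))
  cut <- bad[1L] - 1L
  list(seq = substr(seq, 1L, cut), qual = substr(qual, 1L, cut))
}

# Rejection reasons, in the order they are applied.
.reject_reasons <- c("no_junction", "non_ta_start", "length_out_of_range",
                     "quality_fail")

#' Extract the genomic insert from a single junction read
#'
#' Applies, in order: (1) truncation at the leftmost approximate adapter
#' match (no match: the whole read is kept); (2) reverse complement;
#' (3) truncation at the leftmost approximate junction match (no match:
#' reject `no_junction`); (4) reverse complement back; (5) removal of the
#' first `ir_remnant_len` bases (inverted-repeat remnant); (6) the "TA" start
#' gate and the insert length gate; (7) sliding-window quality truncation,
#' rejecting as `quality_fail` inserts truncated below the minimum length.
#' The quality string tracks the sequence through every step.
#'
#' @param read list with `read_id`, `seq`, `qual` (Phred+33, same length).
#' @param config A [processing_config].
#' @return list with `status` (`"ok"` or a rejection reason) and, when
#'   accepted, `read_id`, `seq`, `qual` of the insert.
#' @export
extract_insert <- function(read, config = processing_config()) {
  stopifnot(nchar(read$seq) == nchar(read$qual))
  seq <- toupper(read$seq); qual <- read$qual
  a <- find_approx(seq, config$adapter_seq, config$max_mismatches)
  if (!is.na(a)) {
    seq <- substr(seq, 1L, a); qual <- substr(qual, 1L, a)
  }
  rc <- .revcomp_str(seq); rq <- .rev_str(qual)
  j <- find_approx(rc, config$junction_seq, config$max_mismatches)
  if (is.na(j)) return(list(status = "no_junction", read_id = read$read_id))
  rc <- substr(rc, 1L, j); rq <- substr(rq, 1L, j)
  seq <- .revcomp_str(rc); qual <- .rev_str(rq)
  if (nchar(seq) <= config$ir_remnant_len) {
    seq <- ""; qual <- ""
  } else {
    seq <- substr(seq, config$ir_remnant_len + 1L, nchar(seq))
    qual <- substr(qual, config$ir_remnant_len + 1L, nchar(qual))
  }
  if (substr(seq, 1L, 2L) != "TA")
    return(list(status = "non_ta_start", read_id = read$read_id))
  n <- nchar(seq)
  if (n < config$min_insert_len || n > config$max_insert_len)
    return(list(status = "length_out_of_range", read_id = read$read_id))
  qt <- quality_truncate(seq, qual, config)
  if (nchar(qt$seq) < config$min_insert_len)
    return(list(status = "quality_fail", read_id = read$read_id))
  list(status = "ok", read_id = read$read_id, seq = qt$seq, qual = qt$qual)
}

.revcomp_str <- function(x) {
  if (nchar(x) == 0L) return(x)
  .revcomp(x)
}
.rev_str <- function(x) {
  if (nchar(x) == 0L) return(x)
  intToUtf8(rev(utf8ToInt(x)))
}

# leftmost approximate-match start (1-based, NA when absent) per subject
.leftmost_vmatch <- function(pattern, subjects, max.mismatch) {
  m <- Biostrings::vmatchPattern(pattern, subjects,
                                 max.mismatch = max.mismatch, fixed = TRUE)
  sl <- Biostrings::startIndex(m)   # plain list: avoids S4 per-read cost
  vapply(sl, function(v) if (length(v)) min(v) else NA_integer_, integer(1))
}

#' Process a FASTQ file of junction reads
#'
#' Vectorized application of [extract_insert] to every read of a FASTQ file
#' (optionally gzipped), preserving input order and accounting for every read
#' in the returned statistics.
#'
#' @param path FASTQ path (Phred+33).
#' @param config A [processing_config].
#' @return list with `inserts` (a [data.table::data.table] of `read_id`,
#'   `seq`, `qual`) and `stats` (class `tn_processing_stats`: counters
#'   `input`, `accepted`, `no_adapter_action`, one counter per rejection
#'   reason, and `mean_insert_len`).
#' @export
process_fastq <- function(path, config = processing_config()) {
  reads <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq",
                                 with.qualities = TRUE),
    error = function(e)
      stop("malformed FASTQ '", path, "': ", conditionMessage(e),
           call. = FALSE))
  n <- length(reads)
  ids <- sub("\\s.*$", "", names(reads))
  quals <- S4Vectors::mcols(reads)$qualities
  status <- rep("ok", n)
  if (n == 0L) {
    return(list(inserts = data.table(read_id = character(),
                                     seq = character(), qual = character()),
                stats = .processing_stats(status, integer(0), 0L)))
  }

  # (1) adapter truncation (keep whole read when no match)
  a <- .leftmost_vmatch(config$adapter_seq, reads, config$max_mismatches)
  no_adapter <- sum(is.na(a))
  ends <- ifelse(is.na(a), Biostrings::width(reads), a - 1L)
  reads <- Biostrings::subseq(reads, start = 1L, end = ends)
  quals <- Biostrings::subseq(quals, start = 1L, end = ends)

  # (2) reverse complement, (3) junction truncation, (4) back to + sense
  rc <- Biostrings::reverseComplement(reads)
  rq <- Biostrings::reverse(quals)
  j <- .leftmost_vmatch(config$junction_seq, rc, config$max_mismatches)
  status[is.na(j)] <- "no_junction"
  jend <- ifelse(is.na(j), 0L, j - 1L)
  rc <- Biostrings::subseq(rc, start = 1L, end = jend)
  rq <- Biostrings::subseq(rq, start = 1L, end = jend)
  sq <- as.character(Biostrings::reverseComplement(rc))
  ql <- as.character(Biostrings::reverse(rq))

  # (5) drop the inverted-repeat remnant
  sq <- substr(sq, config$ir_remnant_len + 1L, nchar(sq))
  ql <- substr(ql, config$ir_remnant_len + 1L, nchar(ql))

  # (6) TA gate, then length gate
  live <- status == "ok"
  status[live & substr(sq, 1L, 2L) != "TA"] <- "non_ta_start"
  live <- status == "ok"
  len <- nchar(sq)
  status[live & (len < config$min_insert_len |
                 len > config$max_insert_len)] <- "length_out_of_range"
  live <- status == "ok"

  # (7) quality truncation with minimum-length check
  if (any(live)) {
    if (config$qual_window == 1L) {
      hi <- 33L + config$qual_threshold - 1L
      if (hi >= 33L) {
        cls <- sprintf("[\\x%02x-\\x%02x]", 33L, min(hi, 126L))
        cut <- regexpr(cls, ql, perl = TRUE)
        trunc <- live & cut > 0L
        sq[trunc] <- substr(sq[trunc], 1L, cut[trunc] - 1L)
        ql[trunc] <- substr(ql[trunc], 1L, cut[trunc] - 1L)
      }
    } else {
      for (i in which(live)) {
        qt <- quality_truncate(sq[i], ql[i], config)
        sq[i] <- qt$seq; ql[i] <- qt$qual
      }
    }
    status[live & nchar(sq) < config$min_insert_len] <- "quality_fail"
  }

  acc <- status == "ok"
  inserts <- data.table(read_id = ids[acc], seq = sq[acc], qual = ql[acc])
  list(inserts = inserts,
       stats = .processing_stats(status, nchar(sq[acc]), no_adapter))
}

.processing_stats <- function(status, accepted_lens, no_adapter_action) {
  counters <- vapply(.reject_reasons, function(r) sum(status == r),
                     integer(1))
  structure(list(input = length(status),
                 accepted = sum(status == "ok"),
                 no_adapter_action = as.integer(no_adapter_action),
                 rejected = as.list(counters),
                 mean_insert_len = if (length(accepted_lens))
                   mean(accepted_lens) else NA_real_),
            class = "tn_processing_stats")
}

#' @export
print.tn_processing_stats <- function(x, ...) {
  cat("tn_processing_stats:", x$input, "reads,", x$accepted, "accepted\n")
  for (r in names(x$rejected))
    cat(sprintf("  %-20s %d\n", r, x$rejected[[r]]))
  cat(sprintf("  mean insert length   %.2f bp\n", x$mean_insert_len))
  invisible(x)
}
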