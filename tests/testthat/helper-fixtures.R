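# Shared fixtures and independent brute-force oracles. Oracles are written
# as plain quadratic/naive scans so they stay independent of the package's
# index-based implementations.

rc <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

write_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

write_fastq <- function(ids, seqs, quals,
                        path = tempfile(fileext = ".fastq")) {
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), path)
  path
}

# a raw junction read wrapping `insert` in the documented layout
make_read <- function(insert, config = processing_config(),
                      ir = strrep("G", config$ir_remnant_len),
                      filler = "CAGTCCAGT", q = "?") {
  seq <- paste0(rc(config$junction_seq), ir, insert, config$adapter_seq,
                filler)
  list(read_id = "r", seq = seq, qual = strrep(q, nchar(seq)))
}

# --- oracles -------------------------------------------------------------

# every position p with seq[p..p+1] == "TA", 0-based, by direct scan
bf_ta_positions <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  if (length(v) < 2L) return(integer(0))
  which(v[-length(v)] == "T" & v[-1] == "A") - 1L
}

# duplicated flags by quadratic comparison of the multiset of all site
# k-mers (both orientations), mirroring the stated rule only
bf_dup_flags <- function(index) {
  n <- nrow(index)
  keys <- rbind(data.frame(uid = seq_len(n), kmer = index$fwd_kmer),
                data.frame(uid = seq_len(n), kmer = index$rev_kmer))
  keys <- keys[!is.na(keys$kmer), ]
  dup <- logical(n)
  for (i in seq_len(nrow(keys))) {
    others <- keys$kmer[keys$uid != keys$uid[i]]
    if (keys$kmer[i] %in% others) dup[keys$uid[i]] <- TRUE
  }
  dup | is.na(index$fwd_kmer) | is.na(index$rev_kmer)
}

# leftmost Hamming match by full scan
bf_find_approx <- function(seq, pattern, mm) {
  s <- strsplit(seq, "")[[1]]; p <- strsplit(pattern, "")[[1]]
  n <- length(s); m <- length(p)
  if (m > n) return(NA_integer_)
  for (i in 0:(n - m))
    if (sum(s[(i + 1):(i + m)] != p) <= mm) return(i)
  NA_integer_
}

# per-gene interval scan over TA positions
bf_gene_profile <- function(gene, positions, dup) {
  len <- gene$end - gene$start
  inside <- positions >= gene$start & positions < gene$end
  off <- if (gene$strand == "+") positions - gene$start
         else (gene$end - 2L) - positions
  f95 <- inside & off < floor(0.95 * len)
  c(total = sum(inside), unique = sum(inside & !dup), first95 = sum(f95))
}

# all exact occurrences of a query on both strands by naive substring scan
bf_occurrences <- function(seqs, query) {
  hits <- 0L
  L <- nchar(query); rq <- rc(query)
  for (s in seqs) {
    n <- nchar(s)
    if (n < L) next
    subs <- substring(s, 1:(n - L + 1), L:n)
    hits <- hits + sum(subs == query) + sum(subs == rq)
  }
  hits
}

small_sim <- function(seed = 42, reads = 20000, reps = 2) {
  sim_config(seed = seed,
             replicon_lengths = c(chr = 50000L, pls = 6000L),
             n_genes = 40L, gene_length_range = c(300L, 900L),
             reads_per_replicate = reads, n_replicates = reps)
}
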