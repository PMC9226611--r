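# Synthetic Tn-seq data with a ground-truth ledger: genome + annotation,
# pooled mutant library with per-gene fitness classes, and raw junction
# reads in the documented layout. Every output is a pure function of
# (config, seed).

#' Simulation configuration
#'
#' Defaults emulate the study system the analysis assumes: a ~4.2 Mb
#' chromosome plus a small plasmid at 64% GC, ~4,000 genes, a pooled mariner
#' mutant library hitting half of all TA sites, three replicates of 2
#' million junction reads each, and per-gene fitness classes (13% essential,
#' 3% growth defect, 82% neutral, 2% growth advantage). Selection acts on
#' mutant abundances before multinomial read sampling: first-95% sites of
#' essential genes drop to zero, growth-defect sites are depleted 20-fold,
#' growth-advantage sites enriched 4-fold; intergenic and last-5% sites are
#' untouched. Insert lengths are drawn from a distribution concentrated at
#' the 14 bp MmeI expectation (mean 14.5 bp).
#'
#' @param seed Integer seed; all simulation stages derive their RNG streams
#'   from it.
#' @param replicon_lengths Named integer vector of replicon lengths (bp).
#' @param topology Replicon topology, recycled.
#' @param gc_fraction i.i.d. base composition.
#' @param n_genes Total gene count, split across replicons by length.
#' @param gene_length_range Uniform gene length range (bp).
#' @param class_fractions Named fractions (essential, defect, neutral,
#'   advantage); must sum to 1.
#' @param defect_depletion Multiplicative abundance factor for growth-defect
#'   gene sites.
#' @param advantage_enrichment Factor for growth-advantage gene sites.
#' @param reads_per_replicate Multinomial read total per replicate.
#' @param n_replicates Replicates per condition.
#' @param insertion_density Fraction of TA sites carrying a mutant.
#' @param insert_len_probs Named probabilities over insert lengths 14-18.
#' @param read_length Raw read length (bp); reads are padded with random
#'   filler after the adapter.
#' @param ir_remnant_seq Literal inverted-repeat remnant bases placed between
#'   junction and insert; its length must equal the processing config's
#'   `ir_remnant_len`.
#' @param error_rate Per-base substitution error rate in raw reads.
#' @param lowqual_frac Fraction of reads given a low-quality base inside the
#'   insert (planted quality failures).
#' @param processing A [processing_config] describing the read layout.
#' @return list of class `tn_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       replicon_lengths = c(chromosome = 4200000L,
                                            plasmid = 130000L),
                       topology = "circular",
                       gc_fraction = 0.64,
                       n_genes = 4000L,
                       gene_length_range = c(300L, 1500L),
                       class_fractions = c(essential = 0.13, defect = 0.03,
                                           neutral = 0.82, advantage = 0.02),
                       defect_depletion = 0.05,
                       advantage_enrichment = 4,
                       reads_per_replicate = 2e6,
                       n_replicates = 3L,
                       insertion_density = 0.5,
                       insert_len_probs = c("14" = 0.65, "15" = 0.25,
                                            "16" = 0.06, "17" = 0.03,
                                            "18" = 0.01),
                       read_length = 75L,
                       ir_remnant_seq = "ACGG",
                       error_rate = 0,
                       lowqual_frac = 0,
                       processing = processing_config()) {
  stopifnot(length(replicon_lengths) >= 1L,
            !is.null(names(replicon_lengths)),
            gc_fraction >= 0, gc_fraction <= 1,
            n_genes >= 1L, length(gene_length_range) == 2L,
            gene_length_range[1] <= gene_length_range[2],
            insertion_density >= 0, insertion_density <= 1,
            error_rate >= 0, error_rate <= 1,
            lowqual_frac >= 0, lowqual_frac <= 1,
            defect_depletion >= 0, advantage_enrichment > 0,
            reads_per_replicate >= 1, n_replicates >= 1L)
  if (abs(sum(class_fractions) - 1) > 1e-8)
    stop("class_fractions must sum to 1")
  if (!setequal(names(class_fractions),
                c("essential", "defect", "neutral", "advantage")))
    stop("class_fractions must be named essential/defect/neutral/advantage")
  if (nchar(ir_remnant_seq) != processing$ir_remnant_len)
    stop("ir_remnant_seq length must equal processing$ir_remnant_len")
  if (abs(sum(insert_len_probs) - 1) > 1e-8)
    stop("insert_len_probs must sum to 1")
  min_read <- nchar(processing$junction_seq) + nchar(ir_remnant_seq) +
    processing$max_insert_len + nchar(processing$adapter_seq)
  if (read_length < min_read)
    stop("read_length must be at least ", min_read,
         " bp to hold junction + IR + longest insert + adapter")
  lens <- as.integer(names(insert_len_probs))
  if (any(lens < processing$min_insert_len | lens > processing$max_insert_len))
    stop("insert_len_probs lengths outside processing insert length range")
  structure(list(seed = as.integer(seed),
                 replicon_lengths = replicon_lengths,
                 topology = topology,
                 gc_fraction = gc_fraction, n_genes = as.integer(n_genes),
                 gene_length_range = as.integer(gene_length_range),
                 class_fractions = class_fractions,
                 defect_depletion = defect_depletion,
                 advantage_enrichment = advantage_enrichment,
                 reads_per_replicate = reads_per_replicate,
                 n_replicates = as.integer(n_replicates),
                 insertion_density = insertion_density,
                 insert_len_probs = insert_len_probs,
                 read_length = as.integer(read_length),
                 ir_remnant_seq = toupper(ir_remnant_seq),
                 error_rate = error_rate, lowqual_frac = lowqual_frac,
                 processing = processing),
            class = "tn_sim_config")
}

.base_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

# 0-based T indices of TA dinucleotides fully inside [start, end) of a
# base vector (self-contained: unaffected by sequence outside the span)
.ta_count_inside <- function(v, start0, end0) {
  if (end0 - start0 < 2L) return(0L)
  i <- (start0 + 1L):(end0 - 1L)            # 1-based candidate T positions
  sum(v[i] == "T" & v[i + 1L] == "A")
}

#' Simulate a genome, annotation, and per-gene fitness classes
#'
#' Draws i.i.d. bases at the configured GC content, places non-overlapping
#' genes on random strands with random intergenic gaps (genes allocated to
#' replicons proportionally to length), and resamples any gene span until it
#' contains at least 5 TA dinucleotides so that every gene is scoreable.
#' Each gene is assigned a fitness class by the configured fractions.
#' Deterministic given `config$seed`.
#'
#' @param config A [sim_config].
#' @return list of class `tn_sim` with `genome` ([tn_genome]), `genes`
#'   (annotation data.frame as from [load_annotation]), `truth`
#'   (data.table `gene_id`, `class`), and `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "tn_sim_config"))
  set.seed(config$seed)
  probs <- .base_probs(config$gc_fraction)
  bases <- names(probs)
  rl <- config$replicon_lengths
  n_per <- round(config$n_genes * (as.numeric(rl) / sum(as.numeric(rl))))
  n_per[1L] <- config$n_genes - sum(n_per[-1L])
  if (any(n_per < 0L)) stop("infeasible gene allocation across replicons")

  seqs <- character(length(rl))
  genes_list <- list()
  gid <- 0L
  for (k in seq_along(rl)) {
    L <- rl[[k]]
    n <- n_per[[k]]
    v <- sample(bases, L, replace = TRUE, prob = probs)
    if (n > 0L) {
      glen <- sample(seq(config$gene_length_range[1],
                         config$gene_length_range[2]), n, replace = TRUE)
      total_gap <- L - sum(glen)
      if (total_gap < n + 1L)
        stop("infeasible packing: genes do not fit replicon '",
             names(rl)[k], "'")
      gaps <- as.vector(stats::rmultinom(1L, total_gap, rep(1, n + 1L)))
      starts <- cumsum(gaps[-(n + 1L)]) + c(0L, cumsum(glen[-n]))
      ends <- starts + glen
      # guarantee every gene span holds >= 5 TA dinucleotides
      repeat {
        cnt <- vapply(seq_len(n), function(i)
          .ta_count_inside(v, starts[i], ends[i]), integer(1))
        bad <- which(cnt < 5L)
        if (length(bad) == 0L) break
        for (i in bad)
          v[(starts[i] + 1L):ends[i]] <-
            sample(bases, glen[i], replace = TRUE, prob = probs)
      }
      genes_list[[k]] <- data.frame(
        gene_id = sprintf("g%05d", gid + seq_len(n)),
        replicon_id = names(rl)[k],
        start = starts, end = ends,
        strand = sample(c("+", "-"), n, replace = TRUE),
        product = "hypothetical protein",
        stringsAsFactors = FALSE)
      gid <- gid + n
    }
    seqs[k] <- paste(v, collapse = "")
  }
  genes <- do.call(rbind, genes_list)
  rownames(genes) <- NULL
  cls <- sample(names(config$class_fractions), nrow(genes), replace = TRUE,
                prob = config$class_fractions)
  structure(list(genome = tn_genome(stats::setNames(seqs, names(rl)),
                                    topology = config$topology),
                 genes = genes,
                 truth = data.table(gene_id = genes$gene_id, class = cls),
                 config = config),
            class = "tn_sim")
}

#' Simulate the pooled mutant library and per-replicate read draws
#'
#' Mutagenizes TA sites independently at the configured insertion density,
#' gives each mutant an Exponential(1) pre-selection abundance, applies the
#' per-gene selection model to sites in the first 95% of genes (essential:
#' zero; defect: depleted; advantage: enriched; intergenic/last-5%:
#' unchanged), and draws one independent multinomial read vector of size
#' `reads_per_replicate` per replicate over the post-selection abundances.
#'
#' @param sim A `tn_sim` from [simulate_genome].
#' @param ta_index Optional precomputed `tn_ta_index` for `sim$genome`.
#' @return list of class `tn_sim_library` with `sites` (data.table:
#'   `replicon`, `pos`, `gene_id`, `class`, `first95`, `mutagenized`,
#'   `abundance`, `post_abundance`, and one `reads_rep<i>` column per
#'   replicate) and `config`.
#' @export
simulate_library <- function(sim, ta_index = NULL) {
  stopifnot(inherits(sim, "tn_sim"))
  config <- sim$config
  set.seed(config$seed + 1L)
  if (is.null(ta_index)) ta_index <- enumerate_ta_sites(sim$genome)
  sites <- data.table(replicon = ta_index$replicon, pos = ta_index$pos)

  gdt <- as.data.table(sim$genes)
  hit <- sites[gdt, on = .(replicon = replicon_id, pos >= start, pos < end),
               .(replicon = x.replicon, pos = x.pos, gene_id = i.gene_id,
                 strand = i.strand, gstart = i.start, gend = i.end),
               nomatch = NULL]
  hit[, offset := ifelse(strand == "+", pos - gstart, (gend - 2L) - pos)]
  hit[, first95 := offset < floor(0.95 * (gend - gstart))]
  sites <- merge(sites, hit[, .(replicon, pos, gene_id, first95)],
                 by = c("replicon", "pos"), all.x = TRUE)
  sites <- merge(sites, sim$truth, by = "gene_id", all.x = TRUE)
  setkey(sites, replicon, pos)

  n <- nrow(sites)
  sites[, mutagenized := stats::runif(n) < config$insertion_density]
  sites[, abundance := fifelse(mutagenized, stats::rexp(n), 0)]
  mult <- rep(1, n)
  sel <- !is.na(sites$class) & !is.na(sites$first95) & sites$first95
  mult[sel & sites$class == "essential"] <- 0
  mult[sel & sites$class == "defect"] <- config$defect_depletion
  mult[sel & sites$class == "advantage"] <- config$advantage_enrichment
  sites[, post_abundance := abundance * mult]
  if (sum(sites$post_abundance) <= 0)
    stop("no surviving mutant abundance to sample reads from")
  draws <- stats::rmultinom(config$n_replicates,
                            size = config$reads_per_replicate,
                            prob = sites$post_abundance)
  for (r in seq_len(config$n_replicates))
    set(sites, j = paste0("reads_rep", r), value = draws[, r])
  structure(list(sites = sites[], config = config),
            class = "tn_sim_library")
}

# insert sequence at a site: forward = L bases starting at the T; reverse =
# reverse complement of the L bases ending at the A. Both begin "TA".
.site_inserts <- function(genome, replicon, pos, len, strand) {
  out <- character(length(pos))
  key <- paste(replicon, len, strand)
  for (k in unique(key)) {
    i <- which(key == k)
    id <- replicon[i[1L]]; L <- len[i[1L]]
    km <- .site_kmers(genome$seq[[id]], pos[i], L, genome$topology[[id]])
    out[i] <- if (strand[i[1L]] == "+") km$fwd else km$rev
  }
  out
}

#' Per-replicate insertion tables straight from the truth ledger
#'
#' Converts the library's exact per-site read draws into
#' `tn_insertion_table` objects, bypassing read encoding and decoding: reads
#' at sites flagged duplicated are tallied as multi-mapping (their 14-mer
#' context cannot be placed uniquely) and all other reads as uniquely
#' mapped at their site. This is the ledger-level equivalent of
#' [process_fastq] + [map_inserts] + [tally_insertions] for error-free
#' reads, and is what makes full-scale classifier recovery experiments
#' cheap.
#'
#' @param lib A `tn_sim_library`.
#' @param ta_index A `tn_ta_index` with `duplicated` flags filled in.
#' @return list of `tn_insertion_table`, one per replicate.
#' @export
library_insertion_tables <- function(lib, ta_index) {
  stopifnot(inherits(lib, "tn_sim_library"),
            inherits(ta_index, "tn_ta_index"))
  if (anyNA(ta_index$duplicated))
    stop("run mark_duplicated_sites() first")
  s <- merge(lib$sites,
             data.table(replicon = ta_index$replicon, pos = ta_index$pos,
                        dup = ta_index$duplicated),
             by = c("replicon", "pos"), all.x = TRUE)
  lapply(seq_len(lib$config$n_replicates), function(r) {
    reads <- s[[paste0("reads_rep", r)]]
    keep <- reads > 0 & !s$dup
    sites <- data.table(replicon = s$replicon[keep], pos = s$pos[keep],
                        reads_fwd = as.integer(reads[keep]),
                        reads_rev = 0L,
                        reads_total = as.integer(reads[keep]))
    setkey(sites, replicon, pos)
    structure(list(sites = sites[],
                   totals = list(total_unique_mapped = sum(reads[keep]),
                                 total_multi = sum(reads[s$dup]),
                                 total_unmapped = 0L,
                                 n_sites = nrow(sites))),
              class = "tn_insertion_table")
  })
}

#' Simulate raw junction reads for every replicate
#'
#' Converts the library's per-site read draws into FASTQ files with the
#' documented read layout
#' `[revcomp(junction)][IR remnant][insert][adapter][filler]` at uniform
#' Q30 qualities, one file per replicate, together with a truth ledger of
#' the planted site, strand, and insert length of every read. Reads whose
#' insert cannot be extracted on the drawn strand at a linear replicon edge
#' are redrawn on the opposite strand. Optional per-base substitution errors
#' and planted low-quality reads are controlled by the config.
#'
#' @param lib A `tn_sim_library`.
#' @param sim The `tn_sim` the library was built from.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix; files are `<prefix>_rep<i>.fastq`.
#' @param compress Write gzipped FASTQ.
#' @return list with `fastq` (paths per replicate) and `ledger`
#'   (data.table: `read_id`, `replicate`, `replicon`, `pos`, `strand`,
#'   `insert_len`, `planted_lowqual`).
#' @export
simulate_reads <- function(lib, sim, dir, prefix = "sim", compress = FALSE) {
  stopifnot(inherits(lib, "tn_sim_library"), inherits(sim, "tn_sim"))
  config <- lib$config
  pc <- config$processing
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  head_seq <- paste0(.revcomp(pc$junction_seq), config$ir_remnant_seq)
  bases <- c("A", "C", "G", "T")
  lens <- as.integer(names(config$insert_len_probs))
  paths <- character(config$n_replicates)
  ledgers <- vector("list", config$n_replicates)

  for (r in seq_len(config$n_replicates)) {
    set.seed(config$seed + 100L + r)
    counts <- lib$sites[[paste0("reads_rep", r)]]
    idx <- rep(seq_len(nrow(lib$sites)), counts)
    n <- length(idx)
    replicon <- lib$sites$replicon[idx]
    pos <- lib$sites$pos[idx]
    strand <- sample(c("+", "-"), n, replace = TRUE)
    ilen <- sample(lens, n, replace = TRUE,
                   prob = config$insert_len_probs)
    ins <- .site_inserts(sim$genome, replicon, pos, ilen, strand)
    flip <- is.na(ins)
    if (any(flip)) {   # linear replicon edge: recover from the other side
      strand[flip] <- ifelse(strand[flip] == "+", "-", "+")
      ins[flip] <- .site_inserts(sim$genome, replicon[flip], pos[flip],
                                 ilen[flip], strand[flip])
      if (anyNA(ins)) stop("site too close to both replicon edges")
    }
    fill_len <- pmax(0L, config$read_length - nchar(head_seq) - ilen -
                       nchar(pc$adapter_seq))
    filler <- character(n)
    for (m in unique(fill_len)) {
      i <- which(fill_len == m)
      if (m == 0L) { filler[i] <- ""; next }
      ch <- matrix(sample(bases, length(i) * m, replace = TRUE), ncol = m)
      filler[i] <- do.call(paste0, as.data.frame(ch, stringsAsFactors = FALSE))
    }
    seq <- paste0(head_seq, ins, pc$adapter_seq, filler)
    if (config$error_rate > 0) {
      seq <- vapply(seq, function(s) {
        v <- strsplit(s, "")[[1]]
        hit <- which(stats::runif(length(v)) < config$error_rate)
        if (length(hit))
          v[hit] <- vapply(v[hit], function(b)
            sample(setdiff(bases, b), 1L), character(1))
        paste(v, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    qual <- strrep("?", nchar(seq))   # Q30
    lowq <- stats::runif(n) < config$lowqual_frac
    if (any(lowq)) {
      # plant a Q2 base a few bases into the insert so that quality
      # truncation leaves it below the minimum length
      p <- nchar(head_seq) + 5L
      substr(qual[lowq], p, p) <- "#"
    }
    read_id <- sprintf("%s_rep%d_%07d", prefix, r, seq_len(n))
    path <- file.path(dir, sprintf("%s_rep%d.fastq%s", prefix, r,
                                   if (compress) ".gz" else ""))
    con <- if (compress) gzfile(path, "wb") else file(path, "wb")
    writeLines(paste0("@", read_id, "\n", seq, "\n+\n", qual), con)
    close(con)
    paths[r] <- path
    ledgers[[r]] <- data.table(read_id = read_id, replicate = r,
                               replicon = replicon, pos = pos,
                               strand = strand, insert_len = ilen,
                               planted_lowqual = lowq)
  }
  list(fastq = paths, ledger = rbindlist(ledgers))
}

#' Write a complete simulated dataset to disk
#'
#' Genome FASTA, GFF3 annotation, per-replicate FASTQ files, the truth
#' ledger, and the exact configuration (JSON) for reproduction.
#'
#' @param config A [sim_config].
#' @param dir Output directory.
#' @param compress Gzip the FASTQ files.
#' @return Invisibly, a list with all file paths plus the `tn_sim` and
#'   `tn_sim_library` objects.
#' @export
simulate_dataset <- function(config = sim_config(), dir,
                             compress = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(config)
  lib <- simulate_library(sim)
  reads <- simulate_reads(lib, sim, dir, compress = compress)
  fasta <- file.path(dir, "genome.fasta")
  gff <- file.path(dir, "genes.gff3")
  write_genome_fasta(sim$genome, fasta)
  write_genes_gff3(sim$genes, gff)
  fwrite(lib$sites, file.path(dir, "truth_sites.tsv"), sep = "\t")
  fwrite(sim$truth, file.path(dir, "truth_genes.tsv"), sep = "\t")
  fwrite(reads$ledger, file.path(dir, "truth_reads.tsv"), sep = "\t")
  cfg <- config
  cfg$processing <- unclass(cfg$processing)
  jsonlite::write_json(unclass(cfg), file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(fasta = fasta, gff = gff, fastq = reads$fastq,
                 ledger = reads$ledger, sim = sim, library = lib))
}
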