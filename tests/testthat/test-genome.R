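test_that("FASTA loading builds replicons in order, normalizes case, and rejects bad alphabets", {
  p <- write_fasta(c(chr = strrep("ACGT", 25), plasmid = "acgtacgtacgtacgtacgt"))
  g <- load_genome(p)
  expect_s3_class(g, "tn_genome")
  expect_identical(names(g$seq), c("chr", "plasmid"))
  expect_identical(unname(nchar(g$seq)), c(100L, 20L))
  expect_identical(unname(g$seq[["plasmid"]]), strrep("ACGT", 5))

  bad <- write_fasta(c(ok = "ACGT", oops = "ACXGT"))
  expect_error(load_genome(bad), "oops")
  empty <- tempfile(); file.create(empty)
  expect_error(load_genome(empty), "empty|FASTA")
})

test_that("GFF3 annotation converts 1-based inclusive to 0-based half-open", {
  g <- tn_genome(c(chr = random_dna(400)))
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\ttest\tgene\t101\t300\t.\t+\t.\tID=gA;product=thing",
               "chr\ttest\tgene\t5\t40\t.\t-\t.\tID=gB",
               "chr\ttest\tgene\t350\t392\t.\t+\t.\tID=gC"), gff)
  genes <- load_annotation(gff, g)
  expect_identical(genes$gene_id, c("gA", "gB", "gC"))
  expect_identical(genes$start, c(100L, 4L, 349L))
  expect_identical(genes$end, c(300L, 40L, 392L))
  expect_identical(genes$product[1], "thing")

  writeLines(c("##gff-version 3",
               "nope\ttest\tgene\t1\t10\t.\t+\t.\tID=gX"), gff)
  expect_error(load_annotation(gff, g), "unknown replicon")
  writeLines(c("##gff-version 3",
               "chr\ttest\tgene\t1\t10\t.\t+\t.\tID=gX",
               "chr\ttest\tgene\t20\t30\t.\t+\t.\tID=gX"), gff)
  expect_error(load_annotation(gff, g), "duplicate")
  writeLines(c("##gff-version 3",
               "chr\ttest\tgene\t390\t450\t.\t+\t.\tID=gY"), gff)
  expect_error(load_annotation(gff, g), "outside")
})

test_that("genome statistics match character counts, N excluded from GC denominator", {
  g <- tn_genome(c(a = "ATGC", b = "GGGG", c = "ATNN"), "linear")
  st <- genome_stats(g)
  expect_equal(st$length_bp, c(4L, 4L, 4L))
  expect_equal(st$gc_percent, c(50, 100, 0))
  expect_equal(st$gc[3], 0)   # denominator 2, not 4
})

test_that("TA enumeration finds overlapping-register sites and matches a brute-force scan", {
  g <- tn_genome(c(x = "TATA"), "linear")
  expect_identical(enumerate_ta_sites(g)$pos, c(0L, 2L))
  g2 <- tn_genome(c(x = "GGCCGG"), "linear")
  expect_identical(nrow(enumerate_ta_sites(g2)), 0L)

  set.seed(101)
  s <- random_dna(10000, gc = 0.6)
  idx <- enumerate_ta_sites(tn_genome(c(chr = s)))
  expect_identical(idx$pos, bf_ta_positions(s))
  # every listed position really is a TA
  expect_true(all(substring(s, idx$pos + 1, idx$pos + 2) == "TA"))
})

test_that("TA site set is reverse-complement invariant under p -> L - 2 - p", {
  set.seed(7)
  for (i in 1:3) {
    s <- random_dna(3000, gc = 0.64)
    L <- nchar(s)
    a <- enumerate_ta_sites(tn_genome(c(chr = s)))$pos
    b <- enumerate_ta_sites(tn_genome(c(chr = rc(s))))$pos
    expect_setequal(L - 2L - a, b)
  }
})

test_that("duplicate-site flags agree with constructed cases and the quadratic oracle", {
  # two TA sites sharing a forward 14-mer
  g <- tn_genome(c(chr = paste0("TA", strrep("A", 16), "TA", strrep("A", 16))),
                 "circular")
  idx <- mark_duplicated_sites(enumerate_ta_sites(g))
  two <- idx[idx$pos %in% c(0L, 18L), ]
  expect_true(all(two$duplicated))

  # two sites with distinct downstream and upstream context
  set.seed(11)
  repeat {
    s <- paste0(random_dna(20), "TA", random_dna(30), "TA", random_dna(20))
    idx2 <- enumerate_ta_sites(tn_genome(c(chr = s)))
    if (nrow(idx2) == 2L) break
  }
  idx2 <- mark_duplicated_sites(idx2)
  expect_false(any(idx2$duplicated))

  # random 20 kb genome vs brute-force multiset comparison
  set.seed(13)
  g3 <- tn_genome(c(chr = random_dna(15000, 0.64),
                    pls = random_dna(5000, 0.64)))
  idx3 <- mark_duplicated_sites(enumerate_ta_sites(g3))
  expect_identical(idx3$duplicated, bf_dup_flags(idx3))
})

test_that("linear replicon edges make k-mers undefined and conservatively duplicated", {
  s <- paste0("TA", random_dna(40), "TA")
  idx <- mark_duplicated_sites(enumerate_ta_sites(tn_genome(c(chr = s),
                                                            "linear")))
  first <- idx[idx$pos == 0L, ]
  expect_true(is.na(first$rev_kmer))
  expect_true(first$duplicated)
  # the same sequence on a circular replicon wraps instead
  idxc <- enumerate_ta_sites(tn_genome(c(chr = s), "circular"))
  expect_false(anyNA(idxc$rev_kmer))
})

test_that("gene TA profiles respect the strand-aware first-95% boundary", {
  # gene [100, 300) on +: len 200, floor(0.95*200) = 190, so offset 189 is
  # the last position inside the first 95%
  s1 <- paste(c(rep("G", 289), "T", "A", rep("G", 109)), collapse = "")
  s2 <- paste(c(rep("G", 290), "T", "A", rep("G", 108)), collapse = "")
  genes <- data.frame(gene_id = "g1", replicon_id = "chr", start = 100L,
                      end = 300L, strand = "+", product = NA)
  for (case in list(list(seq = s1, first95 = 1L),
                    list(seq = s2, first95 = 0L))) {
    idx <- mark_duplicated_sites(
      enumerate_ta_sites(tn_genome(c(chr = case$seq), "linear")))
    prof <- gene_ta_profile(genes, idx)
    expect_identical(prof$n_ta_total, 1L)
    expect_identical(prof$n_ta_first95, case$first95)
  }
})

test_that("gene TA profiles equal per-gene brute-force interval scans", {
  set.seed(17)
  s <- random_dna(20000, gc = 0.64)
  g <- tn_genome(c(chr = s))
  idx <- mark_duplicated_sites(enumerate_ta_sites(g))
  starts <- sort(sample(1:18000, 12))
  genes <- data.frame(gene_id = paste0("g", 1:12), replicon_id = "chr",
                      start = starts, end = starts + sample(200:1500, 12),
                      strand = sample(c("+", "-"), 12, TRUE),
                      product = NA)
  genes$end <- pmin(genes$end, 20000L)
  prof <- gene_ta_profile(genes, idx)
  for (i in 1:12) {
    o <- bf_gene_profile(genes[i, ], idx$pos, idx$duplicated)
    expect_equal(prof$n_ta_total[i], unname(o["total"]))
    expect_equal(prof$n_ta_unique[i], unname(o["unique"]))
    expect_equal(prof$n_ta_first95[i], unname(o["first95"]))
  }
  # sites in overlapping genes are credited to each gene
  ov <- data.frame(gene_id = c("a", "b"), replicon_id = "chr",
                   start = c(1000L, 1200L), end = c(2000L, 2200L),
                   strand = "+", product = NA)
  pov <- gene_ta_profile(ov, idx)
  both <- sum(idx$pos >= 1200 & idx$pos < 2000)
  expect_gte(sum(pov$n_ta_total), both)
})

test_that("heme motif scan counts non-overlapping CX(2-4)CH matches, shortest spacer first", {
  hits <- scan_heme_motifs(c(p1 = "CAACH", p2 = "CCH",
                             p3 = "MCAACHCAAAACHR", p4 = "CAAAAACH"))
  expect_identical(hits$n_motifs, c(1L, 0L, 2L, 0L))
  # octaheme-like protein
  octa <- paste(rep("CAACHGG", 8), collapse = "")
  expect_identical(scan_heme_motifs(c(x = octa))$n_motifs, 8L)
})
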