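test_that("approximate matching returns the leftmost Hamming match", {
  expect_identical(find_approx("AAAGATTACAAA", "GATTACA", 0L), 3L)
  expect_identical(find_approx("AAAGATTTCAAA", "GATTACA", 2L), 3L)
  expect_true(is.na(find_approx("AAAA", "GATTACA", 2L)))

  set.seed(23)
  for (i in 1:20) {
    s <- random_dna(200)
    pat <- random_dna(12)
    pos <- sample(0:(200 - 12), 1)
    mutated <- strsplit(pat, "")[[1]]
    at <- sample(12, 2)
    mutated[at] <- vapply(mutated[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    substr(s, pos + 1, pos + 12) <- paste(mutated, collapse = "")
    mm <- sample(2:3, 1)
    expect_identical(find_approx(s, pat, mm), bf_find_approx(s, pat, mm))
  }
})

test_that("sliding-window quality truncation cuts before the first low-quality window", {
  cfg <- processing_config()
  qs <- function(q) intToUtf8(q + 33L)
  r <- quality_truncate("ACGTT", qs(c(30, 30, 30, 15, 30)), cfg)
  expect_identical(r$seq, "ACG")
  r2 <- quality_truncate("ACGTT", qs(rep(30, 5)), cfg)
  expect_identical(r2$seq, "ACGTT")
  r3 <- quality_truncate("ACGTT", qs(rep(10, 5)), cfg)
  expect_identical(r3$seq, "")
})

test_that("insert extraction recovers the planted insert from the documented layout", {
  cfg <- processing_config(adapter_seq = "AGATCGGAAGAGC",
                           junction_seq = "TCCGACAAGGTTAAGGTCAA",
                           ir_remnant_len = 4L)
  ins <- "TACGTACGTACGTA"
  r <- extract_insert(make_read(ins, cfg, ir = "ACGG"), cfg)
  expect_identical(r$status, "ok")
  expect_identical(r$seq, ins)
  expect_identical(nchar(r$seq), 14L)

  # non-TA insert
  r2 <- extract_insert(make_read("GGCGTACGTACGTA", cfg, ir = "ACGG"), cfg)
  expect_identical(r2$status, "non_ta_start")
  # 13 bp insert
  r3 <- extract_insert(make_read("TACGTACGTACGT", cfg, ir = "ACGG"), cfg)
  expect_identical(r3$status, "length_out_of_range")
  # missing junction
  bare <- list(read_id = "r", seq = paste0(ins, cfg$adapter_seq),
               qual = strrep("?", 14 + 13))
  expect_identical(extract_insert(bare, cfg)$status, "no_junction")
  # low quality inside the insert
  lq <- make_read(ins, cfg, ir = "ACGG")
  p <- nchar(cfg$junction_seq) + 4L + 5L
  substr(lq$qual, p, p) <- "#"
  expect_identical(extract_insert(lq, cfg)$status, "quality_fail")
})

test_that("a read without trailing adapter (whole-read keep) still yields its insert", {
  cfg <- processing_config()
  ins <- "TATTGGCCAATTGGCC"   # 16 bp
  seq <- paste0(rc(cfg$junction_seq), "ACGG", ins)   # read ends at the insert
  r <- extract_insert(list(read_id = "r", seq = seq,
                           qual = strrep("?", nchar(seq))), cfg)
  expect_identical(r$status, "ok")
  expect_identical(r$seq, ins)
})

test_that("appending adapter plus filler to a read does not change its insert", {
  cfg <- processing_config()
  set.seed(31)
  for (i in 1:10) {
    L <- sample(14:18, 1)
    ins <- paste0("TA", random_dna(L - 2))
    base <- paste0(rc(cfg$junction_seq), "ACGG", ins)
    with_tail <- paste0(base, cfg$adapter_seq, random_dna(10))
    r1 <- extract_insert(list(read_id = "r", seq = base,
                              qual = strrep("?", nchar(base))), cfg)
    r2 <- extract_insert(list(read_id = "r", seq = with_tail,
                              qual = strrep("?", nchar(with_tail))), cfg)
    expect_identical(r1$status, "ok")
    expect_identical(r1$seq, r2$seq)
  }
})

test_that("FASTQ processing preserves order, reconciles counters, and matches the scalar path", {
  cfg <- processing_config()
  set.seed(37)
  n <- 400L
  status_plan <- sample(c("ok", "non_ta", "short"), n, replace = TRUE,
                        prob = c(0.8, 0.1, 0.1))
  ins <- vapply(status_plan, function(st) {
    if (st == "non_ta") paste0("GG", random_dna(12))
    else if (st == "short") paste0("TA", random_dna(10))
    else paste0("TA", random_dna(sample(12:16, 1)))
  }, character(1))
  seqs <- paste0(rc(cfg$junction_seq), "ACGG", ins, cfg$adapter_seq,
                 strrep("C", 8))
  path <- write_fastq(sprintf("r%03d", 1:n), seqs, strrep("?", nchar(seqs)))
  out <- process_fastq(path, cfg)
  st <- out$stats
  expect_identical(st$input, n)
  expect_identical(st$accepted + Reduce(`+`, st$rejected), n)
  expect_identical(st$rejected$non_ta_start, sum(status_plan == "non_ta"))
  expect_identical(st$rejected$length_out_of_range, sum(status_plan == "short"))
  expect_identical(st$accepted, sum(status_plan == "ok"))
  expect_identical(out$inserts$read_id,
                   sprintf("r%03d", which(status_plan == "ok")))
  expect_identical(out$inserts$seq, unname(ins[status_plan == "ok"]))

  # vectorized path agrees with the scalar reference read by read
  for (i in sample(n, 25)) {
    r <- extract_insert(list(read_id = "x", seq = seqs[i],
                             qual = strrep("?", nchar(seqs[i]))), cfg)
    if (r$status == "ok") {
      expect_true(seqs[i] %in% seqs[which(status_plan == "ok")])
      expect_identical(r$seq, ins[[i]])
    } else {
      expect_false(i %in% which(status_plan == "ok"))
    }
  }
})

test_that("an all-accepted uniform library reports mean insert length 14", {
  cfg <- processing_config()
  set.seed(41)
  ins <- vapply(1:200, function(i) paste0("TA", random_dna(12)), character(1))
  seqs <- paste0(rc(cfg$junction_seq), "TTTT", ins, cfg$adapter_seq)
  path <- write_fastq(sprintf("r%d", 1:200), seqs, strrep("?", nchar(seqs)))
  out <- process_fastq(path, cfg)
  expect_identical(out$stats$accepted, 200L)
  expect_equal(out$stats$mean_insert_len, 14)
})

test_that("an empty FASTQ yields empty output and zero counters", {
  path <- tempfile(fileext = ".fastq"); file.create(path)
  out <- process_fastq(path)
  expect_identical(nrow(out$inserts), 0L)
  expect_identical(out$stats$input, 0L)
  expect_identical(out$stats$accepted, 0L)
})
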