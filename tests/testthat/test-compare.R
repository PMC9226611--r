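# toy tn_calls construction
toy_calls <- function(map) {
  df <- data.frame(gene_id = names(map), consensus = unname(map),
                   stringsAsFactors = FALSE)
  class(df) <- c("tn_calls", class(df))
  df
}

test_that("condition summaries count the five categories with Excluded apart", {
  calls <- toy_calls(c(a = "Essential", b = "NonEssential",
                       c = "NonEssential", d = "Uncertain",
                       e = "Excluded"))
  s <- summarize_condition(calls)
  expect_identical(unname(s[c("Essential", "NonEssential", "Uncertain",
                              "Excluded")]), c(1L, 2L, 1L, 1L))
  expect_identical(unname(s["GrowthDefect"]), 0L)
  empty <- toy_calls(setNames(character(0), character(0)))
  expect_true(all(summarize_condition(empty) == 0L))
})

test_that("the core essential genome is the intersection of per-condition essential sets", {
  mk <- function(ess, all_genes = letters[1:6]) {
    cons <- ifelse(all_genes %in% ess, "Essential", "NonEssential")
    toy_calls(setNames(cons, all_genes))
  }
  cl <- list(c1 = mk(c("a", "b", "c")), c2 = mk(c("a", "b")),
             c3 = mk(c("a", "b", "d")))
  expect_setequal(core_essential(cl), c("a", "b"))
  expect_identical(length(core_essential(list(mk("a"), mk("b")))), 0L)
  expect_error(core_essential(list(mk("a"))), ">= 2")
})

test_that("membership patterns partition the union of essential genes", {
  mk <- function(ess, all_genes = letters[1:10]) {
    cons <- ifelse(all_genes %in% ess, "Essential", "NonEssential")
    toy_calls(setNames(cons, all_genes))
  }
  cl <- list(A = mk(c("a", "b", "c", "d")),
             B = mk(c("a", "b", "e")),
             C = mk(c("a", "f")))
  m <- membership_matrix(cl)
  expect_identical(sum(m$n), 6L)   # union a..f
  row_abc <- m[m$A & m$B & m$C, ]
  expect_identical(row_abc$genes[[1]], "a")
  row_onlyA <- m[m$A & !m$B & !m$C, ]
  expect_setequal(row_onlyA$genes[[1]], c("c", "d"))

  # brute-force enumeration oracle on random call tables
  set.seed(79)
  for (rep in 1:5) {
    genes <- paste0("g", 1:40)
    cl2 <- lapply(1:3, function(i) {
      cons <- sample(c("Essential", "NonEssential", "Uncertain"), 40,
                     replace = TRUE)
      toy_calls(setNames(cons, genes))
    })
    names(cl2) <- c("x", "y", "z")
    m2 <- membership_matrix(cl2)
    ess <- lapply(cl2, essential_set)
    union_ess <- unique(unlist(ess))
    expect_identical(sum(m2$n), length(union_ess))
    for (gidx in seq_along(union_ess)) {
      gg <- union_ess[gidx]
      pat <- paste(as.integer(vapply(ess, function(s) gg %in% s,
                                     logical(1))), collapse = "")
      hit <- m2[m2$pattern == pat, ]
      expect_true(gg %in% hit$genes[[1]])
    }
  }

  single <- membership_matrix(cl["A"])
  expect_identical(sum(single$n), 4L)
})

test_that("condition-specific sets follow target-and-not-background algebra", {
  mk <- function(ess, all_genes = paste0("g", 1:20)) {
    cons <- ifelse(all_genes %in% ess, "Essential", "NonEssential")
    toy_calls(setNames(cons, all_genes))
  }
  cl <- list(LBS = mk(c("g1", "g2")), SWB = mk(c("g1", "g3")),
             PreEC = mk(c("g1")), OC = mk(c("g4", "g5", "g6")),
             EC = mk(c("g4", "g5", "g7")))
  expect_setequal(condition_specific(cl, "EC", c("LBS", "SWB", "PreEC", "OC")),
                  "g7")
  expect_setequal(condition_specific(cl, c("EC", "OC"),
                                     c("LBS", "SWB", "PreEC")),
                  c("g4", "g5"))
  expect_error(condition_specific(cl, "EC", c("EC", "OC")), "overlap")

  # empty background equals the target intersection
  expect_setequal(condition_specific(cl, c("EC", "OC"), character(0)),
                  intersect(essential_set(cl$EC), essential_set(cl$OC)))

  # random-table oracle
  set.seed(83)
  for (rep in 1:5) {
    genes <- paste0("g", 1:30)
    cl2 <- setNames(lapply(1:4, function(i)
      toy_calls(setNames(sample(c("Essential", "NonEssential"), 30, TRUE),
                         genes))), c("w", "x", "y", "z"))
    got <- condition_specific(cl2, c("w", "x"), c("y", "z"))
    want <- genes[vapply(genes, function(gg)
      gg %in% essential_set(cl2$w) && gg %in% essential_set(cl2$x) &&
        !(gg %in% essential_set(cl2$y)) && !(gg %in% essential_set(cl2$z)),
      logical(1))]
    expect_setequal(got, want)
  }
})

test_that("core essential genes are contained in every condition's essential set", {
  set.seed(89)
  genes <- paste0("g", 1:50)
  cl <- setNames(lapply(1:4, function(i)
    toy_calls(setNames(sample(c("Essential", "NonEssential", "Uncertain"),
                              50, TRUE, prob = c(0.4, 0.5, 0.1)), genes))),
    paste0("c", 1:4))
  core <- core_essential(cl)
  for (cc in cl) expect_true(all(core %in% essential_set(cc)))
  m <- membership_matrix(cl)
  expect_identical(sum(m$n), length(unique(unlist(lapply(cl, essential_set)))))
})
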