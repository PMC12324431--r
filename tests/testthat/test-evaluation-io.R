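# Structure comparison metrics, file formats, shuffling.

test_that("pair-level confusion counts use exact index identity", {
  self <- compare_structures("((..))", "((..))")
  expect_equal(unname(unlist(self)), c(2, 0, 0))
  # partial overlap
  pc <- compare_structures(rbind(c(1, 10), c(2, 9)),
                           rbind(c(1, 10), c(3, 8)), n = 10)
  expect_equal(unname(unlist(pc)), c(1, 1, 1))
  # nothing predicted
  pc2 <- compare_structures("......", "((..))")
  expect_equal(unname(unlist(pc2)), c(0, 0, 2))
  expect_error(compare_structures("...", "...."), "lengths differ")
})

test_that("global F1 pools counts before computing rates", {
  one <- tibble::tibble(tp = 1, fp = 1, fn = 1)
  r1 <- global_f1(one)
  expect_equal(c(r1$sensitivity, r1$ppv, r1$f1), c(0.5, 0.5, 0.5))
  two <- tibble::tibble(tp = c(3, 0), fp = c(1, 0), fn = c(0, 2))
  r2 <- global_f1(two)
  expect_equal(r2$sensitivity, 0.6)
  expect_equal(r2$ppv, 0.75)
  expect_equal(r2$f1, 2 * 0.6 * 0.75 / 1.35)
  # pooled global F1 differs from the mean of per-sequence F1
  per_seq_f1 <- c(2 * 1 * 0.75 / 1.75, 0)
  expect_false(isTRUE(all.equal(r2$f1, mean(per_seq_f1))))
  # degenerate conventions
  none <- global_f1(tibble::tibble(tp = 0, fp = 0, fn = 0))
  expect_true(is.na(none$f1))
  missed <- global_f1(tibble::tibble(tp = 0, fp = 0, fn = 3))
  expect_equal(missed$f1, 0)
})

test_that("evaluating a structure set against itself gives F1 = 1", {
  d <- toy_labelled()
  d_pairs <- d[vapply(d$structure, function(x) grepl("\\(", x), logical(1)), ]
  expect_equal(evaluate_structures(d_pairs, d_pairs)$f1, 1)
})

test_that("FASTA round-trips and rejects/drops bad records", {
  d <- rna_tbl(vapply(5:14, function(n) random_rna(n), character(1)))
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(d, path)
  expect_equal(read_fasta(path), d)
  # T is mapped to U
  writeLines(c(">t1", "ACGT"), path)
  expect_identical(read_fasta(path)$seq, "ACGU")
  # degenerate residues: dropped with a warning by default, error on demand
  writeLines(c(">ok", "ACGU", ">bad", "ACGN"), path)
  expect_warning(kept <- read_fasta(path), "degenerate")
  expect_identical(kept$id, "ok")
  expect_error(read_fasta(path, degenerate = "error"), "bad")
  writeLines(c(">dup", "ACGU", ">dup", "GGCC"), path)
  expect_error(read_fasta(path), "duplicate")
})

test_that("dot-bracket files round-trip and malformed records are rejected", {
  d <- toy_labelled()
  path <- withr::local_tempfile(fileext = ".db")
  write_dotbracket(d, path)
  expect_equal(read_dotbracket(path), d)
  expect_equal(db_to_pairs("((..))")[, ], rbind(c(i = 1, j = 6), c(2, 5)),
               ignore_attr = TRUE)
  writeLines(c(">x", "GGAAC", "((..)"), path)
  expect_error(read_dotbracket(path), "unbalanced")
  writeLines(c(">x", "GGAAACC", "(<...>)"), path)
  expect_error(read_dotbracket(path), "pseudoknot")
  writeLines(c(">x", "GGAAC", "(...)", ">x", "AAAAA", "....."), path)
  expect_error(read_dotbracket(path), "duplicate")
  writeLines(c("GGAAC", "(...)"), path)
  expect_error(read_dotbracket(path), "3 lines")
})

test_that("CT files round-trip and inconsistencies carry line numbers", {
  d <- toy_labelled()
  path <- withr::local_tempfile(fileext = ".ct")
  write_ct(d, path)
  expect_equal(read_ct(path), d)
  # non-reciprocal partner
  writeLines(c("4 x", "1 G 0 2 4 1", "2 A 1 3 0 2", "3 A 2 4 0 3",
               "4 C 3 0 2 4"), path)
  expect_error(read_ct(path), "non-reciprocal")
  # out-of-order index
  writeLines(c("2 y", "1 G 0 2 0 1", "3 A 1 3 0 3"), path)
  expect_error(read_ct(path), "out of order")
})

test_that("shuffling preserves composition exactly and is seed-driven", {
  set.seed(123)
  d <- rna_tbl(c(random_rna(300), random_rna(40)))
  s1 <- shuffle_sequences(d, seed = 4)
  s2 <- shuffle_sequences(d, seed = 4)
  expect_identical(s1, s2)
  for (r in 1:2) {
    expect_identical(sort(strsplit(s1$seq[r], "")[[1]]),
                     sort(strsplit(d$seq[r], "")[[1]]))
  }
  # a long non-constant sequence essentially never maps to itself
  different <- vapply(1:10, function(k) {
    shuffle_sequences(d, seed = k)$seq[1] != d$seq[1]
  }, logical(1))
  expect_true(all(different))
})
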