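# Inside algorithm, unique-parse scoring, enumeration oracle, gradients.

test_that("inside matches hand-derived probabilities at uniform parameters", {
  u <- uniform_params("G6")
  # "A": unique parse S->L, L->a gives (1-tS)(1-tL)ps(A) = 0.5*0.5*0.25
  expect_equal(inside_loglik("A", u), log(0.0625), tolerance = 1e-12)
  # "AA": unique parse S->LS with two L->a
  expect_equal(inside_loglik("AA", u), log(0.00390625), tolerance = 1e-12)
  u5 <- uniform_params("G5")
  # "A": S->aS then S->eps
  expect_equal(inside_loglik("A", u5), log((1 / 3) * 0.25 * (1 / 3)),
               tolerance = 1e-12)
  expect_error(inside_loglik("", u), "nonempty")
})

test_that("inside equals the enumerate-and-score oracle on random instances", {
  set.seed(101)
  for (k in 1:10) {
    n <- sample(2:12, 1)
    s <- random_rna(n)
    p <- random_params("G6", seed = 100 + k)
    expect_equal(inside_loglik(s, p), brute_force_loglik(s, p),
                 tolerance = 1e-10)
  }
  for (k in 1:8) {
    n <- sample(2:9, 1)
    s <- random_rna(n)
    p <- random_params("G5", seed = 200 + k)
    expect_equal(inside_loglik(s, p), brute_force_loglik(s, p),
                 tolerance = 1e-10)
  }
})

test_that("G5 with tp = 0 reduces to the geometric-length i.i.d. model", {
  p <- g5_params(tu = 0.4, tp = 0, ps = c(0.1, 0.2, 0.3, 0.4),
                 pbp = matrix(1 / 16, 4, 4))
  s <- "GGAUC"
  closed <- 5 * log(0.4) + log(0.6) +
    sum(log(c(0.3, 0.3, 0.1, 0.4, 0.2)))
  expect_equal(inside_loglik(s, p), closed, tolerance = 1e-12)
})

test_that("score_parse reproduces the unique-derivation product", {
  u <- uniform_params("G6")
  # GAAC with pair (1,4): (1-tS)^2 (1-tL)^2 tL (1-tF) pbp(G,C) ps(A)^2 = 2^-14
  lp <- score_parse("GAAC", "(..)", u)
  expect_equal(as.numeric(lp), log(6.103515625e-05), tolerance = 1e-12)
  cc <- attr(lp, "counts")
  expect_equal(unname(cc$rules[c("SL", "LaFb", "La", "FLS", "FaFb", "SLS")]),
               c(2, 1, 2, 1, 0, 0))
  # only one structure exists for n = 2, so joint equals marginal
  expect_equal(as.numeric(score_parse("AA", "..", u)), inside_loglik("AA", u))
  # a hairpin loop below 2 is not derivable by G6, error names the pair
  expect_error(score_parse("GAC", "(.)", u), "\\(1,3\\)")
  expect_error(score_parse("GGAAC", "((..)", u), "unbalanced")
})

test_that("structure enumeration is exhaustive and duplicate-free", {
  expect_length(enumerate_structures(1, "G6"), 1)
  e4 <- enumerate_structures(4, "G6")
  expect_length(e4, 2)
  e5 <- enumerate_structures(5, "G6")
  expect_length(e5, 4)
  keys <- sapply(e5, function(m) paste(m, collapse = ","))
  expect_identical(sort(keys), sort(c("", "1,4", "1,5", "2,5")))
  expect_error(enumerate_structures(15, "G6"), "n <= 14")
  # G5 allows adjacent pairs: n = 2 has 2 structures (empty, (1,2))
  expect_length(enumerate_structures(2, "G5"), 2)
})

test_that("the grammar is a distribution over all finite sequences", {
  u <- uniform_params("G6")
  total <- 0
  prev <- 0
  for (n in 1:4) {
    seqs <- apply(expand.grid(rep(list(c("A", "C", "G", "U")), n)), 1, paste,
                  collapse = "")
    mass_n <- sum(exp(vapply(seqs, inside_loglik, numeric(1), params = u)))
    expect_lte(mass_n, 1 + 1e-12)
    total <- total + mass_n
    expect_gte(total, prev)
    prev <- total
  }
  expect_lte(total, 1 + 1e-12)
})

test_that("analytic gradients match central finite differences", {
  set.seed(33)
  for (k in 1:3) {
    s <- random_rna(sample(5:9, 1))
    p <- random_params("G6", seed = 300 + k)
    g <- inside_grad(s, p)
    h <- 1e-6
    for (f in c("tS", "tL", "tF")) {
      p1 <- p; p1[[f]] <- p[[f]] + h
      p2 <- p; p2[[f]] <- p[[f]] - h
      fd <- (inside_loglik(s, p1) - inside_loglik(s, p2)) / (2 * h)
      expect_equal(g$gradient[[f]], fd, tolerance = 1e-4)
    }
  }
})

test_that("expected counts sum to the derivation-length identities", {
  # expected single emissions + 2 * expected pair emissions = n
  set.seed(44)
  for (gr in c("G6", "G5")) {
    s <- random_rna(15)
    p <- random_params(gr, seed = 77)
    g <- inside_grad(s, p)
    expect_equal(sum(g$ps_counts) + 2 * sum(g$pbp_counts), 15,
                 tolerance = 1e-9)
  }
})

test_that("inside matrices dump to readable tab-separated files", {
  prefix <- file.path(withr::local_tempdir(), "dp")
  write_inside_matrices("GGGAAACCC", uniform_params("G6"), prefix)
  m <- as.matrix(utils::read.table(paste0(prefix, "_IS.tsv"), sep = "\t"))
  expect_identical(dim(m), c(9L, 9L))
  expect_equal(unname(m[1, 9]),
               inside_loglik("GGGAAACCC", uniform_params("G6")),
               tolerance = 1e-9)
})
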