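# Posteriors, MEA decoding, CYK decoding.

test_that("posteriors satisfy the per-position completeness identity", {
  set.seed(55)
  for (gr in c("G6", "G5")) {
    for (n in c(8, 25, 50)) {
      s <- random_rna(n)
      p <- random_params(gr, seed = n)
      post <- pair_posteriors(s, p)
      rowsum <- vapply(seq_len(n), function(i) {
        post$unpaired_post[i] + sum(post$pair_post[i, ]) +
          sum(post$pair_post[, i])
      }, numeric(1))
      expect_equal(rowsum, rep(1, n), tolerance = 1e-6)
      expect_true(all(post$pair_post >= 0 & post$pair_post <= 1 + 1e-12))
    }
  }
})

test_that("posteriors match the brute-force enumeration posterior", {
  set.seed(56)
  s <- random_rna(9)
  p <- random_params("G6", seed = 8)
  post <- pair_posteriors(s, p)
  structs <- enumerate_structures(9, "G6")
  lps <- vapply(structs, function(st) as.numeric(score_parse(s, st, p)),
                numeric(1))
  Z <- inside_loglik(s, p)
  for (i in 1:6) for (j in (i + 3):9) {
    with_pair <- vapply(structs, function(st) {
      nrow(st) > 0 && any(st[, 1] == i & st[, 2] == j)
    }, logical(1))
    expect_equal(post$pair_post[i, j], sum(exp(lps[with_pair] - Z)),
                 tolerance = 1e-8)
  }
})

test_that("geometrically or emission-impossible pairs get zero posterior", {
  u <- uniform_params("G6")
  # n = 3: G6 needs a hairpin loop of 2, so no pair fits
  post <- pair_posteriors("ACG", u)
  expect_equal(sum(post$pair_post), 0)
  expect_equal(post$unpaired_post, rep(1, 3))
  # emissions allow only G:C pairs; an all-A sequence cannot pair
  p <- uniform_params("G6")
  p$pbp[] <- 0
  p$pbp["G", "C"] <- 0.5
  p$pbp["C", "G"] <- 0.5
  post2 <- pair_posteriors("AAAA", p)
  expect_equal(sum(post2$pair_post), 0)
})

test_that("MEA decoding maximizes the posterior-weighted objective", {
  u <- uniform_params("G6")
  # all pair posteriors ~0 -> empty structure
  m0 <- mea_decode(pair_posteriors("ACG", u))
  expect_identical(m0$db, "...")
  # exhaustive check on a random instance
  set.seed(57)
  s <- random_rna(10)
  p <- random_params("G6", seed = 13)
  post <- pair_posteriors(s, p)
  m <- mea_decode(post, gamma = 1)
  structs <- enumerate_structures(10, "G6")
  obj <- vapply(structs, function(st) {
    paired <- if (nrow(st)) as.vector(st) else integer(0)
    2 * sum(post$pair_post[st[, , drop = FALSE]]) +
      sum(post$unpaired_post[setdiff(1:10, paired)])
  }, numeric(1))
  expect_equal(m$score, max(obj), tolerance = 1e-9)
  # a single dominant posterior cell wins against the unpaired option
  fake <- structure(list(n = 8, seq = strrep("A", 8), grammar = "G6",
                         pair_post = matrix(0, 8, 8),
                         unpaired_post = rep(0.05, 8), loglik = -1),
                    class = "scfg_posterior")
  fake$pair_post[2, 7] <- 0.9
  m2 <- mea_decode(fake, gamma = 1)
  expect_equal(m2$pairs[, ], c(i = 2, j = 7))
})

test_that("MEA output is grammar-compatible and monotone in gamma", {
  set.seed(58)
  s <- random_rna(40)
  p <- random_params("G6", seed = 21)
  post <- pair_posteriors(s, p)
  previous <- -1
  for (gamma in c(0.5, 1, 2, 4, 8)) {
    m <- mea_decode(post, gamma = gamma)
    if (nrow(m$pairs) > 0)
      expect_true(all(m$pairs[, 2] - m$pairs[, 1] >= 3))
    expect_gte(nrow(m$pairs), previous)
    previous <- nrow(m$pairs)
  }
})

test_that("CYK returns the most probable structure", {
  u <- uniform_params("G6")
  expect_identical(cyk_decode("AA", u)$db, "..")
  # hand enumeration for GAAAC: candidates are empty, (1,4), (1,5), (2,5)
  cands <- list(matrix(integer(0), 0, 2), rbind(c(1L, 4L)), rbind(c(1L, 5L)),
                rbind(c(2L, 5L)))
  scores <- vapply(cands, function(st) as.numeric(score_parse("GAAAC", st, u)),
                   numeric(1))
  ck <- cyk_decode("GAAAC", u)
  expect_equal(ck$logp, max(scores), tolerance = 1e-12)
  # random instances against enumeration argmax
  set.seed(59)
  for (gr in c("G6", "G5")) {
    n <- if (gr == "G6") 12 else 9
    s <- random_rna(n)
    p <- random_params(gr, seed = 31)
    structs <- enumerate_structures(n, gr)
    best <- max(vapply(structs, function(st)
      as.numeric(score_parse(s, st, p)), numeric(1)))
    ck <- cyk_decode(s, p)
    expect_equal(ck$logp, best, tolerance = 1e-9)
    expect_equal(as.numeric(score_parse(s, ck$pairs, p)), ck$logp,
                 tolerance = 1e-9)
  }
})

test_that("predict_structures returns a tidy table", {
  d <- rna_tbl(c("GGGAAACCC", "ACGU"), id = c("a", "b"))
  p <- wcf_reference_params()
  out <- predict_structures(d, p)
  expect_named(out, c("id", "seq", "structure", "n_pairs"))
  expect_identical(nchar(out$structure), nchar(out$seq))
  out2 <- predict_structures(d, p, method = "cyk")
  expect_identical(nchar(out2$structure), nchar(out2$seq))
})
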