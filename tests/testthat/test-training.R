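# Sequence-only SGD training and ML estimation.

test_that("the loss is the mean negative log-likelihood", {
  u <- uniform_params("G6")
  one <- rna_tbl("A")
  expect_equal(nll_loss(one, u), -log(0.0625), tolerance = 1e-12)
  two <- rna_tbl(c("A", "A"))
  expect_equal(nll_loss(two, u), nll_loss(one, u))
  mixed <- rna_tbl(c("GGGAAACCC", "ACGU", "AAAA"))
  shuffled <- mixed[c(3, 1, 2), ]
  expect_equal(nll_loss(mixed, u), nll_loss(shuffled, u))
  expect_error(nll_loss(mixed[0, ], u), "no sequences")
})

test_that("SGD is reproducible, keeps valid snapshots, and lowers the loss", {
  set.seed(1)
  train <- sample_from_grammar(wcf_reference_params(), 30, seed = 5,
                               min_length = 15, max_length = 120)
  f1 <- sgd_train(train, grammar = "G6", epochs = 15, seed = 7)
  f2 <- sgd_train(train, grammar = "G6", epochs = 15, seed = 7)
  expect_equal(f1$params, f2$params, tolerance = 1e-15)
  expect_equal(f1$trajectory, f2$trajectory)
  f3 <- sgd_train(train, grammar = "G6", epochs = 15, seed = 8)
  expect_false(isTRUE(all.equal(f1$params$pbp, f3$params$pbp)))
  # epochs are numbered 0..epochs-1 and snapshot 0 is the initialization
  expect_identical(f1$trajectory$epoch, 0:14)
  expect_equal(f1$snapshots[["0"]], uniform_params("G6"))
  for (snap in f1$snapshots) expect_valid_params(snap)
  expect_valid_params(f1$params)
  # optimization makes progress on the full training set
  expect_lt(nll_loss(train, f1$params), nll_loss(train, f1$snapshots[["0"]]))
  # the full-loss option records a per-epoch training-set loss
  f4 <- sgd_train(train, grammar = "G6", epochs = 3, seed = 7,
                  full_loss = TRUE)
  expect_true("full_loss" %in% names(f4$trajectory))
  expect_equal(f4$trajectory$full_loss[1],
               nll_loss(train, uniform_params("G6")), tolerance = 1e-10)
})

test_that("G5 SGD runs and returns a valid fit", {
  set.seed(2)
  train <- sample_from_grammar(wcf_reference_params(), 20, seed = 9,
                               min_length = 10, max_length = 80)
  f <- sgd_train(train, grammar = "G5", epochs = 10, seed = 3)
  expect_valid_params(f$params)
  expect_identical(f$params$grammar, "G5")
  expect_lt(nll_loss(train, f$params), nll_loss(train, uniform_params("G5")))
})

test_that("tidy/glance/autoplot summarize a fit", {
  train <- rna_tbl(c("GGGAAACCC", "GCGAAACGC", "AAAAA", "ACGUACGUA"))
  f <- sgd_train(train, grammar = "G6", epochs = 4, seed = 1)
  td <- tidy(f)
  expect_identical(names(td), c("component", "term", "estimate"))
  expect_identical(nrow(td), 3L + 4L + 16L)
  expect_identical(nrow(tidy(f, type = "trajectory")), 4L)
  gl <- glance(f)
  expect_identical(gl$grammar, "G6")
  expect_identical(gl$n_free_parameters, 21L)
  expect_s3_class(autoplot(f), "ggplot")
  expect_s3_class(autoplot(f$params), "ggplot")
})

test_that("ML estimation normalizes derivation counts exactly", {
  # single pair: all counts come from the unique GAAC derivation
  d <- rna_tbl("GAAC", id = "x", structure = "(..)")
  p <- ml_estimate(d, "G6")
  expect_equal(p$pbp[["G", "C"]], 1)
  expect_equal(p$ps[["A"]], 1)
  expect_equal(p$tS, 0)
  expect_equal(p$tL, 1 / 3)   # 1 helix start vs 2 unpaired residues
  expect_equal(p$tF, 0)       # no stacked pair observed
  # zero counts stay zero without smoothing; pseudocounts lift them
  expect_equal(p$pbp[["A", "U"]], 0)
  ps <- ml_estimate(d, "G6", pseudocount = 1)
  expect_gt(ps$pbp[["A", "U"]], 0)
  expect_valid_params(ps)
  # count ratio: 2 helix starts vs 9 unpaired residues -> tL = 2/11
  d2 <- rna_tbl(c("GAACAAA", "CAAGAA"), id = c("a", "b"),
                structure = c("(..)...", "(..).."))
  est2 <- ml_estimate(d2, "G6")
  expect_equal(est2$tL, 2 / 11)
  expect_error(ml_estimate(rna_tbl("GAC", id = "bad", structure = "(.)"),
                           "G6"), "bad")
})

test_that("ML recovers the generating parameters from sampled structures", {
  truth <- wcf_reference_params()
  smp <- sample_from_grammar(truth, 600, seed = 17, max_length = 2000)
  est <- ml_estimate(smp, "G6")
  expect_lt(abs(est$tL - truth$tL) / truth$tL, 0.10)
  expect_lt(abs(est$tF - truth$tF) / truth$tF, 0.05)
  expect_gt(canonical_pbp_mass(est), 0.9)
})

test_that("SGD and ML agree on the same structured sample", {
  smp <- sample_from_grammar(wcf_reference_params(), 80, seed = 19,
                             min_length = 40, max_length = 150)
  ml <- ml_estimate(smp, "G6")
  fit <- sgd_train(smp, grammar = "G6", epochs = 200, seed = 20)
  expect_lt(abs(fit$params$tL - ml$tL), 0.1)
  expect_lt(abs(fit$params$tF - ml$tF), 0.1)
  expect_gt(canonical_pbp_mass(fit$params), 0.8)
  # end-to-end: the sequence-only fit predicts held-out structures about
  # as well as decoding with the true generating parameters (the
  # ceiling for structures that are posterior draws, around F1 0.6)
  test <- sample_from_grammar(wcf_reference_params(), 60, seed = 26,
                              min_length = 40, max_length = 150)
  f1 <- evaluate_structures(predict_structures(test, fit$params), test)$f1
  oracle <- evaluate_structures(predict_structures(test,
                                                   wcf_reference_params()),
                                test)$f1
  expect_gte(f1, 0.5)
  expect_gt(f1, oracle - 0.15)
})
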