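# shared test helpers: random sequences/params built in code

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                collapse = "")

# a small structured-RNA-like labelled set (hand-built, G6-compatible)
toy_labelled <- function() {
  rna_tbl(
    seq = c("GGGAAACCC", "GCGAAACGCAA", "AAGGGAAACCCAA", "ACGUACGU"),
    id = paste0("toy", 1:4),
    structure = c("(((...)))", "(((...)))..", "..(((...)))..", "........"))
}

expect_valid_params <- function(p) {
  expect_s3_class(p, "scfg_params")
  expect_silent(validate_params(p))
}
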