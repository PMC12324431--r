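# Base-pair posteriors and structure decoding (MEA and CYK).

#' Base-pair and unpaired posterior probabilities
#'
#' Computes, via the Inside and Outside passes, the posterior
#' probability that positions i and j are base-paired given the
#' sequence, and the posterior that each position is unpaired.  Because
#' every residue is emitted either as part of exactly one pair or as an
#' unpaired single, each position's unpaired posterior plus its summed
#' pair posteriors equals 1.
#'
#' @inheritParams inside_loglik
#' @return An object of class `scfg_posterior`: a list with `n`, `seq`,
#'   `grammar`, `pair_post` (n x n upper-triangular matrix),
#'   `unpaired_post` (length-n vector) and `loglik`.
#' @export
pair_posteriors <- function(seq, params) {
  validate_params(params)
  s <- as_codes(seq)
  io <- inside_outside(s, params)
  structure(list(n = length(s), seq = decode_rna(s),
                 grammar = params$grammar,
                 pair_post = io$pair_post,
                 unpaired_post = as.numeric(io$unpaired_post),
                 loglik = io$loglik),
            class = "scfg_posterior")
}

#' @export
print.scfg_posterior <- function(x, ...) {
  cat("<scfg_posterior>", x$grammar, "n =", x$n,
      sprintf("loglik = %.4f\n", x$loglik))
  cat("  expected pairs:", sprintf("%.2f", sum(x$pair_post)), "\n")
  invisible(x)
}

#' Tidy a posterior matrix
#'
#' @param x An `scfg_posterior` object.
#' @param min_prob Drop pair entries below this posterior (default 0
#'   keeps all geometrically possible pairs).
#' @param ... Unused.
#' @return A tibble with columns `i`, `j`, `prob` (pairs) — use
#'   `x$unpaired_post` for the per-position unpaired posteriors.
#' @method tidy scfg_posterior
#' @export
tidy.scfg_posterior <- function(x, min_prob = 0, ...) {
  idx <- which(upper.tri(x$pair_post), arr.ind = TRUE)
  out <- tibble(i = idx[, 1], j = idx[, 2],
                prob = x$pair_post[idx])
  dplyr::arrange(dplyr::filter(out, .data$prob >= min_prob),
                 .data$i, .data$j)
}

#' Maximum expected accuracy (MEA) structure decoding
#'
#' Finds the nested, grammar-compatible structure maximizing
#' `sum over pairs of 2 * gamma * pair_post(i,j) + sum over unpaired
#' positions of unpaired_post(i)`.  `gamma` trades sensitivity for
#' positive predictive value; larger values predict more pairs.  Ties
#' prefer the unpaired option and then the smallest pairing partner,
#' making the decoder deterministic.
#'
#' @param post An `scfg_posterior` from [pair_posteriors()].
#' @param gamma Positive pair weight (default 1).
#' @return A list with `pairs` (1-based matrix), `db` (dot-bracket
#'   string) and `score` (the achieved MEA objective).
#' @export
mea_decode <- function(post, gamma = 1.0) {
  if (!inherits(post, "scfg_posterior"))
    abort("`post` must come from pair_posteriors()")
  if (!is.numeric(gamma) || gamma <= 0) abort("`gamma` must be positive")
  res <- mea_cpp(post$pair_post, post$unpaired_post, gamma,
                 min_pair_span(post$grammar))
  pairs <- res$pairs
  colnames(pairs) <- c("i", "j")
  list(pairs = pairs, db = pairs_to_db(pairs, post$n), score = res$score)
}

#' Most probable structure (CYK decoding)
#'
#' Returns the single most probable parse, `argmax over structures of
#' P(seq, structure)`, via the max-product version of the Inside
#' recursion with traceback.
#'
#' @inheritParams inside_loglik
#' @return A list with `pairs`, `db` and `logp` (the joint log
#'   probability of the returned structure).
#' @export
cyk_decode <- function(seq, params) {
  validate_params(params)
  s <- as_codes(seq)
  res <- if (params$grammar == "G6") {
    g6_cyk_cpp(s, params$tS, params$tL, params$tF,
               unname(params$ps), unname(params$pbp))
  } else {
    g5_cyk_cpp(s, params$tu, params$tp,
               unname(params$ps), unname(params$pbp))
  }
  pairs <- res$pairs
  colnames(pairs) <- c("i", "j")
  list(pairs = pairs, db = pairs_to_db(pairs, length(s)), logp = res$logp)
}

#' Predict secondary structures for a sequence table
#'
#' Tidy prediction wrapper: computes posteriors and decodes a structure
#' for every sequence in `data`.
#'
#' @param data A data frame with `id` and `seq` columns.
#' @param params An `scfg_params` object.
#' @param method `"mea"` (maximum expected accuracy, the default) or
#'   `"cyk"` (single most probable structure).
#' @param gamma MEA pair weight, ignored for CYK.
#' @return `data` as a tibble with added `structure` (dot-bracket) and
#'   `n_pairs` columns.
#' @export
predict_structures <- function(data, params, method = c("mea", "cyk"),
                               gamma = 1.0) {
  check_seq_tbl(data)
  method <- match.arg(method)
  out <- as_tibble(data)
  decoded <- purrr::map(out$seq, function(sq) {
    if (method == "mea") mea_decode(pair_posteriors(sq, params), gamma = gamma)
    else cyk_decode(sq, params)
  })
  out$structure <- purrr::map_chr(decoded, "db")
  out$n_pairs <- purrr::map_int(decoded, function(d) nrow(d$pairs))
  out
}
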