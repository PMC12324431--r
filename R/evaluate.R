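# Base-pair-level structure comparison and pooled F1.

#' Compare predicted and true structures at base-pair level
#'
#' A predicted pair counts as correct only if both indices match a true
#' pair exactly (no slipping credit).  Vectorized over pairs of
#' dot-bracket strings of the same lengths.
#'
#' @param predicted,truth Character vectors of dot-bracket strings (or
#'   single 1-based pair matrices, with `n` supplied).
#' @param n Sequence length, required only for the matrix form.
#' @return A tibble with one row per structure pair and columns `tp`,
#'   `fp`, `fn`.
#' @export
compare_structures <- function(predicted, truth, n = NULL) {
  one <- function(p, t) {
    if (is.character(p)) {
      if (nchar(p) != nchar(t))
        abort(paste0("structure lengths differ (", nchar(p), " vs ",
                     nchar(t), ")"))
      p <- db_to_pairs(p); t <- db_to_pairs(t)
    } else {
      if (is.null(n)) abort("`n` is required when passing pair matrices")
      p <- validate_structure(p, n); t <- validate_structure(t, n)
    }
    key <- function(m) if (length(m) == 0) character(0)
                       else paste(m[, 1], m[, 2], sep = ":")
    kp <- key(p); kt <- key(t)
    tibble(tp = sum(kp %in% kt), fp = sum(!kp %in% kt),
           fn = sum(!kt %in% kp))
  }
  if (is.character(predicted) && length(predicted) > 1) {
    if (length(predicted) != length(truth))
      abort("`predicted` and `truth` must have the same length")
    dplyr::bind_rows(purrr::map2(predicted, truth, one))
  } else {
    one(predicted, truth)
  }
}

#' Pooled sensitivity, PPV and global F1
#'
#' Sums true/false positives and false negatives across all sequences
#' *first*, then computes sensitivity `TP/(TP+FN)`, positive predictive
#' value `TP/(TP+FP)` and their harmonic mean F1.  Pooling differs from
#' averaging per-sequence F1: short sequences do not get outsized
#' weight.  Conventions: a denominator of zero yields 0 for that rate;
#' if there are no true and no predicted pairs anywhere, all three
#' values are `NA` (nothing to evaluate); F1 is 0 whenever
#' `sensitivity + ppv` is 0.
#'
#' @param confusions A data frame with `tp`, `fp`, `fn` columns, e.g.
#'   from [compare_structures()].
#' @return A one-row tibble with `tp`, `fp`, `fn`, `sensitivity`,
#'   `ppv`, `f1`.
#' @export
global_f1 <- function(confusions) {
  if (!is.data.frame(confusions) ||
      !all(c("tp", "fp", "fn") %in% names(confusions)))
    abort("`confusions` must be a data frame with tp, fp, fn columns")
  if (nrow(confusions) == 0) abort("`confusions` is empty")
  TP <- sum(confusions$tp); FP <- sum(confusions$fp); FN <- sum(confusions$fn)
  if (TP + FP + FN == 0)
    return(tibble(tp = 0L, fp = 0L, fn = 0L,
                  sensitivity = NA_real_, ppv = NA_real_, f1 = NA_real_))
  sens <- if (TP + FN > 0) TP / (TP + FN) else 0
  ppv <- if (TP + FP > 0) TP / (TP + FP) else 0
  f1 <- if (sens + ppv > 0) 2 * sens * ppv / (sens + ppv) else 0
  tibble(tp = TP, fp = FP, fn = FN, sensitivity = sens, ppv = ppv, f1 = f1)
}

#' Evaluate predicted structures against a reference
#'
#' Joins predictions and references by `id`, compares them pair by
#' pair, and reports the pooled global metrics.
#'
#' @param predicted,truth Data frames with `id` and `structure`
#'   columns.
#' @return A one-row tibble as from [global_f1()].
#' @export
evaluate_structures <- function(predicted, truth) {
  for (d in list(predicted, truth))
    if (!all(c("id", "structure") %in% names(d)))
      abort("both inputs need `id` and `structure` columns")
  merged <- dplyr::inner_join(
    dplyr::select(as_tibble(predicted), "id", pred = "structure"),
    dplyr::select(as_tibble(truth), "id", true = "structure"),
    by = "id")
  if (nrow(merged) == 0) abort("no shared ids between predictions and truth")
  global_f1(compare_structures(merged$pred, merged$true))
}

#' Composition-preserving sequence shuffling
#'
#' Replaces each sequence by a uniform random permutation of its own
#' residues: the mononucleotide composition is preserved exactly while
#' any base-pairing signal is destroyed.  The standard negative control
#' for sequence-only structure learning.
#'
#' @param data A data frame with `id` and `seq` columns.
#' @param seed Integer seed; `NULL` uses the session RNG.
#' @return `data` as a tibble with shuffled `seq` (any `structure`
#'   column is dropped, as it no longer applies).
#' @export
shuffle_sequences <- function(data, seed = NULL) {
  check_seq_tbl(data)
  run <- function() {
    out <- as_tibble(data)
    out$seq <- vapply(out$seq, function(s) {
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
    out$structure <- NULL
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
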