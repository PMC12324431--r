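# Inside algorithm wrappers, unique-parse scoring, and the exhaustive
# enumeration oracle used to validate the dynamic programs.

as_codes <- function(seq) {
  if (is.character(seq)) encode_rna(seq) else as.integer(seq)
}

#' Log marginal probability of a sequence under an SCFG
#'
#' Runs the log-space Inside algorithm: the total probability of the
#' sequence summed over all secondary structures (parses), the SCFG
#' analogue of the McCaskill partition-function computation.  O(n^3)
#' time, O(n^2) memory; all sums are log-sum-exp with explicit `-Inf`
#' handling.
#'
#' @param seq A single RNA sequence (character string) or an integer
#'   code vector from [encode_rna()].
#' @param params An `scfg_params` object (G6 or G5).
#' @param matrices If `TRUE`, also return the triangular Inside tables.
#' @return The log marginal probability (a single number), or when
#'   `matrices = TRUE` a list with `loglik` and the per-nonterminal
#'   tables (`IS`, `IL`, `IF` for G6; `I` for G5).
#' @examples
#' inside_loglik("GGGAAACCC", uniform_params("G6"))
#' @export
inside_loglik <- function(seq, params, matrices = FALSE) {
  validate_params(params)
  s <- as_codes(seq)
  if (length(s) < 1) abort("sequence must have length >= 1")
  res <- if (params$grammar == "G6") {
    g6_inside_cpp(s, params$tS, params$tL, params$tF,
                  unname(params$ps), unname(params$pbp))
  } else {
    g5_inside_cpp(s, params$tu, params$tp,
                  unname(params$ps), unname(params$pbp))
  }
  if (matrices) res else res$loglik
}

#' Per-sequence log-likelihoods for a sequence table
#'
#' Tidy wrapper around [inside_loglik()]: takes a sequence tibble and
#' appends a `loglik` column.
#'
#' @param data A data frame with `id` and `seq` columns.
#' @param params An `scfg_params` object.
#' @return `data` as a tibble with an added `loglik` column.
#' @export
sequence_loglik <- function(data, params) {
  check_seq_tbl(data)
  out <- as_tibble(data)
  out$loglik <- purrr::map_dbl(out$seq, inside_loglik, params = params)
  out
}

# ------------------------------------------------ unique-parse scoring --

min_pair_span <- function(grammar) if (grammar == "G6") 3L else 1L

# Rule-usage counts of the unique G6 derivation of (seq, structure).
# In G6 a pair is emitted by F (helix extension) exactly when the
# enclosing pair (i-1, j+1) is also present; otherwise it is emitted by
# L (helix initiation).  Every unpaired residue comes from L -> a.  The
# S chains (the root interval and each hairpin/multiloop interior) with
# m top-level elements contribute S -> LS and S -> L uses.
g6_parse_counts <- function(s, pairs) {
  n <- length(s)
  partner <- integer(n)
  npair <- nrow(pairs)
  if (npair > 0) {
    bad <- pairs[, 2] - pairs[, 1] < 3
    if (any(bad))
      abort(paste0("pair (", pairs[bad, 1][1], ",", pairs[bad, 2][1],
                   ") has hairpin loop < 2; not derivable by G6"))
    partner[pairs[, 1]] <- pairs[, 2]
    partner[pairs[, 2]] <- pairs[, 1]
  }
  # count top-level elements of closed interval [a, b]
  n_elements <- function(a, b) {
    m <- 0L; pos <- a
    while (pos <= b) {
      m <- m + 1L
      pos <- if (partner[pos] > pos) partner[pos] + 1L else pos + 1L
    }
    m
  }
  ps_counts <- numeric(4)
  pbp_counts <- matrix(0, 4, 4)
  unpaired <- which(partner == 0L)
  for (i in unpaired) ps_counts[s[i] + 1L] <- ps_counts[s[i] + 1L] + 1
  nLaFb <- 0; nFaFb <- 0; nSLS <- 0; nSL <- 0; nFLS <- 0
  if (npair > 0) {
    for (r in seq_len(npair)) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      pbp_counts[s[i] + 1L, s[j] + 1L] <- pbp_counts[s[i] + 1L, s[j] + 1L] + 1
      stacked <- i > 1 && j < n && partner[i - 1L] == j + 1L
      if (stacked) nFaFb <- nFaFb + 1 else nLaFb <- nLaFb + 1
      closing <- partner[i + 1L] != j - 1L  # interior not a stacked pair
      if (closing) {
        m <- n_elements(i + 1L, j - 1L)
        # F -> LS takes the first element; the rest form an S chain
        nFLS <- nFLS + 1
        nSL <- nSL + 1
        nSLS <- nSLS + (m - 2L)
      }
    }
  }
  m0 <- n_elements(1L, n)
  nSLS <- nSLS + (m0 - 1L)
  nSL <- nSL + 1
  list(rules = c(SLS = nSLS, SL = nSL, LaFb = nLaFb, La = length(unpaired),
                 FaFb = nFaFb, FLS = nFLS),
       ps_counts = ps_counts, pbp_counts = pbp_counts)
}

g5_parse_counts <- function(s, pairs) {
  n <- length(s)
  ps_counts <- numeric(4)
  pbp_counts <- matrix(0, 4, 4)
  npair <- nrow(pairs)
  paired_pos <- if (npair > 0) as.vector(pairs[, 1:2]) else integer(0)
  unpaired <- setdiff(seq_len(n), paired_pos)
  for (i in unpaired) ps_counts[s[i] + 1L] <- ps_counts[s[i] + 1L] + 1
  if (npair > 0)
    for (r in seq_len(npair)) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      pbp_counts[s[i] + 1L, s[j] + 1L] <- pbp_counts[s[i] + 1L, s[j] + 1L] + 1
    }
  # each aSbS branch adds one extra epsilon leaf to the derivation tree
  list(rules = c(aS = length(unpaired), aSbS = npair, eps = 1 + npair),
       ps_counts = ps_counts, pbp_counts = pbp_counts)
}

xlogy <- function(x, y) {
  # counts-times-log-prob with the 0 * log(0) = 0 convention
  out <- numeric(length(x))
  nz <- x != 0
  out[nz] <- x[nz] * log(y[nz])
  sum(out)
}

#' Joint log probability of a (sequence, structure) pair
#'
#' Both grammars are unambiguous: a compatible structure has exactly one
#' derivation, so the joint probability is the product of the rule and
#' emission probabilities used by that derivation.  The rule-usage
#' counts (the sufficient statistics for maximum-likelihood estimation)
#' are attached as attribute `"counts"`.
#'
#' @inheritParams inside_loglik
#' @param structure A dot-bracket string or a 1-based integer pair
#'   matrix (columns i, j).
#' @return The joint log probability, with attribute `counts`.  A
#'   structure the grammar cannot derive (for G6, any pair with hairpin
#'   loop < 2) is an error naming the offending pair.
#' @export
score_parse <- function(seq, structure, params) {
  validate_params(params)
  s <- as_codes(seq)
  n <- length(s)
  pairs <- if (is.character(structure)) {
    if (nchar(structure) != n)
      abort("structure length does not match sequence length")
    db_to_pairs(structure)
  } else {
    validate_structure(structure, n)
  }
  if (params$grammar == "G6") {
    cc <- g6_parse_counts(s, pairs)
    r <- cc$rules
    lp <- xlogy(c(r[["SLS"]], r[["SL"]], r[["LaFb"]], r[["La"]],
                  r[["FaFb"]], r[["FLS"]]),
                c(params$tS, 1 - params$tS, params$tL, 1 - params$tL,
                  params$tF, 1 - params$tF)) +
      xlogy(cc$ps_counts, unname(params$ps)) +
      xlogy(as.vector(cc$pbp_counts), as.vector(unname(params$pbp)))
  } else {
    cc <- g5_parse_counts(s, pairs)
    r <- cc$rules
    lp <- xlogy(c(r[["aS"]], r[["aSbS"]], r[["eps"]]),
                c(params$tu, params$tp, 1 - params$tu - params$tp)) +
      xlogy(cc$ps_counts, unname(params$ps)) +
      xlogy(as.vector(cc$pbp_counts), as.vector(unname(params$pbp)))
  }
  structure(lp, counts = cc)
}

# ------------------------------------------------- enumeration oracle --

#' Enumerate all structures a grammar can derive for length n
#'
#' Exhaustive, duplicate-free enumeration of nested base-pair sets:
#' every G6 pair spans at least 4 positions (hairpin loop >= 2); G5
#' additionally allows adjacent pairs.  A brute-force oracle for the
#' dynamic programs — guarded to small n.
#'
#' @param n Sequence length (at most 14).
#' @param grammar `"G6"` or `"G5"`.
#' @return A list of 1-based integer pair matrices (the empty structure
#'   is a 0-row matrix).
#' @export
enumerate_structures <- function(n, grammar = "G6") {
  grammar <- check_grammar(grammar)
  if (n > 14) abort("enumeration is limited to n <= 14")
  if (n < 1) abort("`n` must be >= 1")
  span <- min_pair_span(grammar)
  empty <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
  memo <- new.env(parent = emptyenv())
  enum <- function(i, j) {
    if (i > j) return(list(empty))
    key <- paste0(i, ",", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- lapply(enum(i + 1, j), identity)  # position i unpaired
    ks <- if (i + span <= j) seq.int(i + span, j) else integer(0)
    for (k in ks) {
      inner <- enum(i + 1, k - 1)
      outer <- enum(k + 1, j)
      for (a in inner) for (b in outer)
        out[[length(out) + 1]] <- rbind(c(i, k), a, b)
    }
    memo[[key]] <- out
    out
  }
  lapply(enum(1L, n), function(m) {
    m <- matrix(as.integer(m), ncol = 2)
    colnames(m) <- c("i", "j")
    m
  })
}

#' Brute-force log marginal by structure enumeration
#'
#' Independent oracle for [inside_loglik()]: enumerates every structure
#' the grammar can derive and log-sum-exps their unique-parse scores.
#'
#' @inheritParams inside_loglik
#' @return The log marginal probability.
#' @export
brute_force_loglik <- function(seq, params) {
  s <- as_codes(seq)
  structs <- enumerate_structures(length(s), params$grammar)
  lps <- vapply(structs, function(st) as.numeric(score_parse(s, st, params)),
                numeric(1))
  m <- max(lps)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(lps - m)))
}

# ------------------------------------------------------ exact gradient --

#' Log-marginal gradient and expected rule counts
#'
#' Runs the Inside and Outside passes and returns the expected rule and
#' emission usage counts under the posterior over parses, together with
#' the exact gradient of the log marginal probability.  For an SCFG the
#' derivative of `log P(seq)` with respect to the log of a rule
#' probability equals the expected number of uses of that rule, which
#' is what gradient training consumes; `gradient` additionally reports
#' derivatives with respect to the raw probabilities.
#'
#' @inheritParams inside_loglik
#' @return A list with `loglik`, `counts` (expected rule-usage counts),
#'   `ps_counts`, `pbp_counts` (expected emission counts), and
#'   `gradient` (a list with the same fields as `params`, holding
#'   `d loglik / d theta` for each raw parameter).
#' @export
inside_grad <- function(seq, params) {
  validate_params(params)
  s <- as_codes(seq)
  io <- inside_outside(s, params)
  safe_div <- function(cnt, p) ifelse(cnt == 0, 0, cnt / p)
  cnt <- io$counts
  if (params$grammar == "G6") {
    grad <- list(
      tS = safe_div(cnt[["SLS"]], params$tS) - safe_div(cnt[["SL"]], 1 - params$tS),
      tL = safe_div(cnt[["LaFb"]], params$tL) - safe_div(cnt[["La"]], 1 - params$tL),
      tF = safe_div(cnt[["FaFb"]], params$tF) - safe_div(cnt[["FLS"]], 1 - params$tF),
      ps = safe_div(io$ps_counts, unname(params$ps)),
      pbp = matrix(safe_div(as.vector(io$pbp_counts),
                            as.vector(unname(params$pbp))), 4, 4))
  } else {
    eps <- 1 - params$tu - params$tp
    grad <- list(
      tu = safe_div(cnt[["aS"]], params$tu) - safe_div(cnt[["eps"]], eps),
      tp = safe_div(cnt[["aSbS"]], params$tp) - safe_div(cnt[["eps"]], eps),
      ps = safe_div(io$ps_counts, unname(params$ps)),
      pbp = matrix(safe_div(as.vector(io$pbp_counts),
                            as.vector(unname(params$pbp))), 4, 4))
  }
  list(loglik = io$loglik, counts = io$counts, ps_counts = io$ps_counts,
       pbp_counts = io$pbp_counts, gradient = grad)
}

# shared inside+outside driver (internal)
inside_outside <- function(s, params) {
  if (params$grammar == "G6") {
    ins <- g6_inside_cpp(s, params$tS, params$tL, params$tF,
                         unname(params$ps), unname(params$pbp))
    if (!is.finite(ins$loglik))
      abort("sequence has zero probability under these parameters")
    out <- g6_outside_cpp(s, params$tS, params$tL, params$tF,
                          unname(params$ps), unname(params$pbp),
                          ins$IS, ins$IL, ins$IF, ins$SPLIT, ins$loglik)
  } else {
    ins <- g5_inside_cpp(s, params$tu, params$tp,
                         unname(params$ps), unname(params$pbp))
    if (!is.finite(ins$loglik))
      abort("sequence has zero probability under these parameters")
    out <- g5_outside_cpp(s, params$tu, params$tp,
                          unname(params$ps), unname(params$pbp),
                          ins$I, ins$loglik)
  }
  c(list(loglik = ins$loglik), out)
}

#' Dump Inside matrices as tab-separated files
#'
#' Debugging aid: writes each triangular Inside table (`IS`, `IL`, `IF`
#' for G6; `I` for G5) as a tab-separated matrix with `-Inf` for
#' unreachable cells.
#'
#' @inheritParams inside_loglik
#' @param prefix Output path prefix; one `<prefix>_<name>.tsv` per
#'   table.
#' @return The written paths, invisibly.
#' @export
write_inside_matrices <- function(seq, params, prefix) {
  res <- inside_loglik(seq, params, matrices = TRUE)
  tabs <- res[setdiff(names(res), "loglik")]
  tabs <- tabs[names(tabs) %in% c("IS", "IL", "IF", "I")]
  paths <- character(0)
  for (nm in names(tabs)) {
    path <- paste0(prefix, "_", nm, ".tsv")
    utils::write.table(tabs[[nm]], path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
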