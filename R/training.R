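# Sequence-only gradient training and maximum-likelihood estimation.

#' Negative log-likelihood of a batch of sequences
#'
#' The training loss: minus the mean, over the sequences, of the log
#' marginal probability computed by the Inside algorithm.  No structure
#' information enters — the Inside pass marginalizes over all parses.
#'
#' @param data A data frame with `id` and `seq` columns.
#' @param params An `scfg_params` object.
#' @return A single number (nats per sequence).
#' @export
nll_loss <- function(data, params) {
  check_seq_tbl(data)
  -mean(purrr::map_dbl(data$seq, inside_loglik, params = params))
}

#' Train an SCFG from sequences alone by stochastic gradient descent
#'
#' At each epoch a batch of `batch_size` sequences is drawn uniformly at
#' random (with replacement) from the training set; the gradient of the
#' batch negative log-likelihood with respect to the log-parameters of
#' the normalized rule distributions — computed exactly from the
#' expected rule-usage counts of the Outside pass — drives a step of
#' size `learning_rate` in log-parameter space, after which every rule
#' distribution is renormalized.  No structures and no alignments are
#' used.  Fully reproducible given `seed`.
#'
#' @param data A data frame with `id` and `seq` columns.
#' @param grammar `"G6"` or `"G5"` (ignored when `params` is supplied).
#' @param epochs Number of SGD updates (default 100, reported as epochs
#'   0..epochs-1).
#' @param learning_rate Step size in log-parameter space (default 0.1).
#' @param batch_size Sequences per batch (default 10).
#' @param init `"uniform"` (maximum-entropy start, the default) or
#'   `"random"`.
#' @param seed Integer driving batch selection and, for
#'   `init = "random"`, the starting point; `NULL` uses the session RNG.
#' @param params Optional explicit starting `scfg_params`, overriding
#'   `init`.
#' @param full_loss If `TRUE`, additionally record the loss over the
#'   whole training set at every epoch (costlier; the default records
#'   the batch loss only).
#' @param snapshot_epochs Integer epochs at which to keep parameter
#'   snapshots (default all epochs).  The snapshot at epoch e holds the
#'   parameters *entering* epoch e, so epoch 0 is the initialization.
#' @param verbose Emit a progress message every 10 epochs.
#' @return An object of class `scfg_fit` with elements `params` (final,
#'   after the last update), `trajectory` (tibble of epoch/loss),
#'   `snapshots` (named list of `scfg_params`), `init_params` and
#'   `config`.
#' @seealso [ml_estimate()] for supervised training, [tidy.scfg_fit()],
#'   [autoplot.scfg_fit()]
#' @export
sgd_train <- function(data, grammar = "G6", epochs = 100,
                      learning_rate = 0.1, batch_size = 10,
                      init = c("uniform", "random"), seed = NULL,
                      params = NULL, full_loss = FALSE,
                      snapshot_epochs = NULL, verbose = FALSE) {
  check_seq_tbl(data)
  init <- match.arg(init)
  if (epochs < 1 || learning_rate <= 0 || batch_size < 1)
    abort("`epochs`, `learning_rate` and `batch_size` must be positive")
  run <- function() {
    p <- params
    if (is.null(p)) {
      p <- if (init == "uniform") uniform_params(grammar)
           else random_params(grammar)
    }
    grammar <- p$grammar
    init_p <- p
    if (is.null(snapshot_epochs)) snapshot_epochs <- seq_len(epochs) - 1L
    snapshots <- list()
    losses <- numeric(epochs)
    full_losses <- if (full_loss) numeric(epochs) else NULL
    nseq <- nrow(data)
    for (e in seq_len(epochs) - 1L) {
      if ((e %% 10L == 0L) && verbose)
        message(sprintf("epoch %d", e))
      if (e %in% snapshot_epochs) snapshots[[as.character(e)]] <- p
      idx <- sample.int(nseq, batch_size, replace = TRUE)
      grads <- vector("list", batch_size)
      for (b in seq_len(batch_size)) {
        g <- tryCatch(inside_grad(data$seq[idx[b]], p), error = function(err) {
          abort(paste0("non-finite loss/gradient at epoch ", e,
                       " for sequence '", data$id[idx[b]], "': ",
                       conditionMessage(err)))
        })
        grads[[b]] <- g
      }
      losses[e + 1L] <- -mean(purrr::map_dbl(grads, "loglik"))
      if (full_loss) full_losses[e + 1L] <- nll_loss(data, p)
      if (!is.finite(losses[e + 1L]))
        abort(paste0("non-finite batch loss at epoch ", e))
      # the loss is the batch-mean NLL, so the step uses batch-averaged
      # expected counts; with the summed loss the step size would scale
      # with batch size times sequence length and overshoot
      tot <- function(field) Reduce(`+`, purrr::map(grads, field)) / batch_size
      cnt <- tot("counts")
      lr <- learning_rate
      # ascent on log P in the log space of each *normalized* rule
      # distribution: the gradient for log theta_r is the centered
      # E[n_r] - theta_r * sum(E[n]) (an uncentered step diverges to the
      # simplex corner with the larger count); renormalization then
      # restores the simplex exactly
      step <- function(theta, counts) {
        w <- log(pmax(theta, PROB_FLOOR)) +
          lr * (counts - theta * sum(counts))
        ew <- exp(w - max(w))
        ew / sum(ew)
      }
      if (grammar == "G6") {
        bS <- step(c(p$tS, 1 - p$tS), c(cnt[["SLS"]], cnt[["SL"]]))
        bL <- step(c(p$tL, 1 - p$tL), c(cnt[["LaFb"]], cnt[["La"]]))
        bF <- step(c(p$tF, 1 - p$tF), c(cnt[["FaFb"]], cnt[["FLS"]]))
        p <- normalize_params(structure(list(
          grammar = "G6", tS = bS[1], tL = bL[1], tF = bF[1],
          ps = step(unname(p$ps), tot("ps_counts")),
          pbp = matrix(step(as.vector(unname(p$pbp)),
                            as.vector(tot("pbp_counts"))), 4, 4)),
          class = c("g6_params", "scfg_params")))
      } else {
        t3 <- step(c(p$tu, p$tp, 1 - p$tu - p$tp),
                   c(cnt[["aS"]], cnt[["aSbS"]], cnt[["eps"]]))
        p <- normalize_params(structure(list(
          grammar = "G5", tu = t3[1], tp = t3[2],
          ps = step(unname(p$ps), tot("ps_counts")),
          pbp = matrix(step(as.vector(unname(p$pbp)),
                            as.vector(tot("pbp_counts"))), 4, 4)),
          class = c("g5_params", "scfg_params")))
      }
    }
    traj <- tibble(epoch = seq_len(epochs) - 1L, loss = losses)
    if (full_loss) traj$full_loss <- full_losses
    structure(list(params = p, init_params = init_p, trajectory = traj,
                   snapshots = snapshots,
                   config = list(grammar = grammar, epochs = epochs,
                                 learning_rate = learning_rate,
                                 batch_size = batch_size, init = init,
                                 seed = seed, n_train = nrow(data))),
              class = "scfg_fit")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.scfg_fit <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<scfg_fit> %s, %d epochs (lr %.3g, batch %d, %d training sequences)\n",
              cfg$grammar, cfg$epochs, cfg$learning_rate, cfg$batch_size,
              cfg$n_train))
  cat(sprintf("  loss: %.4f (epoch 0) -> %.4f (epoch %d)\n",
              x$trajectory$loss[1], utils::tail(x$trajectory$loss, 1),
              cfg$epochs - 1))
  print(x$params)
  invisible(x)
}

#' Tidy and summarize fitted grammars
#'
#' `tidy()` on an `scfg_fit` returns the final parameter estimates (one
#' row per parameter, broom-style), or the per-epoch loss trajectory
#' with `type = "trajectory"`.  `tidy()` on an `scfg_params` object
#' returns the same parameter layout.  `glance()` gives a one-row model
#' summary.
#'
#' @param x An `scfg_fit` (or `scfg_params`) object.
#' @param type `"parameters"` (default) or `"trajectory"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy scfg_fit
#' @export
tidy.scfg_fit <- function(x, type = c("parameters", "trajectory"), ...) {
  type <- match.arg(type)
  if (type == "trajectory") return(x$trajectory)
  tidy(x$params)
}

#' @rdname tidy.scfg_fit
#' @method glance scfg_fit
#' @export
glance.scfg_fit <- function(x, ...) {
  p <- x$params
  base <- tibble(grammar = x$config$grammar,
                 n_free_parameters = count_free_parameters(p),
                 epochs = x$config$epochs,
                 learning_rate = x$config$learning_rate,
                 batch_size = x$config$batch_size,
                 n_train = x$config$n_train,
                 initial_loss = x$trajectory$loss[1],
                 final_loss = utils::tail(x$trajectory$loss, 1),
                 canonical_pbp_mass = canonical_pbp_mass(p))
  if (p$grammar == "G6") dplyr::mutate(base, tL = p$tL, tF = p$tF)
  else dplyr::mutate(base, tu = p$tu, tp = p$tp)
}

#' Write an SGD trajectory to a tab-separated file
#'
#' @param fit An `scfg_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(fit, path) {
  utils::write.table(fit$trajectory, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Maximum-likelihood estimation from labelled structures
#'
#' Accumulates the rule-usage counts of each (sequence, structure)
#' pair's unique derivation and normalizes them into probabilities —
#' the exact ML estimator for an unambiguous SCFG.  With
#' `pseudocount = 0` (the default) rules never observed get probability
#' zero; a distribution with no observations at all falls back to
#' uniform.
#'
#' @param data A data frame with `id`, `seq` and `structure`
#'   (dot-bracket) columns.
#' @param grammar `"G6"` or `"G5"`.
#' @param pseudocount Added to every count before normalization
#'   (default 0).
#' @return An `scfg_params` object with the accumulated counts attached
#'   as attribute `"counts"`.
#' @export
ml_estimate <- function(data, grammar = "G6", pseudocount = 0) {
  check_seq_tbl(data, need_structure = TRUE)
  grammar <- check_grammar(grammar)
  ref <- uniform_params(grammar)
  rules <- if (grammar == "G6") {
    c(SLS = 0, SL = 0, LaFb = 0, La = 0, FaFb = 0, FLS = 0)
  } else {
    c(aS = 0, aSbS = 0, eps = 0)
  }
  ps_counts <- numeric(4)
  pbp_counts <- matrix(0, 4, 4)
  for (r in seq_len(nrow(data))) {
    cc <- tryCatch(
      attr(score_parse(data$seq[r], data$structure[r], ref), "counts"),
      error = function(err) {
        abort(paste0("record '", data$id[r], "': ", conditionMessage(err)))
      })
    rules <- rules + cc$rules
    ps_counts <- ps_counts + cc$ps_counts
    pbp_counts <- pbp_counts + cc$pbp_counts
  }
  mle <- function(c1, c0) {
    c1 <- c1 + pseudocount; c0 <- c0 + pseudocount
    if (c1 + c0 == 0) return(0)
    c1 / (c1 + c0)
  }
  simplex <- function(x) {
    x <- x + pseudocount
    if (sum(x) == 0) return(rep(1 / length(x), length(x)))
    x / sum(x)
  }
  out <- if (grammar == "G6") {
    g6_params(tS = mle(rules[["SLS"]], rules[["SL"]]),
              tL = mle(rules[["LaFb"]], rules[["La"]]),
              tF = mle(rules[["FaFb"]], rules[["FLS"]]),
              ps = simplex(ps_counts),
              pbp = matrix(simplex(as.vector(pbp_counts)), 4, 4))
  } else {
    t3 <- simplex(c(rules[["aS"]], rules[["aSbS"]], rules[["eps"]]))
    g5_params(tu = t3[1], tp = t3[2], ps = simplex(ps_counts),
              pbp = matrix(simplex(as.vector(pbp_counts)), 4, 4))
  }
  attr(out, "counts") <- list(rules = rules, ps_counts = ps_counts,
                              pbp_counts = pbp_counts)
  out
}
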