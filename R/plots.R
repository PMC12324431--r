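# ggplot2 displays for fits, parameters, and posterior matrices.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_tile
#'   labs facet_wrap scale_fill_gradient theme_minimal coord_fixed
NULL

#' Plot an SGD training trajectory
#'
#' Loss (negative log-likelihood per sequence) against epoch; when the
#' fit recorded the full-training-set loss it is drawn alongside the
#' batch loss.
#'
#' @param object An `scfg_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot scfg_fit
#' @export
autoplot.scfg_fit <- function(object, ...) {
  traj <- object$trajectory
  long <- tidyr::pivot_longer(traj, -"epoch", names_to = "which",
                              values_to = "nll")
  ggplot(long, aes(x = .data$epoch, y = .data$nll,
                   colour = .data$which)) +
    geom_line() +
    labs(x = "epoch", y = "negative log-likelihood / sequence",
         colour = NULL,
         title = sprintf("%s training (%d sequences)",
                         object$config$grammar, object$config$n_train)) +
    theme_minimal()
}

#' Plot grammar parameters as probability bars
#'
#' One panel per distribution (transitions, single-nucleotide
#' emissions, base-pair emissions), mirroring the way trained pair
#' probabilities are usually displayed to show whether canonical
#' base-pairing has emerged.
#'
#' @param object An `scfg_params`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot scfg_params
#' @export
autoplot.scfg_params <- function(object, ...) {
  td <- tidy(object)
  td$term <- factor(td$term, levels = unique(td$term))
  ggplot(td, aes(x = .data$term, y = .data$estimate)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~component, scales = "free_x") +
    labs(x = NULL, y = "probability") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a base-pair posterior matrix
#'
#' Upper-triangular heat map of pairing posteriors (a probability
#' dot-plot).
#'
#' @param object An `scfg_posterior`.
#' @param min_prob Hide entries below this posterior (default 1e-3).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot scfg_posterior
#' @export
autoplot.scfg_posterior <- function(object, min_prob = 1e-3, ...) {
  td <- tidy(object, min_prob = min_prob)
  ggplot(td, aes(x = .data$j, y = .data$i, fill = .data$prob)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "darkred", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    coord_fixed() +
    labs(x = "position j", y = "position i", fill = "P(i:j)") +
    theme_minimal()
}
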