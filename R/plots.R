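#' @describeIn consensus_cluster PAC and consensus-CDF diagnostics for
#'   choosing the number of classes.
#' @param object A `consensus_result`.
#' @param ... Ignored.
#' @method autoplot consensus_result
#' @export
autoplot.consensus_result <- function(object, ...) {
  ggplot2::ggplot(object$cdf,
                  ggplot2::aes(x = .data$value, y = .data$cdf,
                               colour = factor(.data$k))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "consensus index", y = "CDF", colour = "k",
                  title = paste0("Consensus CDF (chosen k = ", object$chosen_k, ")"),
                  subtitle = paste0(
                    "PAC: ",
                    paste(object$metrics$k, signif(object$metrics$pac, 3),
                          sep = "=", collapse = "  "))) +
    ggplot2::theme_minimal()
}

#' @describeIn snr_scores Signal-to-noise score versus gene rank, the
#'   diagnostic used to pick classifier marker panels.
#' @param object An `snr_table`.
#' @param ... Ignored.
#' @method autoplot snr_table
#' @export
autoplot.snr_table <- function(object, ...) {
  classes <- attr(object, "classes")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank_a, y = .data$snr)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = paste0("gene rank (", classes[1], " direction)"),
                  y = "signal-to-noise ratio",
                  title = "SNR score versus gene rank") +
    ggplot2::theme_minimal()
}

#' @describeIn core37_score Component scatter of the two signature scores,
#'   colored by the unified score.
#' @param object A `core_score` tibble.
#' @param ... Ignored.
#' @method autoplot core_score
#' @export
autoplot.core_score <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$c1_component, y = .data$c2_component,
                               colour = .data$unified)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient2(low = "#2166ac", mid = "grey85",
                                    high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = "C1-like score", y = "C2-like score",
                  colour = "unified", title = "Signature component scores") +
    ggplot2::theme_minimal()
}

#' @describeIn time_dependent_auc AUC(t) by horizon.
#' @param object A `td_auc` tibble.
#' @param ... Ignored.
#' @method autoplot td_auc
#' @export
autoplot.td_auc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$years, y = .data$auc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "years since resection", y = "IPCW AUC(t)",
                  title = "Time-dependent discrimination") +
    ggplot2::theme_minimal()
}
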