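#' Plot a beta sweep: coverage-accuracy trade-off
#'
#' Two stacked panels over the (log-scaled) entropy threshold: weighted
#' average accuracy on included images, and abstain percentage. The AP
#' curve is non-increasing by construction; reading the two panels together
#' shows the price in coverage paid for each accuracy level.
#'
#' @param object A [beta_sweep()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.beta_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("waa", "ap"),
                              names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric, levels = c("waa", "ap"),
                        labels = c("WAA (included images)", "Abstain %"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$beta, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = expression(beta ~ "(bits, log scale)"), y = NULL,
                  title = "Elastic ensemble: accuracy vs. coverage") +
    ggplot2::theme_minimal()
}

#' Plot the confusion matrix of an elastic evaluation
#'
#' Tile heat map of the truth-by-prediction counts over non-abstained
#' images.
#'
#' @param object An [evaluate_folds()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.elastic_eval <- function(object, ...) {
  if (is.null(object$metrics)) {
    stop_parameter("nothing to plot: every image abstained")
  }
  conf <- attr(object$metrics, "confusion")
  df <- as_tibble(as.data.frame(as.table(conf)))
  names(df) <- c("truth", "prediction", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "#4a6fa5") +
    ggplot2::labs(x = "Predicted grade", y = "True grade",
                  title = sprintf("Confusion over included images (beta = %s bits)",
                                  format(object$beta))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot per-member entropy distributions
#'
#' Box plots of the Shannon entropies each member produced across images,
#' with the gating threshold drawn as a horizontal line. Members whose
#' boxes sit below the line drive the elastic selection; members entirely
#' above it never contribute.
#'
#' @param predictions A [predict_members()]-shaped tibble over many images.
#' @param beta Optional threshold to draw.
#' @return A ggplot object.
#' @export
plot_member_entropy <- function(predictions, beta = NULL) {
  p <- ggplot2::ggplot(predictions,
                       ggplot2::aes(x = .data$member_id,
                                    y = .data$entropy_bits)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "Ensemble member", y = "Shannon entropy (bits)",
                  title = "Per-member output entropy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(beta)) {
    p <- p + ggplot2::geom_hline(yintercept = beta, linetype = "dashed",
                                 color = "#b03030")
  }
  p
}
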