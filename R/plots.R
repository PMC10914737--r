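#' Plot a joint confusion matrix as a heat map
#'
#' @param object A `"full_confusion"` matrix.
#' @param normalize Normalize counts within each label row.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.full_confusion <- function(object, normalize = FALSE, ...) {
  df <- tidy.full_confusion(object)
  if (normalize) {
    df <- dplyr::mutate(df, n = n / pmax(sum(n), 1), .by = "label")
  }
  rn <- rownames(unclass(object))
  cn <- colnames(unclass(object))
  df$label <- factor(df$label, levels = rev(rn))
  df$pred <- factor(df$pred, levels = cn)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$label,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$n > 0,
                                                   signif(.data$n, 3), "")),
                       size = 2.6) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "labeled", fill = if (normalize)
      "fraction" else "count") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a training curve
#'
#' @param object A fitted `"har_cnn"` or `"adl_net"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adl_net <- function(object, ...) {
  h <- tidy.adl_net(object)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "masked balanced BCE") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.adl_net
#' @export
autoplot.har_cnn <- function(object, ...) {
  h <- tidy.har_cnn(object)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "weighted cross-entropy") +
    ggplot2::theme_minimal()
}

#' Plot a session's predicted ADL probabilities over time
#'
#' @param pred Output of [predict_session()].
#' @param threshold Optional horizontal threshold line.
#' @return A ggplot object, one facet per ADL.
#' @export
plot_session_predictions <- function(pred, threshold = 0.5) {
  long <- tidyr::pivot_longer(pred, cols = -"t", names_to = "adl",
                              values_to = "p")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t / 60, y = .data$p)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                        colour = "grey50") +
    ggplot2::facet_wrap(~adl, ncol = 3) +
    ggplot2::labs(x = "time (min)", y = "probability") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
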