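#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted low-level activity CNN
#'
#' @param x A `"har_cnn"`.
#' @param ... Unused.
#' @return The training history as a tibble (`epoch`, `loss`, `accuracy`).
#' @export
tidy.har_cnn <- function(x, ...) {
  x$history %||% tibble::tibble(epoch = integer(), loss = numeric(),
                                accuracy = numeric())
}

#' @rdname tidy.har_cnn
#' @export
glance.har_cnn <- function(x, ...) {
  n_params <- sum(vapply(collect_params(x$layers), length, integer(1)))
  h <- x$history
  tibble::tibble(
    n_classes = length(x$classes),
    input_len = x$cfg$input_len,
    n_parameters = n_params,
    epochs_trained = if (is.null(h)) 0L else nrow(h),
    final_loss = if (is.null(h) || nrow(h) == 0) NA_real_ else
      h$loss[nrow(h)],
    final_accuracy = if (is.null(h) || nrow(h) == 0) NA_real_ else
      h$accuracy[nrow(h)]
  )
}

#' Tidy a fitted ADL sequence network
#'
#' @param x An `"adl_net"`.
#' @param ... Unused.
#' @return The training history as a tibble (`epoch`, `loss`).
#' @export
tidy.adl_net <- function(x, ...) {
  x$history %||% tibble::tibble(epoch = integer(), loss = numeric())
}

#' @rdname tidy.adl_net
#' @export
glance.adl_net <- function(x, ...) {
  n_params <- sum(vapply(collect_params(x$layers), length, integer(1)))
  h <- x$history
  tibble::tibble(
    use_lstm = x$cfg$use_lstm,
    lstm_units = if (x$cfg$use_lstm) x$cfg$lstm_units else 0L,
    n_features = x$n_features,
    n_parameters = n_params,
    epochs_trained = if (is.null(h)) 0L else nrow(h),
    final_loss = if (is.null(h) || nrow(h) == 0) NA_real_ else h$loss[nrow(h)]
  )
}

#' Tidy a full confusion matrix into long format
#'
#' @param x A `"full_confusion"`.
#' @param ... Unused.
#' @return A tibble with columns `label`, `pred`, `n`.
#' @export
tidy.full_confusion <- function(x, ...) {
  df <- as.data.frame(as.table(unclass(x)), stringsAsFactors = FALSE)
  names(df) <- c("label", "pred", "n")
  tibble::as_tibble(df)
}
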