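#' Temporally smooth a probability series
#'
#' Replaces each probability vector by the arithmetic mean of the vectors in a
#' centered window of `kernel` grid steps (truncated at the edges). Means of
#' simplex vectors are simplex vectors, so the output still sums to 1 per row.
#' `kernel = 1` is the identity.
#'
#' @param series A [prob_series()].
#' @param kernel Odd window length in grid steps.
#' @return A smoothed [prob_series()] on the same grid.
#' @export
smooth_predictions <- function(series, kernel = 3) {
  if (kernel %% 2 == 0 || kernel < 1) {
    stop("kernel must be odd and >= 1", call. = FALSE)
  }
  if (kernel == 1 || nrow(series) == 0) return(series)
  m <- prob_matrix(series)
  n <- nrow(m)
  half <- (kernel - 1) / 2
  cs <- rbind(0, apply(m, 2, cumsum))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  out <- (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
  prob_series(series$t, out, prob_classes(series))
}

#' Aggregate a probability series to per-minute labels
#'
#' For each minute, the probability vectors of the grid steps starting inside
#' it are averaged and the label is the argmax of the mean vector, with ties
#' broken by the declared class order. Minutes containing no grid step are
#' labeled missing (`NA`).
#'
#' @param series A [prob_series()] whose grid step divides 60 s evenly.
#' @param t0 Start of the first minute (default 0).
#' @param t_end End of the covered span; defaults to the last grid step's end.
#' @return A tibble with columns `minute_start` and `label`.
#' @export
aggregate_to_minutes <- function(series, t0 = 0, t_end = NULL) {
  step <- prob_step(series)
  if (!is.na(step) && abs(60 / step - round(60 / step)) > 1e-9) {
    stop("grid step must divide 60 s evenly", call. = FALSE)
  }
  if (is.null(t_end)) {
    t_end <- if (nrow(series) > 0) max(series$t) + (step %||% 60) else t0
  }
  n_min <- max(ceiling((t_end - t0) / 60), 0)
  classes <- prob_classes(series)
  m <- prob_matrix(series)
  starts <- t0 + (seq_len(n_min) - 1) * 60
  labels <- vapply(starts, function(m0) {
    inside <- series$t >= m0 & series$t < m0 + 60
    if (!any(inside)) return(NA_character_)
    mv <- colMeans(m[inside, , drop = FALSE])
    classes[which.max(mv)] # which.max takes the first maximum: declared order
  }, character(1))
  tibble::tibble(minute_start = starts, label = labels)
}

#' Drop running minutes from the low-level training labels
#'
#' Running is irrelevant for ADL detection and too rare to train on, so
#' running minutes become missing (`NA`) and are excluded from training.
#'
#' @param labels A minute-label tibble from [aggregate_to_minutes()].
#' @return The labels with running minutes set to `NA`. Warns when nothing
#'   labeled remains.
#' @export
drop_running <- function(labels) {
  out <- labels
  out$label[out$label == "running"] <- NA_character_
  if (nrow(out) > 0 && all(is.na(out$label))) {
    warning("no labeled minutes remain after dropping running")
  }
  out
}

`%||%` <- function(x, y) if (is.null(x) || (length(x) == 1 && is.na(x))) y else x
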