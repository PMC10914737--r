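#' Activity probability series
#'
#' A probability series holds one probability vector over a fixed class set per
#' time step on a regular grid: a tibble with column `t` (grid start times,
#' constant step) and one `p_<class>` column per class. Every row is a valid
#' probability simplex.
#'
#' @param t Numeric vector of grid times (constant step).
#' @param probs Numeric matrix, `length(t)` rows, one column per class.
#' @param classes Ordered class names.
#' @return A tibble of class `"prob_series"` with attributes `classes` and
#'   `step`.
#' @export
prob_series <- function(t, probs, classes) {
  probs <- as.matrix(probs)
  stopifnot(length(t) == nrow(probs), ncol(probs) == length(classes))
  if (nrow(probs) > 0) {
    if (any(probs < -1e-9)) stop("probabilities must be non-negative",
                                 call. = FALSE)
    sums <- rowSums(probs)
    if (any(abs(sums - 1) > 1e-6)) {
      stop("probability rows must sum to 1 (max deviation ",
           signif(max(abs(sums - 1)), 3), ")", call. = FALSE)
    }
    if (length(t) > 1) {
      steps <- diff(t)
      if (max(abs(steps - steps[1])) > 1e-9) {
        stop("grid step must be constant", call. = FALSE)
      }
    }
  }
  step <- if (length(t) > 1) t[2] - t[1] else NA_real_
  out <- tibble::as_tibble(as.data.frame(probs))
  names(out) <- paste0("p_", gsub(" ", "_", classes))
  out <- tibble::add_column(out, t = t, .before = 1)
  structure(out, classes = classes, step = step,
            class = c("prob_series", class(tibble::tibble())))
}

#' @export
print.prob_series <- function(x, ...) {
  cat("<prob_series> classes:", paste(attr(x, "classes"), collapse = ", "),
      " step:", attr(x, "step"), "s\n")
  NextMethod()
}

prob_matrix <- function(series) {
  as.matrix(series[, paste0("p_", gsub(" ", "_", attr(series, "classes"))),
                   drop = FALSE])
}

prob_classes <- function(series) attr(series, "classes", exact = TRUE)

prob_step <- function(series) attr(series, "step", exact = TRUE)

#' Convert a wearable probability stream to a probability series
#'
#' The wearable stream arrives as a `wearable_probs` sensor series with
#' `p_<class>` columns every 7.5 s; this snaps it onto its regular grid and
#' renormalizes tiny numeric drift.
#'
#' @param series A `wearable_probs` [sensor_series()].
#' @param classes Class names in the column order; defaults to the five
#'   wearable low-level classes.
#' @return A [prob_series()].
#' @export
as_prob_series <- function(series, classes = lowlevel_classes(wearable = TRUE)) {
  cols <- paste0("p_", gsub(" ", "_", classes))
  missing_cols <- setdiff(cols, names(series))
  if (length(missing_cols) > 0) {
    stop("missing probability column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(series[, cols, drop = FALSE])
  m <- m / rowSums(m)
  prob_series(series$t, m, classes)
}

#' Resample a probability series onto a new grid step
#'
#' Last-observation-carried-forward onto a regular grid starting at `t0`.
#' Grid points before the first observation get the uniform vector.
#'
#' @param series A [prob_series()].
#' @param step Target grid step in seconds.
#' @param t0 Grid origin (default 0).
#' @param t_end End of the grid (exclusive); defaults to the last observation.
#' @return A [prob_series()] on the new grid.
#' @export
resample_probs <- function(series, step, t0 = 0, t_end = NULL) {
  classes <- prob_classes(series)
  if (is.null(t_end)) t_end <- max(series$t) + step
  grid <- seq(t0, t_end - 1e-9, by = step)
  m <- prob_matrix(series)
  idx <- findInterval(grid + 1e-9, series$t)
  out <- matrix(1 / length(classes), length(grid), length(classes))
  has <- idx >= 1
  out[has, ] <- m[idx[has], , drop = FALSE]
  prob_series(grid, out, classes)
}
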