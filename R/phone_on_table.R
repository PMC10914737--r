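#' Phone-on-table detection configuration
#'
#' Thresholds of the stationary-phone detector: over each window the mean of
#' the Z axis must exceed `z_mean_abs_min` in absolute value (phone flat,
#' screen up or down) and the standard deviation of each axis separately must
#' stay below `std_max` (no motion beyond sensor noise). All comparisons are
#' strict, so boundary values fail. Units are m/s² unless `units = "g"`, in
#' which case the thresholds are auto-scaled by 9.80665.
#'
#' @param window_s Window length in seconds.
#' @param z_mean_abs_min Minimum |mean(Z)| in m/s².
#' @param std_max Maximum per-axis standard deviation in m/s².
#' @param units `"ms2"` (default) or `"g"`.
#' @return A list of class `"on_table_config"`.
#' @export
on_table_config <- function(window_s = 1, z_mean_abs_min = 9, std_max = 0.7,
                            units = c("ms2", "g")) {
  units <- match.arg(units)
  stopifnot(window_s > 0, z_mean_abs_min > 0, std_max > 0)
  if (units == "g") {
    z_mean_abs_min <- z_mean_abs_min / 9.80665
    std_max <- std_max / 9.80665
  }
  structure(list(window_s = window_s, z_mean_abs_min = z_mean_abs_min,
                 std_max = std_max, units = units),
            class = "on_table_config")
}

#' Detect periods when the phone lies stationary on a surface
#'
#' Splits the accelerometer stream into consecutive windows of
#' `cfg$window_s` seconds and flags a window as "on table" when
#' `|mean(Z)| > z_mean_abs_min` **and** each axis' standard deviation is
#' `< std_max`. Windows with fewer than two samples cannot support a standard
#' deviation and are flagged `FALSE` with a warning.
#'
#' @param accel Accelerometer [sensor_series()].
#' @param cfg An [on_table_config()].
#' @return A tibble of class `"on_table_mask"` with columns `start` (window
#'   start time, consecutive at `window_s` spacing) and `on_table` (logical).
#' @export
#' @examples
#' acc <- sensor_series(
#'   data.frame(t = seq(0, 0.96875, by = 1/32), x = 0, y = 0, z = 9.81),
#'   "accelerometer")
#' detect_on_table(acc)
detect_on_table <- function(accel, cfg = on_table_config()) {
  stopifnot(series_modality(accel) == "accelerometer")
  if (nrow(accel) == 0) {
    return(structure(tibble::tibble(start = numeric(), on_table = logical()),
                     window_s = cfg$window_s,
                     class = c("on_table_mask", class(tibble::tibble()))))
  }
  t0 <- accel$t[1]
  win <- floor((accel$t - t0) / cfg$window_s)
  n_win <- max(win) + 1
  idx <- win + 1
  counts <- tabulate(idx, nbins = n_win)

  sum_by <- function(v) {
    out <- numeric(n_win)
    agg <- rowsum(v, idx)
    out[as.integer(rownames(agg))] <- agg
    out
  }
  n <- counts
  ok <- n >= 2
  if (any(!ok)) {
    warning(sum(!ok), " window(s) with < 2 samples: std undefined, flagged FALSE")
  }
  flags <- logical(n_win)
  stats_axis <- function(v) {
    s1 <- sum_by(v)
    s2 <- sum_by(v^2)
    mean_v <- ifelse(n > 0, s1 / n, NA_real_)
    # sample sd (n-1 denominator), guarded against tiny negative fp error
    var_v <- ifelse(n >= 2, pmax(s2 - n * mean_v^2, 0) / (n - 1), NA_real_)
    list(mean = mean_v, sd = sqrt(var_v))
  }
  sx <- stats_axis(accel$x)
  sy <- stats_axis(accel$y)
  sz <- stats_axis(accel$z)
  flags[ok] <- (abs(sz$mean[ok]) > cfg$z_mean_abs_min) &
    (sx$sd[ok] < cfg$std_max) & (sy$sd[ok] < cfg$std_max) &
    (sz$sd[ok] < cfg$std_max)
  structure(tibble::tibble(start = t0 + (seq_len(n_win) - 1) * cfg$window_s,
                           on_table = flags),
            window_s = cfg$window_s,
            class = c("on_table_mask", class(tibble::tibble())))
}

#' Overrule wrist-worn minute labels with on-table detections
#'
#' The wrist-worn wearable cannot see the phone, so minutes during which the
#' phone was detected stationary are relabeled `"on table"`. A minute is
#' overruled when the fraction of flagged detector windows inside it reaches
#' `min_fraction` (default: a majority of the minute).
#'
#' @param minute_labels A tibble with columns `minute_start` (seconds) and
#'   `label` (low-level class or `NA` for missing), as produced by
#'   [aggregate_to_minutes()].
#' @param mask An `"on_table_mask"` from [detect_on_table()].
#' @param min_fraction Fraction of flagged windows needed to overrule.
#' @return The minute labels with overruled minutes set to `"on table"`.
#' @export
overrule_with_on_table <- function(minute_labels, mask, min_fraction = 0.5) {
  stopifnot(all(c("minute_start", "label") %in% names(minute_labels)),
            min_fraction > 0, min_fraction <= 1)
  if (nrow(minute_labels) == 0) return(minute_labels)
  if (nrow(mask) == 0) {
    stop("mask does not cover the labeled span (empty mask)", call. = FALSE)
  }
  window_s <- attr(mask, "window_s", exact = TRUE)
  mask_end <- mask$start[nrow(mask)] + window_s
  span_lo <- min(minute_labels$minute_start)
  span_hi <- max(minute_labels$minute_start) + 60
  if (mask$start[1] >= span_hi || mask_end <= span_lo) {
    stop("mask and minute labels cover disjoint spans", call. = FALSE)
  }
  frac <- vapply(minute_labels$minute_start, function(m0) {
    inside <- mask$start >= m0 & mask$start < m0 + 60
    if (!any(inside)) return(0)
    mean(mask$on_table[inside])
  }, numeric(1))
  out <- minute_labels
  out$label[frac >= min_fraction] <- "on table"
  out
}
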