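#' Construct a sensor series
#'
#' A sensor series is a tibble of time-stamped samples for one modality of one
#' session: a column `t` (seconds since session start) plus the modality's
#' value columns (`x,y,z` for the accelerometer, `value` for scalar streams,
#' `event` for screen status, `app` for foreground apps, `room` for the
#' location sensor, `p_<class>` for wearable activity probabilities).
#' Timestamps are sorted ascending; among duplicated timestamps the last
#' occurrence wins (sensor retransmission convention).
#'
#' @param data A data frame with a `t` column and the modality's value columns.
#' @param modality Modality identifier, see [modality_registry()].
#' @param nominal_rate Nominal sampling rate in Hz, or `NA` for event streams.
#' @return A tibble of class `"sensor_series"` with attributes `modality` and
#'   `nominal_rate`.
#' @export
#' @examples
#' sensor_series(data.frame(t = c(0, 1, 2), value = c(5, 6, 7)), "step")
sensor_series <- function(data, modality, nominal_rate = NA_real_) {
  if (!is_registered_modality(modality)) {
    stop("modality '", modality, "' is not in the registry; see ",
         "modality_registry()", call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  if (!"t" %in% names(data)) stop("sensor series needs a 't' column",
                                  call. = FALSE)
  if (nrow(data) > 0) {
    if (any(!is.finite(data$t)) || any(data$t < 0)) {
      stop("timestamps must be finite and non-negative", call. = FALSE)
    }
    ord <- order(data$t)
    data <- data[ord, , drop = FALSE]
    # duplicate timestamps: keep last
    keep <- !duplicated(data$t, fromLast = TRUE)
    data <- data[keep, , drop = FALSE]
  }
  vc <- value_cols_for(modality)
  if (modality == "wearable_probs") {
    vc <- grep("^p_", names(data), value = TRUE)
    if (nrow(data) > 0 && length(vc) == 0) {
      stop("wearable_probs series needs p_<class> columns", call. = FALSE)
    }
  }
  missing_cols <- setdiff(vc, names(data))
  if (length(missing_cols) > 0) {
    stop("modality '", modality, "' requires column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  structure(data[, c("t", vc), drop = FALSE],
            modality = modality, nominal_rate = nominal_rate,
            class = c("sensor_series", class(tibble::tibble())))
}

#' @export
print.sensor_series <- function(x, ...) {
  cat("<sensor_series> modality:", attr(x, "modality"),
      " samples:", nrow(x), "\n")
  NextMethod()
}

series_modality <- function(x) attr(x, "modality", exact = TRUE)

#' Read one sensor stream from CSV
#'
#' Expected layout: a header row, a `timestamp` column and the modality's value
#' column(s) (`x,y,z` for the accelerometer; `value` for scalar streams;
#' `event` for screen; `app` for foreground apps; `room` for location;
#' `p_<class>` columns for wearable probabilities). Timestamps may be seconds
#' since session start or epoch milliseconds; values above `epoch_ms_cutoff`
#' are treated as epoch milliseconds and rebased to seconds since the first
#' sample.
#'
#' @param path CSV file path.
#' @param modality Modality identifier from the registry.
#' @param nominal_rate Declared rate in Hz (`NA` for event streams).
#' @param epoch_ms_cutoff Timestamps at or above this are read as epoch ms.
#' @return A [sensor_series()] sorted by time, with the original row count
#'   preserved (up to duplicate-timestamp deduplication).
#' @export
read_sensor_csv <- function(path, modality, nominal_rate = NA_real_,
                            epoch_ms_cutoff = 1e9) {
  if (!is_registered_modality(modality)) {
    stop("modality '", modality, "' is not in the registry", call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"timestamp" %in% names(df)) {
    stop("CSV ", path, " has no 'timestamp' column", call. = FALSE)
  }
  ts <- suppressWarnings(as.numeric(df$timestamp))
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop("unparseable timestamp at data row ", bad, " of ", path,
         call. = FALSE)
  }
  if (length(ts) > 0 && any(ts >= epoch_ms_cutoff)) {
    ts <- (ts - min(ts)) / 1000
  }
  df$timestamp <- NULL
  df <- tibble::as_tibble(df)
  df$t <- ts
  sensor_series(df, modality, nominal_rate = nominal_rate)
}

#' Write one sensor stream to CSV
#'
#' Inverse of [read_sensor_csv()]: writes `timestamp` (seconds) plus the value
#' columns, so a read-write-read cycle round-trips.
#'
#' @param series A [sensor_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sensor_csv <- function(series, path) {
  df <- as.data.frame(series)
  names(df)[names(df) == "t"] <- "timestamp"
  df <- df[, c("timestamp", setdiff(names(df), "timestamp")), drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundle the streams of one recording session
#'
#' @param participant_id Non-empty participant identifier.
#' @param streams Named list of [sensor_series()]; names are modalities.
#' @param adl_labels Tibble of self-reported label entries with columns
#'   `start`, `end` (seconds) and `adls` (list-column of character vectors, the
#'   ADL names as reported).
#' @param duration Session duration in seconds; defaults to the latest
#'   timestamp across streams and labels.
#' @return A list of class `"session_bundle"`.
#' @export
session_bundle <- function(participant_id, streams, adl_labels = NULL,
                           duration = NULL) {
  stopifnot(is.character(participant_id), nzchar(participant_id))
  stopifnot(is.list(streams))
  if (length(streams) > 0 && is.null(names(streams))) {
    stop("streams must be a named list (names = modalities)", call. = FALSE)
  }
  for (nm in names(streams)) {
    s <- streams[[nm]]
    if (!inherits(s, "sensor_series")) {
      stop("stream '", nm, "' is not a sensor_series", call. = FALSE)
    }
  }
  if (is.null(adl_labels)) {
    adl_labels <- tibble::tibble(start = numeric(), end = numeric(),
                                 adls = list())
  }
  adl_labels <- tibble::as_tibble(adl_labels)
  stopifnot(all(c("start", "end", "adls") %in% names(adl_labels)))
  if (nrow(adl_labels) > 0 && any(adl_labels$start >= adl_labels$end)) {
    stop("label entries must have start < end", call. = FALSE)
  }
  if (is.null(duration)) {
    tmax <- vapply(streams, function(s) if (nrow(s) > 0) max(s$t) else 0,
                   numeric(1))
    duration <- max(c(tmax, adl_labels$end, 0))
  }
  bad <- vapply(streams, function(s) nrow(s) > 0 && max(s$t) > duration,
                logical(1))
  if (any(bad)) {
    stop("stream(s) ", paste(names(streams)[bad], collapse = ", "),
         " have samples beyond the declared duration", call. = FALSE)
  }
  structure(list(participant_id = participant_id, streams = streams,
                 adl_labels = adl_labels, duration = duration),
            class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  cat("<session_bundle> participant:", x$participant_id,
      " duration:", round(x$duration, 1), "s\n")
  cat("  streams:", paste(names(x$streams), collapse = ", "), "\n")
  cat("  label entries:", nrow(x$adl_labels), "\n")
  invisible(x)
}

#' Slice a series into fixed-length windows
#'
#' Windows are half-open `[start, start + window_s)`: a sample exactly at the
#' right edge belongs to the next window. For a series spanning `T` seconds
#' (from its first to its last sample) the window count is
#' `floor((T - window_s) / stride_s) + 1`; a series shorter than one window
#' yields an empty result.
#'
#' @param series A [sensor_series()].
#' @param window_s Window length in seconds (> 0).
#' @param stride_s Stride in seconds (> 0).
#' @return A tibble with columns `start` (window start time) and `samples`
#'   (list-column of tibbles holding each window's rows).
#' @export
#' @examples
#' s <- sensor_series(data.frame(t = 0:12, value = 0), "step")
#' slice_windows(s, 6, 3)$start
slice_windows <- function(series, window_s, stride_s) {
  stopifnot(window_s > 0, stride_s > 0)
  if (nrow(series) == 0) {
    return(tibble::tibble(start = numeric(), samples = list()))
  }
  t0 <- series$t[1]
  span <- series$t[nrow(series)] - t0
  if (span < window_s) {
    return(tibble::tibble(start = numeric(), samples = list()))
  }
  n_win <- floor((span - window_s) / stride_s + 1e-9) + 1
  starts <- t0 + (seq_len(n_win) - 1) * stride_s
  samples <- lapply(starts, function(s0) {
    series[series$t >= s0 & series$t < s0 + window_s, , drop = FALSE]
  })
  tibble::tibble(start = starts, samples = samples)
}

#' Resample an accelerometer stream onto its nominal grid
#'
#' Component-wise linear interpolation onto a regular `1/rate` grid, applied
#' when timestamp jitter exceeds `jitter_tol` (relative deviation of observed
#' sampling intervals from the nominal interval). Streams already on-grid are
#' returned unchanged.
#'
#' @param series Accelerometer [sensor_series()].
#' @param rate Target rate in Hz (default 32, the rate implied by 192 samples
#'   per 6-second window).
#' @param jitter_tol Relative jitter above which resampling kicks in.
#' @return A [sensor_series()] on the regular grid.
#' @export
resample_accel <- function(series, rate = 32, jitter_tol = 0.1) {
  stopifnot(series_modality(series) == "accelerometer")
  n <- nrow(series)
  if (n < 2) return(series)
  dt <- diff(series$t)
  nominal <- 1 / rate
  if (max(abs(dt - nominal)) <= jitter_tol * nominal) return(series)
  grid <- seq(series$t[1], series$t[n], by = nominal)
  out <- tibble::tibble(
    t = grid,
    x = stats::approx(series$t, series$x, xout = grid, rule = 2)$y,
    y = stats::approx(series$t, series$y, xout = grid, rule = 2)$y,
    z = stats::approx(series$t, series$z, xout = grid, rule = 2)$y
  )
  sensor_series(out, "accelerometer", nominal_rate = rate)
}

#' Read a session from a manifest
#'
#' The manifest is a YAML file mapping each modality to a CSV path (relative
#' to the manifest) and an optional declared rate:
#' ```yaml
#' participant_id: P01
#' duration: 5400
#' streams:
#'   accelerometer: {path: accel.csv, rate: 32}
#'   location: {path: location.csv}
#' labels: labels.csv
#' ```
#' The labels CSV has columns `start,end,adls` with ADL names separated by
#' `|` inside `adls`.
#'
#' @param manifest_path Path to the YAML manifest.
#' @return A [session_bundle()].
#' @export
read_session <- function(manifest_path) {
  man <- yaml::read_yaml(manifest_path)
  base <- dirname(manifest_path)
  streams <- list()
  for (modality in names(man$streams)) {
    entry <- man$streams[[modality]]
    rate <- if (!is.null(entry$rate)) as.numeric(entry$rate) else NA_real_
    streams[[modality]] <- read_sensor_csv(file.path(base, entry$path),
                                           modality, nominal_rate = rate)
  }
  adl_labels <- NULL
  if (!is.null(man$labels)) {
    lab <- utils::read.csv(file.path(base, man$labels),
                           stringsAsFactors = FALSE)
    adl_labels <- tibble::tibble(
      start = as.numeric(lab$start), end = as.numeric(lab$end),
      adls = strsplit(lab$adls, "|", fixed = TRUE)
    )
  }
  session_bundle(man$participant_id, streams, adl_labels = adl_labels,
                 duration = if (!is.null(man$duration))
                   as.numeric(man$duration) else NULL)
}

#' Write a session to a directory as CSV files plus a manifest
#'
#' @param session A [session_bundle()].
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- list(participant_id = session$participant_id,
              duration = session$duration, streams = list())
  for (modality in names(session$streams)) {
    fn <- paste0(modality, ".csv")
    write_sensor_csv(session$streams[[modality]], file.path(dir, fn))
    rate <- attr(session$streams[[modality]], "nominal_rate")
    man$streams[[modality]] <- if (is.na(rate)) list(path = fn) else
      list(path = fn, rate = rate)
  }
  if (nrow(session$adl_labels) > 0) {
    lab <- data.frame(
      start = session$adl_labels$start, end = session$adl_labels$end,
      adls = vapply(session$adl_labels$adls, paste, character(1),
                    collapse = "|")
    )
    utils::write.csv(lab, file.path(dir, "labels.csv"), row.names = FALSE,
                     quote = FALSE)
    man$labels <- "labels.csv"
  }
  manifest <- file.path(dir, "session.yaml")
  yaml::write_yaml(man, manifest)
  invisible(manifest)
}
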