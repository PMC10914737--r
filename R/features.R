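#' Reconstruct app usage intervals from foreground and screen events
#'
#' The phone logs an entry whenever a new app comes to the foreground; apps
#' disappear from the foreground either because the user switches apps or
#' because the screen locks / turns off. The reconstruction follows five
#' steps: (1) drop foreground entries for system utilities (e.g. the
#' keyboard); (2) insert `Off` entries at every screen `off` / `locked` event;
#' (3) sort ascending by time; (4) set each entry's end to the next entry's
#' timestamp; (5) drop the `Off` entries. What remains are the periods of
#' active smartphone use. Consecutive entries of the same app are merged
#' (foreground re-notifications).
#'
#' @param apps An `app` [sensor_series()] (columns `t`, `app`) or a tibble with
#'   those columns.
#' @param screens A `screen` [sensor_series()] (columns `t`, `event` with
#'   states on/off/locked/unlocked), or `NULL`.
#' @param system_utils Character vector of app names to filter out; defaults
#'   to [default_system_utils()].
#' @return A tibble with columns `app`, `start`, `end`; intervals are
#'   non-overlapping and ordered.
#' @export
#' @examples
#' apps <- tibble::tibble(t = c(0, 30), app = c("mail", "browser"))
#' screens <- tibble::tibble(t = 50, event = "locked")
#' reconstruct_usage_intervals(apps, screens)
reconstruct_usage_intervals <- function(apps, screens = NULL,
                                        system_utils = default_system_utils()) {
  apps <- tibble::as_tibble(apps)[, c("t", "app")]
  # step 1: filter system utilities
  apps <- apps[!apps$app %in% system_utils, , drop = FALSE]
  # step 2: insert Off entries at screen lock / off events
  off_t <- numeric()
  if (!is.null(screens)) {
    screens <- tibble::as_tibble(screens)
    off_t <- screens$t[screens$event %in% c("off", "locked")]
  }
  entries <- dplyr::bind_rows(
    tibble::tibble(t = apps$t, app = apps$app),
    tibble::tibble(t = off_t, app = ".off")
  )
  if (nrow(entries) == 0) {
    return(tibble::tibble(app = character(), start = numeric(),
                          end = numeric()))
  }
  # step 3: sort ascending (Off entries before app entries at equal times, so
  # an app opened at the lock instant starts a new interval)
  entries <- entries[order(entries$t, entries$app != ".off"), , drop = FALSE]
  # a re-notification of the app already in the foreground does not start a
  # new interval: drop entries repeating their predecessor (Off kept)
  if (nrow(entries) > 1) {
    dup <- c(FALSE, entries$app[-1] == entries$app[-nrow(entries)] &
               entries$app[-1] != ".off")
    entries <- entries[!dup, , drop = FALSE]
  }
  # step 4: end = successor's timestamp; the last entry has no successor and
  # is dropped unless it is an Off entry (an open-ended final app would have
  # an unknown end)
  n <- nrow(entries)
  entries$end <- c(entries$t[-1], NA_real_)
  # step 5: drop Off entries and zero-length or open-ended intervals
  out <- entries[entries$app != ".off" & !is.na(entries$end) &
                   entries$end > entries$t, , drop = FALSE]
  tibble::tibble(app = out$app, start = as.numeric(out$t),
                 end = as.numeric(out$end))
}

#' Default system-utility app list
#'
#' Apps that come to the foreground without implying smartphone use (input
#' methods, launchers, system UI). Shipped as a plain-text file; users can
#' supply their own list via `reconstruct_usage_intervals(system_utils = )` or
#' [read_system_utils()].
#'
#' @return Character vector of app names.
#' @export
default_system_utils <- function() {
  path <- system.file("extdata", "system_utils.txt", package = "adlsense")
  if (nzchar(path)) read_system_utils(path) else c("keyboard", "launcher",
                                                   "systemui")
}

#' Read a system-utility list from a plain-text file (one app name per line)
#'
#' @param path File path.
#' @return Character vector of app names.
#' @export
read_system_utils <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Binary phone-usage feature
#'
#' 1 when `t` falls inside some usage interval (half-open `[start, end)`),
#' else 0.
#'
#' @param intervals Tibble from [reconstruct_usage_intervals()].
#' @param t Numeric vector of query times.
#' @return Integer vector of 0/1.
#' @export
phone_usage_feature <- function(intervals, t) {
  if (nrow(intervals) == 0) return(integer(length(t)))
  out <- integer(length(t))
  for (i in seq_len(nrow(intervals))) {
    out[t >= intervals$start[i] & t < intervals$end[i]] <- 1L
  }
  out
}

#' Step count per feature bin
#'
#' Counts step-detector events in each half-open bin `[t, t + bin_s)`.
#'
#' @param steps A `step` [sensor_series()] of point events.
#' @param t Bin start times.
#' @param bin_s Bin width in seconds (default 3).
#' @return Integer vector of counts.
#' @export
step_feature <- function(steps, t, bin_s = 3) {
  if (nrow(steps) == 0) return(integer(length(t)))
  lo <- findInterval(t - 1e-9, steps$t)
  hi <- findInterval(t + bin_s - 1e-9, steps$t)
  as.integer(hi - lo)
}

#' Mean ambient light per feature bin
#'
#' Arithmetic mean of the 1 Hz lux samples in each half-open bin; empty bins
#' carry the last known sample forward, and bins before any sample are 0.
#'
#' @param light A `light_phone` (or `light_<room>`) [sensor_series()].
#' @param t Bin start times.
#' @param bin_s Bin width in seconds.
#' @return Numeric vector of mean lux values.
#' @export
light_mean_feature <- function(light, t, bin_s = 3) {
  if (nrow(light) == 0) return(numeric(length(t)))
  cs <- c(0, cumsum(light$value))
  lo <- findInterval(t - 1e-9, light$t)
  hi <- findInterval(t + bin_s - 1e-9, light$t)
  n <- hi - lo
  out <- numeric(length(t))
  has <- n > 0
  out[has] <- (cs[hi[has] + 1] - cs[lo[has] + 1]) / n[has]
  # carry last known value into empty bins; 0 before the first sample
  carry <- light$value[pmax(lo, 1)]
  carry[lo == 0] <- 0
  out[!has] <- carry[!has]
  out
}

#' Scale lux values for model input
#'
#' Raw lux is unbounded; values are passed through `log1p` and min-max scaled
#' against a fixed ceiling (default 10,000 lux, bright daylight indoors).
#'
#' @param lux Numeric vector of lux values.
#' @param ceiling_lux The lux value mapping to 1.
#' @return Values in `[0, 1]` (clipped at the ceiling).
#' @export
scale_lux <- function(lux, ceiling_lux = 1e4) {
  pmin(log1p(pmax(lux, 0)) / log1p(ceiling_lux), 1)
}

#' Normalized time since the last trigger event
#'
#' `min(t - t_last, cap) / cap` where `t_last` is the latest trigger at or
#' before `t`; with no prior event the feature is 1 (an appliance unused for
#' at least the cap is indistinguishable from never used). The default cap is
#' 12 hours.
#'
#' @param events Numeric vector of trigger times, or a [sensor_series()] whose
#'   `t` column holds them.
#' @param t Query times.
#' @param cap Normalization period in seconds (default 43,200 s = 12 h).
#' @return Numeric vector in `[0, 1]`.
#' @export
elapsed_since_feature <- function(events, t, cap = 43200) {
  stopifnot(cap > 0)
  ev <- if (is.data.frame(events)) events$t else events
  if (length(ev) == 0) return(rep(1, length(t)))
  ev <- sort(ev)
  idx <- findInterval(t + 1e-9, ev)
  out <- rep(1, length(t))
  has <- idx >= 1
  out[has] <- pmin(t[has] - ev[idx[has]], cap) / cap
  out
}

#' Convert an appliance power stream to usage trigger times
#'
#' The power meter is used only as a binary switch: a trigger is emitted at
#' every upward crossing of `on_threshold`, and (by default) throughout any
#' above-threshold period the appliance counts as in use, so additional
#' triggers are emitted on the power grid while the appliance stays on.
#'
#' @param power A `power_<appliance>` [sensor_series()] with watt values.
#' @param on_threshold Power threshold in watts.
#' @param during_use If `TRUE` (default), every above-threshold sample is a
#'   trigger; if `FALSE`, only rising edges are.
#' @return Numeric vector of trigger times.
#' @export
power_to_events <- function(power, on_threshold = 5, during_use = TRUE) {
  stopifnot(on_threshold > 0)
  if (nrow(power) == 0) return(numeric())
  on <- power$value > on_threshold
  if (during_use) return(power$t[on])
  rising <- on & !c(FALSE, on[-length(on)])
  power$t[rising]
}

#' Room-location feature
#'
#' The room the person is in at time `t`: the last location event at or before
#' `t`, or `"unknown"` before any event.
#'
#' @param locs A `location` [sensor_series()] (columns `t`, `room`).
#' @param t Query times.
#' @param rooms Registered room names (from [home_config()]).
#' @return Factor with levels `c(rooms, "unknown")`.
#' @export
room_location_feature <- function(locs, t, rooms = home_config()$rooms) {
  if (nrow(locs) > 0) {
    bad <- setdiff(unique(locs$room), rooms)
    if (length(bad) > 0) {
      stop("unregistered room(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  out <- rep("unknown", length(t))
  if (nrow(locs) > 0) {
    idx <- findInterval(t + 1e-9, locs$t)
    has <- idx >= 1
    out[has] <- locs$room[idx[has]]
  }
  factor(out, levels = c(rooms, "unknown"))
}

#' Binary room-light feature
#'
#' The last on/off state at or before `t` (1 = on); 0 before any event.
#'
#' @param light_state A `light_<room>` [sensor_series()] with `value` 0/1.
#' @param t Query times.
#' @return Integer vector of 0/1.
#' @export
room_light_binary <- function(light_state, t) {
  out <- integer(length(t))
  if (nrow(light_state) > 0) {
    idx <- findInterval(t + 1e-9, light_state$t)
    has <- idx >= 1
    out[has] <- as.integer(light_state$value[idx[has]] > 0)
  }
  out
}

#' The eight feature-combination presets
#'
#' @return Character vector of the preset names.
#' @export
feature_presets <- function() {
  c("probs_only", "probs_phone_steps", "probs_appliances", "probs_all_phone",
    "probs_location", "all", "all_except_location", "ambient_only")
}

preset_groups <- function(preset) {
  switch(preset,
    probs_only          = "probs",
    probs_phone_steps   = c("probs", "phone_usage", "steps"),
    probs_appliances    = c("probs", "appliances"),
    probs_all_phone     = c("probs", "phone_usage", "steps", "light_phone"),
    probs_location      = c("probs", "location"),
    all                 = c("probs", "phone_usage", "steps", "light_phone",
                            "appliances", "room_lights", "location"),
    all_except_location = c("probs", "phone_usage", "steps", "light_phone",
                            "appliances", "room_lights"),
    ambient_only        = c("appliances", "room_lights", "location"),
    stop("unknown preset '", preset, "'; see feature_presets()", call. = FALSE)
  )
}

#' Build the per-session ADL feature matrix
#'
#' Constructs the full feature matrix on the 3-second grid for one session and
#' one preset. Columns per group: `probs` = the low-level activity
#' probabilities; `phone_usage` = binary active-use; `steps` = step count per
#' bin; `light_phone` = scaled mean lux; `appliances` = normalized time since
#' the fridge and each monitored appliance was last used; `room_lights` =
#' binary light state per monitored room; `location` = one-hot room (registry
#' rooms + unknown).
#'
#' @param session A [session_bundle()].
#' @param probs Low-level activity [prob_series()] on (or resampled to) the
#'   3-second grid.
#' @param preset One of [feature_presets()].
#' @param home A [home_config()].
#' @param step_s Feature grid step (3 s).
#' @return A list of class `"feature_matrix"`: `t` (grid), `x` (T x F matrix),
#'   `feature_names`, `preset`.
#' @export
build_feature_matrix <- function(session, probs, preset = "probs_only",
                                 home = home_config(), step_s = 3) {
  groups <- preset_groups(preset)
  t_grid <- seq(0, session$duration - step_s + 1e-9, by = step_s)
  cols <- list()
  nms <- character()
  need <- function(modality) {
    s <- session$streams[[modality]]
    if (is.null(s)) {
      stop("preset '", preset, "' requires modality '", modality,
           "' which is missing from the session", call. = FALSE)
    }
    s
  }
  if ("probs" %in% groups) {
    if (is.null(probs)) stop("preset '", preset,
                             "' requires low-level probabilities",
                             call. = FALSE)
    ps <- resample_probs(probs, step = step_s, t0 = 0,
                         t_end = session$duration)
    m <- prob_matrix(ps)[seq_along(t_grid), , drop = FALSE]
    cols <- c(cols, list(m))
    nms <- c(nms, paste0("p_", gsub(" ", "_", prob_classes(ps))))
  }
  if ("phone_usage" %in% groups) {
    iv <- reconstruct_usage_intervals(
      need("app"),
      if (!is.null(session$streams$screen)) session$streams$screen else NULL)
    cols <- c(cols, list(matrix(phone_usage_feature(iv, t_grid), ncol = 1)))
    nms <- c(nms, "phone_usage")
  }
  if ("steps" %in% groups) {
    cols <- c(cols, list(matrix(step_feature(need("step"), t_grid, step_s),
                                ncol = 1)))
    nms <- c(nms, "steps")
  }
  if ("light_phone" %in% groups) {
    lux <- light_mean_feature(need("light_phone"), t_grid, step_s)
    cols <- c(cols, list(matrix(scale_lux(lux), ncol = 1)))
    nms <- c(nms, "light_phone")
  }
  if ("appliances" %in% groups) {
    fr <- need("fridge")
    cols <- c(cols, list(matrix(elapsed_since_feature(fr, t_grid), ncol = 1)))
    nms <- c(nms, "since_fridge")
    for (ap in home$appliances) {
      mod <- paste0("power_", ap)
      pw <- need(mod)
      ev <- power_to_events(pw)
      cols <- c(cols, list(matrix(elapsed_since_feature(ev, t_grid),
                                  ncol = 1)))
      nms <- c(nms, paste0("since_", ap))
    }
  }
  if ("room_lights" %in% groups) {
    for (rm in home$light_rooms) {
      mod <- paste0("light_", rm)
      ls <- need(mod)
      cols <- c(cols, list(matrix(room_light_binary(ls, t_grid), ncol = 1)))
      nms <- c(nms, paste0("light_", rm))
    }
  }
  if ("location" %in% groups) {
    rooms <- room_location_feature(need("location"), t_grid,
                                   rooms = home$rooms)
    lv <- levels(rooms)
    onehot <- matrix(0L, length(t_grid), length(lv))
    onehot[cbind(seq_along(t_grid), as.integer(rooms))] <- 1L
    cols <- c(cols, list(onehot))
    nms <- c(nms, paste0("room_", lv))
  }
  x <- do.call(cbind, cols)
  colnames(x) <- nms
  structure(list(t = t_grid, x = x, feature_names = nms, preset = preset),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> preset:", x$preset, " ", length(x$t), "steps x",
      length(x$feature_names), "features\n")
  invisible(x)
}

#' Slice a feature matrix into model windows
#'
#' Cuts the session-long 3-second feature grid into windows of
#' `window_s` seconds with `stride_s` stride (defaults: 10 min / 2 min), each
#' a `window_s/3 x F` matrix (200 rows for the default window).
#'
#' @param fm A [build_feature_matrix()] result.
#' @param window_s,stride_s Window length and stride in seconds.
#' @return A list with `starts` and `x` (N x steps x F array). Empty when the
#'   session is shorter than one window.
#' @export
feature_windows <- function(fm, window_s = 600, stride_s = 120) {
  step_s <- fm$t[2] - fm$t[1]
  steps <- round(window_s / step_s)
  stride <- round(stride_s / step_s)
  total <- length(fm$t)
  if (total < steps) {
    return(list(starts = numeric(),
                x = array(0, c(0, steps, ncol(fm$x)))))
  }
  starts_idx <- seq(1, total - steps + 1, by = stride)
  X <- array(0, c(length(starts_idx), steps, ncol(fm$x)))
  for (i in seq_along(starts_idx)) {
    X[i, , ] <- fm$x[starts_idx[i] + 0:(steps - 1), ]
  }
  list(starts = fm$t[starts_idx], x = X)
}

#' Assemble the feature sequence for one window
#'
#' Convenience wrapper: builds the session feature matrix for `preset` and
#' returns the single window starting at `window_start` as a
#' `steps x F` matrix (200 x F for the default 10-minute window).
#'
#' @inheritParams build_feature_matrix
#' @param window_start Window start time in seconds.
#' @param window_s Window length in seconds.
#' @return A list with `window_start`, `step`, `matrix`, `feature_names`,
#'   `preset`.
#' @export
assemble_features <- function(session, probs, preset, window_start = 0,
                              window_s = 600, home = home_config(),
                              step_s = 3) {
  fm <- build_feature_matrix(session, probs, preset, home = home,
                             step_s = step_s)
  idx <- which(fm$t >= window_start - 1e-9 &
                 fm$t < window_start + window_s - 1e-9)
  steps <- round(window_s / step_s)
  if (length(idx) != steps) {
    stop("window [", window_start, ", ", window_start + window_s,
         ") is not fully covered by the session", call. = FALSE)
  }
  list(window_start = window_start, step = step_s,
       matrix = fm$x[idx, , drop = FALSE], feature_names = fm$feature_names,
       preset = preset)
}
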