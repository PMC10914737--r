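#' Low-level activity signature bank
#'
#' Synthetic accelerometer signatures, one per low-level activity: a gravity
#' orientation, an oscillation (frequency and amplitude) and a noise level.
#' The signatures are pairwise separable by construction — distinct gravity
#' orientation or frequency — so that model tests exercise the pipeline's
#' plumbing rather than raw learning difficulty. The "on table" signature is a
#' clean flat-Z gravity vector (|mean Z| > 9, per-axis std < 0.7) so the
#' threshold detector fires on exactly those spans; sitting and standing keep
#' |mean Z| below 9.
#'
#' @param amp_scale Multiplier on the oscillation amplitudes (used for mild
#'   per-participant variation).
#' @return A tibble with columns `class`, `gx`, `gy`, `gz`, `freq`, `amp`,
#'   `noise`.
#' @export
activity_signature_bank <- function(amp_scale = 1) {
  tibble::tibble(
    class = c("lying down", "on table", "running", "sitting", "standing",
              "walking"),
    gx = c(9.81, 0.00, 0.0, 0.00, 5.00, 0.0),
    gy = c(0.00, 0.00, 2.0, 7.00, 0.00, 0.0),
    gz = c(0.00, 9.81, 9.6, 6.87, 8.44, 9.0),
    freq = c(0, 0, 3, 0, 0, 2),
    amp = c(0, 0, 6, 0, 0, 3) * amp_scale,
    noise = c(0.2, 0.05, 0.5, 0.2, 0.2, 0.3)
  )
}

# Default posture and room per ADL; `phone` marks activities during which the
# phone typically lies on a surface.
.adl_defaults <- tibble::tibble(
  adl = c("preparing drink", "preparing meal", "toileting", "eating",
          "using computer", "watching tv", "walking", "showering",
          "organizing", "using phone", "room transition", "other"),
  posture = c("standing", "standing", "sitting", "sitting", "sitting",
              "sitting", "walking", "standing", "standing", "sitting",
              "walking", "standing"),
  room = c("kitchen", "kitchen", "toilet", "living", "living", "living",
           "hallway", "bathroom", "bedroom", "living", "hallway", "bedroom"),
  phone = c("worn", "worn", "worn", "worn", "worn", "table", "worn", "table",
            "worn", "worn", "worn", "worn")
)

.parallel_plausible <- list(
  c("eating", "watching tv"),
  c("using phone", "watching tv"),
  c("using computer", "using phone")
)

#' Build a scenario script
#'
#' A scenario script is an ordered list of activity segments that drives the
#' synthetic session generator. Each segment states the ADL, its duration,
#' the room it happens in, the low-level posture (defaulting per ADL), whether
#' the phone is worn or on a surface, and an optional parallel secondary ADL
#' (restricted to plausible combinations such as eating while watching TV).
#'
#' @param segments A data frame with columns `adl`, `duration` and optionally
#'   `room`, `posture`, `phone`, `parallel_with`.
#' @param label_noise Numeric vector `c(jitter_s, merge_prob, drop_prob)`
#'   describing self-report pathologies, see [corrupt_labels()].
#' @return A tibble of class `"scenario_script"` with attribute `label_noise`.
#' @export
scenario_script <- function(segments,
                            label_noise = c(jitter_s = 0, merge_prob = 0,
                                            drop_prob = 0)) {
  segments <- tibble::as_tibble(segments)
  stopifnot(all(c("adl", "duration") %in% names(segments)),
            all(segments$duration > 0))
  bad <- setdiff(segments$adl, .adl_defaults$adl)
  if (length(bad) > 0) {
    stop("unknown ADL(s) in script: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  def_idx <- match(segments$adl, .adl_defaults$adl)
  if (!"room" %in% names(segments)) segments$room <- NA_character_
  if (!"posture" %in% names(segments)) segments$posture <- NA_character_
  if (!"phone" %in% names(segments)) segments$phone <- NA_character_
  if (!"parallel_with" %in% names(segments)) {
    segments$parallel_with <- NA_character_
  }
  segments$room[is.na(segments$room)] <- .adl_defaults$room[def_idx][
    is.na(segments$room)]
  segments$posture[is.na(segments$posture)] <- .adl_defaults$posture[def_idx][
    is.na(segments$posture)]
  segments$phone[is.na(segments$phone)] <- .adl_defaults$phone[def_idx][
    is.na(segments$phone)]
  stopifnot(all(segments$room %in% home_config()$rooms),
            all(segments$posture %in% activity_signature_bank()$class),
            all(segments$phone %in% c("worn", "table")))
  par <- which(!is.na(segments$parallel_with))
  for (i in par) {
    pair <- sort(c(segments$adl[i], segments$parallel_with[i]))
    ok <- any(vapply(.parallel_plausible,
                     function(p) identical(sort(p), pair), logical(1)))
    if (!ok) {
      stop("implausible parallel pair: ", paste(pair, collapse = " + "),
           call. = FALSE)
    }
  }
  segments$start <- cumsum(c(0, segments$duration[-nrow(segments)]))
  segments$end <- segments$start + segments$duration
  structure(segments, label_noise = label_noise,
            class = c("scenario_script", class(tibble::tibble())))
}

#' A randomized day-like scenario
#'
#' A template of common household activity sequences with randomized segment
#' durations and short room transitions in between. Two sequences are fixed by
#' design: eating always directly follows preparing a meal, and using the
#' computer always follows toileting — under a location-only feature set,
#' eating and using the computer have identical instantaneous features
#' (sitting in the living room), so only their temporal context separates
#' them. Durations vary uniformly within realistic per-activity ranges.
#'
#' @param seed RNG seed for the durations.
#' @param label_noise Self-report noise passed to [scenario_script()].
#' @return A `"scenario_script"`.
#' @export
default_scenario <- function(seed = 1, label_noise = c(jitter_s = 0,
                                                       merge_prob = 0,
                                                       drop_prob = 0)) {
  set.seed(seed)
  blocks <- list(
    c("other", 180, 300),
    c("preparing drink", 120, 240),
    c("using phone", 180, 300),
    c("preparing meal", 300, 480),
    c("eating", 240, 420),
    c("toileting", 90, 180),
    c("using computer", 300, 480),
    c("watching tv", 300, 480),
    c("showering", 300, 420),
    c("organizing", 180, 300),
    c("toileting", 90, 150),
    c("walking", 60, 120)
  )
  rows <- list()
  for (b in blocks) {
    dur <- stats::runif(1, as.numeric(b[2]), as.numeric(b[3]))
    rows <- c(rows, list(tibble::tibble(adl = b[1], duration = round(dur))))
    rows <- c(rows, list(tibble::tibble(adl = "room transition",
                                        duration = round(stats::runif(1, 15,
                                                                      30)))))
  }
  segments <- dplyr::bind_rows(rows[-length(rows)]) # no trailing transition
  scenario_script(segments, label_noise = label_noise)
}

#' Corrupt ground-truth labels into self-report-style entries
#'
#' Emulates the pathologies of self-reported activity logs: interval
#' boundaries jittered uniformly by up to `jitter_s` seconds, adjacent entries
#' merged into a single multi-label entry with probability `merge_prob`, and
#' entries dropped entirely with probability `drop_prob`. Zero noise is the
#' identity.
#'
#' @param entries Label tibble (`start`, `end`, `adls` list-column).
#' @param noise Numeric vector `c(jitter_s, merge_prob, drop_prob)`.
#' @param seed RNG seed.
#' @return A corrupted label tibble in the same layout.
#' @export
corrupt_labels <- function(entries, noise, seed = 1) {
  jitter_s <- noise[[1]]; merge_prob <- noise[[2]]; drop_prob <- noise[[3]]
  stopifnot(merge_prob >= 0, merge_prob <= 1, drop_prob >= 0, drop_prob <= 1)
  if (nrow(entries) == 0) return(entries)
  set.seed(seed)
  out <- entries
  if (drop_prob > 0) {
    out <- out[stats::runif(nrow(out)) >= drop_prob, , drop = FALSE]
  }
  if (nrow(out) == 0) return(out)
  if (jitter_s > 0) {
    out$start <- pmax(out$start + stats::runif(nrow(out), -jitter_s, jitter_s),
                      0)
    out$end <- out$end + stats::runif(nrow(out), -jitter_s, jitter_s)
    keep <- out$end > out$start
    out <- out[keep, , drop = FALSE]
  }
  if (merge_prob > 0 && nrow(out) > 1) {
    merged <- list()
    cur <- list(start = out$start[1], end = out$end[1], adls = out$adls[[1]])
    for (i in 2:nrow(out)) {
      if (stats::runif(1) < merge_prob) {
        cur$end <- out$end[i]
        cur$adls <- unique(c(cur$adls, out$adls[[i]]))
      } else {
        merged <- c(merged, list(cur))
        cur <- list(start = out$start[i], end = out$end[i],
                    adls = out$adls[[i]])
      }
    }
    merged <- c(merged, list(cur))
    out <- tibble::tibble(
      start = vapply(merged, `[[`, numeric(1), "start"),
      end = vapply(merged, `[[`, numeric(1), "end"),
      adls = lapply(merged, `[[`, "adls"))
  }
  out
}

# Dirichlet sample with concentration alpha (vector), via gamma draws.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Generate one synthetic session from a scenario script
#'
#' Produces a full session bundle with every modality the pipeline consumes,
#' driven by the script's activity semantics: cooking segments emit fridge and
#' cooking-plate/hood activity, drink preparation runs the kettle or coffee
#' machine, watching TV powers the TV, showering happens in the bathroom with
#' its light on, toileting in the toilet with its light on, phone-use segments
#' emit app and screen events, and room changes emit location events. The
#' accelerometer stream follows the signature bank for each segment's posture
#' (or the on-table signature while the phone lies on a surface); the
#' wrist-worn probability stream is a Dirichlet-softened one-hot of the
#' scripted posture every 7.5 s. Deterministic given `seed`.
#'
#' @param script A [scenario_script()].
#' @param bank An [activity_signature_bank()].
#' @param seed RNG seed.
#' @param participant_id Participant identifier.
#' @param accel_rate Accelerometer rate in Hz.
#' @param dirichlet_alpha Concentration added to the true class for the
#'   wearable and oracle probability streams.
#' @return A list of class `"synthetic_session"` with elements `session` (a
#'   [session_bundle()] whose `adl_labels` carry the corrupted self-report
#'   entries), `truth` (the noiseless label tibble), `dense` (the ground-truth
#'   `"dense_labels"` from the noiseless entries), `minute_labels` (true
#'   low-level labels per minute, phone-visible: on-table spans included) and
#'   `oracle_probs` (a 6-class [prob_series()] at 3-second step standing in
#'   for the smartphone network's output).
#' @export
generate_session <- function(script, bank = activity_signature_bank(),
                             seed = 1, participant_id = "P01",
                             accel_rate = 32, dirichlet_alpha = 20) {
  stopifnot(inherits(script, "scenario_script"))
  set.seed(seed)
  duration <- max(script$end)
  home <- home_config()
  classes6 <- lowlevel_classes()
  classes5 <- lowlevel_classes(wearable = TRUE)

  seg_at <- function(t) findInterval(t, script$start, left.open = FALSE)
  # posture of the person and of the phone at each segment
  phone_regime <- ifelse(script$phone == "table", "on table", script$posture)

  ## accelerometer (follows the phone)
  t_acc <- seq(0, duration - 1 / accel_rate, by = 1 / accel_rate)
  seg_idx <- pmax(seg_at(t_acc + 1e-9), 1)
  sig_idx <- match(phone_regime[seg_idx], bank$class)
  osc <- bank$amp[sig_idx] * sin(2 * pi * bank$freq[sig_idx] * t_acc)
  nse <- bank$noise[sig_idx]
  acc <- tibble::tibble(
    t = t_acc,
    x = bank$gx[sig_idx] + 0.5 * osc + stats::rnorm(length(t_acc), 0, nse),
    y = bank$gy[sig_idx] + stats::rnorm(length(t_acc), 0, nse),
    z = bank$gz[sig_idx] + osc + stats::rnorm(length(t_acc), 0, nse)
  )
  streams <- list(accelerometer = sensor_series(acc, "accelerometer",
                                                nominal_rate = accel_rate))

  ## wrist-worn probabilities every 7.5 s (person posture; wearable cannot
  ## see the phone, and never reports "on table")
  t_wear <- seq(0, duration - 7.5, by = 7.5)
  wear_seg <- pmax(seg_at(t_wear + 1e-9), 1)
  wear_cls <- script$posture[wear_seg]
  wp <- t(vapply(wear_cls, function(cl) {
    rdirichlet1(1 + dirichlet_alpha * (classes5 == cl))
  }, numeric(5)))
  wear <- tibble::as_tibble(as.data.frame(wp))
  names(wear) <- paste0("p_", gsub(" ", "_", classes5))
  wear$t <- t_wear
  streams$wearable_probs <- sensor_series(wear, "wearable_probs",
                                          nominal_rate = 1 / 7.5)

  ## oracle low-level probabilities at 3 s over the 6 phone classes
  t3 <- seq(0, duration - 3, by = 3)
  o_seg <- pmax(seg_at(t3 + 1e-9), 1)
  o_cls <- phone_regime[o_seg]
  op <- t(vapply(o_cls, function(cl) {
    rdirichlet1(1 + dirichlet_alpha * (classes6 == cl))
  }, numeric(6)))
  oracle_probs <- prob_series(t3, op, classes6)

  ## step detector: events during ambulatory postures (~1.9 steps/s)
  walk_rows <- which(script$posture %in% c("walking", "running"))
  step_t <- unlist(lapply(walk_rows, function(i) {
    n <- floor(script$duration[i] * 1.9)
    if (n < 1) return(numeric())
    sort(script$start[i] + stats::runif(n, 0, script$duration[i]))
  }))
  streams$step <- sensor_series(
    tibble::tibble(t = step_t %||% numeric(), value = 1), "step")

  ## phone ambient light at 1 Hz, room-dependent
  room_lux <- c(kitchen = 300, living = 200, bathroom = 250, toilet = 150,
                bedroom = 100, hallway = 80)
  t1 <- seq(0, duration - 1, by = 1)
  lux <- room_lux[script$room[pmax(seg_at(t1 + 1e-9), 1)]] *
    exp(stats::rnorm(length(t1), 0, 0.1))
  streams$light_phone <- sensor_series(
    tibble::tibble(t = t1, value = unname(lux)), "light_phone",
    nominal_rate = 1)

  ## location events on room changes
  rooms_seq <- script$room
  chg <- c(TRUE, rooms_seq[-1] != rooms_seq[-length(rooms_seq)])
  streams$location <- sensor_series(
    tibble::tibble(t = script$start[chg], room = rooms_seq[chg]), "location")

  ## screen + app events during phone-use segments; keyboard noise
  use_rows <- which(script$adl == "using phone" |
                      script$parallel_with %in% "using phone")
  app_t <- c(); app_nm <- c(); scr_t <- c(); scr_ev <- c()
  for (i in use_rows) {
    s0 <- script$start[i]; s1 <- script$end[i]
    scr_t <- c(scr_t, s0, s1)
    scr_ev <- c(scr_ev, "unlocked", "locked")
    n_apps <- 1 + stats::rbinom(1, 2, 0.5)
    at <- sort(c(s0, stats::runif(n_apps - 1, s0, s1)))
    app_t <- c(app_t, at)
    app_nm <- c(app_nm, sample(c("messages", "browser", "news", "mail"),
                               n_apps, replace = TRUE))
    if (stats::runif(1) < 0.5) { # system-utility event inside the session
      app_t <- c(app_t, stats::runif(1, s0, s1))
      app_nm <- c(app_nm, "keyboard")
    }
  }
  streams$screen <- sensor_series(
    tibble::tibble(t = scr_t %||% numeric(),
                   event = scr_ev %||% character()), "screen")
  streams$app <- sensor_series(
    tibble::tibble(t = app_t %||% numeric(), app = app_nm %||% character()),
    "app")

  ## fridge contact events
  fridge_t <- c()
  for (i in which(script$adl == "preparing meal")) {
    fridge_t <- c(fridge_t,
                  script$start[i] + stats::runif(2, 0, script$duration[i]))
  }
  for (i in which(script$adl == "preparing drink")) {
    if (stats::runif(1) < 0.7) {
      fridge_t <- c(fridge_t,
                    script$start[i] + stats::runif(1, 0, script$duration[i]))
    }
  }
  streams$fridge <- sensor_series(
    tibble::tibble(t = sort(fridge_t %||% numeric()), value = 1), "fridge")

  ## appliance power at 15 s cadence with rectangular pulses
  tp <- seq(0, duration - 1, by = 15)
  pulse <- function(rows, watts, lead = 0, max_len = Inf) {
    v <- numeric(length(tp))
    for (i in rows) {
      on <- tp >= script$start[i] + lead &
        tp < min(script$end[i], script$start[i] + lead + max_len)
      v[on] <- watts
    }
    v
  }
  meal_rows <- which(script$adl == "preparing meal")
  drink_rows <- which(script$adl == "preparing drink")
  tv_rows <- which(script$adl == "watching tv" |
                     script$parallel_with %in% "watching tv")
  appl <- list(
    cooking_plate = pulse(meal_rows, 1500),
    cooking_hood = pulse(meal_rows, 80, lead = 30),
    kettle = pulse(drink_rows, 2000, max_len = 120),
    coffee_machine = pulse(drink_rows, 800, lead = 60, max_len = 90),
    tv = pulse(tv_rows, 100)
  )
  for (ap in names(appl)) {
    streams[[paste0("power_", ap)]] <- sensor_series(
      tibble::tibble(t = tp, value = appl[[ap]] +
                       stats::runif(length(tp), 0, 0.5)),
      paste0("power_", ap))
  }

  ## room lights (motion-triggered toilet, switched bathroom)
  for (rm in home$light_rooms) {
    rows <- which(script$room == rm)
    ev_t <- c(); ev_v <- c()
    for (i in rows) {
      ev_t <- c(ev_t, script$start[i], script$end[i])
      ev_v <- c(ev_v, 1, 0)
    }
    streams[[paste0("light_", rm)]] <- sensor_series(
      tibble::tibble(t = ev_t %||% numeric(), value = ev_v %||% numeric()),
      paste0("light_", rm))
  }

  ## ground-truth ADL label entries (parallel activities share the interval)
  truth <- tibble::tibble(
    start = script$start, end = script$end,
    adls = lapply(seq_len(nrow(script)), function(i) {
      if (is.na(script$parallel_with[i])) script$adl[i] else
        c(script$adl[i], script$parallel_with[i])
    }))
  noise <- attr(script, "label_noise", exact = TRUE)
  reported <- corrupt_labels(truth, noise, seed = seed + 1)

  ## true low-level minute labels (phone-visible regimes)
  n_min <- floor(duration / 60)
  mins <- (seq_len(n_min) - 1) * 60
  minute_lab <- vapply(mins, function(m0) {
    # regime occupying most of the minute
    tt <- seq(m0, m0 + 59.5, by = 0.5)
    reg <- phone_regime[pmax(seg_at(tt + 1e-9), 1)]
    names(which.max(table(factor(reg, levels = classes6))))
  }, character(1))
  minute_labels <- tibble::tibble(minute_start = mins, label = minute_lab)

  session <- session_bundle(participant_id, streams, adl_labels = reported,
                            duration = duration)
  structure(list(session = session, truth = truth,
                 dense = densify(truth, duration),
                 minute_labels = minute_labels,
                 oracle_probs = oracle_probs, script = script, seed = seed),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat("<synthetic_session> participant:", x$session$participant_id,
      " duration:", round(x$session$duration), "s,",
      nrow(x$script), "scripted segments\n")
  invisible(x)
}

#' Generate a cohort of synthetic participants
#'
#' Per-participant seeds are derived deterministically from the master seed;
#' each participant gets a freshly randomized scenario and a mildly perturbed
#' signature bank (oscillation amplitudes scaled by up to ±20 %).
#'
#' @param n_participants Number of participants (>= 2).
#' @param seed Master seed.
#' @param scenario_fn Function `(seed, label_noise) -> scenario_script`.
#' @param label_noise Self-report noise triple applied to every participant.
#' @return A list of `"synthetic_session"` objects named by participant id.
#' @export
generate_cohort <- function(n_participants, seed = 1,
                            scenario_fn = default_scenario,
                            label_noise = c(jitter_s = 0, merge_prob = 0,
                                            drop_prob = 0)) {
  stopifnot(n_participants >= 2)
  set.seed(seed)
  p_seeds <- sample.int(.Machine$integer.max - 1, n_participants)
  amp <- stats::runif(n_participants, 0.8, 1.2)
  out <- vector("list", n_participants)
  ids <- sprintf("P%02d", seq_len(n_participants))
  for (i in seq_len(n_participants)) {
    script <- scenario_fn(seed = p_seeds[i], label_noise = label_noise)
    out[[i]] <- generate_session(script,
                                 bank = activity_signature_bank(amp[i]),
                                 seed = p_seeds[i], participant_id = ids[i])
  }
  names(out) <- ids
  out
}
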