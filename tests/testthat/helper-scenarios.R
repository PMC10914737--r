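# A posture-rich scenario covering all five trainable low-level classes
# (lying down, on table, sitting, standing, walking), used for the
# accelerometer-network recovery tests.
posture_scenario <- function(seed, label_noise = c(0, 0, 0)) {
  set.seed(seed)
  segs <- list(
    c("watching tv", "living", "sitting", "table"),
    c("walking", "hallway", "walking", "worn"),
    c("other", "bedroom", "lying down", "worn"),
    c("using computer", "living", "sitting", "worn"),
    c("organizing", "bedroom", "standing", "worn"),
    c("walking", "hallway", "walking", "worn"),
    c("watching tv", "living", "lying down", "table"),
    c("showering", "bathroom", "standing", "worn"),
    c("toileting", "toilet", "sitting", "worn")
  )
  df <- do.call(rbind, lapply(segs, function(s) {
    data.frame(adl = s[1], room = s[2], posture = s[3], phone = s[4],
               duration = round(stats::runif(1, 120, 240)))
  }))
  scenario_script(df, label_noise = label_noise)
}

# Constant-signal accelerometer series at 32 Hz.
const_accel <- function(x, y, z, duration = 1, rate = 32, noise = 0) {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  sensor_series(
    data.frame(t = t,
               x = x + stats::rnorm(length(t), 0, noise),
               y = y + stats::rnorm(length(t), 0, noise),
               z = z + stats::rnorm(length(t), 0, noise)),
    "accelerometer", nominal_rate = rate)
}

# Stack per-session HAR windows for a set of participants.
collect_har_windows <- function(cohort, ids, pure_only = FALSE) {
  xs <- list(); ls <- list()
  for (id in ids) {
    s <- cohort[[id]]
    ml <- lowlevel_label_chain(s$session)
    tw <- har_training_windows(s$session$streams$accelerometer, ml)
    keep <- rep(TRUE, length(tw$label))
    if (pure_only) {
      sc <- s$script
      regime <- ifelse(sc$phone == "table", "on table", sc$posture)
      seg <- findInterval(tw$start + 1e-9, sc$start)
      keep <- tw$start >= sc$start[seg] & (tw$start + 6) <= sc$end[seg] &
        regime[seg] == tw$label
    }
    xs <- c(xs, list(tw$x[keep, , , drop = FALSE]))
    ls <- c(ls, list(tw$label[keep]))
  }
  n <- sum(vapply(xs, function(a) dim(a)[1], integer(1)))
  X <- array(0, c(n, 192, 3)); pos <- 0
  for (a in xs) {
    X[pos + seq_len(dim(a)[1]), , ] <- a
    pos <- pos + dim(a)[1]
  }
  list(x = X, label = unlist(ls))
}
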