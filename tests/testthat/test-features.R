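test_that("usage intervals follow the five-step reconstruction", {
  # no app events -> no intervals
  empty <- reconstruct_usage_intervals(
    tibble::tibble(t = numeric(), app = character()), NULL)
  expect_equal(nrow(empty), 0)
  # app A at 0, screen off at 60 -> one interval (A, 0, 60)
  iv <- reconstruct_usage_intervals(
    tibble::tibble(t = 0, app = "A"),
    tibble::tibble(t = 60, event = "off"))
  expect_equal(iv, tibble::tibble(app = "A", start = 0, end = 60))
  # A at 0, B at 30, lock at 50 -> (A,0,30), (B,30,50)
  iv <- reconstruct_usage_intervals(
    tibble::tibble(t = c(0, 30), app = c("A", "B")),
    tibble::tibble(t = 50, event = "locked"))
  expect_equal(iv$app, c("A", "B"))
  expect_equal(iv$start, c(0, 30))
  expect_equal(iv$end, c(30, 50))
  # a keyboard-utility event between A(0) and lock(50) is filtered: (A,0,50)
  iv <- reconstruct_usage_intervals(
    tibble::tibble(t = c(0, 10), app = c("A", "keyboard")),
    tibble::tibble(t = 50, event = "locked"),
    system_utils = "keyboard")
  expect_equal(iv, tibble::tibble(app = "A", start = 0, end = 50))
  # screen on/unlocked events do not end usage
  iv <- reconstruct_usage_intervals(
    tibble::tibble(t = 0, app = "A"),
    tibble::tibble(t = c(20, 60), event = c("unlocked", "off")))
  expect_equal(iv$end, 60)
})

test_that("usage intervals match a sweep-line oracle on random sequences", {
  # Oracle: walk the event list in time order tracking which app holds the
  # foreground; emit an interval whenever the foreground changes. A repeated
  # event for the app already in the foreground changes nothing; an off event
  # clears the foreground. An open-ended final app has no known end.
  sweepline <- function(apps, offs, utils) {
    apps <- apps[!apps$app %in% utils, , drop = FALSE]
    ev <- rbind(data.frame(t = as.numeric(apps$t), what = apps$app),
                data.frame(t = as.numeric(offs), what = rep(NA_character_, length(offs))))
    ev <- ev[order(ev$t, !is.na(ev$what)), , drop = FALSE]
    cur <- NA_character_; t0 <- NA_real_
    out <- list()
    for (i in seq_len(nrow(ev))) {
      if (identical(cur, ev$what[i])) next
      if (!is.na(cur) && ev$t[i] > t0) {
        out <- c(out, list(data.frame(app = cur, start = t0, end = ev$t[i])))
      }
      cur <- ev$what[i]; t0 <- ev$t[i]
    }
    if (length(out) == 0) {
      return(data.frame(app = character(), start = numeric(),
                        end = numeric()))
    }
    do.call(rbind, out)
  }
  set.seed(77)
  utils <- c("kbd", "sysui")
  pool <- c("A", "B", "C", "kbd", "sysui")
  res <- vapply(1:1000, function(i) {
    n_app <- sample(0:6, 1)
    n_off <- sample(0:3, 1)
    apps <- tibble::tibble(t = sort(sample(0:100, n_app)),
                           app = sample(pool, n_app, replace = TRUE))
    # drop duplicate timestamps (reader convention: keep last)
    apps <- apps[!duplicated(apps$t, fromLast = TRUE), ]
    offs <- sort(sample(setdiff(0:100, apps$t), n_off))
    got <- reconstruct_usage_intervals(
      apps, tibble::tibble(t = offs, event = "off"), system_utils = utils)
    want <- sweepline(apps, offs, utils)
    agree <- nrow(got) == nrow(want) &&
      (nrow(got) == 0 || (identical(got$app, want$app) &&
                            identical(got$start, want$start) &&
                            identical(got$end, want$end)))
    # structural invariants: no overlaps, starts at non-utility app events
    structural <- nrow(got) == 0 ||
      (all(got$start[-1] >= got$end[-nrow(got)]) &&
         all(got$start %in% apps$t[!apps$app %in% utils]))
    agree && structural
  }, logical(1))
  expect_true(all(res))
})

test_that("phone usage, steps and light features use half-open bins", {
  iv <- tibble::tibble(app = "A", start = 10, end = 20)
  expect_equal(phone_usage_feature(iv, c(9, 10, 19.9, 20, 25)),
               c(0L, 1L, 1L, 0L, 0L))
  expect_equal(phone_usage_feature(tibble::tibble(app = character(),
                                                  start = numeric(),
                                                  end = numeric()), 5), 0L)
  steps <- sensor_series(
    tibble::tibble(t = c(1, 1.5, 2, 2.9, 3), value = 1), "step")
  expect_equal(step_feature(steps, c(0, 3), bin_s = 3), c(4L, 1L))
  expect_equal(step_feature(steps, 10, bin_s = 3), 0L)

  light <- sensor_series(
    tibble::tibble(t = c(0, 1, 2), value = c(100, 200, 300)), "light_phone")
  expect_equal(light_mean_feature(light, 0, bin_s = 3), 200)
  # empty bin carries the last known value
  light2 <- sensor_series(tibble::tibble(t = 0, value = 80), "light_phone")
  expect_equal(light_mean_feature(light2, 6, bin_s = 3), 80)
  # bins before any sample are 0
  light3 <- sensor_series(tibble::tibble(t = 50, value = 80), "light_phone")
  expect_equal(light_mean_feature(light3, 0, bin_s = 3), 0)
})

test_that("elapsed-since features normalize over 12 h and cap at 1", {
  expect_equal(elapsed_since_feature(3600 * 0, 3600, cap = 43200),
               3600 / 43200)
  expect_equal(elapsed_since_feature(c(10), 10), 0)
  expect_equal(elapsed_since_feature(numeric(), 100), 1)
  # beyond the cap saturates at 1
  expect_equal(elapsed_since_feature(0, 1e6), 1)
})

test_that("power streams become trigger events at threshold crossings", {
  mk <- function(v) sensor_series(
    tibble::tibble(t = seq_along(v) - 1, value = v), "power_tv")
  expect_equal(power_to_events(mk(c(0, 1, 2, 0)), 5), numeric())
  # rectangular pulse: rising edge only
  expect_equal(power_to_events(mk(c(0, 0, 100, 100, 0)), 5,
                               during_use = FALSE), 2)
  # during-use default: every above-threshold sample counts
  expect_equal(power_to_events(mk(c(0, 0, 100, 100, 0)), 5), c(2, 3))
  # two pulses -> two rising edges
  expect_equal(power_to_events(mk(c(0, 100, 0, 100, 0)), 5,
                               during_use = FALSE), c(1, 3))
})

test_that("room location and room light carry the last state forward", {
  locs <- sensor_series(
    tibble::tibble(t = c(0, 100), room = c("kitchen", "living")), "location")
  f <- room_location_feature(locs, c(50, 150))
  expect_equal(as.character(f), c("kitchen", "living"))
  expect_equal(as.character(room_location_feature(locs, -5)), "unknown")
  bad <- sensor_series(tibble::tibble(t = 0, room = "attic"), "location")
  expect_error(room_location_feature(bad, 0), "unregistered")

  ls <- sensor_series(
    tibble::tibble(t = c(10, 30), value = c(1, 0)), "light_toilet")
  expect_equal(room_light_binary(ls, c(5, 20, 40)), c(0L, 1L, 0L))
})

test_that("presets determine the feature width and fail on missing streams", {
  ss <- generate_session(default_scenario(seed = 2), seed = 2)
  fm <- build_feature_matrix(ss$session, ss$oracle_probs, "probs_only")
  expect_equal(ncol(fm$x), 6)
  # probs + location: 6 probs + 6 rooms + unknown = 13
  fm <- build_feature_matrix(ss$session, ss$oracle_probs, "probs_location")
  expect_equal(ncol(fm$x), 6 + 7)
  # ambient_only excludes every phone feature
  fm <- build_feature_matrix(ss$session, ss$oracle_probs, "ambient_only")
  expect_false(any(grepl("^p_|phone|steps|light_phone", fm$feature_names)))
  # all: 6 probs + 3 phone + 6 appliances/fridge + 2 room lights + 7 rooms
  fm <- build_feature_matrix(ss$session, ss$oracle_probs, "all")
  expect_equal(ncol(fm$x), 6 + 3 + 6 + 2 + 7)
  # the matrix is one row per 3 s
  expect_equal(nrow(fm$x), floor(ss$session$duration / 3))
  # missing modality produces an error naming it
  s2 <- ss$session
  s2$streams$location <- NULL
  expect_error(build_feature_matrix(s2, ss$oracle_probs, "probs_location"),
               "location")
  expect_error(build_feature_matrix(s2, ss$oracle_probs, "nope"),
               "unknown preset")
})

test_that("feature values live in their stated ranges", {
  ss <- generate_session(default_scenario(seed = 9), seed = 9)
  fm <- build_feature_matrix(ss$session, ss$oracle_probs, "all")
  x <- fm$x
  binary_cols <- grepl("^(phone_usage|light_toilet|light_bathroom|room_)",
                       fm$feature_names)
  expect_true(all(x[, binary_cols] %in% c(0, 1)))
  elapsed_cols <- grepl("^since_", fm$feature_names)
  expect_true(all(x[, elapsed_cols] >= 0 & x[, elapsed_cols] <= 1))
  prob_cols <- grepl("^p_", fm$feature_names)
  expect_equal(rowSums(x[, prob_cols]), rep(1, nrow(x)), tolerance = 1e-6)
  expect_true(all(x[, fm$feature_names == "light_phone"] >= 0 &
                    x[, fm$feature_names == "light_phone"] <= 1))
})

test_that("assemble_features returns a 200-step window", {
  ss <- generate_session(default_scenario(seed = 4), seed = 4)
  w <- assemble_features(ss$session, ss$oracle_probs, "probs_location",
                         window_start = 120)
  expect_equal(nrow(w$matrix), 200)
  expect_equal(ncol(w$matrix), 13)
  expect_equal(w$feature_names[1], "p_lying_down")
  expect_error(assemble_features(ss$session, ss$oracle_probs, "probs_only",
                                 window_start = ss$session$duration - 60),
               "not fully covered")
})
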