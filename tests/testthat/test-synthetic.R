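test_that("the generator is byte-identical under a fixed seed", {
  s1 <- generate_session(default_scenario(seed = 5), seed = 5)
  s2 <- generate_session(default_scenario(seed = 5), seed = 5)
  expect_identical(s1, s2)
  s3 <- generate_session(default_scenario(seed = 6), seed = 6)
  expect_false(identical(s1$session$streams$accelerometer,
                         s3$session$streams$accelerometer))
})

test_that("scripted activity semantics drive the ambient streams", {
  ss <- generate_session(default_scenario(seed = 8), seed = 8)
  sc <- ss$script
  streams <- ss$session$streams
  # cooking emits fridge events and cooking-plate power inside the segment
  meal <- sc[sc$adl == "preparing meal", ]
  expect_true(any(streams$fridge$t >= meal$start & streams$fridge$t <
                    meal$end))
  plate <- streams$power_cooking_plate
  expect_true(all(plate$value[plate$t >= meal$start &
                                plate$t < meal$end] > 1000))
  expect_true(all(plate$value[plate$t < meal$start |
                                plate$t >= meal$end] < 5))
  # watching TV powers the TV
  tv_seg <- sc[sc$adl == "watching tv", ][1, ]
  tv <- streams$power_tv
  expect_true(all(tv$value[tv$t >= tv_seg$start & tv$t < tv_seg$end] > 50))
  # showering happens in the bathroom with its light on
  shower <- sc[sc$adl == "showering", ][1, ]
  mid <- (shower$start + shower$end) / 2
  expect_equal(as.character(room_location_feature(streams$location, mid)),
               "bathroom")
  expect_equal(room_light_binary(streams$light_bathroom, mid), 1L)
  expect_equal(room_light_binary(streams$light_bathroom, shower$end + 1), 0L)
  # phone-use segments emit app and screen events
  phone <- sc[sc$adl == "using phone", ][1, ]
  expect_true(any(streams$app$t >= phone$start & streams$app$t < phone$end))
  expect_true(any(streams$screen$t == phone$start))
})

test_that("on-table detection recovers the scripted flat spans", {
  ss <- generate_session(default_scenario(seed = 13), seed = 13)
  mask <- detect_on_table(ss$session$streams$accelerometer)
  sc <- ss$script
  spans <- sc[sc$phone == "table", c("start", "end")]
  inside <- rep(FALSE, nrow(mask))
  for (i in seq_len(nrow(spans))) {
    inside <- inside | (mask$start >= spans$start[i] &
                          mask$start < spans$end[i] - 1)
  }
  expect_gte(mean(mask$on_table[inside]), 0.99)
  expect_lte(mean(mask$on_table[!inside]), 0.02)
})

test_that("noiseless labels reproduce the script exactly", {
  script <- default_scenario(seed = 3, label_noise = c(0, 0, 0))
  ss <- generate_session(script, seed = 3)
  expect_identical(ss$session$adl_labels, ss$truth)
  # every grid step inside a scripted segment carries that segment's ADL
  d <- ss$dense
  expect_true(all(d$w == 1))
  k <- findInterval(d$t + 1e-9, script$start)
  expect_true(all(d$Y[cbind(seq_along(d$t),
                            match(script$adl[k], adl_registry()))] == 1))
})

test_that("corrupt_labels implements jitter, merge and drop", {
  entries <- tibble::tibble(start = c(0, 100, 200), end = c(100, 200, 300),
                            adls = list("eating", "toileting", "walking"))
  # zero noise is the identity (on many random scripts)
  set.seed(17)
  for (i in 1:50) {
    n <- sample(1:6, 1)
    bounds <- sort(stats::runif(n + 1, 0, 1000))
    e <- tibble::tibble(start = bounds[-(n + 1)], end = bounds[-1],
                        adls = as.list(sample(adl_registry(), n,
                                              replace = TRUE)))
    expect_identical(corrupt_labels(e, c(0, 0, 0), seed = i), e)
  }
  # drop_prob 1 removes everything
  expect_equal(nrow(corrupt_labels(entries, c(0, 0, 1), seed = 1)), 0)
  # merge_prob 1 collapses adjacent entries into one multi-label entry
  merged <- corrupt_labels(entries, c(0, 1, 0), seed = 1)
  expect_equal(nrow(merged), 1)
  expect_setequal(merged$adls[[1]], c("eating", "toileting", "walking"))
  expect_equal(merged$start, 0)
  expect_equal(merged$end, 300)
  # jitter moves boundaries by at most the stated amount
  j <- corrupt_labels(entries, c(5, 0, 0), seed = 2)
  expect_true(all(abs(j$start - entries$start) <= 5))
  expect_true(all(abs(j$end - entries$end) <= 5))
})

test_that("cohorts have distinct participants and derive from the master seed", {
  c1 <- generate_cohort(4, seed = 9)
  expect_equal(names(c1), sprintf("P%02d", 1:4))
  expect_length(unique(vapply(c1, function(s) s$session$participant_id,
                              character(1))), 4)
  # distinct participants get non-identical accelerometer streams
  expect_false(identical(c1$P01$session$streams$accelerometer,
                         c1$P02$session$streams$accelerometer))
  # master seed reproduces the cohort byte-identically
  c2 <- generate_cohort(4, seed = 9)
  expect_identical(c1, c2)
  expect_error(generate_cohort(1), "n_participants")
})

test_that("implausible parallel pairs are rejected by the script", {
  expect_error(
    scenario_script(data.frame(adl = "showering", duration = 60,
                               parallel_with = "eating")),
    "implausible")
  s <- scenario_script(data.frame(adl = "eating", duration = 600,
                                  parallel_with = "watching tv"))
  expect_equal(s$parallel_with, "watching tv")
})

test_that("wearable stream is a softened one-hot of the scripted posture", {
  ss <- generate_session(default_scenario(seed = 14), seed = 14)
  wear <- as_prob_series(ss$session$streams$wearable_probs)
  sc <- ss$script
  m <- as.matrix(wear[, -1])
  cls <- lowlevel_classes(wearable = TRUE)[max.col(m)]
  seg <- findInterval(wear$t + 1e-9, sc$start)
  truth <- sc$posture[seg]
  # interior steps (excluding segment boundaries) agree almost surely
  interior <- wear$t > sc$start[seg] & (wear$t + 7.5) < sc$end[seg]
  expect_gte(mean(cls[interior] == truth[interior]), 0.95)
  expect_equal(rowSums(m), rep(1, nrow(m)), tolerance = 1e-9)
})
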