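noise_free_config <- function(seed = 1, schedule = short_schedule(),
                              stride_mean = 1.0) {
  simulation_config(
    seed = seed, schedule = schedule,
    stride_duration = list(walking = c(mean = stride_mean, sd = 0),
                           ascending_stairs = c(mean = 1.4, sd = 0),
                           descending_stairs = c(mean = 1.2, sd = 0)),
    amplitude_jitter_fraction = 0,
    noise_sd = c(acc = 0, gyro = 0),
    static_noise_sd = c(acc = 0, gyro = 0))
}

test_that("generation is deterministic for a fixed seed", {
  cfg <- simulation_config(seed = 99, schedule = short_schedule())
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$recording$channels, b$recording$channels)
  expect_identical(a$labels, b$labels)
  expect_identical(a$stride_boundaries, b$stride_boundaries)
  c <- generate_recording(simulation_config(seed = 100,
                                            schedule = short_schedule()))
  expect_false(identical(a$recording$channels, c$recording$channels))
})

test_that("labels tile the recording and stride boundaries stay inside their interval", {
  sim <- generate_recording(simulation_config(seed = 3))
  lab <- sim$labels
  expect_equal(lab$start_frame[1], 0)
  expect_equal(tail(lab$end_frame, 1), sim$recording$n_frames)
  expect_equal(lab$start_frame[-1], head(lab$end_frame, -1))
  for (i in seq_len(nrow(lab))) {
    b <- sim$stride_boundaries[[i]]
    if (lab$activity[i] %in% locomotion_activities()) {
      expect_gte(length(b), 2)
      expect_true(all(b >= lab$start_frame[i] & b <= lab$end_frame[i]))
      expect_true(all(diff(b) > 0))
    } else {
      expect_length(b, 0)
    }
  }
})

test_that("a 60 s walking schedule at exactly 1 s strides yields 59 interior boundaries", {
  cfg <- noise_free_config(schedule = data.frame(activity = "walking",
                                                 duration_s = 60))
  sim <- generate_recording(cfg)
  b <- sim$stride_boundaries[[1]]
  expect_length(b, 61)
  expect_equal(b[1], 0)
  expect_equal(tail(b, 1), 6000)
  expect_true(all(diff(b) == 100))
})

test_that("noise- and jitter-free strides repeat exactly", {
  cfg <- noise_free_config(schedule = data.frame(activity = "walking",
                                                 duration_s = 10))
  sim <- generate_recording(cfg)
  sn <- extract_snippets(sim$recording, sim$labels, sim$stride_boundaries)
  accz <- Filter(function(s) s$axis == "AccZ", sn)
  expect_gte(length(accz), 2)
  for (k in 2:length(accz)) {
    expect_identical(accz[[k]]$samples, accz[[1]]$samples)
  }
  # gravity offset present on the vertical axis
  expect_equal(mean(sim$recording$channels$AccZ), 9.81, tolerance = 0.05)
})

test_that("tilting rotates the gravity vector by the expected trigonometry", {
  rec <- constant_recording(100)
  t15 <- apply_tilt(rec, c(x = 15))
  expect_equal(t15$channels$AccZ, rep(9.81 * cos(15 * pi / 180), 100))
  expect_equal(apply_tilt(rec, c(y = 0)), rec)
  twice <- apply_tilt(apply_tilt(rec, c(x = 90)), c(x = 90))
  expect_equal(twice$channels, apply_tilt(rec, c(x = 180))$channels)
})

test_that("invalid schedules are rejected", {
  expect_error(simulation_config(schedule = data.frame(activity = "walking",
                                                       duration_s = -1)),
               "invalid schedule")
  expect_error(simulation_config(schedule = data.frame(activity = "flying",
                                                       duration_s = 10)),
               "unknown activity")
})

test_that("noise-free recordings match templates built from their own strides almost perfectly", {
  cfg <- noise_free_config(schedule = data.frame(activity = "walking",
                                                 duration_s = 30))
  sim <- generate_recording(cfg)
  sn <- extract_snippets(sim$recording, sim$labels, sim$stride_boundaries)
  ts <- build_template_set(sn)
  tmpl <- ts$activities$walking$axes$AccZ
  sm <- sliding_match(sim$recording$channels$AccZ, tmpl)
  # identical strides make the template an exact stride copy; matched
  # sections differ from it only through window phase effects
  expect_lt(median(sm$ed), 0.05 * sum(abs(tmpl - mean(tmpl))))
})

test_that("derived thresholds cover all axes and keep most own-class frames above zero probability", {
  cfg <- simulation_config(seed = 17, schedule = data.frame(
    activity = c("walking", "standing"), duration_s = c(40, 10)))
  sim <- generate_recording(cfg)
  sn <- extract_snippets(sim$recording, sim$labels, sim$stride_boundaries)
  ts <- build_template_set(sn)
  thr <- derive_thresholds(sim$recording, sim$labels, ts)
  expect_s3_class(thr, "threshold_table")
  expect_equal(sort(names(thr$walking)), sort(imu_axes()))
  expect_true(all(thr$walking > 0))
  thr2 <- derive_thresholds(sim$recording, sim$labels, ts,
                            stride_boundaries = sim$stride_boundaries,
                            method = "snippet")
  expect_true(all(thr2$walking > 0))
})
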