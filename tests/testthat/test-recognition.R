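test_that("frame probability matches its analytic anchors and decreases strictly", {
  expect_equal(frame_probability(0, 120), 100)
  expect_equal(frame_probability(120, 120), 0)   # 101 - 101^1 at the boundary
  expect_equal(frame_probability(130, 120), 0)
  expect_equal(frame_probability(60, 120), 101 - sqrt(101), tolerance = 1e-12)
  ed <- seq(0, 119.9, by = 0.1)
  p <- frame_probability(ed, 120)
  expect_true(all(diff(p) < 0))
  expect_true(all(p >= 0 & p <= 100))
  expect_error(frame_probability(-1, 120), "non-negative")
  expect_error(frame_probability(10, 0), "positive")
})

test_that("axis combination is a weighted mean with the zero-axes cutoff", {
  cfg <- default_axis_config()
  used <- cfg$walking$used
  w <- cfg$walking$weights

  # three of five axes at zero force the overall probability to zero
  p0 <- setNames(c(80, 90, 0, 0, 0), c("AccX", "AccZ", "GyroX", "GyroY",
                                       "GyroZ"))
  expect_equal(combine_axes(p0, used, w), 0)
  expect_equal(combine_axes(setNames(rep(0, 5), used), used, w), 0)

  # double-weighted vertical axis: (80 + 2*90 + 70 + 70 + 70) / 6
  p1 <- setNames(c(80, 90, 70, 70, 70), c("AccX", "AccZ", "GyroX", "GyroY",
                                          "GyroZ"))
  expect_equal(combine_axes(p1, used, w), 470 / 6, tolerance = 1e-12)

  # only two zeros: the mean survives
  p2 <- setNames(c(80, 90, 0, 0, 60), c("AccX", "AccZ", "GyroX", "GyroY",
                                        "GyroZ"))
  expect_gt(combine_axes(p2, used, w), 0)

  # result lies between min and max input when the cutoff does not fire
  set.seed(4)
  for (rep in 1:20) {
    p <- setNames(runif(5, 1, 100), used)
    out <- combine_axes(p, used, w)
    expect_gte(out, min(p))
    expect_lte(out, max(p))
  }
  expect_error(combine_axes(p1[-1], used, w), "missing")
})

test_that("the length penalty halves at a quarter reference and never raises p", {
  expect_equal(length_penalty(80, 50, 100), 80)     # boundary: exactly 50%
  expect_equal(length_penalty(80, 25, 100), 40)     # 80 * (2 * 25 / 100)
  expect_equal(length_penalty(80, 100, 100), 80)
  set.seed(8)
  for (rep in 1:50) {
    p <- runif(1, 0, 100)
    sl <- sample(1:150, 1)
    expect_lte(length_penalty(p, sl, 100), p)
  }
})

test_that("classification takes the arg-max with the fixed tie order", {
  m <- rbind(c(90, 10, 0), c(0, 0, 0), c(50, 50, 10))
  colnames(m) <- locomotion_activities()
  expect_equal(classify_frames(m),
               c("walking", "no_selected_activity", "walking"))
})

test_that("sliding matching assigns zero distance on exact template content", {
  ts <- toy_template_set(L = 100)
  tmpl <- ts$activities$walking$axes$AccZ

  # signal identical to the template
  sm <- sliding_match(tmpl, tmpl)
  expect_equal(sm$ed, rep(0, 100))
  expect_equal(sm$section_length, rep(100, 100))

  # two concatenated copies: full coverage at near-zero distance (window
  # phase can leave a small residual where a window straddles the join)
  sm2 <- sliding_match(rep(tmpl, 2), tmpl)
  expect_true(all(is.finite(sm2$ed)))
  expect_gte(mean(sm2$ed == 0), 0.5)
  expect_lt(max(sm2$ed), 0.1 * sum(abs(tmpl)))
})

test_that("a constant-zero signal gets one uniform positive distance", {
  tmpl <- bump_template(100)
  sm <- sliding_match(rep(0, 500), tmpl)
  expect_true(all(is.finite(sm$ed)))
  expect_equal(length(unique(sm$ed)), 1)
  expect_gt(sm$ed[1], 0)
})

test_that("every frame is covered after gap handling on arbitrary signals", {
  set.seed(13)
  tmpl <- bump_template(60)
  for (rep in 1:5) {
    sig <- rnorm(sample(200:700, 1))
    sm <- sliding_match(sig, tmpl)
    expect_true(all(is.finite(sm$ed)))
    expect_true(all(sm$section_length >= 1))
  }
})

test_that("recognition labels template-copy recordings as walking and flat signals as nothing", {
  ts <- toy_template_set(L = 100)
  rec <- copies_recording(ts, 12)
  scores <- recognize(rec, ts, axes = walking_only_axes())
  expect_s3_class(scores, "frame_scores")
  expect_gte(mean(scores$label == "walking"), 0.95)

  # constant-zero recording: every distance above threshold, nothing selected
  zero_rec <- constant_recording(600, setNames(rep(0, 6), imu_axes()))
  scores0 <- recognize(zero_rec, ts, axes = walking_only_axes())
  expect_true(all(scores0$label == "no_selected_activity"))

  expect_error(recognize(rec, ts, axes = axis_config(list())), "named list")
  expect_error(
    recognize(rec, ts,
              axes = axis_config(list(ascending_stairs = list(
                used = c("AccX", "AccZ"))))),
    "no template")
})

test_that("frame scores export the documented per-frame CSV", {
  ts <- toy_template_set(L = 50)
  rec <- copies_recording(ts, 4)
  scores <- recognize(rec, ts, axes = walking_only_axes())
  tmp <- tempfile(fileext = ".csv")
  write_frame_scores(scores, tmp)
  df <- read.csv(tmp)
  expect_equal(names(df), c("frame", "label", "p_walking", "p_ascending",
                            "p_descending"))
  expect_equal(nrow(df), rec$n_frames)
  expect_equal(df$frame[1], 0)
  expect_true(all(df$p_ascending == 0))
})

test_that("recognition configuration files override defaults selectively", {
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    axes = list(walking = list(used = c("AccX", "AccZ"),
                               weights = list(AccZ = 2))),
    zero_axes_cutoff = 2,
    window_factor = 2), tmp, auto_unbox = TRUE)
  cfg <- read_recognition_config(tmp)
  expect_equal(names(cfg$axes), "walking")
  expect_equal(cfg$axes$walking$weights[["AccZ"]], 2)
  expect_equal(cfg$control$zero_axes_cutoff, 2L)
  expect_equal(cfg$control$window_factor, 2)
  expect_equal(cfg$control$overlap_fraction, 0.25)
  expect_equal(cfg$thresholds$walking[["AccX"]], 120)
})
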