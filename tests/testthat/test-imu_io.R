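test_that("recordings load from CSV, honour column maps, and reject bad input", {
  tmp <- tempfile(fileext = ".csv")
  df <- data.frame(AccX = 0, AccY = 0, AccZ = c(0, 0, 0),
                   GyroX = 0, GyroY = 0, GyroZ = 0)
  write.csv(df, tmp, row.names = FALSE)
  rec <- read_recording(tmp)
  expect_s3_class(rec, "imu_recording")
  expect_equal(rec$n_frames, 3)
  expect_true(all(vapply(rec$channels, function(x) all(x == 0), logical(1))))

  # reordered, renamed columns mapped back to canonical order
  set.seed(1)
  vals <- matrix(rnorm(18), 3, 6)
  canon <- setNames(as.data.frame(vals), imu_axes())
  shuffled <- canon[, c(4, 1, 6, 3, 2, 5)]
  names(shuffled) <- paste0("col_", names(shuffled))
  write.csv(shuffled, tmp, row.names = FALSE)
  rec2 <- read_recording(tmp, column_map = setNames(paste0("col_", imu_axes()),
                                                    imu_axes()))
  for (ax in imu_axes()) expect_equal(rec2$channels[[ax]], canon[[ax]])

  # missing column
  write.csv(df[setdiff(names(df), "GyroZ")], tmp, row.names = FALSE)
  expect_error(read_recording(tmp), "GyroZ")

  # non-numeric cell reported with its row
  bad <- df
  bad$AccY <- c("0", "oops", "0")
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(read_recording(tmp), "row 2")

  # NaNs are rejected, not repaired
  nan <- df
  nan$AccZ <- c(0, NaN, 0)
  write.csv(nan, tmp, row.names = FALSE)
  expect_error(read_recording(tmp), "non-finite")
})

test_that("write/read round trip preserves numeric content exactly", {
  set.seed(7)
  rec <- imu_recording(setNames(lapply(1:6, function(i) rnorm(50)), imu_axes()))
  tmp <- tempfile(fileext = ".csv")
  write_recording(rec, tmp)
  back <- read_recording(tmp)
  for (ax in imu_axes()) {
    expect_identical(back$channels[[ax]], rec$channels[[ax]])
  }
})

test_that("axis rotation permutes and sign-flips channels and inverts itself", {
  rec <- imu_recording(list(AccX = c(1, 2), AccY = c(3, 4), AccZ = c(5, 6),
                            GyroX = c(7, 8), GyroY = c(9, 10),
                            GyroZ = c(11, 12)))
  expect_equal(rotate_axes(rec, c(AccX = "AccX")), rec)

  swap <- c(AccX = "AccY", AccY = "AccX")
  once <- rotate_axes(rec, swap)
  expect_equal(once$channels$AccX, c(3, 4))
  expect_equal(rotate_axes(once, swap), rec)

  flipped <- rotate_axes(rec, c(AccZ = "-AccZ"))
  expect_equal(flipped$channels$AccZ, c(-5, -6))

  expect_error(rotate_axes(rec, c(AccX = "GyroX", GyroX = "AccX")), "mix")
  expect_error(rotate_axes(rec, c(AccX = "AccY")), "bijection")
})

test_that("standing-offset correction shifts accelerometer axes to nominal and is idempotent", {
  n <- 200
  rec <- constant_recording(n, c(AccX = 0.5, AccY = -0.25, AccZ = 10.81,
                                 GyroX = 3, GyroY = 0, GyroZ = 0))
  standing <- data.frame(start_frame = 0, end_frame = 50)
  out <- correct_standing_offset(rec, standing)
  expect_equal(out$channels$AccZ, rep(9.81, n))
  expect_equal(out$channels$AccX, rep(0, n))
  expect_equal(out$channels$AccY, rep(0, n))
  # gyroscope passes through unchanged
  expect_equal(out$channels$GyroX, rec$channels$GyroX)

  # already-nominal recording is unchanged
  nom <- constant_recording(n)
  expect_equal(correct_standing_offset(nom, standing)$channels,
               nom$channels)

  # idempotence
  twice <- correct_standing_offset(out, standing)
  expect_equal(twice$channels, out$channels)

  expect_error(correct_standing_offset(rec, data.frame(start_frame = integer(0),
                                                       end_frame = integer(0))),
               "no standing reference")
  expect_error(correct_standing_offset(rec, data.frame(start_frame = 0,
                                                       end_frame = n + 1)),
               "bounds")
})

test_that("label tracks validate their interval structure and round-trip", {
  df <- data.frame(activity = c("walking", "standing"),
                   start_frame = c(0, 100), end_frame = c(100, 150))
  lt <- label_track(df)
  expect_s3_class(lt, "label_track")
  expect_error(label_track(data.frame(activity = "a", start_frame = 5,
                                      end_frame = 5)), "start_frame < end_frame")
  expect_error(label_track(data.frame(activity = c("a", "b"),
                                      start_frame = c(0, 50),
                                      end_frame = c(80, 100))), "overlap")
  tmp_csv <- tempfile(fileext = ".csv")
  tmp_json <- tempfile(fileext = ".json")
  write_labels(lt, tmp_csv)
  write_labels(lt, tmp_json)
  expect_equal(read_labels(tmp_csv), lt)
  expect_equal(read_labels(tmp_json), lt)
})
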