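# Harmonic stride profiles per activity and axis.  Each entry is a list of
# c(k, amp, phase) components evaluated as amp * sin(2*pi*k*t + phase) over
# stride-relative time t in [0, 1).  Amplitude ratios and harmonic content
# separate the three classes (vertical impact grows from walking to stair
# descent, cadence slows for stair ascent) while remaining partially
# overlapping, so misclassification paths stay exercisable.
default_stride_profiles <- function() {
  list(
    walking = list(
      AccX = list(c(1, 0.5, 0.0), c(2, 1.2, 0.8)),
      AccY = list(c(1, 1.0, 0.0), c(3, 0.3, 0.5)),
      AccZ = list(c(2, 2.0, 0.0), c(4, 0.5, 1.0)),
      GyroX = list(c(1, 25, 0.0), c(2, 8, 0.6)),
      GyroY = list(c(1, 6, 0.3), c(2, 20, 0.0)),
      GyroZ = list(c(1, 30, 0.0), c(2, 10, 1.2))),
    ascending_stairs = list(
      AccX = list(c(1, 0.6, 0.5), c(2, 0.8, 0.0)),
      AccY = list(c(1, 1.3, 0.0), c(3, 0.3, 0.8)),
      AccZ = list(c(2, 3.2, 0.4), c(4, 0.8, 0.0)),
      GyroX = list(c(1, 14, 0.0), c(2, 6, 0.4)),
      GyroY = list(c(1, 8, 0.0), c(2, 28, 0.5)),
      GyroZ = list(c(1, 17, 0.6), c(2, 5, 0.0))),
    descending_stairs = list(
      AccX = list(c(1, 0.4, 0.2), c(2, 1.6, 0.0)),
      AccY = list(c(1, 0.9, 0.0), c(3, 0.45, 0.3)),
      AccZ = list(c(2, 4.2, 0.9), c(6, 1.0, 0.0)),
      GyroX = list(c(1, 20, 0.4), c(2, 5, 0.0)),
      GyroY = list(c(1, 10, 0.0), c(2, 24, 0.8)),
      GyroZ = list(c(1, 23, 0.0), c(2, 12, 0.5))))
}

# 10-minute free-living-style mixture: locomotion bouts interleaved with
# standing and sitting, stair bouts much shorter than walking bouts.
default_schedule <- function() {
  data.frame(
    activity = c("standing", "walking", "standing", "ascending_stairs",
                 "standing", "walking", "descending_stairs", "sitting",
                 "walking", "standing", "ascending_stairs",
                 "descending_stairs", "sitting"),
    duration_s = c(30, 120, 15, 45, 15, 90, 45, 60, 60, 15, 30, 30, 45))
}

#' Configuration of the synthetic IMU generator
#'
#' The generator emulates the structure of free-living lower-back IMU
#' recordings: quasi-periodic stride waveforms for the three locomotion
#' classes (low-order harmonics per axis, per-stride duration and
#' amplitude variability), interleaved with non-periodic standing (static
#' gravity vector) and sitting (tilted gravity vector) phases.  Defaults:
#' 100 Hz, a 10-minute mixed schedule, stride durations of
#' 1.1/1.4/1.2 s (sd 0.08/0.12/0.10) for walking/ascent/descent —
#' plausible for older adults — 10% per-stride amplitude jitter, white
#' noise of 0.15 m/s^2 (acc) and 2 deg/s (gyro) during movement.
#'
#' @param seed Integer seed; the generator is deterministic given the
#'   configuration.
#' @param schedule Data frame with columns `activity`, `duration_s`.
#' @param stride_duration Named list per activity: `c(mean, sd)` seconds.
#' @param profiles Harmonic profiles per activity and axis.
#' @param amplitude_jitter_fraction Relative sd of the per-stride
#'   amplitude factor.
#' @param noise_sd Named vector `c(acc=, gyro=)`, white-noise sd during
#'   locomotion.
#' @param static_noise_sd Named vector `c(acc=, gyro=)`, sd during
#'   standing/sitting.
#' @param gravity Gravity value on the vertical axis (m/s^2).
#' @param sitting_tilt_deg Forward tilt of the gravity vector while
#'   sitting (degrees).
#' @param sampling_rate_hz Fixed at 100 for this pipeline.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              schedule = default_schedule(),
                              stride_duration = list(
                                walking = c(mean = 1.1, sd = 0.08),
                                ascending_stairs = c(mean = 1.4, sd = 0.12),
                                descending_stairs = c(mean = 1.2, sd = 0.10)),
                              profiles = default_stride_profiles(),
                              amplitude_jitter_fraction = 0.10,
                              noise_sd = c(acc = 0.15, gyro = 2.0),
                              static_noise_sd = c(acc = 0.03, gyro = 0.3),
                              gravity = 9.81,
                              sitting_tilt_deg = 20,
                              sampling_rate_hz = 100) {
  schedule <- as.data.frame(schedule)
  if (!all(c("activity", "duration_s") %in% names(schedule)) ||
      nrow(schedule) == 0) {
    stop("invalid schedule: needs non-empty columns activity, duration_s")
  }
  if (any(schedule$duration_s <= 0)) stop("invalid schedule: durations must be > 0")
  known <- c(LOCOMOTION_ACTIVITIES, "standing", "sitting")
  bad <- setdiff(schedule$activity, known)
  if (length(bad) > 0) {
    stop("invalid schedule: unknown activity ", paste(bad, collapse = ", "))
  }
  for (act in LOCOMOTION_ACTIVITIES) {
    sd_ <- stride_duration[[act]]
    if (is.null(sd_) || sd_[["mean"]] <= 0 || sd_[["sd"]] < 0) {
      stop("invalid stride_duration for ", act)
    }
  }
  structure(list(seed = as.integer(seed), schedule = schedule,
                 stride_duration = stride_duration, profiles = profiles,
                 amplitude_jitter_fraction = amplitude_jitter_fraction,
                 noise_sd = noise_sd, static_noise_sd = static_noise_sd,
                 gravity = gravity, sitting_tilt_deg = sitting_tilt_deg,
                 sampling_rate_hz = sampling_rate_hz),
            class = "simulation_config")
}

# one stride waveform: frames x 6 matrix (no noise, no gravity offset)
stride_waveform <- function(profile, n_frames, jitter) {
  t <- (seq_len(n_frames) - 1) / n_frames
  out <- matrix(0, n_frames, length(IMU_AXES),
                dimnames = list(NULL, IMU_AXES))
  for (ax in IMU_AXES) {
    w <- numeric(n_frames)
    for (h in profile[[ax]]) {
      w <- w + h[2] * sin(2 * pi * h[1] * t + h[3])
    }
    out[, ax] <- jitter * w
  }
  out
}

#' Generate a synthetic labelled IMU recording
#'
#' Deterministic for a fixed configuration (including its seed).
#' Locomotion segments are concatenations of harmonic stride waveforms
#' with per-stride duration and amplitude variability plus white noise;
#' standing is low-variance noise around the static gravity vector and
#' sitting around a tilted gravity vector.  Ground-truth labels and
#' per-stride boundary frames (for complete strides) are returned.
#'
#' @param config A [simulation_config()].
#' @return List with `recording` ([imu_recording()]), `labels`
#'   ([label_track()], one interval per schedule entry) and
#'   `stride_boundaries` (list parallel to the label rows; for locomotion
#'   intervals the 0-based frame indices of complete stride boundaries,
#'   including the interval-relative start of every complete stride and
#'   the end of the last one).
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  fs <- config$sampling_rate_hz
  segs <- list()
  labels <- list()
  boundaries <- list()
  offset <- 0L  # 0-based global frame offset

  for (i in seq_len(nrow(config$schedule))) {
    act <- config$schedule$activity[i]
    n_seg <- as.integer(round(config$schedule$duration_s[i] * fs))
    if (act %in% LOCOMOTION_ACTIVITIES) {
      sd_ <- config$stride_duration[[act]]
      prof <- config$profiles[[act]]
      chunks <- list()
      bnd <- integer(0)      # 0-based boundaries of complete strides
      filled <- 0L
      ended_partial <- FALSE
      while (filled < n_seg) {
        dur <- rnorm(1, sd_[["mean"]], sd_[["sd"]])
        dur <- min(max(dur, 0.5 * sd_[["mean"]]), 1.8 * sd_[["mean"]])
        nf <- max(20L, as.integer(round(dur * fs)))
        jit <- if (config$amplitude_jitter_fraction > 0) {
          max(0.5, rnorm(1, 1, config$amplitude_jitter_fraction))
        } else 1
        wave <- stride_waveform(prof, nf, jit)
        complete <- nf <= (n_seg - filled)
        if (complete) {
          bnd <- c(bnd, offset + filled)            # stride start
        } else {
          # truncated tail stride: close the list at its start, which is
          # the end of the last complete stride
          if (length(bnd) > 0) bnd <- c(bnd, offset + filled)
          ended_partial <- TRUE
        }
        emit <- min(nf, n_seg - filled)
        chunks[[length(chunks) + 1L]] <- wave[seq_len(emit), , drop = FALSE]
        filled <- filled + emit
        if (ended_partial) break
      }
      if (!ended_partial && length(bnd) > 0) bnd <- c(bnd, offset + filled)
      seg <- do.call(rbind, chunks)
      seg[, "AccZ"] <- seg[, "AccZ"] + config$gravity
      for (ax in ACC_AXES) {
        seg[, ax] <- seg[, ax] + rnorm(n_seg, 0, config$noise_sd[["acc"]])
      }
      for (ax in GYRO_AXES) {
        seg[, ax] <- seg[, ax] + rnorm(n_seg, 0, config$noise_sd[["gyro"]])
      }
      boundaries[[i]] <- bnd
    } else {
      mean_vec <- if (act == "standing") {
        c(AccX = 0, AccY = 0, AccZ = config$gravity,
          GyroX = 0, GyroY = 0, GyroZ = 0)
      } else {  # sitting: gravity tilted forward about the mediolateral axis
        th <- config$sitting_tilt_deg * pi / 180
        c(AccX = config$gravity * sin(th), AccY = 0,
          AccZ = config$gravity * cos(th),
          GyroX = 0, GyroY = 0, GyroZ = 0)
      }
      seg <- matrix(0, n_seg, length(IMU_AXES),
                    dimnames = list(NULL, IMU_AXES))
      for (ax in IMU_AXES) {
        fam <- if (ax %in% ACC_AXES) "acc" else "gyro"
        seg[, ax] <- mean_vec[[ax]] +
          rnorm(n_seg, 0, config$static_noise_sd[[fam]])
      }
      boundaries[[i]] <- integer(0)
    }
    segs[[i]] <- seg
    labels[[i]] <- data.frame(activity = act, start_frame = offset,
                              end_frame = offset + n_seg)
    offset <- offset + n_seg
  }
  full <- do.call(rbind, segs)
  rec <- imu_recording(as.data.frame(full), fs)
  list(recording = rec,
       labels = label_track(do.call(rbind, labels)),
       stride_boundaries = boundaries)
}

#' Tilt a recording's sensor frame
#'
#' Rotates the accelerometer and gyroscope vectors of every frame by
#' rotations about the body axes, emulating sensor misplacement.  The
#' rotation applied is `R = Rz(z) %*% Ry(y) %*% Rx(x)`.  Intended for
#' small misplacement angles (up to about 30 degrees), though any angle
#' is accepted so rotations compose exactly.
#'
#' @param rec An [imu_recording()].
#' @param tilt_deg Named numeric vector with any of `x`, `y`, `z`
#'   (degrees); missing entries are 0.
#' @return A new [imu_recording()].
#' @export
apply_tilt <- function(rec, tilt_deg) {
  stopifnot(inherits(rec, "imu_recording"))
  ang <- c(x = 0, y = 0, z = 0)
  ang[names(tilt_deg)] <- tilt_deg
  ang <- ang * pi / 180
  rx <- matrix(c(1, 0, 0,
                 0, cos(ang[["x"]]), -sin(ang[["x"]]),
                 0, sin(ang[["x"]]), cos(ang[["x"]])), 3, byrow = TRUE)
  ry <- matrix(c(cos(ang[["y"]]), 0, sin(ang[["y"]]),
                 0, 1, 0,
                 -sin(ang[["y"]]), 0, cos(ang[["y"]])), 3, byrow = TRUE)
  rz <- matrix(c(cos(ang[["z"]]), -sin(ang[["z"]]), 0,
                 sin(ang[["z"]]), cos(ang[["z"]]), 0,
                 0, 0, 1), 3, byrow = TRUE)
  rot <- rz %*% ry %*% rx
  ch <- rec$channels
  acc <- cbind(ch$AccX, ch$AccY, ch$AccZ) %*% t(rot)
  gyro <- cbind(ch$GyroX, ch$GyroY, ch$GyroZ) %*% t(rot)
  imu_recording(list(AccX = acc[, 1], AccY = acc[, 2], AccZ = acc[, 3],
                     GyroX = gyro[, 1], GyroY = gyro[, 2],
                     GyroZ = gyro[, 3]),
                rec$sampling_rate_hz)
}

#' Derive distance thresholds from a calibration recording
#'
#' The published threshold table is specific to its source population,
#' units and sampling rate; for other data (synthetic in particular)
#' thresholds must be re-derived.  Method `"match"` (default) runs the
#' layer-1 sliding matcher for every activity and axis over the
#' calibration recording's own gold intervals of that activity and takes
#' the `prob` quantile of the resulting per-frame distances — calibrating
#' the thresholds on the distance distribution they will actually face.
#' Method `"snippet"` instead takes the quantile of the DTW distances from
#' each ground-truth stride snippet to its template.
#'
#' @param rec Calibration [imu_recording()].
#' @param labels Gold [label_track()] for `rec`.
#' @param templates `template_set` whose thresholds are wanted.
#' @param stride_boundaries Required for method `"snippet"`: as in
#'   [extract_snippets()].
#' @param prob Quantile of the within-class distance distribution
#'   (default 0.95).
#' @param method `"match"` or `"snippet"`.
#' @param control A [recognition_control()].
#' @return A [threshold_table()] covering all six axes for every activity
#'   with a template and at least one gold interval.
#' @export
derive_thresholds <- function(rec, labels, templates,
                              stride_boundaries = NULL, prob = 0.95,
                              method = c("match", "snippet"),
                              control = recognition_control()) {
  method <- match.arg(method)
  stopifnot(inherits(rec, "imu_recording"), inherits(labels, "label_track"),
            inherits(templates, "template_set"))
  out <- list()
  for (act in names(templates$activities)) {
    rows <- which(labels$activity == act)
    if (length(rows) == 0) next
    tmpl <- templates$activities[[act]]
    thr <- setNames(numeric(length(IMU_AXES)), IMU_AXES)
    if (method == "match") {
      for (ax in IMU_AXES) {
        eds <- numeric(0)
        for (i in rows) {
          idx <- interval_frames(labels$start_frame[i], labels$end_frame[i])
          sm <- sliding_match(rec$channels[[ax]][idx], tmpl$axes[[ax]],
                              control)
          eds <- c(eds, sm$ed)
        }
        thr[[ax]] <- as.numeric(quantile(eds, prob))
      }
    } else {
      if (is.null(stride_boundaries)) {
        stop("method 'snippet' needs `stride_boundaries`")
      }
      snips <- extract_snippets(rec, labels, stride_boundaries)
      snips <- Filter(function(s) s$activity == act, snips)
      for (ax in IMU_AXES) {
        of_ax <- Filter(function(s) s$axis == ax, snips)
        d <- vapply(of_ax, function(s) {
          dtw_distance_cpp(s$samples, tmpl$axes[[ax]])
        }, numeric(1))
        thr[[ax]] <- as.numeric(quantile(d, prob))
      }
    }
    thr[thr <= 0] <- 1e-6  # thresholds must stay positive
    out[[act]] <- thr
  }
  threshold_table(out)
}
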