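#' Construct an IMU recording
#'
#' A recording is a fixed-rate six-channel signal: tri-axial accelerometer
#' (`AccX`, `AccY`, `AccZ`, in m/s^2) and tri-axial gyroscope (`GyroX`,
#' `GyroY`, `GyroZ`, in degrees/s), sampled at a common rate (100 Hz for
#' this pipeline).  All channels must be present, numeric, of equal length
#' and free of missing values.
#'
#' @param channels Named list or data frame holding the six channels.
#' @param sampling_rate_hz Positive sampling rate in Hz (default 100).
#' @return An object of class `imu_recording` with elements `channels`
#'   (named list of numeric vectors), `sampling_rate_hz` and `n_frames`.
#' @export
imu_recording <- function(channels, sampling_rate_hz = 100) {
  if (is.data.frame(channels)) channels <- as.list(channels)
  if (!is.list(channels)) stop("`channels` must be a named list or data frame")
  missing_ax <- setdiff(IMU_AXES, names(channels))
  if (length(missing_ax) > 0) {
    stop("missing channel(s): ", paste(missing_ax, collapse = ", "))
  }
  channels <- channels[IMU_AXES]
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1) stop("all channels must have equal length")
  for (ax in IMU_AXES) {
    x <- channels[[ax]]
    if (!is.numeric(x)) stop("channel '", ax, "' is not numeric")
    if (anyNA(x) || any(!is.finite(x))) {
      stop("channel '", ax, "' contains missing or non-finite values")
    }
    channels[[ax]] <- as.numeric(x)
  }
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1 ||
      sampling_rate_hz <= 0) {
    stop("`sampling_rate_hz` must be a positive number")
  }
  structure(list(channels = channels,
                 sampling_rate_hz = as.numeric(sampling_rate_hz),
                 n_frames = unname(lens[1])),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %d frames @ %g Hz (%.1f s)\n",
              x$n_frames, x$sampling_rate_hz,
              x$n_frames / x$sampling_rate_hz))
  invisible(x)
}

#' Read an IMU recording from CSV
#'
#' Expects one row per frame and the six canonical numeric columns (see
#' [imu_axes()]); extra columns are ignored.  A `time` column, if present,
#' is checked against the declared sampling rate.  `column_map` allows
#' files with other column names (e.g. ADAPT-style exports) to be mapped
#' onto the canonical axes.
#'
#' @param path CSV file path.
#' @param column_map Optional named character vector mapping canonical axis
#'   names to the column names used in the file, e.g.
#'   `c(AccX = "acc_ap", ...)`.
#' @param sampling_rate_hz Sampling rate the file is assumed to have.
#' @return An [imu_recording()].
#' @export
read_recording <- function(path, column_map = NULL, sampling_rate_hz = 100) {
  df <- read.csv(path, check.names = FALSE)
  if (!is.null(column_map)) {
    if (is.null(names(column_map)) || !all(names(column_map) %in% IMU_AXES)) {
      stop("`column_map` must be named by canonical axis names")
    }
    for (ax in names(column_map)) {
      src <- column_map[[ax]]
      if (!src %in% names(df)) {
        stop("format error: column '", src, "' (mapped to ", ax,
             ") not found in ", path)
      }
    }
  }
  channels <- list()
  for (ax in IMU_AXES) {
    src <- if (!is.null(column_map) && ax %in% names(column_map)) {
      column_map[[ax]]
    } else {
      ax
    }
    if (!src %in% names(df)) {
      stop("format error: missing column '", src, "' in ", path)
    }
    col <- df[[src]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad) > 0) {
        stop("parse error: non-numeric value in column '", src,
             "' at row ", bad[1])
      }
      col <- num
    }
    if (anyNA(col) || any(!is.finite(col))) {
      bad <- which(is.na(col) | !is.finite(col))
      stop("column '", src, "' contains missing/non-finite value at row ",
           bad[1])
    }
    channels[[ax]] <- col
  }
  tcol <- intersect(c("time", "Time", "t"), names(df))
  if (length(tcol) > 0 && nrow(df) >= 2) {
    dt <- median(diff(df[[tcol[1]]]))
    if (is.finite(dt) && abs(dt - 1 / sampling_rate_hz) > 1e-6) {
      stop(sprintf("time column spacing (%.6f s) does not match %g Hz",
                   dt, sampling_rate_hz))
    }
  }
  imu_recording(channels, sampling_rate_hz)
}

#' Write an IMU recording to CSV
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces the numeric content exactly.
#'
#' @param rec An [imu_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  cols <- lapply(rec$channels, function(x) sprintf("%.17g", x))
  lines <- c(paste(IMU_AXES, collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a label track
#'
#' A label track is a set of non-overlapping activity intervals over a
#' recording.  Frames are 0-based and intervals half-open `[start, end)`,
#' which keeps interval arithmetic unambiguous.
#'
#' @param intervals Data frame with columns `activity`, `start_frame`,
#'   `end_frame`.
#' @return An object of class `label_track` (a data frame).
#' @export
label_track <- function(intervals) {
  df <- as.data.frame(intervals)
  need <- c("activity", "start_frame", "end_frame")
  if (!all(need %in% names(df))) {
    stop("label track needs columns: ", paste(need, collapse = ", "))
  }
  df <- df[need]
  df$activity <- as.character(df$activity)
  df$start_frame <- as.integer(df$start_frame)
  df$end_frame <- as.integer(df$end_frame)
  if (nrow(df) > 0) {
    if (any(df$start_frame < 0)) stop("start_frame must be >= 0")
    if (any(df$start_frame >= df$end_frame)) {
      stop("intervals must satisfy start_frame < end_frame")
    }
    if (is.unsorted(df$start_frame)) stop("intervals must be sorted by start")
    if (nrow(df) > 1 &&
        any(df$start_frame[-1] < df$end_frame[-nrow(df)])) {
      stop("intervals may not overlap")
    }
  }
  rownames(df) <- NULL
  class(df) <- c("label_track", "data.frame")
  df
}

#' Validate a label track against a recording length
#' @param labels A [label_track()].
#' @param n_frames Number of frames in the associated recording.
#' @return `labels`, invisibly.
#' @export
validate_labels <- function(labels, n_frames) {
  stopifnot(inherits(labels, "label_track"))
  if (nrow(labels) > 0 && max(labels$end_frame) > n_frames) {
    stop("label interval extends beyond recording (", n_frames, " frames)")
  }
  invisible(labels)
}

#' Read activity labels from CSV or JSON
#'
#' @param path File path; `.json` files are parsed as a list of objects
#'   with keys `activity`, `start_frame`, `end_frame`, anything else as CSV
#'   with the same header.
#' @return A [label_track()].
#' @export
read_labels <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    df <- read.csv(path)
  }
  label_track(df)
}

#' Write activity labels to CSV or JSON
#' @param labels A [label_track()].
#' @param path Output path; format chosen by extension as in [read_labels()].
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_track"))
  df <- as.data.frame(unclass(labels), stringsAsFactors = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = FALSE)
  } else {
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# interval frames as 1-based indices (0-based half-open on disk)
interval_frames <- function(start_frame, end_frame) {
  seq.int(start_frame + 1L, end_frame)
}

#' Rotate / permute the axes of a recording
#'
#' Applies an axis permutation with optional sign flips so that arbitrary
#' mounting conventions can be brought onto the canonical frame
#' (z vertical, y mediolateral, x anterior-posterior).  The permutation
#' must map accelerometer axes to accelerometer axes and gyroscope axes to
#' gyroscope axes.
#'
#' @param rec An [imu_recording()].
#' @param rotation Named character vector: names are destination axes,
#'   values are source axes, optionally prefixed with `-` for a sign flip,
#'   e.g. `c(AccX = "AccY", AccY = "-AccX")`.  Axes not mentioned are left
#'   unchanged.
#' @return A new [imu_recording()].
#' @export
rotate_axes <- function(rec, rotation) {
  stopifnot(inherits(rec, "imu_recording"))
  if (length(rotation) == 0) return(rec)
  dst <- names(rotation)
  if (is.null(dst) || any(!dst %in% IMU_AXES)) {
    stop("rotation must be named by canonical destination axes")
  }
  if (anyDuplicated(dst)) stop("duplicate destination axis in rotation")
  sign <- ifelse(grepl("^-", rotation), -1, 1)
  src <- sub("^-", "", rotation)
  if (any(!src %in% IMU_AXES)) {
    stop("unknown source axis: ", paste(setdiff(src, IMU_AXES), collapse = ", "))
  }
  # fill identity for unmentioned axes, then check bijection + family purity
  full_src <- setNames(IMU_AXES, IMU_AXES)
  full_sign <- setNames(rep(1, 6), IMU_AXES)
  full_src[dst] <- src
  full_sign[dst] <- sign
  if (anyDuplicated(full_src)) stop("rotation is not a bijection of the axes")
  acc_ok <- all(full_src[ACC_AXES] %in% ACC_AXES)
  gyro_ok <- all(full_src[GYRO_AXES] %in% GYRO_AXES)
  if (!acc_ok || !gyro_ok) {
    stop("rotation may not mix accelerometer and gyroscope axes")
  }
  ch <- rec$channels
  new_ch <- lapply(IMU_AXES, function(ax) full_sign[[ax]] * ch[[full_src[[ax]]]])
  names(new_ch) <- IMU_AXES
  imu_recording(new_ch, rec$sampling_rate_hz)
}

#' Correct the accelerometer standing offset
#'
#' In upright standing with an ideally attached lower-back sensor, the
#' vertical accelerometer reads the gravity value (9.81 m/s^2) and the two
#' perpendicular accelerometer axes read 0.  The mean over the supplied
#' standing frames is compared against these nominal values and the whole
#' accelerometer channel is shifted by the measured-minus-nominal
#' difference.  Gyroscope channels pass through unchanged.  The operation
#' is idempotent.
#'
#' @param rec An [imu_recording()].
#' @param standing_intervals Data frame (or [label_track()]) with columns
#'   `start_frame`, `end_frame` (0-based half-open) giving the standing
#'   phases; must be non-empty and within the recording.
#' @param gravity Nominal gravity value on `AccZ` (default 9.81 m/s^2).
#' @return A corrected [imu_recording()] with attribute `"offsets"` holding
#'   the subtracted per-axis offsets.
#' @export
correct_standing_offset <- function(rec, standing_intervals, gravity = 9.81) {
  stopifnot(inherits(rec, "imu_recording"))
  si <- as.data.frame(standing_intervals)
  if (nrow(si) == 0) stop("no standing reference: `standing_intervals` is empty")
  if (!all(c("start_frame", "end_frame") %in% names(si))) {
    stop("`standing_intervals` needs columns start_frame, end_frame")
  }
  if (any(si$start_frame < 0) || any(si$end_frame > rec$n_frames) ||
      any(si$start_frame >= si$end_frame)) {
    stop("standing interval out of recording bounds")
  }
  idx <- unlist(mapply(interval_frames, si$start_frame, si$end_frame,
                       SIMPLIFY = FALSE))
  nominal <- c(AccX = 0, AccY = 0, AccZ = gravity)
  ch <- rec$channels
  offsets <- setNames(numeric(3), ACC_AXES)
  for (ax in ACC_AXES) {
    offsets[[ax]] <- mean(ch[[ax]][idx]) - nominal[[ax]]
    ch[[ax]] <- ch[[ax]] - offsets[[ax]]
  }
  out <- imu_recording(ch, rec$sampling_rate_hz)
  attr(out, "offsets") <- offsets
  out
}
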