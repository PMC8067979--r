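#' Per-axis maximum-acceptable-distance thresholds
#'
#' The default table gives the maximum acceptable accumulated DTW distance
#' per activity and axis for 100 Hz lower-back recordings in m/s^2 (acc)
#' and deg/s (gyro); distances above the threshold yield a frame
#' probability of 0.  The values are configuration, not constants: any
#' deviation in units or sampling rate invalidates them, and for synthetic
#' data thresholds should be re-derived with [derive_thresholds()].
#'
#' @return Object of class `threshold_table`: named list (activity) of
#'   named numeric vectors (axis -> threshold).
#' @export
default_thresholds <- function() {
  threshold_table(list(
    walking = c(AccX = 120, AccY = 70, AccZ = 80,
                GyroX = 13, GyroY = 12, GyroZ = 21),
    ascending_stairs = c(AccX = 110, AccY = 110, AccZ = 120,
                         GyroX = 14, GyroY = 14, GyroZ = 20),
    descending_stairs = c(AccX = 110, AccY = 90, AccZ = 120,
                          GyroX = 14, GyroY = 11, GyroZ = 25)))
}

#' Validate a threshold table
#' @param x Named list (activity) of named numeric vectors (axis ->
#'   positive threshold).
#' @return `x` with class `threshold_table`.
#' @export
threshold_table <- function(x) {
  if (!is.list(x) || is.null(names(x)) || length(x) == 0) {
    stop("threshold table must be a non-empty named list")
  }
  for (act in names(x)) {
    v <- x[[act]]
    if (!is.numeric(v) || is.null(names(v)) || !all(names(v) %in% IMU_AXES)) {
      stop("thresholds for '", act, "' must be named by canonical axes")
    }
    if (any(v <= 0)) stop("thresholds for '", act, "' must be positive")
  }
  structure(x, class = "threshold_table")
}

#' Per-activity axis selection and weights
#'
#' The default configuration reflects which axes discriminate each
#' activity best at the L5 sensor position: the vertical (`AccZ`) and
#' anterior-posterior (`AccX`) accelerometer axes are used for every
#' activity; walking additionally uses all three gyroscope axes with the
#' vertical accelerometer weighted double (it alone separates walking
#' well); stair ascent adds `AccY` and `GyroY`; stair descent adds `AccY`,
#' `GyroY` and `GyroZ`.
#'
#' @return Object of class `axis_config`: named list (activity) of
#'   `list(used, weights)`.
#' @export
default_axis_config <- function() {
  axis_config(list(
    walking = list(used = c("AccX", "AccZ", "GyroX", "GyroY", "GyroZ"),
                   weights = c(AccZ = 2)),
    ascending_stairs = list(used = c("AccX", "AccY", "AccZ", "GyroY")),
    descending_stairs = list(used = c("AccX", "AccY", "AccZ",
                                      "GyroY", "GyroZ"))))
}

#' Validate an axis configuration
#'
#' @param x Named list (activity) of lists with elements `used` (axis
#'   names; must contain `AccX` and `AccZ`) and optional `weights` (named
#'   positive numbers, default 1).
#' @return `x`, normalized, with class `axis_config`.
#' @export
axis_config <- function(x) {
  if (!is.list(x) || is.null(names(x)) || length(x) == 0) {
    stop("axis config must be a non-empty named list of activities")
  }
  for (act in names(x)) {
    used <- x[[act]]$used
    if (is.null(used) || !all(used %in% IMU_AXES)) {
      stop("axes for '", act, "' must come from the six canonical axes")
    }
    if (!all(c("AccX", "AccZ") %in% used)) {
      stop("'", act, "': AccX and AccZ must be used for every activity")
    }
    w <- setNames(rep(1, length(used)), used)
    if (!is.null(x[[act]]$weights)) {
      ww <- x[[act]]$weights
      if (is.null(names(ww)) || !all(names(ww) %in% used)) {
        stop("weights for '", act, "' must be named by used axes")
      }
      if (any(ww <= 0)) stop("weights must be positive")
      w[names(ww)] <- ww
    }
    x[[act]] <- list(used = used, weights = w)
  }
  structure(x, class = "axis_config")
}

#' Tunable parameters of the recognition pipeline
#'
#' All defaults are the method's published operating point at 100 Hz:
#' sliding windows of 1.5 reference lengths, stretch regions of at least
#' 10% of the reference length as trim borders, refined windows of at
#' least 40%, 25% window overlap, gap rules at 25%/75%, overall
#' probability forced to 0 when at least 3 axes show 0, and the length
#' penalty below 50% of the reference length.
#'
#' @param window_factor Sliding window length as a multiple of the
#'   reference template length.
#' @param overlap_fraction Overlap of consecutive windows, as a fraction
#'   of the reference length.
#' @param stretch_min_fraction Minimum stretch-region length (fraction of
#'   reference length) used for window refinement.
#' @param min_window_fraction Minimum refined-window length (fraction of
#'   reference length).
#' @param gap_fill_max_fraction Gaps shorter than this fraction of the
#'   reference length are filled from the bordering sections.
#' @param gap_rematch_max_fraction Gaps up to this fraction are re-matched
#'   as one window; longer gaps re-enter the sliding loop.
#' @param zero_axes_cutoff Number of zero-probability axes that forces the
#'   combined probability to 0.
#' @param length_cutoff_fraction Sections shorter than this fraction of
#'   the reference length have their probability scaled down.
#' @return A named list of class `recognition_control`.
#' @export
recognition_control <- function(window_factor = 1.5,
                                overlap_fraction = 0.25,
                                stretch_min_fraction = 0.10,
                                min_window_fraction = 0.40,
                                gap_fill_max_fraction = 0.25,
                                gap_rematch_max_fraction = 0.75,
                                zero_axes_cutoff = 3L,
                                length_cutoff_fraction = 0.5) {
  stopifnot(window_factor > 0, overlap_fraction >= 0,
            stretch_min_fraction > 0, stretch_min_fraction < 1,
            min_window_fraction > 0, min_window_fraction < 1,
            gap_fill_max_fraction > 0,
            gap_rematch_max_fraction >= gap_fill_max_fraction,
            zero_axes_cutoff >= 1, length_cutoff_fraction > 0)
  structure(list(window_factor = window_factor,
                 overlap_fraction = overlap_fraction,
                 stretch_min_fraction = stretch_min_fraction,
                 min_window_fraction = min_window_fraction,
                 gap_fill_max_fraction = gap_fill_max_fraction,
                 gap_rematch_max_fraction = gap_rematch_max_fraction,
                 zero_axes_cutoff = as.integer(zero_axes_cutoff),
                 length_cutoff_fraction = length_cutoff_fraction),
            class = "recognition_control")
}

#' Layer 1: sliding-window template matching on one axis
#'
#' Slides a window of `window_factor` reference lengths along the signal;
#' each window is refined to its best-matching section by
#' [refine_and_score()], and the section's accumulated distance and length
#' are assigned to every frame of the section (where assignments overlap,
#' the smaller distance always wins).  The next window starts at the
#' section end minus `overlap_fraction` of the reference length.  Gaps
#' left between sections are then closed: gaps shorter than
#' `gap_fill_max_fraction` of the reference length inherit the smaller
#' bordering section's values, gaps up to `gap_rematch_max_fraction` are
#' re-matched as a single window, and longer gaps re-enter the sliding
#' loop, so that every frame ends up with a distance.
#'
#' @param signal_axis Numeric vector, one channel of a recording.
#' @param template_axis Numeric vector, the matching template channel.
#' @param control A [recognition_control()].
#' @return List with numeric vectors `ed` (per-frame accumulated DTW
#'   distance of the section covering the frame) and `section_length`
#'   (its length in frames), both of `length(signal_axis)`.
#' @export
sliding_match <- function(signal_axis, template_axis,
                          control = recognition_control()) {
  n <- length(signal_axis)
  L <- length(template_axis)
  if (n < 1 || L < 1) stop("signal and template must be non-empty")
  W <- max(1L, as.integer(round(control$window_factor * L)))
  ov <- as.integer(round(control$overlap_fraction * L))

  span_sections <- function(lo, hi) {
    secs <- list()
    pos <- lo
    repeat {
      we <- min(pos + W - 1L, hi)
      r <- refine_and_score(signal_axis[pos:we], template_axis,
                            control$min_window_fraction,
                            control$stretch_min_fraction)
      s_abs <- pos + r$best_start - 1L
      e_abs <- pos + r$best_end - 1L
      secs[[length(secs) + 1L]] <- c(s_abs, e_abs, r$best_distance)
      if (we >= hi) break
      pos <- max(pos + 1L, e_abs - ov + 1L)
    }
    secs
  }

  ed <- rep(Inf, n)
  sl <- rep(NA_real_, n)
  pending <- span_sections(1L, n)
  for (sweep in 1:20) {
    for (s in pending) {
      idx <- s[1]:s[2]
      upd <- idx[ed[idx] > s[3]]
      ed[upd] <- s[3]
      sl[upd] <- s[2] - s[1] + 1
    }
    pending <- list()
    open <- is.infinite(ed)
    if (!any(open)) break
    r <- rle(open)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (g in which(r$values)) {
      g1 <- starts[g]; g2 <- ends[g]
      len <- g2 - g1 + 1L
      if (len > control$gap_rematch_max_fraction * L + 1e-9) {
        pending <- c(pending, span_sections(g1, g2))
      } else if (len >= control$gap_fill_max_fraction * L - 1e-9) {
        rr <- refine_and_score(signal_axis[g1:g2], template_axis,
                               control$min_window_fraction,
                               control$stretch_min_fraction)
        pending <- c(pending, list(c(g1 + rr$best_start - 1L,
                                     g1 + rr$best_end - 1L,
                                     rr$best_distance)))
      } else {
        # short gap: inherit the smaller bordering section's values
        left <- if (g1 > 1L) ed[g1 - 1L] else Inf
        right <- if (g2 < n) ed[g2 + 1L] else Inf
        if (is.finite(left) || is.finite(right)) {
          src <- if (left <= right) g1 - 1L else g2 + 1L
          ed[g1:g2] <- ed[src]
          sl[g1:g2] <- sl[src]
        }
      }
    }
    if (length(pending) == 0 && !any(is.infinite(ed))) break
  }
  # safety net: any frame still open inherits its nearest assigned neighbour
  open <- which(is.infinite(ed))
  for (i in open) {
    fin <- which(is.finite(ed))
    j <- fin[which.min(abs(fin - i))]
    ed[i] <- ed[j]
    sl[i] <- sl[j]
  }
  list(ed = ed, section_length = sl)
}

#' Layer 2: distance-to-probability conversion (per frame, per axis)
#'
#' Converts an accumulated DTW distance into a probability (in percent)
#' that the frame belongs to the activity the template describes:
#' `P = 101 - 101^(ed / threshold)` for `ed < threshold`, and 0 otherwise.
#' A perfect match (`ed = 0`) gives 100; the probability decreases
#' strictly and continuously with growing distance and reaches 0 at the
#' threshold.
#'
#' @param ed Non-negative accumulated distance(s); vectorized.
#' @param threshold Positive maximum acceptable distance.
#' @return Probability value(s) in `[0, 100]`.
#' @export
frame_probability <- function(ed, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop("`threshold` must be a positive number")
  }
  if (any(ed < 0, na.rm = TRUE)) stop("`ed` must be non-negative")
  p <- ifelse(ed < threshold, 101 - 101^(ed / threshold), 0)
  pmin(pmax(p, 0), 100)
}

# vectorized combination over a frames x axes probability matrix
combine_axes_matrix <- function(p_mat, weights, zero_axes_cutoff) {
  w <- weights[colnames(p_mat)]
  comb <- as.numeric(p_mat %*% w) / sum(w)
  zeros <- rowSums(p_mat == 0)
  comb[zeros >= zero_axes_cutoff] <- 0
  comb
}

#' Combine per-axis probabilities into one activity probability
#'
#' The combined value is the weight-weighted arithmetic mean of the
#' per-axis probabilities (for walking the vertical accelerometer axis is
#' weighted double by default), except that the result is forced to 0 when
#' at least `zero_axes_cutoff` axes show probability 0.
#'
#' @param p_axis Named numeric vector of per-axis probabilities covering
#'   exactly `used_axes`.
#' @param used_axes Axes entering the combination (default: the names of
#'   `p_axis`).
#' @param weights Named positive weights (default 1 per axis).
#' @param zero_axes_cutoff Zero-axis count that forces the result to 0
#'   (default 3).
#' @return Combined probability in `[0, 100]`.
#' @export
combine_axes <- function(p_axis, used_axes = names(p_axis), weights = NULL,
                         zero_axes_cutoff = 3L) {
  if (is.null(names(p_axis))) stop("`p_axis` must be named by axis")
  miss <- setdiff(used_axes, names(p_axis))
  if (length(miss) > 0) {
    stop("axis missing from p_axis: ", paste(miss, collapse = ", "))
  }
  extra <- setdiff(names(p_axis), used_axes)
  if (length(extra) > 0) {
    stop("p_axis must cover exactly the used axes; unexpected: ",
         paste(extra, collapse = ", "))
  }
  w <- setNames(rep(1, length(used_axes)), used_axes)
  if (!is.null(weights)) w[names(weights)] <- weights
  p_mat <- matrix(p_axis[used_axes], nrow = 1,
                  dimnames = list(NULL, used_axes))
  combine_axes_matrix(p_mat, w, zero_axes_cutoff)
}

#' Penalize probabilities of implausibly short sections
#'
#' A regular stride is unlikely to take less than half the reference
#' length, so when the matched section covering a frame is shorter than
#' `cutoff_fraction` of the reference length, the probability is scaled by
#' `2 * section_length / reference_length`; at and above the cutoff it is
#' unchanged.  The result is clamped to `[0, 100]`.
#'
#' @param p Probability value(s) in percent; vectorized.
#' @param section_length Matched section length(s) in frames.
#' @param reference_length Reference template length in frames.
#' @param cutoff_fraction Fraction of the reference length below which the
#'   penalty applies (default 0.5).
#' @return Penalized probability value(s).
#' @export
length_penalty <- function(p, section_length, reference_length,
                           cutoff_fraction = 0.5) {
  if (reference_length <= 0) stop("`reference_length` must be positive")
  if (any(section_length <= 0)) stop("`section_length` must be positive")
  f <- ifelse(section_length < cutoff_fraction * reference_length,
              2 * section_length / reference_length, 1)
  pmin(pmax(p * f, 0), 100)
}

#' Per-frame classification from overall probabilities
#'
#' Each frame is labelled with the activity of maximal overall probability
#' when that maximum is positive; exact ties go to the earlier activity in
#' the fixed order walking, ascending_stairs, descending_stairs; frames
#' where all probabilities are 0 are labelled `"no_selected_activity"`.
#'
#' @param p_overall Numeric matrix, frames x activities, with activity
#'   column names.
#' @return Character vector of per-frame labels.
#' @export
classify_frames <- function(p_overall) {
  if (is.null(colnames(p_overall))) {
    stop("`p_overall` must have activity column names")
  }
  best <- max.col(p_overall, ties.method = "first")
  lab <- colnames(p_overall)[best]
  mx <- p_overall[cbind(seq_len(nrow(p_overall)), best)]
  lab[mx <= 0] <- NO_ACTIVITY
  lab
}

#' Recognize locomotion in a recording
#'
#' Runs the full two-layer pipeline: for every activity and every used
#' axis, [sliding_match()] assigns a per-frame accumulated DTW distance
#' against the activity's reference template; [frame_probability()]
#' converts distances to per-axis probabilities with the activity/axis
#' threshold; [combine_axes()] merges the axes; the length penalty
#' down-weights implausibly short sections; and [classify_frames()] picks
#' the per-frame label.
#'
#' @param rec A preprocessed [imu_recording()].
#' @param templates A `template_set` covering all configured activities.
#' @param thresholds A [threshold_table()] (default: the published table).
#' @param axes An [axis_config()] (default: the published selection).
#' @param control A [recognition_control()].
#' @return Object of class `frame_scores`: list with `p_overall` (frames x
#'   activities matrix), `label` (character vector), `ed` and
#'   `section_length` (per-activity matrices of per-frame values for the
#'   used axes), `activities`, `n_frames`.
#' @export
recognize <- function(rec, templates,
                      thresholds = default_thresholds(),
                      axes = default_axis_config(),
                      control = recognition_control()) {
  stopifnot(inherits(rec, "imu_recording"),
            inherits(templates, "template_set"))
  if (!inherits(axes, "axis_config")) axes <- axis_config(axes)
  if (!inherits(thresholds, "threshold_table")) {
    thresholds <- threshold_table(thresholds)
  }
  acts <- names(axes)
  miss <- setdiff(acts, names(templates$activities))
  if (length(miss) > 0) {
    stop("no template for activity: ", paste(miss, collapse = ", "))
  }
  n <- rec$n_frames
  p_overall <- matrix(0, n, length(acts), dimnames = list(NULL, acts))
  ed_list <- list()
  sl_list <- list()
  for (act in acts) {
    tmpl <- templates$activities[[act]]
    used <- axes[[act]]$used
    thr <- thresholds[[act]]
    miss_thr <- setdiff(used, names(thr))
    if (length(miss_thr) > 0) {
      stop("missing threshold for ", act, ": ",
           paste(miss_thr, collapse = ", "))
    }
    p_mat <- matrix(0, n, length(used), dimnames = list(NULL, used))
    ed_mat <- matrix(NA_real_, n, length(used), dimnames = list(NULL, used))
    sl_mat <- matrix(NA_real_, n, length(used), dimnames = list(NULL, used))
    for (ax in used) {
      sm <- sliding_match(rec$channels[[ax]], tmpl$axes[[ax]], control)
      ed_mat[, ax] <- sm$ed
      sl_mat[, ax] <- sm$section_length
      p_mat[, ax] <- frame_probability(sm$ed, thr[[ax]])
    }
    comb <- combine_axes_matrix(p_mat, axes[[act]]$weights,
                                control$zero_axes_cutoff)
    sec_len <- apply(sl_mat, 1, median)
    p_overall[, act] <- length_penalty(comb, sec_len,
                                       tmpl$reference_length,
                                       control$length_cutoff_fraction)
    ed_list[[act]] <- ed_mat
    sl_list[[act]] <- sl_mat
  }
  structure(list(p_overall = p_overall,
                 label = classify_frames(p_overall),
                 ed = ed_list,
                 section_length = sl_list,
                 activities = acts,
                 n_frames = n),
            class = "frame_scores")
}

#' @export
print.frame_scores <- function(x, ...) {
  cat(sprintf("<frame_scores> %d frames\n", x$n_frames))
  tab <- table(factor(x$label, levels = c(x$activities, NO_ACTIVITY)))
  for (nm in names(tab)) {
    cat(sprintf("  %-22s %7d frames (%5.1f%%)\n", nm, tab[[nm]],
                100 * tab[[nm]] / x$n_frames))
  }
  invisible(x)
}

#' Write per-frame recognition output to CSV
#'
#' Columns: `frame` (0-based), `label`, `p_walking`, `p_ascending`,
#' `p_descending`.  Probabilities of activities absent from the scored
#' configuration are written as 0.
#'
#' @param scores A `frame_scores` object from [recognize()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_frame_scores <- function(scores, path) {
  stopifnot(inherits(scores, "frame_scores"))
  get_col <- function(act) {
    if (act %in% colnames(scores$p_overall)) scores$p_overall[, act] else
      rep(0, scores$n_frames)
  }
  df <- data.frame(frame = seq_len(scores$n_frames) - 1L,
                   label = scores$label,
                   p_walking = get_col("walking"),
                   p_ascending = get_col("ascending_stairs"),
                   p_descending = get_col("descending_stairs"))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a recognition configuration file
#'
#' JSON (or YAML, if the `yaml` package is available) with any of the
#' keys `thresholds`, `axes` (`{activity: {used: [...], weights: {...}}}`)
#' and the scalar control parameters of [recognition_control()]; missing
#' keys keep their published defaults.
#'
#' @param path Configuration file path.
#' @return List with elements `thresholds`, `axes`, `control`.
#' @export
read_recognition_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configuration")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  thresholds <- if (!is.null(raw$thresholds)) {
    threshold_table(lapply(raw$thresholds, function(v) unlist(v)))
  } else {
    default_thresholds()
  }
  axes <- if (!is.null(raw$axes)) {
    axis_config(lapply(raw$axes, function(a) {
      list(used = unlist(a$used),
           weights = if (!is.null(a$weights)) unlist(a$weights))
    }))
  } else {
    default_axis_config()
  }
  ctrl_args <- raw[intersect(names(raw), names(formals(recognition_control)))]
  control <- do.call(recognition_control, ctrl_args)
  list(thresholds = thresholds, axes = axes, control = control)
}
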