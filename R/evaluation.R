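#' Frame-level evaluation against a gold-standard label track
#'
#' Builds a confusion matrix of performed (gold) versus recognized
#' locomotion classes and per-activity one-vs-rest sensitivity and
#' specificity, all at frame level.  Frames whose gold label is in
#' `excluded_labels`, and frames not covered by any gold interval, are not
#' evaluable and are dropped from every count.  Gold frames outside the
#' locomotion classes form the "other" row and contribute only as
#' negatives (specificity).
#'
#' @param predicted Character vector of per-frame labels (activity names
#'   or `"no_selected_activity"`), one per recording frame.
#' @param gold A [label_track()] over the same recording.
#' @param excluded_labels Gold labels excluded from evaluation
#'   (default `"undefined"` and `"walking with transition"`).
#' @param activities Locomotion classes under evaluation.
#' @return Object of class `confusion_matrix`: list with `counts` (rows =
#'   gold classes + `"other"`, columns = recognized classes +
#'   `"no_selected_activity"`), `row_percent`, `metrics` (data frame with
#'   per-activity `sensitivity` and `specificity` in percent),
#'   `n_evaluable` and `no_evaluable` flag.
#' @export
evaluate_recognition <- function(predicted, gold,
                                 excluded_labels = c("undefined",
                                                     "walking with transition"),
                                 activities = LOCOMOTION_ACTIVITIES) {
  stopifnot(inherits(gold, "label_track"))
  n <- length(predicted)
  if (nrow(gold) > 0 && max(gold$end_frame) > n) {
    stop("length mismatch: gold labels extend beyond the ", n,
         " predicted frames")
  }
  gold_frame <- rep(NA_character_, n)
  for (i in seq_len(nrow(gold))) {
    gold_frame[interval_frames(gold$start_frame[i], gold$end_frame[i])] <-
      gold$activity[i]
  }
  evaluable <- !is.na(gold_frame) & !(gold_frame %in% excluded_labels)
  g <- gold_frame[evaluable]
  p <- as.character(predicted)[evaluable]

  row_levels <- c(activities, "other")
  col_levels <- c(activities, NO_ACTIVITY)
  g_cls <- ifelse(g %in% activities, g, "other")
  p_cls <- ifelse(p %in% activities, p, NO_ACTIVITY)
  counts <- table(factor(g_cls, levels = row_levels),
                  factor(p_cls, levels = col_levels))
  counts <- unclass(counts)
  names(dimnames(counts)) <- c("performed", "recognized")

  n_eval <- sum(evaluable)
  rs <- rowSums(counts)
  row_percent <- counts
  for (r in seq_len(nrow(counts))) {
    row_percent[r, ] <- if (rs[r] > 0) 100 * counts[r, ] / rs[r] else NA_real_
  }

  metrics <- data.frame(activity = activities,
                        sensitivity = NA_real_, specificity = NA_real_)
  for (k in seq_along(activities)) {
    a <- activities[k]
    tp <- counts[a, a]
    fn <- rs[a] - tp
    fp <- sum(counts[setdiff(row_levels, a), a])
    tn <- n_eval - tp - fn - fp
    metrics$sensitivity[k] <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA
    metrics$specificity[k] <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA
  }
  structure(list(counts = counts, row_percent = row_percent,
                 metrics = metrics, n_evaluable = n_eval,
                 no_evaluable = n_eval == 0),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  if (x$no_evaluable) {
    cat("<confusion_matrix> no evaluable frames\n")
    return(invisible(x))
  }
  cat(sprintf("<confusion_matrix> %d evaluable frames\n", x$n_evaluable))
  cat("\nCounts (performed x recognized):\n")
  print(x$counts)
  cat("\nRow percent:\n")
  print(round(x$row_percent, 1))
  cat("\n")
  for (k in seq_len(nrow(x$metrics))) {
    cat(sprintf("  %-18s sensitivity %6.1f%%  specificity %6.1f%%\n",
                x$metrics$activity[k], x$metrics$sensitivity[k],
                x$metrics$specificity[k]))
  }
  invisible(x)
}

#' Write a confusion matrix to CSV files
#'
#' Writes `<prefix>_counts.csv`, `<prefix>_percent.csv` and
#' `<prefix>_metrics.csv`.
#'
#' @param cm A `confusion_matrix` from [evaluate_recognition()].
#' @param prefix Output path prefix.
#' @return The three paths, invisibly.
#' @export
write_confusion_matrix <- function(cm, prefix) {
  stopifnot(inherits(cm, "confusion_matrix"))
  paths <- paste0(prefix, c("_counts.csv", "_percent.csv", "_metrics.csv"))
  write.csv(cm$counts, paths[1])
  write.csv(cm$row_percent, paths[2])
  write.csv(cm$metrics, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Shrink locomotion intervals by their boundary frames
#'
#' Locomotion episodes begin and end with initiation and termination
#' movements that differ from mid-episode strides; dropping the first and
#' last `n_frames` (1 s at 100 Hz) of each locomotion interval removes
#' them from evaluation.  Intervals of length `<= 2 * n_frames` are
#' removed entirely; non-locomotion intervals are untouched.  The trimmed
#' margins are left unlabelled, so [evaluate_recognition()] treats them as
#' non-evaluable.
#'
#' @param gold A [label_track()].
#' @param n_frames Frames to drop on each side (default 100).
#' @param activities Activities subject to trimming (default the three
#'   locomotion classes).
#' @return A new [label_track()].
#' @export
exclude_boundary_frames <- function(gold, n_frames = 100,
                                    activities = LOCOMOTION_ACTIVITIES) {
  stopifnot(inherits(gold, "label_track"), n_frames >= 0)
  if (nrow(gold) == 0 || n_frames == 0) return(gold)
  keep <- logical(nrow(gold))
  df <- as.data.frame(unclass(gold))
  for (i in seq_len(nrow(df))) {
    if (df$activity[i] %in% activities) {
      df$start_frame[i] <- df$start_frame[i] + n_frames
      df$end_frame[i] <- df$end_frame[i] - n_frames
      keep[i] <- df$end_frame[i] > df$start_frame[i]
    } else {
      keep[i] <- TRUE
    }
  }
  label_track(df[keep, , drop = FALSE])
}
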