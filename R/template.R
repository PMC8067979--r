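#' Construct a stride snippet
#'
#' One stride (left heel strike to the next left heel strike) of one axis
#' of one locomotion class, cut out of a labelled recording.
#'
#' @param activity One of [locomotion_activities()].
#' @param axis One of [imu_axes()].
#' @param samples Non-empty numeric vector.
#' @param source Free-text provenance tag.
#' @return Object of class `stride_snippet`.
#' @export
stride_snippet <- function(activity, axis, samples, source = "") {
  if (!activity %in% LOCOMOTION_ACTIVITIES) {
    stop("unknown activity: ", activity)
  }
  if (!axis %in% IMU_AXES) stop("unknown axis: ", axis)
  if (!is.numeric(samples) || length(samples) == 0) {
    stop("`samples` must be a non-empty numeric vector")
  }
  structure(list(activity = activity, axis = axis,
                 samples = as.numeric(samples), source = source),
            class = "stride_snippet")
}

#' Cut stride snippets out of a labelled recording
#'
#' Manual stride selection is replaced by explicitly supplied stride
#' boundaries (ground truth from the synthetic generator, or user
#' supplied).  Each consecutive boundary pair within a labelled locomotion
#' interval yields one snippet per axis.
#'
#' @param rec An [imu_recording()].
#' @param labels A [label_track()] over `rec`.
#' @param stride_boundaries List parallel to the rows of `labels`; for
#'   locomotion intervals an increasing integer vector of 0-based frame
#'   indices inside the interval (`length >= 2`), for other intervals
#'   `NULL` or an empty vector.
#' @return List of [stride_snippet()] objects.
#' @export
extract_snippets <- function(rec, labels, stride_boundaries) {
  stopifnot(inherits(rec, "imu_recording"))
  validate_labels(labels, rec$n_frames)
  if (length(stride_boundaries) != nrow(labels)) {
    stop("`stride_boundaries` must have one entry per label interval")
  }
  out <- list()
  for (i in seq_len(nrow(labels))) {
    b <- stride_boundaries[[i]]
    if (is.null(b) || length(b) < 2) next
    b <- as.integer(b)
    if (is.unsorted(b, strictly = TRUE)) {
      stop("stride boundaries of interval ", i, " must be strictly increasing")
    }
    s0 <- labels$start_frame[i]
    e0 <- labels$end_frame[i]
    bad <- which(b < s0 | b > e0)
    if (length(bad) > 0) {
      stop(sprintf("stride boundary %d outside interval [%d,%d)",
                   b[bad[1]], s0, e0))
    }
    act <- labels$activity[i]
    if (!act %in% LOCOMOTION_ACTIVITIES) {
      stop("stride boundaries supplied for non-locomotion interval ", i)
    }
    for (k in seq_len(length(b) - 1L)) {
      idx <- interval_frames(b[k], b[k + 1L])
      for (ax in IMU_AXES) {
        out[[length(out) + 1L]] <- stride_snippet(
          act, ax, rec$channels[[ax]][idx],
          source = sprintf("interval %d stride %d", i, k))
      }
    }
  }
  out
}

# resample to a target length by linear interpolation
resample_linear <- function(x, n) {
  if (length(x) == n) return(x)
  if (length(x) == 1) return(rep(x, n))
  approx(seq(0, 1, length.out = length(x)), x,
         xout = seq(0, 1, length.out = n))$y
}

#' DTW barycenter averaging (DBA)
#'
#' Builds a single average sequence minimizing the mean DTW distance to a
#' set of snippets.  Initialization is the medoid snippet (smallest sum of
#' DTW distances to the rest; first on ties), resampled to `target_length`
#' by linear interpolation, which makes the procedure fully deterministic.
#' Each iteration aligns every snippet to the current average and replaces
#' every average sample by the mean of the snippet samples aligned to it;
#' iteration stops when the mean DTW distance improves by less than `tol`
#' (the previous, best average is then returned) or after `max_iters`.
#'
#' @param snippets List of numeric vectors or [stride_snippet()] objects
#'   (at least one).
#' @param target_length Length of the returned average (>= 2).
#' @param max_iters Maximum update iterations (default 30).
#' @param tol Convergence tolerance on the mean DTW distance (default 1e-6).
#' @return Numeric vector of `target_length` samples, with attributes
#'   `objective` (mean DTW distance per evaluated iterate, non-increasing)
#'   and `iterations`.
#' @export
dba_average <- function(snippets, target_length, max_iters = 30, tol = 1e-6) {
  if (length(snippets) == 0) stop("empty snippet list")
  seqs <- lapply(snippets, function(s) {
    if (inherits(s, "stride_snippet")) s$samples else as.numeric(s)
  })
  if (any(vapply(seqs, length, integer(1)) == 0)) {
    stop("snippets must be non-empty")
  }
  if (target_length < 2) stop("`target_length` must be >= 2")
  target_length <- as.integer(target_length)

  if (length(seqs) == 1) {
    medoid <- seqs[[1]]
  } else {
    dmat <- dtw_pairwise_cpp(seqs)
    medoid <- seqs[[which.min(rowSums(dmat))]]
  }
  avg <- resample_linear(medoid, target_length)

  objective <- numeric(0)
  prev_avg <- avg
  prev_d <- Inf
  for (it in seq_len(max_iters)) {
    sums <- numeric(target_length)
    cnts <- numeric(target_length)
    dist_sum <- 0
    for (s in seqs) {
      al <- dtw_align_cpp(s, avg)
      dist_sum <- dist_sum + al$distance
      j <- al$index_template
      agg <- rowsum(s[al$index_query], group = j)
      # path covers every template index, so rows are 1..target_length
      sums <- sums + agg[, 1]
      cnts <- cnts + tabulate(j, nbins = target_length)
    }
    d <- dist_sum / length(seqs)
    if (d > prev_d) break       # got worse: keep the previous iterate
    objective <- c(objective, d)
    converged <- d > prev_d - tol
    prev_avg <- avg
    prev_d <- d
    if (converged) break
    avg <- sums / cnts
  }
  out <- prev_avg               # last iterate whose objective was evaluated
  attr(out, "objective") <- objective
  attr(out, "iterations") <- length(objective)
  out
}

#' Build a template set from stride snippets
#'
#' For each activity present in `snippets`, the reference length is the
#' median snippet length (rounded to the nearest integer; robust against
#' outlier strides) and each of the six axes is averaged to that length by
#' [dba_average()].
#'
#' @param snippets List of [stride_snippet()] objects covering, for every
#'   activity present, all six axes.
#' @param max_iters,tol Passed to [dba_average()].
#' @return Object of class `template_set`: list with element `activities`,
#'   a named list of `list(reference_length, axes)` entries.
#' @export
build_template_set <- function(snippets, max_iters = 30, tol = 1e-6) {
  if (length(snippets) == 0) stop("no snippets supplied")
  ok <- vapply(snippets, inherits, logical(1), what = "stride_snippet")
  if (!all(ok)) stop("all elements must be stride_snippet objects")
  acts <- unique(vapply(snippets, function(s) s$activity, character(1)))
  activities <- list()
  for (act in acts) {
    of_act <- Filter(function(s) s$activity == act, snippets)
    lens <- vapply(of_act, function(s) length(s$samples), integer(1))
    ref_len <- as.integer(round(median(lens)))
    axes <- list()
    for (ax in IMU_AXES) {
      of_ax <- Filter(function(s) s$axis == ax, of_act)
      if (length(of_ax) == 0) {
        stop("missing snippets for activity '", act, "', axis '", ax, "'")
      }
      tmpl <- dba_average(lapply(of_ax, function(s) s$samples),
                          ref_len, max_iters = max_iters, tol = tol)
      attributes(tmpl) <- NULL
      axes[[ax]] <- tmpl
    }
    activities[[act]] <- list(reference_length = ref_len, axes = axes)
  }
  structure(list(activities = activities), class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat("<template_set>\n")
  for (act in names(x$activities)) {
    cat(sprintf("  %-18s reference length %d frames\n",
                act, x$activities[[act]]$reference_length))
  }
  invisible(x)
}

#' Write a template set to JSON
#'
#' Numbers are serialized at full precision so that a write/read round
#' trip reproduces the templates exactly.
#'
#' @param templates A `template_set` from [build_template_set()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_template_set <- function(templates, path) {
  stopifnot(inherits(templates, "template_set"))
  jsonlite::write_json(templates$activities, path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a template set from JSON
#' @param path JSON path written by [write_template_set()].
#' @return A `template_set`.
#' @export
read_template_set <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  activities <- list()
  for (act in names(raw)) {
    entry <- raw[[act]]
    ref_len <- as.integer(entry$reference_length)
    axes <- lapply(entry$axes, as.numeric)
    if (!all(IMU_AXES %in% names(axes))) {
      stop("template for '", act, "' does not cover all six axes")
    }
    if (any(vapply(axes, length, integer(1)) != ref_len)) {
      stop("template lengths for '", act,
           "' do not match the declared reference length")
    }
    activities[[act]] <- list(reference_length = ref_len,
                              axes = axes[IMU_AXES])
  }
  structure(list(activities = activities), class = "template_set")
}
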