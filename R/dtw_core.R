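#' Align two scalar series by dynamic time warping
#'
#' Computes the globally optimal alignment under absolute-difference local
#' cost, the three classic steps `(i+1,j)`, `(i,j+1)`, `(i+1,j+1)` and full
#' boundary conditions (the path runs from the first pair of samples to the
#' last).  The returned distance is the accumulated sum of local costs over
#' all path pairs — the "Euclidean distance" of the matching method, not
#' normalized by path length.  Ties between equal-cost paths are broken
#' deterministically: diagonal step first, then query-advance, then
#' template-advance.
#'
#' @param query Numeric vector (the signal window).
#' @param template Numeric vector (the reference template).
#' @return Object of class `warp_alignment`: list with `index_query` and
#'   `index_template` (1-based, parallel vectors describing the warping
#'   path), `distance`, `n_query`, `n_template`.
#' @export
dtw_align <- function(query, template) {
  if (!is.numeric(query) || length(query) == 0) {
    stop("`query` must be a non-empty numeric vector")
  }
  if (!is.numeric(template) || length(template) == 0) {
    stop("`template` must be a non-empty numeric vector")
  }
  if (anyNA(query) || anyNA(template)) stop("inputs may not contain NA")
  al <- dtw_align_cpp(as.numeric(query), as.numeric(template))
  structure(list(index_query = al$index_query,
                 index_template = al$index_template,
                 distance = al$distance,
                 n_query = length(query),
                 n_template = length(template)),
            class = "warp_alignment")
}

#' @export
print.warp_alignment <- function(x, ...) {
  cat(sprintf("<warp_alignment> %d x %d, path length %d, distance %.6g\n",
              x$n_query, x$n_template, length(x$index_query), x$distance))
  invisible(x)
}

#' DTW distance between two scalar series
#'
#' Same model as [dtw_align()] but returns only the accumulated distance
#' (faster, constant memory in the template length).
#'
#' @inheritParams dtw_align
#' @return Non-negative accumulated distance.
#' @export
dtw_distance <- function(query, template) {
  if (length(query) == 0 || length(template) == 0) {
    stop("both sequences must be non-empty")
  }
  dtw_distance_cpp(as.numeric(query), as.numeric(template))
}

#' Find stretched regions of a warping path
#'
#' A stretched region is a maximal run of path pairs in which a single
#' template frame is aligned against consecutive query frames.  Long runs
#' signal a poor local fit: surplus query frames are being absorbed by one
#' template sample.  Only runs of at least `ceil(min_fraction *
#' template_length)` query frames (and at least 2, since a run of one frame
#' is no repetition) are reported.
#'
#' @param align A `warp_alignment` from [dtw_align()].
#' @param template_length Reference template length in frames against which
#'   the fraction is measured.
#' @param min_fraction Minimum run length as a fraction of
#'   `template_length` (default 0.10).
#' @return Data frame with columns `template_index`, `start_query`,
#'   `end_query` (1-based, inclusive) and `length` (query frames), in
#'   query-index order; zero rows when the path has no qualifying run.
#' @export
find_stretch_regions <- function(align, template_length, min_fraction = 0.10) {
  stopifnot(inherits(align, "warp_alignment"))
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction >= 1) {
    stop("`min_fraction` must be in (0, 1)")
  }
  min_len <- max(2L, as.integer(ceiling(min_fraction * template_length - 1e-9)))
  r <- rle(align$index_template)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_len
  data.frame(template_index = r$values[keep],
             start_query = align$index_query[starts[keep]],
             end_query = align$index_query[ends[keep]],
             length = r$lengths[keep])
}

#' Refine a window to its best-matching section
#'
#' Aligns a signal window to a reference template, detects stretched
#' regions of the warping path, and uses their borders as candidate new
#' window borders.  Every candidate sub-window at least
#' `min_window_fraction` of the template length long (shorter events are
#' implausible) is re-aligned to the template; the candidate with the
#' smallest accumulated distance wins.  The untrimmed window is always a
#' candidate, so the result never has a larger distance than the plain
#' alignment; if every trimmed candidate is too short, the untrimmed
#' alignment is returned.  Ties are broken by earliest start, then
#' shortest section.
#'
#' @param window Numeric vector, the signal excerpt to search.
#' @param template Numeric vector, the reference template.
#' @param min_window_fraction Minimum candidate length as a fraction of the
#'   template length (default 0.40).
#' @param stretch_min_fraction Passed to [find_stretch_regions()]
#'   (default 0.10).
#' @return List with `best_start`, `best_end` (1-based window-relative,
#'   inclusive), `best_distance`, and `untrimmed_distance`.
#' @export
refine_and_score <- function(window, template,
                             min_window_fraction = 0.40,
                             stretch_min_fraction = 0.10) {
  if (length(window) < 1 || length(template) < 1) {
    stop("window and template must be non-empty")
  }
  n <- length(window)
  L <- length(template)
  a0 <- dtw_align(window, template)
  regs <- find_stretch_regions(a0, L, stretch_min_fraction)

  # both sides of each region border are candidate cut points: the first
  # pair of a run belongs to the genuine match as much as to the stretch
  cuts <- sort(unique(c(1L, n + 1L,
                        as.integer(regs$start_query),
                        as.integer(regs$start_query) + 1L,
                        as.integer(regs$end_query),
                        as.integer(regs$end_query) + 1L)))
  cuts <- cuts[cuts >= 1L & cuts <= n + 1L]
  min_len <- min_window_fraction * L - 1e-9
  cand_s <- integer(0)
  cand_e <- integer(0)
  for (a in seq_along(cuts)) {
    for (b in seq_along(cuts)) {
      if (cuts[b] <= cuts[a]) next
      s <- cuts[a]; e <- cuts[b] - 1L
      if (s == 1L && e == n) next           # untrimmed handled separately
      if ((e - s + 1L) < min_len) next      # 40% guard
      cand_s <- c(cand_s, s)
      cand_e <- c(cand_e, e)
    }
  }
  # evaluate in (start, length) order with strict improvement, so the first
  # candidate in the tie order (earliest start, then shortest) wins a tie
  cand_s <- c(cand_s, 1L)
  cand_e <- c(cand_e, n)
  ord <- order(cand_s, cand_e - cand_s)
  best_s <- 1L; best_e <- n; best_d <- Inf
  for (k in ord) {
    s <- cand_s[k]; e <- cand_e[k]
    d <- if (s == 1L && e == n) a0$distance else
      dtw_distance_cpp(window[s:e], as.numeric(template))
    if (d < best_d) {
      best_d <- d; best_s <- s; best_e <- e
    }
  }
  list(best_start = best_s, best_end = best_e,
       best_distance = best_d, untrimmed_distance = a0$distance)
}
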