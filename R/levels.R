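#' Level segmentation by greedy recursive partitioning
#'
#' Identifies segments of a time series with a stable mean by binary
#' recursive splitting on the observation order, the regression-tree rule
#' for a single ordered predictor. At each node every breakpoint leaving
#' `min_segment_size` observations on both sides is scored by the
#' two-segment residual sum of squares; the best (leftmost on ties) is
#' accepted only if it reduces the node's sum of squares by at least
#' `cp` times the root total sum of squares, and splitting recurses into
#' both children. Deterministic; missing values are skipped while original
#' time indices are retained.
#'
#' @param value Numeric scores (`NA` skipped).
#' @param time Assessment indices (default observation order); reported
#'   breakpoints refer to these.
#' @param min_segment_size Minimum observations per segment (>= 2).
#' @param cp Complexity parameter: minimum residual-sum-of-squares
#'   reduction expressed as a fraction of the root total sum of squares.
#' @return An object of class `level_segmentation`: `breakpoints` (time
#'   indices starting each new segment), `segment_starts` (observation
#'   positions), `segment_means`, `segments` (per-observation assignment),
#'   `rss`, `too_short` (series shorter than one splittable node).
#' @export
#' @examples
#' detect_levels(c(rep(5, 10), rep(2, 10)))$segment_means  # 5, 2
detect_levels <- function(value, time = seq_along(value),
                          min_segment_size = 2L, cp = 0.01) {
  keep <- !is.na(value)
  value <- value[keep]; time <- time[keep]
  n <- length(value)
  min_segment_size <- as.integer(min_segment_size)
  if (min_segment_size < 2L) stopf("min_segment_size must be >= 2")
  too_short <- n < 2L * min_segment_size
  if (n == 0L) stopf("detect_levels: no non-missing observations")
  cs <- cumsum(value); cs2 <- cumsum(value^2)
  seg_sum <- function(lo, hi) cs[hi] - if (lo > 1L) cs[lo - 1L] else 0
  seg_rss <- function(lo, hi) {
    s <- seg_sum(lo, hi)
    (cs2[hi] - if (lo > 1L) cs2[lo - 1L] else 0) - s^2 / (hi - lo + 1L)
  }
  tss_root <- seg_rss(1L, n)
  starts <- integer(0)
  recurse <- function(lo, hi) {
    if (hi - lo + 1L < 2L * min_segment_size) return(invisible())
    node_rss <- seg_rss(lo, hi)
    best_j <- NA_integer_; best_rss <- Inf
    for (j in seq.int(lo + min_segment_size - 1L, hi - min_segment_size)) {
      r <- seg_rss(lo, j) + seg_rss(j + 1L, hi)
      if (r < best_rss) { best_rss <- r; best_j <- j }
    }
    gain <- node_rss - best_rss
    if (is.na(best_j) || gain < cp * tss_root || gain <= 0) return(invisible())
    starts <<- c(starts, best_j + 1L)
    recurse(lo, best_j)
    recurse(best_j + 1L, hi)
  }
  if (!too_short) recurse(1L, n)
  else warning("series too short to split; returning a single segment")
  starts <- sort(starts)
  bounds <- c(1L, starts, n + 1L)
  segments <- rep(seq_len(length(bounds) - 1L), diff(bounds))
  means <- vapply(seq_len(length(bounds) - 1L), function(k)
    mean(value[bounds[k]:(bounds[k + 1L] - 1L)]), 0)
  structure(list(breakpoints = time[starts], segment_starts = starts,
                 segment_means = means, segments = segments,
                 rss = sum((value - means[segments])^2),
                 n = n, too_short = too_short),
            class = "level_segmentation")
}

#' @export
print.level_segmentation <- function(x, ...) {
  cat(sprintf("Level segmentation: %d segment(s), means %s\n",
              length(x$segment_means),
              paste(sprintf("%.3g", x$segment_means), collapse = ", ")))
  invisible(x)
}

# Coarse textual classification of the level change implied by a
# segmentation, for report tables: compares the final segment mean with
# the first.
classify_level_change <- function(seg, tol = 1e-8) {
  m <- seg$segment_means
  if (length(m) < 2L) return("no change in level")
  d <- m[length(m)] - m[1L]
  if (d < -tol) "decreases" else if (d > tol) "increases" else "no change in level"
}
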