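#' Split-middle baseline trend line
#'
#' The baseline series is split into first and second halves by time order;
#' for an odd count the middle observation belongs to both halves. Each
#' half is summarized by its (median time index, median value) point and
#' the returned line passes through the two summary points. The slope is in
#' outcome units per assessment index.
#'
#' @param time Numeric assessment indices, strictly increasing.
#' @param value Numeric scores (same length; `NA` pairs dropped).
#' @return List with `slope` and `intercept`.
#' @export
#' @examples
#' split_middle_trend(1:6, c(5, 3, 4, 2, 1, 3))  # slope -2/3, intercept 16/3
split_middle_trend <- function(time, value) {
  keep <- !is.na(value) & !is.na(time)
  time <- time[keep]; value <- value[keep]
  n <- length(value)
  if (n < 4L) stopf("split-middle trend needs at least 4 baseline observations")
  if (is.unsorted(time, strictly = TRUE)) stopf("'time' must be strictly increasing")
  first <- seq_len(ceiling(n / 2))
  second <- seq.int(floor(n / 2) + 1L, n)
  x1 <- stats::median(time[first]); y1 <- stats::median(value[first])
  x2 <- stats::median(time[second]); y2 <- stats::median(value[second])
  if (x2 == x1) stopf("degenerate split-middle trend: half median indices coincide")
  slope <- (y2 - y1) / (x2 - x1)
  list(slope = slope, intercept = y1 - slope * x1)
}

#' Baseline trend stability envelope
#'
#' A baseline point lies within the envelope when its absolute deviation
#' from the split-middle trend line is at most 25% of the baseline median
#' value. The baseline is called stable when at least 80% of its points
#' fall within the envelope.
#'
#' @param time,value Baseline series (as in [split_middle_trend()]).
#' @param trend Optional precomputed trend (list with `slope`,
#'   `intercept`); fitted from the data when `NULL`.
#' @param envelope_frac Envelope half-width as a fraction of the baseline
#'   median (default 0.25).
#' @param stability_pct Stability threshold in percent (default 80).
#' @return An object of class `trend_envelope`: `slope`, `intercept`,
#'   `half_width`, `n`, `n_within`, `pct_within`, `stable`.
#' @export
stability_envelope <- function(time, value, trend = NULL,
                               envelope_frac = 0.25, stability_pct = 80) {
  keep <- !is.na(value) & !is.na(time)
  time <- time[keep]; value <- value[keep]
  if (!length(value)) stopf("stability_envelope: baseline has no observations")
  if (is.null(trend)) trend <- split_middle_trend(time, value)
  half_width <- envelope_frac * stats::median(value)
  fit <- trend$intercept + trend$slope * time
  within <- abs(value - fit) <= half_width
  pct <- 100 * mean(within)
  structure(list(slope = trend$slope, intercept = trend$intercept,
                 half_width = half_width, n = length(value),
                 n_within = sum(within), pct_within = pct,
                 stable = pct >= stability_pct),
            class = "trend_envelope")
}

#' @export
print.trend_envelope <- function(x, ...) {
  cat(sprintf("Split-middle trend: slope %.3f (%.0f%% of %d points within +/-%.3g envelope) -> %s\n",
              x$slope, x$pct_within, x$n, x$half_width,
              if (x$stable) "stable" else "not stable"))
  invisible(x)
}
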