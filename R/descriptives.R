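#' Phase-wise descriptive statistics
#'
#' Means and sample standard deviations (n - 1 denominator) of the
#' non-missing scores in the baseline (A0), pooled intervention (B) and
#' pooled withdrawal (A1) phases of one participant's series. Occurrences
#' of a phase kind are merged. Phases without any non-missing observation
#' are absent from the output; single-observation phases report `sd = NA`
#' (variance undefined).
#'
#' @param series Scored-observation data frame for one participant and
#'   outcome (layout of [score_dataset()]).
#' @return Data frame with columns `phase_kind`, `n`, `mean`, `sd`.
#' @export
phase_stats <- function(series) {
  x <- series[!series$missing & !is.na(series$score), , drop = FALSE]
  out <- lapply(c("A0", "B", "A1"), function(kind) {
    v <- x$score[x$phase_kind == kind]
    if (!length(v)) return(NULL)
    data.frame(phase_kind = kind, n = length(v), mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) stopf("phase_stats: no non-missing observations")
  rownames(out) <- NULL
  out
}

#' Percentage of data points exceeding the baseline median (PEM)
#'
#' Proportion of intervention-phase observations beyond the baseline (A0)
#' median in the therapeutic direction. The median uses the usual linear
#' midpoint convention for even counts. A point strictly beyond the median
#' counts 1, a point equal to it counts 0.5 (mirroring the NAP tie
#' convention); the strict integer count is also reported so the
#' ties-count-zero reading can be reproduced.
#'
#' @param baseline Numeric A0 baseline scores (non-missing).
#' @param b_values Numeric pooled B-phase scores (non-missing).
#' @param direction `"decrease"` or `"increase"`: the therapeutic direction.
#' @return An object of class `pem_result` with fields `n_B`,
#'   `n_in_direction` (strict count), `n_ties`, `pem_pct` (0.5 tie weight)
#'   and `pem_strict_pct`.
#' @export
#' @examples
#' pem(c(2, 4, 6, 8), c(3, 5, 9), "decrease")$pem_pct  # 66.7 (2 of 3 below 5)
pem <- function(baseline, b_values, direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  baseline <- baseline[!is.na(baseline)]
  b_values <- b_values[!is.na(b_values)]
  if (!length(baseline)) stopf("pem: baseline phase has no observations")
  if (!length(b_values)) stopf("pem: intervention phases have no observations")
  med <- stats::median(baseline)
  beyond <- if (direction == "decrease") b_values < med else b_values > med
  ties <- b_values == med
  structure(list(n_B = length(b_values),
                 n_in_direction = sum(beyond),
                 n_ties = sum(ties),
                 pem_pct = 100 * (sum(beyond) + 0.5 * sum(ties)) / length(b_values),
                 pem_strict_pct = 100 * sum(beyond) / length(b_values),
                 baseline_median = med, direction = direction),
            class = "pem_result")
}

#' @export
print.pem_result <- function(x, ...) {
  cat(sprintf("PEM: %d/%d beyond baseline median %.3g (%s desired), %d tie(s) -> %.1f%%\n",
              x$n_in_direction, x$n_B, x$baseline_median, x$direction,
              x$n_ties, x$pem_pct))
  invisible(x)
}
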