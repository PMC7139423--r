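#' Median absolute deviation with explicit scale constant
#'
#' `scale_constant * median(|x - median(x)|)`. The default constant 1.4826
#' makes the MAD a consistent estimator of the standard deviation under
#' normality and turns a raw median absolute deviation of 1 (common on
#' integer Likert data) into 1.48; pass `scale_constant = 1` for the raw
#' MAD. Delegates to [stats::mad()].
#'
#' @param values Non-empty numeric vector (`NA` dropped).
#' @param scale_constant Multiplier applied to the raw MAD.
#' @return Non-negative scalar.
#' @export
#' @examples
#' scaled_mad(c(0, 1, 2))  # 1.4826
scaled_mad <- function(values, scale_constant = 1.4826) {
  values <- values[!is.na(values)]
  if (!length(values)) stopf("scaled_mad: 'values' must be non-empty")
  stats::mad(values, constant = scale_constant)
}

#' Phase-wise variability comparison via the MAD
#'
#' Computes the MAD of the baseline (A0) phase and of all intervention (B)
#' occurrences merged, for one participant's series. For anxiety the MAD
#' is taken over the pooled post-recoding *item* values of the non-missing
#' observations (items represent momentary variability better than the
#' item mean); for single-item outcomes it is taken over the scores.
#'
#' @param series Scored-observation data frame for one participant/outcome.
#' @param items Pool item-level values (`TRUE`) or use scores (`FALSE`).
#' @param scale_constant Passed to [scaled_mad()].
#' @return An object of class `variability_result`: `mad_A0`, `mad_B`,
#'   `decreased` (`mad_B < mad_A0`).
#' @export
variability_mad <- function(series, items = TRUE, scale_constant = 1.4826) {
  pool <- function(kind) {
    sel <- series[!series$missing & series$phase_kind == kind, , drop = FALSE]
    v <- if (items) unlist(sel[paste0("item_", 1:6)], use.names = FALSE) else sel$score
    v <- v[!is.na(v)]
    if (!length(v)) stopf("variability_mad: phase %s has no non-missing values", kind)
    v
  }
  mad_A0 <- scaled_mad(pool("A0"), scale_constant)
  mad_B <- scaled_mad(pool("B"), scale_constant)
  structure(list(mad_A0 = mad_A0, mad_B = mad_B, decreased = mad_B < mad_A0),
            class = "variability_result")
}
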