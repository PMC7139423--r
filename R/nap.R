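#' Nonoverlap of all pairs (NAP)
#'
#' Over all `n_A x n_B` pairs of one A-phase and one B-phase observation, a
#' pair scores 1 when the B value lies strictly beyond the A value in the
#' therapeutic direction, 0.5 when tied, 0 otherwise; NAP is the average
#' pair score. It equals the area under the ROC curve, i.e. the
#' tie-corrected Mann-Whitney U statistic divided by `n_A * n_B`. The
#' asymptotic standard error uses the classical area-under-curve variance
#' with `Q1 = A / (2 - A)` and `Q2 = 2 A^2 / (1 + A)`; the normal-quantile
#' interval is truncated to \[0, 1\].
#'
#' @param a_values Numeric A-phase scores (non-missing; `NA` dropped).
#' @param b_values Numeric B-phase scores.
#' @param direction `"decrease"` or `"increase"`: therapeutic direction.
#' @param level Confidence level (default 0.95).
#' @param comparison Label recording which A observations entered:
#'   `"allA_vs_B"` (A0 and all A1 pooled) or `"A0_vs_B"`.
#' @return An object of class `nap_result`: `nap`, `n_A`, `n_B`, `n_ties`,
#'   `se`, `ci` (length-2), `band` (see [classify_effect()]), `comparison`.
#' @export
#' @examples
#' nap(c(3, 4, 5), c(2, 3, 6), "decrease")$nap  # 5.5/9
nap <- function(a_values, b_values, direction = c("decrease", "increase"),
                level = 0.95, comparison = c("allA_vs_B", "A0_vs_B")) {
  direction <- match.arg(direction)
  comparison <- match.arg(comparison)
  a <- a_values[!is.na(a_values)]
  b <- b_values[!is.na(b_values)]
  if (!length(a)) stopf("nap: A-phase group is empty")
  if (!length(b)) stopf("nap: B-phase group is empty")
  improved <- if (direction == "decrease") outer(a, b, ">") else outer(a, b, "<")
  tied <- outer(a, b, "==")
  n_A <- length(a); n_B <- length(b)
  A <- (sum(improved) + 0.5 * sum(tied)) / (n_A * n_B)
  ci <- nap_ci(A, n_A, n_B, level)
  structure(list(nap = A, n_A = n_A, n_B = n_B, n_ties = sum(tied),
                 se = ci$se, ci = c(ci$lower, ci$upper), level = level,
                 band = classify_effect(A), direction = direction,
                 comparison = comparison),
            class = "nap_result")
}

#' Asymptotic standard error and confidence interval for NAP
#'
#' @param nap NAP (area under the curve) in \[0, 1\].
#' @param n_A,n_B Group sizes.
#' @param level Confidence level.
#' @return List with `se`, `lower`, `upper` (interval truncated to \[0, 1\]).
#' @export
nap_ci <- function(nap, n_A, n_B, level = 0.95) {
  if (nap < 0 || nap > 1) stopf("nap must lie in [0, 1]")
  A <- nap
  Q1 <- A / (2 - A)
  Q2 <- 2 * A^2 / (1 + A)
  v <- (A * (1 - A) + (n_B - 1) * (Q1 - A^2) + (n_A - 1) * (Q2 - A^2)) /
    (n_A * n_B)
  se <- sqrt(max(v, 0))
  z <- stats::qnorm((1 + level) / 2)
  list(se = se, lower = max(0, A - z * se), upper = min(1, A + z * se))
}

#' Classify a NAP value into an effect band
#'
#' Bands: 0-0.65 weak, 0.66-0.92 medium, above 0.92 strong. The value is
#' rounded to two decimals first, matching two-decimal reporting and
#' resolving the open interval between the published band edges.
#'
#' @param nap NAP in \[0, 1\].
#' @return `"weak"`, `"medium"` or `"strong"`.
#' @export
#' @examples
#' classify_effect(0.82)  # medium
classify_effect <- function(nap) {
  if (!is_scalar_number(nap) || nap < 0 || nap > 1) stopf("nap must lie in [0, 1]")
  r <- round(nap, 2)
  if (r <= 0.65) "weak" else if (r <= 0.92) "medium" else "strong"
}

#' Flag a possible carryover effect
#'
#' Carryover (the intervention effect persisting into withdrawal phases)
#' compresses the contrast between pooled A phases and B phases while the
#' clean baseline-only contrast stays visible. A series is flagged when the
#' A0-vs-B comparison shows at least a medium effect but the all-A-vs-B
#' comparison shows a weak one.
#'
#' @param nap_allA `nap_result` with `comparison = "allA_vs_B"`.
#' @param nap_A0 `nap_result` with `comparison = "A0_vs_B"`.
#' @return An object of class `carryover_flag`: `flagged`, `band_allA`,
#'   `band_A0`.
#' @export
carryover_flag <- function(nap_allA, nap_A0) {
  if (!inherits(nap_allA, "nap_result") || !inherits(nap_A0, "nap_result"))
    stopf("carryover_flag expects two nap_result objects")
  if (nap_allA$comparison != "allA_vs_B" || nap_A0$comparison != "A0_vs_B")
    stopf("mismatched comparison types: need allA_vs_B and A0_vs_B results")
  if (nap_allA$direction != nap_A0$direction)
    stopf("both NAP results must use the same therapeutic direction")
  structure(list(flagged = nap_A0$band %in% c("medium", "strong") &&
                   nap_allA$band == "weak",
                 band_allA = nap_allA$band, band_A0 = nap_A0$band),
            class = "carryover_flag")
}

#' @export
print.nap_result <- function(x, ...) {
  cat(sprintf("NAP (%s, %s desired): %.2f [%.2f, %.2f] (%s effect; %d x %d pairs, %d tie(s))\n",
              x$comparison, x$direction, x$nap, x$ci[1], x$ci[2], x$band,
              x$n_A, x$n_B, x$n_ties))
  invisible(x)
}

#' @export
print.carryover_flag <- function(x, ...) {
  cat(sprintf("Carryover %s (A0 vs B: %s; all A vs B: %s)\n",
              if (x$flagged) "flagged" else "not flagged",
              x$band_A0, x$band_allA))
  invisible(x)
}
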