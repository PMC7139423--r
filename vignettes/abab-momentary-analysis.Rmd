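---
title: "Analyzing ABAB momentary-assessment studies with scedab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing ABAB momentary-assessment studies with scedab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scedab)
```

## The design and the data

scedab analyzes single-case experimental designs (SCEDs) of the ABAB
withdrawal/reversal type measured by brief repeated momentary assessments.
Each case (participant) starts in an `A0` baseline phase, then alternates
short intervention (`B`) blocks with withdrawal (`A1`) blocks. Outcomes are
assessed several times per school day: here a six-item state-anxiety short
form on a 0.0--10.0 visual-analog metric (items ordered calm, tense, upset,
relaxed, content, worried; items 1, 4, 5 reverse-keyed as `10 - x`) and
teacher-rated disruptive classroom behaviors on a 0--5 Likert frequency
scale (reverse-coded `5 - x` for behaviors whose desired change is an
increase, so every scored series is decrease-desired).

The bundled [`default_design()`] encodes the emulated study conditions:
eight cases, three assessments per day (nominally 10:00, 12:00, 14:00),
seven cases with 20 school days and one (case "5") with 24, baselines of
5--6 days, one-day B blocks, six intervention sessions per case except five
for case "8" — 492 scheduled assessments per outcome in total. The exact
day-by-day schedules within those constraints are not published for the
study the design emulates, so the package fixes one concrete realization
per case; all bookkeeping (the 492-slot count, missingness denominators)
depends only on the stated constraints.

## Individual-level statistics

**Phase descriptives.** Means and sample SDs (n − 1 denominator) pooled
over the occurrences of each phase kind. Phases with no usable data are
reported absent, not as zeros; single-observation phases report an
undefined SD (`NA`).

**PEM.** The percentage of B-phase points beyond the `A0` baseline median
in the therapeutic direction. The median uses the linear midpoint for even
counts. Ties with the median count 0.5 (mirroring the NAP convention); the
strict integer count is also reported so either reading of tie handling can
be reproduced. Note one caveat: invariance of PEM under jointly applied
strictly monotone transforms is exact only for odd-length baselines, where
the median is an order statistic; the even-count interpolated midpoint is
not equivariant under nonlinear maps.

**Split-middle trend and stability envelope.** The baseline is split into
first and second halves by time order (the middle point belongs to both
halves when the count is odd — a recognized convention; the construction is
cited in the applied literature without that detail). Each half is reduced
to its (median time, median value) point and the trend line joins the two.
The envelope half-width is 25% of the median of the baseline *values* (not
of the trend fit), and a baseline is "stable" when at least 80% of its
points fall within the envelope. A zero baseline median degenerates the
envelope to the line itself; points then count as within only when they lie
exactly on it.

**Variability (MAD).** `scaled_mad()` is
`constant * median(|x - median(x)|)` with the normal-consistency constant
1.4826 by default. The default matters: on integer Likert data a raw median
absolute deviation of 1 prints as 1.48 only with the consistency constant,
which is how published MAD tables on such data are reproduced; a raw mode
(`scale_constant = 1`) is available. For the anxiety outcome the MAD pools
the six post-recoding *item* values of all non-missing observations in the
phase (items represent momentary variability better than their mean); all B
occurrences are merged.

**Level segmentation.** `detect_levels()` implements binary recursive
partitioning on the time index — the regression-tree rule for one ordered
predictor. At each node every breakpoint leaving `min_segment_size >= 2`
observations on both sides is scored by the two-segment residual sum of
squares; the best breakpoint (leftmost on ties) is accepted only when it
reduces the node's sum of squares by at least `cp` times the *root* total
sum of squares. Defaults `cp = 0.01` and `min_segment_size = 2` are the
conventional tree defaults; the settings used by any particular published
analysis are rarely reported, so both are exposed. A constant series never
splits (the gain must be strictly positive), and series shorter than
`2 * min_segment_size` return a single flagged segment with a warning.
Missing observations are skipped while original time indices are retained,
so gaps do not shrink trends or relabel breakpoints.

**NAP.** Nonoverlap of all pairs: over all `n_A x n_B` pairs, 1 for a pair
improved in the therapeutic direction, 0.5 for a tie — equivalently the ROC
area / tie-corrected Mann-Whitney U scaled by `n_A n_B` (the package
computes it by pairwise enumeration; the test suite verifies the rank-sum
identity). The asymptotic SE uses the classical area-under-curve variance
with `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`; published SCED reports rarely state
which asymptotic formula their software used, so this choice is validated
against a bootstrap rather than against any published interval. Intervals
are normal-quantile and truncated to [0, 1]. Effect bands (0--0.65 weak,
0.66--0.92 medium, > 0.92 strong) are applied after rounding to two
decimals, which resolves the otherwise-ambiguous open interval
(0.65, 0.66) and the 0.92 edge consistently with two-decimal reporting.

**Carryover.** When an intervention's effect persists into withdrawal
phases, pooled-A-vs-B nonoverlap is compressed while the clean
baseline-only contrast stays visible. `carryover_flag()` flags a series
when the `A0`-vs-B band is at least medium but the all-A-vs-B band is weak.

## The group-level effect size

The between-case standardized mean difference (BC-SMD) summarizes the A-to-B
change across cases on the scale of a between-group standardized mean
difference. The model for observation `j` of case `i` is

$$Y_{ij} = (\mu + u_i) + (\beta + v_i) T_{ij} + e_{ij},$$

with `T_ij = 1` on intervention-day observations (including the first
post-session assessment of a B day), `(u_i, v_i)` jointly mean-zero with
covariance `[[tau_u^2, tau_uv], [tau_uv, tau_v^2]]`, and `e_ij` independent
`N(0, sigma^2)`. Restricted maximum likelihood is used throughout; the
optimizer works on a Cholesky parameterization so the random-effect
covariance is positive semi-definite by construction, and boundary
estimates (`tau_v^2 = 0` is common with few cases) are reported as such.
No baseline or treatment-phase time trends are modeled and within-case
errors are independent by default, since only a random treatment level is
specified in the design-comparable convention for reversal designs; an
AR(1)-within-day error option (`cor_struct = "ar1"`, correlation
`rho^|s - s'|` across slot distances, estimated jointly) is provided but
off by default.

The effect size standardizes by the *baseline* variance:

$$\hat\delta = \hat\beta / \sqrt{\hat\tau_u^2 + \hat\sigma^2},$$

deliberately excluding `tau_v^2` — the denominator is the between- plus
within-case variance a between-group study would see at baseline. The
small-sample correction is `J(nu) = 1 - 3/(4 nu - 1)` with Satterthwaite
degrees of freedom `nu = 2 S^4 / Var(S^2)` for `S^2 = tau_u^2 + sigma^2`,
where `Var(S^2)` comes from the observed information of the variance
components (a guarded central-difference Hessian that holds
boundary-pinned components fixed and shrinks steps that would leave the
admissible region). The reported standard error is the delta-method
approximation `J * sqrt(Var(beta)/S^2 + delta^2/(2 nu))` with a symmetric
normal interval; both are approximations and documented as such.
`stratified_bcsmd()` reruns the identical estimation restricted to one
within-day slot, which is how the duration of a within-day intervention
effect is profiled.

Numerical contract: convergence is declared at a relative restricted
log-likelihood change below 1e-8 (Nelder-Mead followed by an L-BFGS-B
polish); the test suite checks the fit against an independent mixed-model
implementation and against grid searches of the restricted likelihood.

## What the generator emulates — and what it does not

`sim_config()` / `simulate_study()` generate scored series as

`clip(mu0 + u_i + trend*d + (beta + v_i) * m_s * I(B) +
(beta + v_i) * carryover * I(A1) + e_ds)`

with AR(1) residuals across successive within-day slots (resetting
overnight by default — the conservative choice, configurable to persist)
and missingness injected completely at random. Defaults are fixed at the
emulated study conditions and are not tuning dials: anxiety
`mu0 = 3.3, sigma = 1.4, tau_u = 1.0, tau_v = 0.4, beta = -1.8`, decay
`(1, 0.6, 0)` (effect strongest directly after a session, absent four hours
later), `carryover = 0.5` (withdrawal-day means sit close to B-day means),
`ar1_rho = 0.3`, 27% missing; behavior `mu0 = 2.6, sigma = 1.0,
tau_u = 0.8, tau_v = 0.3, beta = -1.2`, 32.7% missing on the 0--5 scale.
Where the emulated study reports no value (the variance partition, the
autocorrelation, the per-case decay heterogeneity) the defaults are one
realistic choice, stated here, chosen once. Anxiety scores are quantized to
one decimal (a 10.0 cm visual-analog line read in mm) and six item values
are backfilled in exact integer-tenths arithmetic so the score equals the
item mean to the last digit; behavior scores are rounded to the Likert
grid. Missingness is MCAR because the attrition mechanisms being emulated
(scheduling, illness) are closest to that; nothing phase-dependent is
generated by default.

What passing tests on generated data do *not* show: real momentary
assessments have reactivity, day-of-week structure, phase-dependent
missingness and rater effects that the generator deliberately omits. The
parameter-recovery experiments therefore validate the *estimator* under the
stated design (8 cases, the ABAB schedule, 3 slots/day, 27% MCAR), not the
full measurement process. For those experiments the generator is run with
the bounds disabled, constant decay `(1, 1, 1)`, no carryover and no
autocorrelation, so the generative process coincides with the fitted
model; Monte-Carlo sizes are 500 replicates per true effect
(`delta = 0, -0.3, -0.5`) for calibration and 200 replicates for the
slot-ordering check under decay `(1, 0.6, 0)`, with balanced
random-intercept checks at 8 cases x 30 observations x 200 replicates.

## One known scale ambiguity

Published behavior tables in this genre occasionally print means above the
nominal 0--5 anchor range (e.g. a phase mean of 6.00), suggesting an
effective 1--6 coding. The package uses the stated 0--5 anchors with
reversal `5 - x` throughout; because every statistic here is either
location-invariant or compares within-series, the choice does not affect
PEM, NAP, MAD, segmentation or the BC-SMD, only the printed level of means.

## Limitations

- The NAP asymptotic SE formula is a reasoned standard choice, not a
  reproduction of any specific software's internals.
- Segmentations of published figures cannot be matched bit-for-bit when the
  original tool's tuning (minimum change, depth) is unreported.
- The BC-SMD assumes normal outcomes and no clear baseline trends; the
  stability envelope is the screening tool for the latter.
- Satterthwaite `nu` and the delta-method SE are approximations; with very
  few cases the interval coverage is approximate as well.
- No Tau-U/PND/IRD nonoverlap variants, no Bayesian or multiple-baseline
  estimation, and no imputation: all statistics use available observations.
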