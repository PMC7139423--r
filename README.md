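# scedab

Analysis of ABAB (withdrawal/reversal) single-case experimental designs
measured by repeated momentary assessments — the setting where a small
number of participants are each observed a few times per school day across
alternating baseline (A0), intervention (B) and withdrawal (A1) phases,
and the question is whether the intervention shifts a self- or
teacher-rated outcome at the individual and at the group level.

The package is written for applied SCED researchers and methodologists. It
covers the full chain:

- **Scoring** — six-item state-anxiety short form on a 0–10 visual-analog
  metric (items 1, 4, 5 reverse-keyed as `10 − x`, score = item mean) and
  0–5 Likert behavior ratings with optional reversal (`5 − x`).
- **Phase descriptives and PEM** — phase means/SDs and the percentage of
  B-phase points beyond the A0 baseline median in the therapeutic
  direction (ties weighted 0.5, strict count also reported).
- **Structured visual analysis** — split-middle baseline trend with the
  ±25%-of-baseline-median stability envelope and 80% rule; phase-wise
  variability via the MAD (consistency constant 1.4826 by default);
  level segmentation by greedy recursive partitioning with a
  regression-tree acceptance rule.
- **Nonoverlap of all pairs (NAP)** — for all A vs B and baseline-only
  vs B, with the area-under-curve asymptotic SE
  (`Q1 = A/(2−A)`, `Q2 = 2A²/(1+A)`), 95% intervals truncated to [0, 1],
  effect bands (≤0.65 weak, ≤0.92 medium, >0.92 strong after two-decimal
  rounding) and a carryover flag for discordant bands.
- **BC-SMD** — the design-comparable between-case standardized mean
  difference from the hierarchical model
  `Y_ij = (μ + u_i) + (β + v_i) T_ij + e_ij`, estimated by restricted
  maximum likelihood written in-package, standardized as
  `δ̂ = β̂ / √(τ̂_u² + σ̂²)` with the small-sample correction
  `J(ν) = 1 − 3/(4ν − 1)` (Satterthwaite ν), overall and stratified by
  within-day slot.
- **Synthetic generator** — ABAB momentary-assessment datasets with known
  ground truth (between-case variance, within-day effect decay, carryover,
  AR(1) noise, MCAR missingness) so every stage is testable without
  external data.

## Worked example

Simulate an eight-case study under the default conditions, analyze one
participant, then estimate the group effect:

```r
library(scedab)

study  <- simulate_study(sim_config("anxiety", seed = 42), behavior = NULL)
scored <- study$scored

one <- scored[scored$participant_id == "3" & !scored$missing, ]
a0   <- one$score[one$phase_kind == "A0"]
b    <- one$score[one$phase_kind == "B"]
aall <- one$score[one$phase_kind %in% c("A0", "A1")]

pem(a0, b, "decrease")
#> PEM: 9/16 beyond baseline median 3.5 (decrease desired), 0 tie(s) -> 56.2%
nap(aall, b, "decrease")
#> NAP (allA_vs_B, decrease desired): 0.60 [0.42, 0.78] (weak effect; 29 x 16 pairs, 5 tie(s))

fit <- fit_reversal_model(scored, drop_insufficient = TRUE)
fit
#> Hierarchical reversal model (REML, 8 cases, 344 observations)
#>   fixed: mu = 3.322, beta = -0.334 (SE 0.161)
#>   variance: tau_u^2 = 1.2482, tau_uv = -0.0427, tau_v^2 = 0.0015, sigma^2 = 1.8991
#>   restricted logLik = -611.762
bcsmd_effect(fit)
#> BC-SMD: g = -0.185 (SE 0.091; 95% CI -0.364 to -0.006), nu = 37.4, J = 0.9798
```

Reading the output: participant 3's intervention-day anxiety sits below the
baseline median for 9 of 16 assessments (PEM 56%), and 60% of all A–B
pairs show improvement — a weak nonoverlap effect for this draw. At the
group level the treatment effect of −0.33 scale points standardizes to
g = −0.19 against the baseline SD √(1.25 + 1.90); the interval excludes
zero, a small group-level reduction. `analyze_study()` runs this chain for
every participant and outcome and `write_report()` emits the tables as
CSV; `inst/cli/scedab.R` exposes `simulate` / `analyze` / `report`
subcommands over the same functions.

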