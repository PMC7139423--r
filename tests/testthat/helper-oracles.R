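# Independent oracles used across the suite.  Each reimplements a quantity
# by a different route than the package (ranks instead of pairwise
# enumeration, naive sums instead of cumulative sums, closed forms instead
# of optimization) so agreement is informative.

# NAP via the rank-sum (Mann-Whitney) route: U / (n_A * n_B) with the
# midrank tie correction.
nap_rank_oracle <- function(a, b, direction = "decrease") {
  r <- rank(c(a, b))
  n_a <- length(a); n_b <- length(b)
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2  # pairs with a > b (+ 0.5 ties)
  if (direction == "decrease") u_a / (n_a * n_b) else 1 - u_a / (n_a * n_b)
}

# Exhaustive recursive segmentation: at every node score each admissible
# breakpoint by directly computed residual sums of squares and accept the
# best under the same gain rule.
segment_oracle <- function(y, min_size = 2L, cp = 0.01) {
  rss <- function(v) sum((v - mean(v))^2)
  tss <- rss(y)
  starts <- integer(0)
  rec <- function(lo, hi) {
    if (hi - lo + 1L < 2L * min_size) return(invisible())
    best <- Inf; bj <- NA_integer_
    for (j in seq.int(lo + min_size - 1L, hi - min_size)) {
      r <- rss(y[lo:j]) + rss(y[(j + 1L):hi])
      if (r < best) { best <- r; bj <- j }
    }
    gain <- rss(y[lo:hi]) - best
    if (!is.na(bj) && gain >= cp * tss && gain > 0) {
      starts <<- c(starts, bj + 1L)
      rec(lo, bj); rec(bj + 1L, hi)
    }
  }
  rec(1L, length(y))
  sort(starts)
}

# Balanced one-way random-effects ANOVA moment estimators (truncated at 0).
anova_moment_oracle <- function(y, case) {
  case <- factor(case)
  n_per <- as.integer(table(case)[1L])
  fit <- stats::anova(stats::lm(y ~ case))
  msb <- fit["case", "Mean Sq"]
  msw <- fit["Residuals", "Mean Sq"]
  list(tau_u_sq = max(0, (msb - msw) / n_per), sigma_sq = msw)
}

# Random well-formed assessment records over a random small design.
random_records <- function(n_participants = 2L, max_days = 6L,
                           missing_rate = 0.25) {
  participants <- lapply(seq_len(n_participants), function(i) {
    k <- sample(0:2, 1L)
    phases <- c("A0", rep(c("B", "A1"), length.out = 2L * k))
    days <- pmax(1L, sample.int(max_days, length(phases), replace = TRUE))
    participant_design(paste0("p", i), phases, days)
  })
  spec <- design_spec(participants, slots_per_day = sample(1:3, 1L))
  grid <- build_design_grid(spec)
  n <- nrow(grid)
  out <- list()
  for (kind in c("anxiety", "behavior")) {
    rec <- grid
    rec$outcome_kind <- kind
    items <- matrix(NA_real_, n, 6L, dimnames = list(NULL, paste0("item_", 1:6)))
    if (kind == "anxiety") items[, 1:6] <- round(matrix(runif(6 * n, 0, 10), n), 1L)
    else items[, 1:2] <- matrix(sample(0:5, 2L * n, replace = TRUE), n)
    rec <- cbind(rec, as.data.frame(items))
    rec$missing <- runif(n) < missing_rate
    for (col in paste0("item_", 1:6)) rec[[col]][rec$missing] <- NA_real_
    out[[kind]] <- rec
  }
  list(spec = spec, records = do.call(rbind, c(out, make.row.names = FALSE)))
}

# Direct hierarchical-model draw (no EMA structure), for estimator tests.
draw_model_data <- function(m = 8L, n_per = 40L, mu = 2, beta = -1,
                            tau_u = 1, tau_v = 0.5, sigma = 1) {
  case <- rep(seq_len(m), each = n_per)
  treat <- rep(rep(0:1, each = n_per / 2L), m)
  u <- rnorm(m, 0, tau_u); v <- rnorm(m, 0, tau_v)
  y <- mu + u[case] + (beta + v[case]) * treat + rnorm(m * n_per, 0, sigma)
  data.frame(participant_id = case, score = y,
             phase_kind = ifelse(treat == 1, "B", "A0"),
             day_index = rep(seq_len(n_per), m), slot_index = 1L,
             missing = FALSE)
}

# sim_config for model-faithful Monte-Carlo work: constant slot effect,
# no carryover/autocorrelation/bounds (VAS quantization to 0.1 retained).
recovery_config <- function(delta, seed, tau_u = 0.8, sigma = 1,
                            tau_v = 0.25, decay = c(1, 1, 1),
                            missing_rate = 0.27) {
  sim_config("anxiety", mu0 = 3.3, sigma = sigma, tau_u = tau_u, tau_v = tau_v,
             beta = delta * sqrt(tau_u^2 + sigma^2), decay = decay,
             carryover = 0, ar1_rho = 0, trend = 0,
             missing_rate = missing_rate, floor = -Inf, ceiling = Inf,
             items = FALSE, seed = seed)
}

simulate_scored_study <- function(config) {
  out <- lapply(config$design$participants, function(p) {
    obs <- simulate_participant(config, p$id)
    inject_missingness(obs, config$missing_rate,
                       scedab:::substream_seed(config$seed, p$id, "mcar"))
  })
  do.call(rbind, out)
}
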