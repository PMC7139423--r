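#' Configure the synthetic momentary-assessment generator
#'
#' The generator emulates an ABAB momentary-assessment study on the scored
#' outcome scale. The value scheduled at day `d`, slot `s` of case `i` is
#'
#' `clip(mu0 + u_i + trend * d + (beta + v_i) * m_s * I(B day)
#'       + (beta + v_i) * carryover * I(A1 day) + e_ds)`
#'
#' with case effects `u_i ~ N(0, tau_u^2)` (level) and `v_i ~ N(0, tau_v^2)`
#' (treatment response), and `e` an AR(1) process across successive
#' within-day slots with marginal SD `sigma` and lag-1 correlation
#' `ar1_rho` (resetting overnight unless `ar1_persist`). The per-slot decay
#' multipliers `m_s` let the intervention effect fade over the school day.
#'
#' Defaults describe the emulated study conditions: eight cases on the
#' [default_design()] schedule, an anxiety-like outcome on the 0-10 scale
#' (or a 0-5 Likert behavior outcome), an intervention effect that is
#' strongest at the first daily assessment and gone by the third, partial
#' carryover into withdrawal days, and missing-completely-at-random rates
#' of 27% (anxiety) / 32.7% (behavior).
#'
#' @param outcome `"anxiety"` or `"behavior"`; selects scale-appropriate
#'   defaults (means, SDs, bounds, granularity, missingness).
#' @param design A [design_spec()].
#' @param mu0 Baseline mean on the scored scale.
#' @param sigma Within-case marginal residual SD (`> 0` unless exactly 0).
#' @param beta Treatment effect on intervention days (signed; negative =
#'   improvement for decrease-desired outcomes).
#' @param decay Per-slot multipliers in \[0, 1\] applied to `beta`,
#'   one per within-day slot.
#' @param carryover Fraction of `beta` persisting on withdrawal (A1) days,
#'   in \[0, 1\].
#' @param tau_u,tau_v Between-case SDs of the level and treatment effects.
#' @param ar1_rho Lag-1 residual autocorrelation in (-1, 1).
#' @param ar1_persist Carry the AR(1) chain across the overnight gap?
#' @param trend Per-day linear drift added throughout.
#' @param missing_rate Probability that a scheduled assessment is missing
#'   (missing completely at random).
#' @param floor,ceiling Outcome bounds used for clipping.
#' @param items Backfill item-level responses (six anxiety items or one
#'   Likert behavior item) around each scored value? Disable for pure
#'   Monte-Carlo work on the scored scale.
#' @param seed Master integer seed; per-participant substreams are derived
#'   by stable hashing of `(seed, participant_id)` so adding participants
#'   never perturbs existing series.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(outcome = c("anxiety", "behavior"),
                       design = default_design(),
                       mu0 = NULL, sigma = NULL, beta = NULL,
                       decay = c(1, 0.6, 0), carryover = 0.5,
                       tau_u = NULL, tau_v = NULL,
                       ar1_rho = 0.3, ar1_persist = FALSE, trend = 0,
                       missing_rate = NULL, floor = NULL, ceiling = NULL,
                       items = TRUE, seed = 1L) {
  outcome <- match.arg(outcome)
  if (!inherits(design, "design_spec")) stopf("'design' must be a design_spec")
  def <- if (outcome == "anxiety")
    list(mu0 = 3.3, sigma = 1.4, beta = -1.8, tau_u = 1.0, tau_v = 0.4,
         missing_rate = 0.27, floor = 0, ceiling = 10)
  else
    list(mu0 = 2.6, sigma = 1.0, beta = -1.2, tau_u = 0.8, tau_v = 0.3,
         missing_rate = 0.327, floor = 0, ceiling = 5)
  cfg <- list(outcome = outcome, design = design,
              mu0 = mu0 %||% def$mu0, sigma = sigma %||% def$sigma,
              beta = beta %||% def$beta, decay = decay,
              carryover = carryover, tau_u = tau_u %||% def$tau_u,
              tau_v = tau_v %||% def$tau_v, ar1_rho = ar1_rho,
              ar1_persist = isTRUE(ar1_persist), trend = trend,
              missing_rate = missing_rate %||% def$missing_rate,
              floor = floor %||% def$floor, ceiling = ceiling %||% def$ceiling,
              items = isTRUE(items), seed = as.integer(seed))
  if (cfg$sigma < 0 || cfg$tau_u < 0 || cfg$tau_v < 0)
    stopf("standard deviations must be >= 0")
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1)
    stopf("missing_rate must lie in [0, 1]")
  if (length(cfg$decay) != design$slots_per_day)
    stopf("'decay' needs one multiplier per within-day slot (%d)", design$slots_per_day)
  if (any(cfg$decay < 0 | cfg$decay > 1)) stopf("decay multipliers must lie in [0, 1]")
  if (cfg$carryover < 0 || cfg$carryover > 1) stopf("carryover must lie in [0, 1]")
  if (abs(cfg$ar1_rho) >= 1) stopf("ar1_rho must lie in (-1, 1)")
  if (cfg$floor > cfg$ceiling) stopf("floor must not exceed ceiling")
  structure(cfg, class = "sim_config")
}

# Backfill six anxiety items (post-recoding scale, integer tenths) whose
# exact mean equals the scored value.  All arithmetic is on integer tenths
# so the score == mean(items) identity holds to the last digit.
backfill_anxiety_items <- function(score_tenths, jitter_sd = 1.2) {
  d <- round(stats::rnorm(6L, 0, jitter_sd * 10))
  d <- d - round(mean(d))
  d[1L] <- d[1L] - sum(d)
  it <- pmin(100, pmax(0, score_tenths + d))
  diff <- 6 * score_tenths - sum(it)
  while (diff != 0) {
    if (diff > 0) {
      i <- which.max(100 - it)
      add <- min(diff, 100 - it[i])
    } else {
      i <- which.max(it)
      add <- max(diff, -it[i])
    }
    it[i] <- it[i] + add
    diff <- diff - add
  }
  it
}

#' Simulate one participant's complete scored series
#'
#' Generates the full (pre-missingness) series of scored observations for
#' one participant under a [sim_config()]. Anxiety scores are quantized to
#' one decimal (a 10.0 cm visual-analog line read in mm) with six item
#' values backfilled so the score equals the item mean exactly; behavior
#' scores are rounded to the 0-5 Likert grid. Reproducible given
#' `(seed, participant_id)`.
#'
#' @param config A [sim_config()].
#' @param participant_id Id of a participant present in the design.
#' @return Data frame of scored observations (layout of [score_dataset()]).
#' @export
simulate_participant <- function(config, participant_id) {
  if (!inherits(config, "sim_config")) stopf("'config' must be a sim_config")
  participant_id <- as.character(participant_id)
  pd <- NULL
  for (p in config$design$participants) if (p$id == participant_id) pd <- p
  if (is.null(pd)) stopf("participant '%s' is not in the design", participant_id)

  set.seed(substream_seed(config$seed, participant_id, config$outcome, "latent"))
  u <- stats::rnorm(1L, 0, config$tau_u)
  v <- stats::rnorm(1L, 0, config$tau_v)

  dp <- day_phases(pd)
  s <- config$design$slots_per_day
  n <- nrow(dp) * s

  set.seed(substream_seed(config$seed, participant_id, config$outcome, "noise"))
  e <- numeric(n)
  rho <- config$ar1_rho
  innov_sd <- config$sigma * sqrt(1 - rho^2)
  prev <- NA_real_
  for (k in seq_len(n)) {
    new_day <- ((k - 1L) %% s) == 0L
    if (is.na(prev) || (new_day && !config$ar1_persist))
      e[k] <- stats::rnorm(1L, 0, config$sigma)
    else
      e[k] <- rho * prev + stats::rnorm(1L, 0, innov_sd)
    prev <- e[k]
  }

  day <- rep(dp$day_index, each = s)
  slot <- rep(seq_len(s), times = nrow(dp))
  kind <- rep(dp$phase_kind, each = s)
  eff <- (config$beta + v) *
    ifelse(kind == "B", config$decay[slot],
           ifelse(kind == "A1", config$carryover, 0))
  value <- config$mu0 + u + config$trend * day + eff + e
  value <- pmin(config$ceiling, pmax(config$floor, value))

  items <- matrix(NA_real_, n, 6L, dimnames = list(NULL, paste0("item_", 1:6)))
  if (config$outcome == "anxiety") {
    tenths <- as.integer(round(value * 10))
    score <- tenths / 10
    if (config$items) {
      set.seed(substream_seed(config$seed, participant_id, config$outcome, "items"))
      for (k in seq_len(n)) items[k, ] <- backfill_anxiety_items(tenths[k]) / 10
    }
  } else {
    score <- as.numeric(round(value))
    if (config$items) items[, 1L] <- score
  }

  out <- data.frame(participant_id = participant_id,
                    day_index = day, slot_index = slot,
                    slot_label = rep(config$design$slot_labels, times = nrow(dp)),
                    time_index = (day - 1L) * s + slot,
                    phase_kind = kind,
                    phase_occurrence = rep(dp$phase_occurrence, each = s),
                    outcome = config$outcome, score = score,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(items))
  out$missing <- FALSE
  attr(out, "latent") <- c(u = u, v = v)
  out
}

#' Flag observations as missing completely at random
#'
#' @param observations Scored-observation data frame.
#' @param rate Missingness probability in \[0, 1\].
#' @param seed Integer seed (an independent substream is derived from it).
#' @return The observations with `missing` flags set and scores/items of
#'   flagged rows blanked to `NA`.
#' @export
inject_missingness <- function(observations, rate, seed = 1L) {
  if (!is_scalar_number(rate) || rate < 0 || rate > 1)
    stopf("'rate' must lie in [0, 1]")
  set.seed(substream_seed(seed, "missingness"))
  flag <- stats::runif(nrow(observations)) < rate
  observations$missing <- observations$missing | flag
  observations$score[observations$missing] <- NA_real_
  for (col in paste0("item_", 1:6))
    observations[[col]][observations$missing] <- NA_real_
  observations
}

#' Simulate a complete ABAB momentary-assessment study
#'
#' Runs [simulate_participant()] and per-participant missingness injection
#' for every case and outcome, and records every latent draw in a
#' ground-truth sidecar, including the design-comparable effect size
#' implied by the configuration, `delta = beta / sqrt(tau_u^2 + sigma^2)`.
#'
#' @param anxiety,behavior [sim_config()] objects (or `NULL` to skip an
#'   outcome). Both must share the anxiety config's design.
#' @return A list with `records` (long-format assessment records, raw item
#'   scale), `scored` (scored observations) and `truth` (per-outcome latent
#'   draws `u`, `v`, the implied `delta`, and a config echo).
#' @export
simulate_study <- function(anxiety = sim_config("anxiety"),
                           behavior = sim_config("behavior")) {
  configs <- Filter(Negate(is.null), list(anxiety = anxiety, behavior = behavior))
  if (!length(configs)) stopf("at least one outcome configuration is required")
  design <- configs[[1L]]$design
  scored <- list()
  truth <- list()
  for (cfg in configs) {
    if (!identical(build_design_grid(cfg$design), build_design_grid(design)))
      stopf("all outcome configurations must share one design")
    u <- v <- numeric(0)
    for (p in design$participants) {
      obs <- simulate_participant(cfg, p$id)
      lat <- attr(obs, "latent")
      u[p$id] <- lat[["u"]]
      v[p$id] <- lat[["v"]]
      obs <- inject_missingness(obs, cfg$missing_rate,
                                substream_seed(cfg$seed, p$id, cfg$outcome, "mcar"))
      scored[[length(scored) + 1L]] <- obs
    }
    truth[[cfg$outcome]] <- list(
      u = u, v = v,
      delta = cfg$beta / sqrt(cfg$tau_u^2 + cfg$sigma^2),
      config = cfg)
  }
  scored <- do.call(rbind, scored)
  rownames(scored) <- NULL
  list(records = scored_to_records(scored), scored = scored, truth = truth)
}

# Convert scored observations back to raw assessment records (undo the
# anxiety item recoding; behavior items are stored unreversed).
scored_to_records <- function(scored) {
  rec <- data.frame(participant_id = scored$participant_id,
                    day_index = scored$day_index,
                    slot_index = scored$slot_index,
                    slot_label = scored$slot_label,
                    phase_kind = scored$phase_kind,
                    phase_occurrence = scored$phase_occurrence,
                    outcome_kind = scored$outcome,
                    stringsAsFactors = FALSE)
  items <- as.matrix(scored[paste0("item_", 1:6)])
  anx <- scored$outcome == "anxiety"
  items[anx, c(1L, 4L, 5L)] <- 10 - items[anx, c(1L, 4L, 5L)]
  rec <- cbind(rec, as.data.frame(items))
  rec$missing <- scored$missing
  rec
}

#' Write a ground-truth sidecar file
#'
#' Flat key-value text: every latent draw, the implied effect size, and an
#' echo of the scalar configuration fields.
#'
#' @param truth The `truth` element of a [simulate_study()] result.
#' @param path Output file path.
#' @export
write_truth_sidecar <- function(truth, path) {
  lines <- character(0)
  for (out in names(truth)) {
    tr <- truth[[out]]
    lines <- c(lines,
               sprintf("%s.delta=%.17g", out, tr$delta),
               sprintf("%s.u.%s=%.17g", out, names(tr$u), tr$u),
               sprintf("%s.v.%s=%.17g", out, names(tr$v), tr$v))
    cfg <- tr$config
    fmt <- function(x) formatC(x, digits = 17, format = "g")
    for (f in c("mu0", "sigma", "beta", "carryover", "tau_u", "tau_v",
                "ar1_rho", "trend", "missing_rate", "floor", "ceiling", "seed"))
      lines <- c(lines, sprintf("%s.config.%s=%s", out, f, fmt(cfg[[f]])))
    lines <- c(lines, sprintf("%s.config.decay=%s", out,
                              paste(fmt(cfg$decay), collapse = ",")))
  }
  writeLines(lines, path)
  invisible(path)
}
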