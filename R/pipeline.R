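#' Run the full ABAB analysis over a scored dataset
#'
#' Per participant and outcome: phase descriptives, PEM, split-middle
#' baseline trend with stability envelope, MAD variability comparison,
#' level segmentation, both NAP comparisons (all A vs B and A0-only vs B)
#' with effect bands, and the carryover flag. When at least three cases
#' are usable, the group-level BC-SMD is estimated overall and separately
#' per within-day slot. Failures of an individual participant's stage are
#' contained and reported as a note on that row; the group stage is absent
#' (with an explanatory flag) when fewer than three cases can be fit.
#' Deterministic given input and options.
#'
#' @param scored Scored-observation data frame ([score_dataset()] layout),
#'   possibly spanning several outcomes.
#' @param design Optional [design_spec()]; enables the missingness table.
#' @param direction Therapeutic direction shared by all outcomes after
#'   recoding (default `"decrease"`).
#' @param level Confidence level for NAP and BC-SMD intervals.
#' @param mad_constant MAD scale constant (see [scaled_mad()]).
#' @param min_segment_size,cp Segmentation parameters ([detect_levels()]).
#' @param verbose Emit one progress line per analysis stage?
#' @return An object of class `study_report`: data frames `descriptives`,
#'   `visual`, `nap`, `bcsmd`, `missingness` (or `NULL`), plus `options`.
#' @export
analyze_study <- function(scored, design = NULL,
                          direction = c("decrease", "increase"),
                          level = 0.95, mad_constant = 1.4826,
                          min_segment_size = 2L, cp = 0.01,
                          verbose = FALSE) {
  direction <- match.arg(direction)
  say <- function(...) if (verbose) message(sprintf(...))
  desc <- vis <- napt <- list()
  group <- list()
  for (out in unique(scored$outcome)) {
    dat <- scored[scored$outcome == out, , drop = FALSE]
    for (id in unique(dat$participant_id)) {
      series <- dat[dat$participant_id == id, , drop = FALSE]
      obs <- series[!series$missing & !is.na(series$score), , drop = FALSE]
      a0 <- obs$score[obs$phase_kind == "A0"]
      a_all <- obs$score[obs$phase_kind %in% c("A0", "A1")]
      b <- obs$score[obs$phase_kind == "B"]
      note <- function(e) conditionMessage(e)

      say("descriptives: outcome %s participant %s (%d rows)", out, id, nrow(obs))
      row <- tryCatch({
        ps <- phase_stats(series)
        pick <- function(kind, col) {
          v <- ps[[col]][ps$phase_kind == kind]
          if (length(v)) v else NA_real_
        }
        pm <- pem(a0, b, direction)
        data.frame(outcome = out, participant_id = id,
                   mean_A0 = pick("A0", "mean"), sd_A0 = pick("A0", "sd"),
                   mean_B = pick("B", "mean"), sd_B = pick("B", "sd"),
                   mean_A1 = pick("A1", "mean"), sd_A1 = pick("A1", "sd"),
                   pem_n = pm$n_in_direction, pem_n_B = pm$n_B,
                   pem_pct = pm$pem_pct, note = NA_character_,
                   stringsAsFactors = FALSE)
      }, error = function(e) data.frame(outcome = out, participant_id = id,
                                        mean_A0 = NA, sd_A0 = NA, mean_B = NA,
                                        sd_B = NA, mean_A1 = NA, sd_A1 = NA,
                                        pem_n = NA, pem_n_B = NA, pem_pct = NA,
                                        note = note(e), stringsAsFactors = FALSE))
      desc[[length(desc) + 1L]] <- row

      say("visual analysis: outcome %s participant %s", out, id)
      row <- tryCatch({
        base <- series[series$phase_kind == "A0", , drop = FALSE]
        env <- stability_envelope(base$time_index[!base$missing],
                                  base$score[!base$missing])
        vr <- variability_mad(series, items = out == "anxiety",
                              scale_constant = mad_constant)
        seg <- suppressWarnings(detect_levels(obs$score, obs$time_index,
                                              min_segment_size, cp))
        data.frame(outcome = out, participant_id = id,
                   slope = env$slope, pct_within = env$pct_within,
                   stable_trend = env$stable,
                   mad_A0 = vr$mad_A0, mad_B = vr$mad_B,
                   mad_decreased = vr$decreased,
                   n_segments = length(seg$segment_means),
                   level_change = classify_level_change(seg),
                   note = NA_character_, stringsAsFactors = FALSE)
      }, error = function(e) data.frame(outcome = out, participant_id = id,
                                        slope = NA, pct_within = NA,
                                        stable_trend = NA, mad_A0 = NA,
                                        mad_B = NA, mad_decreased = NA,
                                        n_segments = NA, level_change = NA,
                                        note = note(e), stringsAsFactors = FALSE))
      vis[[length(vis) + 1L]] <- row

      say("nonoverlap: outcome %s participant %s", out, id)
      row <- tryCatch({
        np_all <- nap(a_all, b, direction, level, comparison = "allA_vs_B")
        np_a0 <- nap(a0, b, direction, level, comparison = "A0_vs_B")
        co <- carryover_flag(np_all, np_a0)
        data.frame(outcome = out, participant_id = id,
                   nap_allA = np_all$nap, ci_lo_allA = np_all$ci[1],
                   ci_hi_allA = np_all$ci[2], band_allA = np_all$band,
                   nap_A0 = np_a0$nap, ci_lo_A0 = np_a0$ci[1],
                   ci_hi_A0 = np_a0$ci[2], band_A0 = np_a0$band,
                   carryover = co$flagged, note = NA_character_,
                   stringsAsFactors = FALSE)
      }, error = function(e) data.frame(outcome = out, participant_id = id,
                                        nap_allA = NA, ci_lo_allA = NA,
                                        ci_hi_allA = NA, band_allA = NA,
                                        nap_A0 = NA, ci_lo_A0 = NA,
                                        ci_hi_A0 = NA, band_A0 = NA,
                                        carryover = NA, note = note(e),
                                        stringsAsFactors = FALSE))
      napt[[length(napt) + 1L]] <- row
    }

    say("group BC-SMD: outcome %s", out)
    slots <- sort(unique(dat$slot_index))
    grow <- function(label, expr) {
      tryCatch({
        es <- expr
        data.frame(outcome = out, stratum = label, g = es$g, se = es$se,
                   ci_lo = es$ci[1], ci_hi = es$ci[2], nu = es$nu, J = es$J,
                   tau_u_sq = es$tau_u_sq, tau_v_sq = es$tau_v_sq,
                   sigma_sq = es$sigma_sq, n_cases = es$n_cases,
                   n_obs = es$n_obs, note = NA_character_,
                   stringsAsFactors = FALSE)
      }, error = function(e) data.frame(outcome = out, stratum = label,
                                        g = NA, se = NA, ci_lo = NA, ci_hi = NA,
                                        nu = NA, J = NA, tau_u_sq = NA,
                                        tau_v_sq = NA, sigma_sq = NA,
                                        n_cases = NA, n_obs = NA,
                                        note = conditionMessage(e),
                                        stringsAsFactors = FALSE))
    }
    group[[length(group) + 1L]] <-
      grow("overall", bcsmd_effect(fit_reversal_model(dat, drop_insufficient = TRUE),
                                   level))
    for (s in slots)
      group[[length(group) + 1L]] <-
        grow(sprintf("slot_%d", s),
             stratified_bcsmd(dat, s, level, drop_insufficient = TRUE))
  }

  miss <- NULL
  if (!is.null(design))
    miss <- tryCatch(missingness_report(scored_to_records(scored), design),
                     error = function(e) NULL)

  structure(list(descriptives = do.call(rbind, desc),
                 visual = do.call(rbind, vis),
                 nap = do.call(rbind, napt),
                 bcsmd = do.call(rbind, group),
                 missingness = miss,
                 options = list(direction = direction, level = level,
                                mad_constant = mad_constant,
                                min_segment_size = min_segment_size, cp = cp)),
            class = "study_report")
}

#' Missingness bookkeeping against the scheduled design grid
#'
#' Scheduled assessments are all slots of the design grid; missing counts
#' are scheduled minus observed non-missing records, per outcome kind.
#' Percentages are rounded to one decimal.
#'
#' @param records Long-format assessment records.
#' @param spec The [design_spec()] the records were collected under.
#' @return Data frame with columns `outcome_kind`, `scheduled`, `missing`,
#'   `missing_pct`.
#' @export
#' @examples
#' # 133 of 492 scheduled -> 27.0%
missingness_report <- function(records, spec) {
  grid <- build_design_grid(spec)
  grid_key <- paste(grid$participant_id, grid$day_index, grid$slot_index, sep = "\r")
  rec_key <- paste(records$participant_id, records$day_index,
                   records$slot_index, sep = "\r")
  bad <- which(!rec_key %in% grid_key)
  if (length(bad))
    stopf("record at row %d (participant %s, day %d, slot %d) is not in the schedule",
          bad[1L], records$participant_id[bad[1L]], records$day_index[bad[1L]],
          records$slot_index[bad[1L]])
  out <- lapply(unique(records$outcome_kind), function(kind) {
    observed <- sum(records$outcome_kind == kind & !records$missing)
    scheduled <- nrow(grid)
    missing <- scheduled - observed
    data.frame(outcome_kind = kind, scheduled = scheduled, missing = missing,
               missing_pct = round(100 * missing / scheduled, 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write a study report as CSV tables plus a machine-readable summary
#'
#' Rendered tables round means, SDs, NAP and MAD values to two decimals
#' and PEM to whole percentages; `summary.json` retains full precision.
#'
#' @param report A [analyze_study()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "study_report")) stopf("'report' must be a study_report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rnd <- function(df, cols, digits) {
    for (col in intersect(cols, names(df))) df[[col]] <- round(df[[col]], digits)
    df
  }
  desc <- rnd(report$descriptives,
              c("mean_A0", "sd_A0", "mean_B", "sd_B", "mean_A1", "sd_A1"), 2L)
  desc <- rnd(desc, "pem_pct", 0L)
  vis <- rnd(report$visual, c("slope", "mad_A0", "mad_B"), 2L)
  vis <- rnd(vis, "pct_within", 0L)
  napt <- rnd(report$nap, c("nap_allA", "ci_lo_allA", "ci_hi_allA",
                            "nap_A0", "ci_lo_A0", "ci_hi_A0"), 2L)
  utils::write.csv(desc, file.path(dir, "descriptives.csv"), row.names = FALSE, na = "")
  utils::write.csv(vis, file.path(dir, "visual_analysis.csv"), row.names = FALSE, na = "")
  utils::write.csv(napt, file.path(dir, "nap.csv"), row.names = FALSE, na = "")
  utils::write.csv(report$bcsmd, file.path(dir, "bcsmd.csv"), row.names = FALSE, na = "")
  if (!is.null(report$missingness))
    utils::write.csv(report$missingness, file.path(dir, "missingness.csv"),
                     row.names = FALSE, na = "")
  jsonlite::write_json(unclass(report), file.path(dir, "summary.json"),
                       dataframe = "columns", digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(dir)
}

#' Re-render report tables from a saved machine-readable summary
#'
#' @param summary_path Path to a `summary.json` written by [write_report()].
#' @param dir Output directory for the re-rendered CSV tables.
#' @return The directory path, invisibly.
#' @export
render_report <- function(summary_path, dir) {
  raw <- jsonlite::read_json(summary_path, simplifyVector = TRUE)
  report <- structure(list(
    descriptives = as.data.frame(raw$descriptives, stringsAsFactors = FALSE),
    visual = as.data.frame(raw$visual, stringsAsFactors = FALSE),
    nap = as.data.frame(raw$nap, stringsAsFactors = FALSE),
    bcsmd = as.data.frame(raw$bcsmd, stringsAsFactors = FALSE),
    missingness = if (!is.null(raw$missingness))
      as.data.frame(raw$missingness, stringsAsFactors = FALSE),
    options = raw$options), class = "study_report")
  write_report(report, dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("ABAB study report: %d participant row(s), %d outcome(s)\n",
              nrow(x$descriptives), length(unique(x$descriptives$outcome))))
  ok <- !is.na(x$bcsmd$g)
  for (i in which(ok))
    cat(sprintf("  BC-SMD %s %s: g = %.3f (SE %.3f)\n", x$bcsmd$outcome[i],
                x$bcsmd$stratum[i], x$bcsmd$g[i], x$bcsmd$se[i]))
  if (any(!ok))
    cat(sprintf("  group stage unavailable for: %s\n",
                paste(unique(x$bcsmd$stratum[!ok]), collapse = ", ")))
  invisible(x)
}
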