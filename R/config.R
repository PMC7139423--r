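# Flat key-value configuration files for the simulator/CLI.
#
#   outcome=anxiety
#   mu0=3.3
#   decay=1,0.6,0
#   design.slots_per_day=3
#   design.slot_labels=10:00,12:00,14:00
#   design.participant.1=A0:5,B:1,A1:2,...
#
# Unlisted fields keep their sim_config() defaults.

SIM_SCALAR_FIELDS <- c("mu0", "sigma", "beta", "carryover", "tau_u", "tau_v",
                       "ar1_rho", "trend", "missing_rate", "floor", "ceiling",
                       "seed")

#' Write a simulation configuration as flat key-value text
#'
#' @param config A [sim_config()].
#' @param path Output file path.
#' @export
write_sim_config <- function(config, path) {
  if (!inherits(config, "sim_config")) stopf("'config' must be a sim_config")
  fmt <- function(x) formatC(x, digits = 17, format = "g")  # keeps "-Inf" readable
  lines <- c(sprintf("outcome=%s", config$outcome),
             sprintf("%s=%s", SIM_SCALAR_FIELDS,
                     fmt(unlist(config[SIM_SCALAR_FIELDS]))),
             sprintf("ar1_persist=%d", as.integer(config$ar1_persist)),
             sprintf("items=%d", as.integer(config$items)),
             sprintf("decay=%s", paste(fmt(config$decay), collapse = ",")),
             sprintf("design.slots_per_day=%d", config$design$slots_per_day),
             sprintf("design.slot_labels=%s",
                     paste(config$design$slot_labels, collapse = ",")))
  for (p in config$design$participants)
    lines <- c(lines, sprintf("design.participant.%s=%s", p$id,
                              paste(sprintf("%s:%d", p$phases, p$days),
                                    collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a simulation configuration from flat key-value text
#'
#' @param path Input file path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  get <- function(key) if (key %in% keys) vals[match(key, keys)] else NULL
  pkeys <- keys[startsWith(keys, "design.participant.")]
  design <- if (length(pkeys)) {
    participants <- lapply(pkeys, function(k) {
      id <- sub("^design\\.participant\\.", "", k)
      parts <- strsplit(strsplit(vals[match(k, keys)], ",")[[1L]], ":")
      participant_design(id,
                         vapply(parts, `[`, "", 1L),
                         as.integer(vapply(parts, `[`, "", 2L)))
    })
    design_spec(participants,
                slots_per_day = as.integer(get("design.slots_per_day") %||% 3L),
                slot_labels = if (!is.null(get("design.slot_labels")))
                  strsplit(get("design.slot_labels"), ",")[[1L]])
  } else default_design()
  args <- list(outcome = get("outcome") %||% "anxiety", design = design)
  for (f in SIM_SCALAR_FIELDS)
    if (!is.null(get(f))) args[[f]] <- as.numeric(get(f))
  if (!is.null(get("seed"))) args$seed <- as.integer(as.numeric(get("seed")))
  if (!is.null(get("decay"))) args$decay <- as.numeric(strsplit(get("decay"), ",")[[1L]])
  if (!is.null(get("ar1_persist"))) args$ar1_persist <- as.numeric(get("ar1_persist")) == 1
  if (!is.null(get("items"))) args$items <- as.numeric(get("items")) == 1
  do.call(sim_config, args)
}
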