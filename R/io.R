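# Long-format CSV layout
# ----------------------
# One row per scheduled assessment and outcome kind:
#   participant_id, day_index, slot_index, slot_label, phase_kind,
#   phase_occurrence, outcome_kind, item_1..item_6, missing (0/1)
# Missing assessments carry empty item fields and missing = 1.  Behavior
# records use item_1..item_3 (unused item columns stay empty).

LONG_CSV_COLUMNS <- c("participant_id", "day_index", "slot_index", "slot_label",
                      "phase_kind", "phase_occurrence", "outcome_kind",
                      paste0("item_", 1:6), "missing")

validate_records <- function(records) {
  missing_cols <- setdiff(LONG_CSV_COLUMNS, names(records))
  if (length(missing_cols))
    stopf("assessment records are missing column(s): %s", paste(missing_cols, collapse = ", "))
  bad <- which(!records$phase_kind %in% c("A0", "B", "A1"))
  if (length(bad))
    stopf("unknown phase label '%s' (row %d)", records$phase_kind[bad[1L]], bad[1L])
  bad <- which(!records$outcome_kind %in% c("anxiety", "behavior"))
  if (length(bad))
    stopf("unknown outcome kind '%s' (row %d)", records$outcome_kind[bad[1L]], bad[1L])
  key <- paste(records$participant_id, records$day_index, records$slot_index,
               records$outcome_kind, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stopf("duplicate (participant, day, slot, outcome) key at row %d", dup[1L])
  items <- as.matrix(records[paste0("item_", 1:6)])
  miss <- as.logical(records$missing)
  for (i in seq_len(nrow(records))) {
    v <- items[i, ]
    if (miss[i]) {
      if (any(!is.na(v)))
        stopf("row %d is flagged missing but carries item values", i)
    } else if (records$outcome_kind[i] == "anxiety") {
      if (anyNA(v[1:6]) || any(v[1:6] < 0 | v[1:6] > 10))
        stopf("row %d: anxiety records need six items within [0, 10]", i)
    } else {
      pres <- v[!is.na(v)]
      if (!length(pres) || any(pres != round(pres)) || any(pres < 0 | pres > 5))
        stopf("row %d: behavior records need integer items within 0..5", i)
    }
  }
  invisible(records)
}

#' Write assessment records to a long-format CSV file
#'
#' Numeric fields are rendered with 17 significant digits so that a write /
#' read round trip reproduces the dataset exactly, including missing
#' markers and phase tags.
#'
#' @param records Data frame of assessment records.
#' @param path Output file path.
#' @export
write_long_csv <- function(records, path) {
  validate_records(records)
  out <- records[LONG_CSV_COLUMNS]
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  for (col in paste0("item_", 1:6)) out[[col]] <- fmt(out[[col]])
  out$missing <- as.integer(as.logical(out$missing))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read assessment records from a long-format CSV file
#'
#' @param path Input file path. The header row must carry the documented
#'   column names; empty item fields encode missing values.
#' @return Validated data frame of assessment records (`missing` logical,
#'   items numeric with `NA` for absent responses).
#' @export
read_long_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(LONG_CSV_COLUMNS, names(raw))
  if (length(missing_cols))
    stopf("%s: missing column(s): %s", path, paste(missing_cols, collapse = ", "))
  to_num <- function(col) {
    x <- raw[[col]]
    x[!nzchar(x)] <- NA
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad)) stopf("%s: non-numeric value '%s' in %s (row %d)",
                           path, x[bad[1L]], col, bad[1L])
    v
  }
  records <- data.frame(participant_id = raw$participant_id,
                        day_index = as.integer(to_num("day_index")),
                        slot_index = as.integer(to_num("slot_index")),
                        slot_label = raw$slot_label,
                        phase_kind = raw$phase_kind,
                        phase_occurrence = as.integer(to_num("phase_occurrence")),
                        outcome_kind = raw$outcome_kind,
                        stringsAsFactors = FALSE)
  for (col in paste0("item_", 1:6)) records[[col]] <- to_num(col)
  records$missing <- as.integer(to_num("missing")) == 1L
  validate_records(records)
  records
}
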