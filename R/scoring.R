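#' Score the six-item state-anxiety short form
#'
#' Items are visual-analog responses in \[0, 10\], ordered calm, tense,
#' upset, relaxed, content, worried. Items 1, 4 and 5 (calm, relaxed,
#' content) are reverse-keyed and recoded as `10 - value`; the score is the
#' arithmetic mean of the six post-recoding items, so higher scores mean
#' more momentary anxiety.
#'
#' @param items Numeric vector of length 6, or a 6-column matrix /
#'   data frame (one row per assessment).
#' @return Numeric score(s) in \[0, 10\].
#' @export
#' @examples
#' score_stai6(c(5, 5, 5, 5, 5, 5))   # 5
#' score_stai6(c(0, 10, 10, 0, 0, 10)) # 10
score_stai6 <- function(items) {
  if (is.data.frame(items)) items <- as.matrix(items)
  if (!is.matrix(items)) {
    if (length(items) != 6L) stopf("score_stai6 expects exactly 6 items, got %d", length(items))
    items <- matrix(items, nrow = 1L)
  }
  if (ncol(items) != 6L) stopf("score_stai6 expects exactly 6 items per row, got %d", ncol(items))
  if (!is.numeric(items) || anyNA(items) || any(items < 0 | items > 10))
    stopf("state-anxiety items must be numeric within [0, 10]")
  rec <- items
  rec[, c(1L, 4L, 5L)] <- 10 - rec[, c(1L, 4L, 5L)]
  drop(rowMeans(rec))
}

# Post-recoding item vector (kept for item-level variability analyses).
recode_stai6 <- function(items) {
  items[c(1L, 4L, 5L)] <- 10 - items[c(1L, 4L, 5L)]
  items
}

#' Score a teacher-rated behavior item
#'
#' Behavior items are 6-point Likert frequencies (0 = never ... 5 = almost
#' always). For behaviors where an *increase* is the desired outcome, the
#' item is reverse-coded as `5 - value` so that every scored series shares
#' the decrease-desired direction.
#'
#' @param item Integer value(s) in 0..5.
#' @param reverse Logical; reverse-code the item?
#' @return Integer score(s) in 0..5.
#' @export
#' @examples
#' score_behavior(2, reverse = TRUE)  # 3
score_behavior <- function(item, reverse = FALSE) {
  if (!is.numeric(item) || anyNA(item) || any(item != as.integer(item)) ||
      any(item < 0 | item > 5))
    stopf("behavior items must be integers within 0..5")
  if (isTRUE(reverse)) 5L - as.integer(item) else as.integer(item)
}

#' Score a long-format assessment dataset
#'
#' Turns raw assessment records (as read by [read_long_csv()] or produced
#' by [simulate_study()]) into scored observations: one anxiety score per
#' record (mean of the six post-recoding items) or one behavior score
#' (selected Likert item, optionally reverse-coded). Post-recoding item
#' values are retained for item-level variability analyses. Missing records
#' keep their place with `score = NA`.
#'
#' @param records Data frame of assessment records (long CSV layout).
#' @param behavior_item Which behavior item column constitutes the analyzed
#'   behavior score; a single index or a named vector keyed by
#'   participant id.
#' @param behavior_reverse Character vector of participant ids whose
#'   selected behavior item is reverse-coded (desired effect is an increase).
#' @param slots_per_day Used to build the global assessment time index;
#'   defaults to the maximum slot index present.
#' @return Data frame of scored observations with columns `participant_id`,
#'   `day_index`, `slot_index`, `slot_label`, `time_index`, `phase_kind`,
#'   `phase_occurrence`, `outcome`, `score`, `item_1`..`item_6`, `missing`.
#' @export
score_dataset <- function(records, behavior_item = 1L, behavior_reverse = character(),
                          slots_per_day = max(records$slot_index)) {
  validate_records(records)
  n <- nrow(records)
  item_cols <- grep("^item_[0-9]+$", names(records), value = TRUE)
  items <- as.matrix(records[item_cols])
  score <- rep(NA_real_, n)
  out_items <- matrix(NA_real_, n, 6L,
                      dimnames = list(NULL, paste0("item_", 1:6)))
  miss <- as.logical(records$missing)
  for (i in seq_len(n)) {
    if (miss[i]) next
    if (records$outcome_kind[i] == "anxiety") {
      v <- recode_stai6(items[i, 1:6])
      out_items[i, ] <- v
      score[i] <- mean(v)
    } else {
      bi <- behavior_item
      if (!is.null(names(bi))) bi <- bi[[records$participant_id[i]]] %||% 1L
      rev <- records$participant_id[i] %in% behavior_reverse
      v <- score_behavior(items[i, bi], reverse = rev)
      out_items[i, 1L] <- v
      score[i] <- v
    }
  }
  out <- data.frame(participant_id = records$participant_id,
                    day_index = records$day_index,
                    slot_index = records$slot_index,
                    slot_label = records$slot_label,
                    time_index = (records$day_index - 1L) * slots_per_day + records$slot_index,
                    phase_kind = records$phase_kind,
                    phase_occurrence = records$phase_occurrence,
                    outcome = records$outcome_kind,
                    score = score,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(out_items))
  out$missing <- miss
  out[order(out$outcome, out$participant_id, out$day_index, out$slot_index), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
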