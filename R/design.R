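#' Define one participant's ABAB phase plan
#'
#' A phase plan is an ordered sequence of phase blocks. It must start with
#' the `A0` baseline block; afterwards intervention (`B`) and withdrawal
#' (`A1`) blocks strictly alternate, beginning with `B`. Consecutive
#' intervention days form a single `B` block (a multi-day session pair is
#' one occurrence).
#'
#' @param id Participant identifier (coerced to character).
#' @param phases Character vector of phase kinds, each one of
#'   `"A0"`, `"B"`, `"A1"`.
#' @param days Integer vector, same length as `phases`: number of school
#'   days in each block (all `>= 1`).
#' @param n_school_days Total school days; must equal `sum(days)`.
#'
#' @return An object of class `participant_design`.
#' @seealso [design_spec()], [build_design_grid()]
#' @export
#' @examples
#' participant_design("1", c("A0", "B", "A1", "B"), c(5, 1, 2, 1))
participant_design <- function(id, phases, days, n_school_days = sum(days)) {
  id <- as.character(id)
  if (length(id) != 1L || !nzchar(id)) stopf("participant id must be a single non-empty string")
  phases <- as.character(phases)
  if (length(phases) != length(days) || length(phases) < 1L)
    stopf("participant %s: 'phases' and 'days' must be non-empty and of equal length", id)
  if (!all(phases %in% c("A0", "B", "A1")))
    stopf("participant %s: unknown phase kind(s): %s", id,
          paste(setdiff(phases, c("A0", "B", "A1")), collapse = ", "))
  days <- as.integer(days)
  if (anyNA(days) || any(days < 1L))
    stopf("participant %s: block lengths must be positive integers", id)
  if (phases[1L] != "A0")
    stopf("participant %s: phase plan must start with the A0 baseline", id)
  if (length(phases) > 1L) {
    expected <- rep(c("B", "A1"), length.out = length(phases) - 1L)
    if (!identical(phases[-1L], expected))
      stopf("participant %s: after A0, B and A1 blocks must strictly alternate starting with B", id)
  }
  if (sum(days) != n_school_days)
    stopf("participant %s: phase-plan days (%d) do not sum to n_school_days (%d)",
          id, sum(days), as.integer(n_school_days))
  structure(list(id = id, phases = phases, days = days,
                 n_school_days = as.integer(n_school_days)),
            class = "participant_design")
}

#' Define an ABAB momentary-assessment study design
#'
#' @param participants List of [participant_design()] objects with unique ids.
#' @param slots_per_day Number of assessments per school day (`>= 1`).
#' @param slot_labels Optional nominal clock labels, one per slot.
#'
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(participants, slots_per_day = 3L, slot_labels = NULL) {
  if (inherits(participants, "participant_design")) participants <- list(participants)
  if (!length(participants) || !all(vapply(participants, inherits, TRUE, "participant_design")))
    stopf("'participants' must be a non-empty list of participant_design objects")
  ids <- vapply(participants, `[[`, "", "id")
  if (anyDuplicated(ids)) stopf("duplicate participant ids: %s",
                                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  slots_per_day <- as.integer(slots_per_day)
  if (is.na(slots_per_day) || slots_per_day < 1L) stopf("slots_per_day must be >= 1")
  if (is.null(slot_labels)) slot_labels <- paste0("slot", seq_len(slots_per_day))
  if (length(slot_labels) != slots_per_day)
    stopf("slot_labels must have length slots_per_day")
  structure(list(participants = participants, slots_per_day = slots_per_day,
                 slot_labels = as.character(slot_labels)),
            class = "design_spec")
}

#' Default eight-participant ABAB design
#'
#' The design emulated by the synthetic generator: eight participants
#' assessed three times per school day (nominally 10:00, 12:00 and 14:00).
#' Seven participants have 20 school days; participant "5" attended three
#' days a week over eight weeks for 24 school days. Baselines last 5-6
#' days, intervention (B) blocks one day, and participants complete six
#' intervention sessions except participant "8" with five.
#'
#' @return A `design_spec` whose grid holds 492 assessment slots.
#' @export
#' @examples
#' nrow(build_design_grid(default_design()))  # 492
default_design <- function() {
  plan20 <- function(id)
    participant_design(id,
      c("A0", rep(c("B", "A1"), 6L)),
      c(5L, 1L, 2L, 1L, 2L, 1L, 2L, 1L, 1L, 1L, 1L, 1L, 1L))
  p5 <- participant_design("5",
      c("A0", rep(c("B", "A1"), 6L)),
      c(6L, 1L, 3L, 1L, 2L, 1L, 3L, 1L, 2L, 1L, 1L, 1L, 1L))
  p8 <- participant_design("8",
      c("A0", rep(c("B", "A1"), 5L)),
      c(6L, 1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L, 1L))
  design_spec(
    list(plan20("1"), plan20("2"), plan20("3"), plan20("4"), p5,
         plan20("6"), plan20("7"), p8),
    slots_per_day = 3L,
    slot_labels = c("10:00", "12:00", "14:00"))
}

# Per-day phase kind and occurrence index implied by a phase plan.
day_phases <- function(pd) {
  occ <- integer(length(pd$phases))
  counter <- c(A0 = 0L, B = 0L, A1 = 0L)
  for (k in seq_along(pd$phases)) {
    counter[pd$phases[k]] <- counter[pd$phases[k]] + 1L
    occ[k] <- counter[pd$phases[k]]
  }
  data.frame(day_index = seq_len(pd$n_school_days),
             phase_kind = rep(pd$phases, pd$days),
             phase_occurrence = rep(occ, pd$days),
             stringsAsFactors = FALSE)
}

#' Expand a design into its grid of scheduled assessment slots
#'
#' Produces one row per participant x school day x within-day slot, each
#' tagged with the phase kind and 1-based phase occurrence implied by the
#' participant's phase plan. The expansion is deterministic and the row
#' count equals `sum_i(n_school_days_i) * slots_per_day`.
#'
#' @param spec A [design_spec()].
#' @return A data frame with columns `participant_id`, `day_index`,
#'   `slot_index`, `slot_label`, `phase_kind`, `phase_occurrence`.
#' @export
build_design_grid <- function(spec) {
  if (!inherits(spec, "design_spec")) stopf("'spec' must be a design_spec")
  s <- spec$slots_per_day
  out <- lapply(spec$participants, function(pd) {
    dp <- day_phases(pd)
    data.frame(participant_id = pd$id,
               day_index = rep(dp$day_index, each = s),
               slot_index = rep(seq_len(s), times = nrow(dp)),
               slot_label = rep(spec$slot_labels, times = nrow(dp)),
               phase_kind = rep(dp$phase_kind, each = s),
               phase_occurrence = rep(dp$phase_occurrence, each = s),
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, out)
  rownames(grid) <- NULL
  grid
}
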