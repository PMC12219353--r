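#' Detect confirmed disability worsening and improvement events
#'
#' Scans each patient's EDSS trajectory left to right against a roving
#' reference and returns all confirmed events. A candidate worsening at a
#' visit requires an EDSS increase over the current reference of at least
#' [cda_threshold()] of the reference value; improvements mirror the rule.
#' A candidate is confirmed by the first visit at least
#' `config$confirmation_days` later that is not within
#' `config$confirmation_relapse_exclusion_days` after any relapse onset
#' (closed window); every visit strictly between onset and confirmation, and
#' the confirmation visit itself, must sustain the change relative to the
#' reference. Relapse-tainted visits are barred from the confirmation role
#' only: they still count toward the sustained-change requirement.
#'
#' After each confirmed event the reference is reset to the confirmation
#' visit and the scan resumes there. Under
#' `baseline_scheme = "relapse_rebaseline"` the reference is additionally
#' reset at the first visit 30 or more days after each relapse onset whose
#' value is not below the original (day 0) baseline; such resets take effect
#' when the scan reaches the reset visit and never move the reference back in
#' time.
#'
#' @param visits Tibble with columns `patient_id`, `day`, `edss`. Values may
#'   be off the half-point grid (as produced by [ric_decompose()]).
#' @param relapses Optional tibble with columns `patient_id`, `onset_day`;
#'   `NULL` means no relapses for any patient.
#' @param config An [analysis_config()].
#' @return Tibble with one row per confirmed event: `patient_id`, `kind`
#'   (`"worsening"` or `"improvement"`), `onset_day`, `onset_value`,
#'   `reference_day`, `reference_value`, `confirmation_day`,
#'   `confirmation_value`, ordered by patient and onset. Events satisfy
#'   `confirmation_day - onset_day >= config$confirmation_days` and are
#'   non-overlapping.
#' @examples
#' visits <- tibble::tibble(patient_id = "p1",
#'                          day = c(0, 84, 168, 252),
#'                          edss = c(2, 3, 3, 3))
#' detect_events(visits)
#' @export
detect_events <- function(visits, relapses = NULL,
                          config = analysis_config()) {
  check_columns(visits, c("patient_id", "day", "edss"), "visits")
  if (is.null(relapses)) {
    relapses <- tibble::tibble(patient_id = character(),
                               onset_day = numeric())
  }
  check_columns(relapses, c("patient_id", "onset_day"), "relapses")

  ord <- order(visits$patient_id, visits$day)
  pid <- visits$patient_id[ord]
  day <- as.numeric(visits$day[ord])
  edss <- as.numeric(visits$edss[ord])
  pats <- unique(pid)
  counts <- table(factor(pid, levels = pats))
  visit_ptr <- c(0L, cumsum(as.integer(counts)))

  rord <- order(match(relapses$patient_id, pats), relapses$onset_day)
  keep <- !is.na(match(relapses$patient_id, pats)[rord])
  rord <- rord[keep]
  rel_day <- as.numeric(relapses$onset_day[rord])
  rcounts <- table(factor(relapses$patient_id[rord], levels = pats))
  relapse_ptr <- c(0L, cumsum(as.integer(rcounts)))

  scheme <- if (config$baseline_scheme == "relapse_rebaseline") 1L else 0L
  res <- detect_events_cpp(day, edss, visit_ptr, rel_day, relapse_ptr,
                           config$confirmation_days,
                           config$confirmation_relapse_exclusion_days,
                           scheme)
  tibble::tibble(
    patient_id = pats[res$patient],
    kind = c("worsening", "improvement")[res$kind_code],
    onset_day = res$onset_day,
    onset_value = res$onset_value,
    reference_day = res$reference_day,
    reference_value = res$reference_value,
    confirmation_day = res$confirmation_day,
    confirmation_value = res$confirmation_value
  )
}

#' Roving-baseline reset after a confirmed event
#'
#' The reference becomes the confirmation visit of the event: its day and the
#' EDSS value observed there.
#'
#' @param state List or one-row tibble with `reference_day` and
#'   `reference_value`.
#' @param event One-row event tibble (a row of [detect_events()] output).
#' @return Updated baseline state (list with `reference_day`,
#'   `reference_value`).
#' @export
apply_roving_baseline <- function(state, event) {
  list(reference_day = as.numeric(event$confirmation_day),
       reference_value = as.numeric(event$confirmation_value))
}

#' Relapse-based re-baseline
#'
#' Resets the reference to the first visit at least
#' `config$confirmation_relapse_exclusion_days` (30 by default) after the
#' relapse onset whose EDSS is not lower than the original (day 0) baseline
#' value. If no such visit exists the state is returned unchanged.
#'
#' @param visits Tibble of one patient's visits (`day`, `edss`), sorted.
#' @param state Baseline state (list with `reference_day`,
#'   `reference_value`).
#' @param relapse_onset_day Relapse onset day.
#' @param config An [analysis_config()].
#' @return Updated (or unchanged) baseline state.
#' @export
apply_relapse_rebaseline <- function(visits, state, relapse_onset_day,
                                     config = analysis_config()) {
  orig <- visits$edss[which.min(visits$day)]
  ok <- which(visits$day >= relapse_onset_day +
                config$confirmation_relapse_exclusion_days &
                visits$edss >= orig - 1e-9)
  if (length(ok) == 0) return(state)
  j <- ok[1]
  list(reference_day = as.numeric(visits$day[j]),
       reference_value = as.numeric(visits$edss[j]))
}
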