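#' Relapse-free windows required for PIRA under each definition
#'
#' Returns the closed intervals (in study days) that must contain no relapse
#' onset for a confirmed worsening to be classified as PIRA:
#' * `standard1`: reference visit to confirmation visit;
#' * `standard2`: reference visit to 30 days after the event, and 30 days
#'   before to 30 days after the confirmation visit;
#' * `standard3`: 90 days before to 30 days after the event, and 90 days
#'   before to 30 days after the confirmation visit;
#' * `non_raw`: the 90 days preceding the event (identical to the RAW
#'   window, making PIRA and RAW complementary by construction).
#'
#' The 30- and 90-day offsets come from `config`
#' (`confirmation_relapse_exclusion_days` and `raw_window_days`).
#'
#' @param definition One of `"standard1"`, `"standard2"`, `"standard3"`,
#'   `"non_raw"`.
#' @param reference_day,onset_day,confirmation_day Event anchor days.
#' @param config An [analysis_config()].
#' @return A list of `c(start, end)` closed intervals.
#' @export
pira_windows <- function(definition, reference_day, onset_day,
                         confirmation_day, config = analysis_config()) {
  d30 <- config$confirmation_relapse_exclusion_days
  d90 <- config$raw_window_days
  switch(definition,
    standard1 = list(c(reference_day, confirmation_day)),
    standard2 = list(c(reference_day, onset_day + d30),
                     c(confirmation_day - d30, confirmation_day + d30)),
    standard3 = list(c(onset_day - d90, onset_day + d30),
                     c(confirmation_day - d90, confirmation_day + d30)),
    non_raw = list(c(onset_day - d90, onset_day)),
    stop(sprintf("unknown PIRA definition: '%s'", definition), call. = FALSE)
  )
}

#' Is a confirmed worsening relapse-associated (RAW)?
#'
#' A worsening is RAW when some relapse onset precedes or coincides with the
#' event onset by at most `config$raw_window_days` days (closed window,
#' `0 <= onset_day - relapse_day <= 90` by default). The event *onset* day is
#' used, not the confirmation day.
#'
#' @param onset_day Event onset day(s).
#' @param relapse_days Numeric vector of the patient's relapse onset days.
#' @param config An [analysis_config()].
#' @return Logical vector.
#' @export
classify_raw <- function(onset_day, relapse_days,
                         config = analysis_config()) {
  vapply(onset_day, function(d) {
    any(d - relapse_days >= -1e-9 &
          d - relapse_days <= config$raw_window_days + 1e-9)
  }, logical(1))
}

#' Classify confirmed events as PIRA, RAW or undefined
#'
#' Applies one of the four event-based PIRA definitions to a table of
#' confirmed events. A worsening is PIRA when every definition window
#' ([pira_windows()]) is free of relapse onsets; otherwise it is RAW if
#' [classify_raw()] holds, and undefined if not. Under `non_raw` the PIRA
#' predicate is exactly the negation of the RAW predicate, so no worsening is
#' left undefined. Improvement events are labelled `"n/a"`.
#'
#' When `visits` is supplied, RAW events are sub-classified as `"transient"`
#' (some visit after the event onset has EDSS not above the event's reference
#' value, i.e. complete recovery) or `"sustained"`; other events get
#' `raw_subtype = "n/a"`.
#'
#' @param events Event tibble from [detect_events()].
#' @param relapses Tibble with `patient_id`, `onset_day` (may be empty or
#'   `NULL`).
#' @param definition One of `"standard1"`, `"standard2"`, `"standard3"`,
#'   `"non_raw"`.
#' @param config An [analysis_config()].
#' @param visits Optional visit tibble used to sub-classify RAW events.
#' @return `events` with added columns `classification` (`"PIRA"`, `"RAW"`,
#'   `"undefined"`, `"n/a"`) and `raw_subtype` (`"transient"`, `"sustained"`,
#'   `"n/a"`).
#' @examples
#' visits <- tibble::tibble(patient_id = "p1", day = c(0, 84, 168, 252),
#'                          edss = c(2, 3, 3, 3))
#' ev <- detect_events(visits)
#' classify_events(ev, NULL, "non_raw")
#' @export
classify_events <- function(events, relapses,
                            definition = c("standard1", "standard2",
                                           "standard3", "non_raw"),
                            config = analysis_config(), visits = NULL) {
  definition <- match.arg(definition)
  if (is.null(relapses)) {
    relapses <- tibble::tibble(patient_id = character(),
                               onset_day = numeric())
  }
  rel_split <- split(as.numeric(relapses$onset_day), relapses$patient_id)
  n <- nrow(events)
  classification <- rep("n/a", n)
  worsening <- which(events$kind == "worsening")
  for (i in worsening) {
    rel <- rel_split[[events$patient_id[i]]]
    if (is.null(rel)) rel <- numeric()
    wins <- pira_windows(definition, events$reference_day[i],
                         events$onset_day[i], events$confirmation_day[i],
                         config)
    clean <- all(vapply(wins, function(w) {
      !any(rel >= w[1] - 1e-9 & rel <= w[2] + 1e-9)
    }, logical(1)))
    if (clean) {
      classification[i] <- "PIRA"
    } else if (classify_raw(events$onset_day[i], rel, config)) {
      classification[i] <- "RAW"
    } else {
      classification[i] <- "undefined"
    }
  }
  events$classification <- classification
  events$raw_subtype <- rep("n/a", n)
  if (!is.null(visits) && any(classification == "RAW")) {
    events$raw_subtype <- classify_raw_subtype(events, visits)
  }
  events
}

#' Sub-classify RAW events as transient or sustained
#'
#' A RAW event is transient when the patient later recovers completely: some
#' visit after the event onset has an EDSS value not above the event's
#' reference value. With no such visit (including when the event sits at the
#' final visits of follow-up) the accumulation is sustained.
#'
#' @param events Event tibble with a `classification` column.
#' @param visits Visit tibble (`patient_id`, `day`, `edss`).
#' @return Character vector aligned with `events` rows: `"transient"`,
#'   `"sustained"`, or `"n/a"` for non-RAW rows.
#' @export
classify_raw_subtype <- function(events, visits) {
  vis_split <- split(visits[, c("day", "edss")], visits$patient_id)
  out <- rep("n/a", nrow(events))
  for (i in which(events$classification == "RAW")) {
    v <- vis_split[[events$patient_id[i]]]
    later <- v$edss[v$day > events$onset_day[i] + 1e-9]
    recovered <- length(later) > 0 &&
      any(later <= events$reference_value[i] + 1e-9)
    out[i] <- if (recovered) "transient" else "sustained"
  }
  out
}
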