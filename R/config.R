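#' Analysis configuration for event detection and classification
#'
#' Bundles the window constants used throughout the package. Time is measured
#' in integer days since randomisation (day 0); all windows are closed
#' intervals in days, so "12 weeks" is 84 days and a gap of exactly 30 days
#' falls inside a 30-day window.
#'
#' @param confirmation_days Minimum separation, in days, between the onset
#'   visit of a candidate event and its confirmation visit. Default 84
#'   (12 weeks).
#' @param confirmation_relapse_exclusion_days A visit occurring within this
#'   many days after a relapse onset cannot serve as a confirmation visit.
#'   The same constant drives the relapse re-baseline scheme (the reset visit
#'   must be at least this many days after the relapse onset). Default 30.
#' @param raw_window_days A confirmed worsening whose onset falls within this
#'   many days after a relapse onset is relapse-associated worsening (RAW).
#'   Default 90.
#' @param baseline_scheme `"roving"` (reference reset at the confirmation of
#'   every confirmed worsening or improvement) or `"relapse_rebaseline"`
#'   (roving plus a reset at the first visit 30+ days after each relapse with
#'   a value not below the original baseline).
#' @param pira_definition Default definition used where one is not given
#'   explicitly: one of `"standard1"`, `"standard2"`, `"standard3"`,
#'   `"non_raw"`.
#'
#' @return A list of class `pira_config`.
#' @examples
#' analysis_config()
#' analysis_config(baseline_scheme = "relapse_rebaseline")
#' @export
analysis_config <- function(confirmation_days = 84L,
                            confirmation_relapse_exclusion_days = 30L,
                            raw_window_days = 90L,
                            baseline_scheme = c("roving", "relapse_rebaseline"),
                            pira_definition = c("standard1", "standard2",
                                                "standard3", "non_raw")) {
  baseline_scheme <- match.arg(baseline_scheme)
  pira_definition <- match.arg(pira_definition)
  for (w in c(confirmation_days, confirmation_relapse_exclusion_days,
              raw_window_days)) {
    if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w <= 0) {
      stop("all window lengths must be single positive numbers", call. = FALSE)
    }
  }
  structure(
    list(confirmation_days = as.integer(confirmation_days),
         confirmation_relapse_exclusion_days =
           as.integer(confirmation_relapse_exclusion_days),
         raw_window_days = as.integer(raw_window_days),
         baseline_scheme = baseline_scheme,
         pira_definition = pira_definition),
    class = "pira_config"
  )
}

#' Minimum EDSS worsening required relative to a reference value
#'
#' The confirmed-disability-accrual threshold: an increase of at least 1.0
#' EDSS points if the reference EDSS is 5.5 or lower, and at least 0.5 points
#' if the reference is above 5.5. The same magnitude rule, mirrored, is used
#' for improvement events. The function is a non-increasing step function of
#' the reference value.
#'
#' @param reference_value Numeric vector of reference EDSS values.
#' @return Numeric vector of minimum score changes (1.0 or 0.5).
#' @examples
#' cda_threshold(c(0, 5.5, 6.0))
#' @export
cda_threshold <- function(reference_value) {
  ifelse(reference_value <= 5.5 + 1e-9, 1.0, 0.5)
}

pira_definitions <- c("standard1", "standard2", "standard3", "non_raw")
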