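#' Extract the relapse-independent component (RIC) of EDSS trajectories
#'
#' Removes relapse-associated changes from each trajectory, relapse by
#' relapse in onset order, each computed on the already-adjusted values.
#' For a relapse at day `r` with influence window `config$raw_window_days`
#' (90 days by default):
#' * the pre-relapse level is the adjusted EDSS at the last visit before
#'   `r` (the first visit if the relapse occurs on day 0);
#' * the acute increment is
#'   `delta = max(0, max EDSS over visits in [r, r + 90] - pre)`;
#' * the sustained residual is
#'   `rho = min(delta, max(0, min EDSS over visits after r + 90 - pre))`
#'   (the minimum guards against attributing later relapse-independent
#'   progression to the relapse); with no visit after the window the
#'   residual is taken at the last visit, where it has nothing left to act
#'   on;
#' * visits in `(r, r + 90]` are lowered by
#'   `min(delta, max(0, edss - pre))`, visits after `r + 90` by `rho`.
#'
#' Adjusted values may leave the half-point grid; they are deliberately not
#' re-rounded, since re-rounding would reintroduce relapse artefacts.
#' On a relapse-free trajectory the function is the identity.
#'
#' @param visits Tibble with `patient_id`, `day`, `edss`.
#' @param relapses Tibble with `patient_id`, `onset_day`, or `NULL`.
#' @param config An [analysis_config()].
#' @return Tibble with the same `patient_id`/`day` rows and adjusted `edss`,
#'   sorted by patient and day.
#' @examples
#' visits <- tibble::tibble(patient_id = "p1",
#'                          day = c(0, 84, 112, 196, 280),
#'                          edss = c(2, 2, 3.5, 2, 2))
#' relapses <- tibble::tibble(patient_id = "p1", onset_day = 100)
#' ric_decompose(visits, relapses)
#' @export
ric_decompose <- function(visits, relapses, config = analysis_config()) {
  check_columns(visits, c("patient_id", "day", "edss"), "visits")
  visits <- dplyr::arrange(tibble::as_tibble(visits), .data$patient_id,
                           .data$day)
  if (is.null(relapses) || nrow(relapses) == 0) return(visits)
  rel_split <- split(as.numeric(relapses$onset_day), relapses$patient_id)
  win <- config$raw_window_days
  out <- visits
  for (pid in names(rel_split)) {
    idx <- which(visits$patient_id == pid)
    if (length(idx) == 0) next
    day <- visits$day[idx]
    adj <- visits$edss[idx]
    for (r in sort(rel_split[[pid]])) {
      before <- which(day < r - 1e-9)
      pre <- if (length(before) > 0) adj[max(before)] else adj[1]
      in_win <- which(day >= r - 1e-9 & day <= r + win + 1e-9)
      sub_win <- which(day > r + 1e-9 & day <= r + win + 1e-9)
      post <- which(day > r + win + 1e-9)
      delta <- if (length(in_win) > 0) max(0, max(adj[in_win]) - pre) else 0
      post_vals <- if (length(post) > 0) adj[post] else adj[length(adj)]
      rho <- min(delta, max(0, min(post_vals) - pre))
      if (length(sub_win) > 0) {
        adj[sub_win] <- adj[sub_win] - pmin(delta, pmax(0, adj[sub_win] - pre))
      }
      if (length(post) > 0) adj[post] <- adj[post] - rho
    }
    out$edss[idx] <- adj
  }
  out
}

#' Detect PIRA as confirmed worsening on the relapse-independent component
#'
#' Runs [ric_decompose()] and then [detect_events()] on the adjusted
#' trajectory (roving baseline; thresholds evaluated on the raw adjusted
#' values). Relapse-tainted visits remain ineligible for the confirmation
#' role, exactly as on the observed trajectory. Every confirmed worsening on
#' the residual trajectory is PIRA by construction and is labelled so.
#'
#' @inheritParams ric_decompose
#' @return Event tibble as from [detect_events()], with `classification`
#'   set to `"PIRA"` for worsening rows and `"n/a"` otherwise, and
#'   `raw_subtype = "n/a"`.
#' @export
detect_pira_ric <- function(visits, relapses, config = analysis_config()) {
  adj <- ric_decompose(visits, relapses, config)
  events <- detect_events(adj, relapses, config)
  events$classification <- ifelse(events$kind == "worsening", "PIRA", "n/a")
  events$raw_subtype <- "n/a"
  events
}
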