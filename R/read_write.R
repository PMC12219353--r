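#' Read a trial's visit and relapse tables from CSV
#'
#' Reads long-format visit data (`patient_id,day,edss`) and relapse data
#' (`patient_id,onset_day`) and validates them. Patients with no relapse rows
#' simply have no entries in the relapse table. Validation problems are
#' aggregated and reported together, each naming the offending row.
#'
#' @param visits_csv Path to the visits CSV (columns `patient_id`, `day`,
#'   `edss`).
#' @param relapses_csv Path to the relapses CSV (columns `patient_id`,
#'   `onset_day`). May contain only the header.
#' @return A list of class `pira_trial` with tibbles `visits` and `relapses`,
#'   each sorted by patient and day.
#' @seealso [write_trial()], [validate_trial()]
#' @export
read_trial <- function(visits_csv, relapses_csv) {
  visits <- readr::read_csv(
    visits_csv,
    col_types = readr::cols(patient_id = readr::col_character(),
                            day = readr::col_integer(),
                            edss = readr::col_double())
  )
  relapses <- readr::read_csv(
    relapses_csv,
    col_types = readr::cols(patient_id = readr::col_character(),
                            onset_day = readr::col_integer())
  )
  check_columns(visits, c("patient_id", "day", "edss"), "visits")
  check_columns(relapses, c("patient_id", "onset_day"), "relapses")
  validate_trial(visits, relapses)
  new_pira_trial(visits, relapses)
}

new_pira_trial <- function(visits, relapses) {
  structure(
    list(visits = dplyr::arrange(tibble::as_tibble(visits),
                                 .data$patient_id, .data$day),
         relapses = dplyr::arrange(tibble::as_tibble(relapses),
                                   .data$patient_id, .data$onset_day)),
    class = "pira_trial"
  )
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s table is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Validate visit and relapse tables
#'
#' Checks the structural invariants of the data model: EDSS on the half-point
#' grid within \[0, 10\], non-negative integer days, no duplicate
#' (patient, day) visits, and a day-0 visit for every patient. All problems
#' found are reported in a single error, each with its row number.
#'
#' @param visits Tibble with columns `patient_id`, `day`, `edss`.
#' @param relapses Tibble with columns `patient_id`, `onset_day`.
#' @return Invisibly `TRUE` when valid; otherwise an error is thrown.
#' @export
validate_trial <- function(visits, relapses) {
  check_columns(visits, c("patient_id", "day", "edss"), "visits")
  check_columns(relapses, c("patient_id", "onset_day"), "relapses")
  problems <- character()
  half_point <- abs(visits$edss * 2 - round(visits$edss * 2)) < 1e-9
  bad <- which(!half_point | visits$edss < 0 | visits$edss > 10 |
                 is.na(visits$edss))
  for (i in bad) {
    problems <- c(problems, sprintf(
      "visits row %d: edss = %s is not a half-point score in [0, 10]",
      i, format(visits$edss[i])))
  }
  bad_day <- which(is.na(visits$day) | visits$day < 0 |
                     visits$day != round(visits$day))
  for (i in bad_day) {
    problems <- c(problems, sprintf(
      "visits row %d: day = %s is not a non-negative integer day",
      i, format(visits$day[i])))
  }
  dup <- which(duplicated(visits[, c("patient_id", "day")]))
  for (i in dup) {
    problems <- c(problems, sprintf(
      "visits row %d: duplicate visit for patient %s on day %s",
      i, visits$patient_id[i], format(visits$day[i])))
  }
  first_day <- tapply(visits$day, visits$patient_id, min)
  for (pid in names(first_day)[first_day != 0]) {
    problems <- c(problems, sprintf(
      "patient %s has no visit at day 0", pid))
  }
  bad_rel <- which(is.na(relapses$onset_day) | relapses$onset_day < 0)
  for (i in bad_rel) {
    problems <- c(problems, sprintf(
      "relapses row %d: onset_day must be a non-negative day", i))
  }
  unknown <- which(!relapses$patient_id %in% visits$patient_id)
  for (i in unknown) {
    problems <- c(problems, sprintf(
      "relapses row %d: patient %s has no visits", i,
      relapses$patient_id[i]))
  }
  if (length(problems) > 0) {
    stop(paste0("invalid trial data:\n  ",
                paste(problems, collapse = "\n  ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a trial back to CSV
#'
#' Inverse of [read_trial()]; on valid input `read_trial()` followed by
#' `write_trial()` round-trips the files bit-identically.
#'
#' @param trial A `pira_trial` (or list with `visits` and `relapses`).
#' @param visits_csv,relapses_csv Output paths.
#' @return Invisibly, the trial.
#' @export
write_trial <- function(trial, visits_csv, relapses_csv) {
  readr::write_csv(trial$visits, visits_csv)
  readr::write_csv(trial$relapses, relapses_csv)
  invisible(trial)
}

#' Write a detected-event table to CSV
#'
#' Writes the standard event columns
#' `patient_id,kind,onset_day,reference_day,reference_value,onset_value,`
#' `confirmation_day,classification,raw_subtype`. Columns absent from
#' `events` (e.g. before classification) are filled with `"n/a"`.
#'
#' @param events Event tibble as returned by [detect_events()] or
#'   [classify_events()].
#' @param path Output path.
#' @return Invisibly, the written tibble.
#' @export
write_events <- function(events, path) {
  out <- events
  if (!"classification" %in% names(out)) out$classification <- "n/a"
  if (!"raw_subtype" %in% names(out)) out$raw_subtype <- "n/a"
  out <- dplyr::select(out, "patient_id", "kind", "onset_day",
                       "reference_day", "reference_value", "onset_value",
                       "confirmation_day", "classification", "raw_subtype")
  readr::write_csv(out, path)
  invisible(out)
}

#' @export
print.pira_trial <- function(x, ...) {
  cat(sprintf("<pira_trial: %d patients, %d visits, %d relapses>\n",
              dplyr::n_distinct(x$visits$patient_id), nrow(x$visits),
              nrow(x$relapses)))
  invisible(x)
}
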