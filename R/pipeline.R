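#' Baseline policy used for a given analysis mode
#'
#' In the simulation study the roving baseline advances only after confirmed
#' events (worsening or improvement); re-baselining after every relapse is
#' disabled, because moving the reference on post-randomisation relapses
#' would itself introduce bias. In observational/trial re-analysis mode the
#' configured scheme (possibly `relapse_rebaseline`) is used as-is.
#'
#' @param config An [analysis_config()].
#' @param mode `"simulation"` or `"observational"`.
#' @return An `analysis_config` with the effective `baseline_scheme`.
#' @export
rebaseline_policy <- function(config = analysis_config(),
                              mode = c("simulation", "observational")) {
  mode <- match.arg(mode)
  if (mode == "simulation") config$baseline_scheme <- "roving"
  config
}

# Per-replicate effect estimates for a set of definitions, plus the truth
# computed from the relapse-independent trajectories alone.
analyze_replicate <- function(trial, definitions, config, bps_draws = 5000,
                              bps_seed = 1) {
  followup <- trial$spec$followup_days
  events <- detect_events(trial$visits, trial$relapses, config)
  indep_visits <- tibble::tibble(patient_id = trial$visits$patient_id,
                                 day = trial$visits$day,
                                 edss = trial$visits$edss_independent)
  true_events <- detect_events(indep_visits, NULL, config)
  true_events$classification <- ifelse(true_events$kind == "worsening",
                                       "PIRA", "n/a")
  rows <- list()
  add <- function(definition, measure, value) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      definition = definition, measure = measure, value = value)
  }
  effects_for <- function(ev, definition) {
    rec <- time_to_first_pira(ev, trial$patients, followup)
    hr <- tryCatch(suppressWarnings(estimate_hr(rec)),
                   error = function(e) NULL)
    add(definition, "HR",
        if (!is.null(hr) && !hr$degenerate) hr$point else NA_real_)
    rr <- tryCatch(estimate_rr(tibble::tibble(arm = rec$arm,
                                              pira = rec$event)),
                   error = function(e) NULL)
    add(definition, "RR",
        if (!is.null(rr) && !rr$degenerate) rr$point else NA_real_)
  }
  effects_for(true_events, "truth")
  for (d in definitions) {
    if (d %in% pira_definitions) {
      ev <- classify_events(events, trial$relapses, d, config)
      effects_for(ev, d)
    } else if (d == "ric") {
      effects_for(detect_pira_ric(trial$visits, trial$relapses, config), d)
    } else if (d == "bps") {
      dat <- bps_data(trial, events)
      fit <- fit_bps(dat, n_draws = bps_draws,
                     burnin = max(500, bps_draws %/% 5),
                     seed = bps_seed)
      add("bps", "RR", fit$rr_median)
    } else {
      stop(sprintf("unknown definition: '%s'", d), call. = FALSE)
    }
  }
  dplyr::bind_rows(rows)
}

#' Run the bias-quantification study
#'
#' For each relapse-reduction level: simulate `spec$n_replicates` trial
#' replicates, detect events on the combined (observed) trajectories, apply
#' each requested definition, estimate the treatment effect on PIRA (hazard
#' ratio from time to first PIRA, risk ratio from PIRA proportions; the
#' principal-stratum model reports a risk ratio only), and compare it with
#' the true effect computed from the relapse-independent trajectories alone.
#' Replicate estimates are aggregated as geometric means with bootstrap
#' percentile intervals; bias (aggregated estimate minus aggregated truth)
#' gets a paired bootstrap interval over the same replicates.
#'
#' Event detection uses the simulation-mode baseline policy (roving
#' baseline; see [rebaseline_policy()]). Replicates in which an estimate is
#' degenerate (e.g. no events in an arm) are excluded from that cell with a
#' message; a cell aborts if more than 5% of replicates fail.
#'
#' @param spec A [scenario_spec()]; its `relapse_reduction` is overridden by
#'   each element of `relapse_reductions`.
#' @param relapse_reductions Numeric vector of relapse-reduction levels.
#' @param definitions Subset of `c("standard1", "standard2", "standard3",
#'   "non_raw", "ric", "bps")`.
#' @param config An [analysis_config()].
#' @param n_boot Bootstrap resamples for CIs.
#' @param bps_draws Posterior draws for the principal-stratum model within
#'   the grid.
#' @param progress Print one line per (reduction, replicate) batch.
#' @return Tibble of class `pira_bias_study`: one row per
#'   (relapse_reduction, definition, measure) with `true_point`,
#'   `true_ci_low/high`, `est_point`, `est_ci_low/high`, `bias`,
#'   `bias_ci_low/high`, `n_replicates`.
#' @export
run_study <- function(spec, relapse_reductions = spec$relapse_reduction,
                      definitions = c("standard1", "non_raw", "ric"),
                      config = analysis_config(), n_boot = 2000,
                      bps_draws = 5000, progress = FALSE) {
  config <- rebaseline_policy(config, "simulation")
  out <- list()
  for (red in relapse_reductions) {
    spec_r <- spec
    spec_r$relapse_reduction <- red
    per_rep <- vector("list", spec_r$n_replicates)
    for (r in seq_len(spec_r$n_replicates)) {
      trial <- simulate_trial(spec_r, r)
      est <- analyze_replicate(trial, definitions, config,
                               bps_draws = bps_draws,
                               bps_seed = mix_seed(spec_r$master_seed, r, 77))
      est$replicate <- r
      per_rep[[r]] <- est
      if (progress && r %% 25 == 0) {
        message(sprintf("reduction %.2f: replicate %d/%d", red, r,
                        spec_r$n_replicates))
      }
    }
    est_long <- dplyr::bind_rows(per_rep)
    out[[length(out) + 1]] <- summarise_cell(est_long, red, definitions,
                                             n_boot, spec_r$master_seed)
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("pira_bias_study", class(res))
  res
}

summarise_cell <- function(est_long, red, definitions, n_boot, seed) {
  wide <- tidyr::pivot_wider(est_long, names_from = "definition",
                             values_from = "value")
  rows <- list()
  for (m in unique(est_long$measure)) {
    w <- wide[wide$measure == m, ]
    truth <- w$truth
    for (d in setdiff(definitions, "truth")) {
      if (!d %in% names(w)) next
      est <- w[[d]]
      if (all(is.na(est))) next # definition does not produce this measure
      ok <- is.finite(est) & is.finite(truth) & est > 0 & truth > 0
      if (mean(!ok) > 0.05) {
        stop(sprintf(
          "cell (reduction %.2f, %s, %s): %.0f%% of replicates failed",
          red, d, m, 100 * mean(!ok)), call. = FALSE)
      }
      if (any(!ok)) {
        message(sprintf(
          "cell (reduction %.2f, %s, %s): excluding %d failed replicate(s)",
          red, d, m, sum(!ok)))
      }
      ta <- aggregate_replicates(truth[ok], n_boot,
                                 seed = mix_seed(seed, 101))
      ea <- aggregate_replicates(est[ok], n_boot,
                                 seed = mix_seed(seed, 102))
      ba <- estimate_bias(est[ok], truth[ok], n_boot,
                          seed = mix_seed(seed, 103))
      rows[[length(rows) + 1]] <- tibble::tibble(
        relapse_reduction = red, definition = d, measure = m,
        true_point = ta$point, true_ci_low = ta$ci_low,
        true_ci_high = ta$ci_high,
        est_point = ea$point, est_ci_low = ea$ci_low,
        est_ci_high = ea$ci_high,
        bias = ba$bias, bias_ci_low = ba$ci_low, bias_ci_high = ba$ci_high,
        n_replicates = ba$n_replicates)
    }
  }
  dplyr::bind_rows(rows)
}

#' Write study results to disk
#'
#' Writes `results.csv` and `results.json` (both deterministic for identical
#' inputs) and one bias-curve plot per measure present in the results.
#'
#' @param results A `pira_bias_study` tibble from [run_study()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
report_study <- function(results, out_dir) {
  if (nrow(results) == 0) stop("empty results; nothing to report",
                               call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  csv <- file.path(out_dir, "results.csv")
  readr::write_csv(as.data.frame(results), csv)
  paths <- c(paths, csv)
  js <- file.path(out_dir, "results.json")
  jsonlite::write_json(as.data.frame(results), js, digits = NA,
                       auto_unbox = TRUE)
  paths <- c(paths, js)
  for (m in unique(results$measure)) {
    p <- file.path(out_dir, sprintf("bias_%s.pdf", m))
    ggplot2::ggsave(p, autoplot(results, measure = m), width = 8,
                    height = 6)
    paths <- c(paths, p)
  }
  invisible(paths)
}
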