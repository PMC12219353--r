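#' Time to first PIRA event per patient
#'
#' Builds the survival records used for hazard-ratio estimation: the event
#' time is the onset day of the patient's first PIRA-classified worsening;
#' patients with no PIRA event are censored at the end of follow-up.
#'
#' @param events Event tibble with a `classification` column (rows of any
#'   kind; only `classification == "PIRA"` worsening rows count).
#' @param patients Tibble with `patient_id` and `arm` (`"control"` /
#'   `"treated"`) covering every randomised patient.
#' @param followup_end Censoring day for patients without a PIRA event.
#' @return Tibble `patient_id`, `arm`, `time_days`, `event` (logical).
#' @export
time_to_first_pira <- function(events, patients, followup_end) {
  pira <- events[events$classification == "PIRA" &
                   events$kind == "worsening", ]
  first <- dplyr::summarise(dplyr::group_by(pira, .data$patient_id),
                            time_days = min(.data$onset_day), .groups = "drop")
  out <- dplyr::left_join(tibble::as_tibble(patients), first,
                          by = "patient_id")
  out$event <- !is.na(out$time_days)
  out$time_days[!out$event] <- followup_end
  out[, c("patient_id", "arm", "time_days", "event")]
}

#' Hazard ratio (treated vs control) from time-to-first-event records
#'
#' Cox proportional-hazards fit with arm as the only covariate and the Efron
#' approximation for ties (integer-day event times tie heavily). The 95% CI
#' comes from the normal approximation on the log scale.
#'
#' @param records Tibble from [time_to_first_pira()].
#' @return One-row tibble: `measure = "HR"`, `point`, `ci_low`, `ci_high`,
#'   `log_se`, `n_events`, `degenerate`. When no arm has any event the
#'   estimate is undefined: the row carries `NA`s and `degenerate = TRUE`
#'   with a warning. Monotone-likelihood fits (all events in one arm) are
#'   flagged the same way.
#' @export
estimate_hr <- function(records) {
  if (sum(records$event) == 0) {
    warning("no events in either arm; hazard ratio undefined")
    return(tibble::tibble(measure = "HR", point = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          log_se = NA_real_, n_events = 0L,
                          degenerate = TRUE))
  }
  arm01 <- as.integer(records$arm == "treated")
  degenerate <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(records$time_days, records$event) ~ arm01,
                    ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite", conditionMessage(w))) {
        degenerate <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- unname(fit$coefficients[1])
  se <- sqrt(unname(fit$var[1, 1]))
  tibble::tibble(measure = "HR", point = exp(beta),
                 ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se),
                 log_se = se, n_events = sum(records$event),
                 degenerate = degenerate || !is.finite(beta))
}

#' Risk ratio (treated vs control) of PIRA proportions
#'
#' The point estimate is the ratio of the per-arm proportions of patients
#' with at least one PIRA event; the 95% CI uses the standard log-RR normal
#' approximation.
#'
#' @param data Tibble with `arm` and logical `pira` (one row per patient).
#' @return One-row tibble: `measure = "RR"`, `point`, `ci_low`, `ci_high`,
#'   `n_events`, `degenerate`. A zero control-arm proportion is an error;
#'   a zero treated-arm proportion yields `point = 0` with `NA` CI and
#'   `degenerate = TRUE`.
#' @export
estimate_rr <- function(data) {
  n1 <- sum(data$arm == "treated")
  n0 <- sum(data$arm == "control")
  x1 <- sum(data$pira[data$arm == "treated"])
  x0 <- sum(data$pira[data$arm == "control"])
  if (n0 == 0 || n1 == 0) stop("both arms must be present", call. = FALSE)
  if (x0 == 0) {
    stop("control-arm PIRA proportion is zero; risk ratio undefined",
         call. = FALSE)
  }
  point <- (x1 / n1) / (x0 / n0)
  if (x1 == 0) {
    return(tibble::tibble(measure = "RR", point = 0, ci_low = NA_real_,
                          ci_high = NA_real_, n_events = x0 + x1,
                          degenerate = TRUE))
  }
  se <- sqrt(1 / x1 - 1 / n1 + 1 / x0 - 1 / n0)
  tibble::tibble(measure = "RR", point = point,
                 ci_low = exp(log(point) - 1.96 * se),
                 ci_high = exp(log(point) + 1.96 * se),
                 n_events = x0 + x1, degenerate = FALSE)
}

#' Aggregate per-replicate ratio estimates with a bootstrap CI
#'
#' Ratio measures (HR, RR) are averaged on the log scale (geometric mean);
#' an arithmetic-mean mode is available for sensitivity analyses. The CI is
#' the 2.5/97.5 percentile interval of the bootstrap distribution of the
#' aggregate, resampling replicates with replacement. Non-finite (or, on the
#' log scale, non-positive) replicate estimates are excluded with a message.
#'
#' @param estimates Numeric vector of per-replicate point estimates.
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed Optional integer seed for the bootstrap resampling.
#' @param scale `"log"` (geometric mean, default) or `"natural"`.
#' @return One-row tibble: `point`, `ci_low`, `ci_high`, `n_replicates`.
#' @examples
#' aggregate_replicates(c(0.5, 2.0), seed = 1)$point # geometric mean = 1
#' @export
aggregate_replicates <- function(estimates, n_boot = 2000, seed = NULL,
                                 scale = c("log", "natural")) {
  scale <- match.arg(scale)
  ok <- is.finite(estimates) & (scale == "natural" | estimates > 0)
  if (any(!ok)) {
    message(sprintf("excluding %d non-finite replicate estimate(s)",
                    sum(!ok)))
  }
  x <- estimates[ok]
  if (length(x) < 2) stop("need at least 2 replicate estimates",
                          call. = FALSE)
  agg <- function(v) {
    if (scale == "log") exp(mean(log(v))) else mean(v)
  }
  if (!is.null(seed)) set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    agg(x[sample.int(length(x), replace = TRUE)])
  }, numeric(1))
  tibble::tibble(point = agg(x),
                 ci_low = unname(quantile(boot, 0.025)),
                 ci_high = unname(quantile(boot, 0.975)),
                 n_replicates = length(x))
}

#' Bias of an aggregated estimate relative to the aggregated truth
#'
#' Bias is the difference between the aggregated estimated effect and the
#' aggregated true effect. Because estimated and true effects are computed on
#' the same replicates, the CI uses a *paired* bootstrap: each resample draws
#' replicate indices once and recomputes both aggregates on them.
#'
#' @param estimated,true Numeric vectors of per-replicate estimated and true
#'   effects, aligned by replicate.
#' @param n_boot,seed,scale Passed through as in [aggregate_replicates()].
#' @return One-row tibble: `bias`, `ci_low`, `ci_high`, `n_replicates`.
#' @export
estimate_bias <- function(estimated, true, n_boot = 2000, seed = NULL,
                          scale = c("log", "natural")) {
  scale <- match.arg(scale)
  stopifnot(length(estimated) == length(true))
  ok <- is.finite(estimated) & is.finite(true) &
    (scale == "natural" | (estimated > 0 & true > 0))
  if (any(!ok)) {
    message(sprintf("excluding %d replicate pair(s) with non-finite values",
                    sum(!ok)))
  }
  est <- estimated[ok]
  tru <- true[ok]
  if (length(est) < 2) stop("need at least 2 replicate pairs", call. = FALSE)
  agg <- function(v) if (scale == "log") exp(mean(log(v))) else mean(v)
  if (!is.null(seed)) set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(length(est), replace = TRUE)
    agg(est[idx]) - agg(tru[idx])
  }, numeric(1))
  tibble::tibble(bias = agg(est) - agg(tru),
                 ci_low = unname(quantile(boot, 0.025)),
                 ci_high = unname(quantile(boot, 0.975)),
                 n_replicates = length(est))
}
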