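# Independent reference implementations used to validate the package's
# algorithms, plus small fixture generators. Deliberately written in a
# different style from the package code (pair enumeration instead of a
# single left-to-right scan).

# Brute-force confirmed-event detection under a roving baseline: at each
# step, enumerate all (onset, confirmation) visit pairs against the current
# reference, take the first admissible pair in (onset, confirmation) order,
# reset the reference to the confirmation visit, and continue after it.
oracle_detect <- function(day, edss, rel = numeric(), conf_days = 84,
                          excl_days = 30) {
  thr <- function(ref) if (ref <= 5.5) 1.0 else 0.5
  excluded <- function(d) any(d - rel >= 0 & d - rel <= excl_days)
  n <- length(day)
  ref_day <- day[1]
  ref_val <- edss[1]
  pos <- 1
  out <- list()
  repeat {
    found <- NULL
    for (v in seq_len(n)) {
      if (v <= pos) next
      for (kind in c("worsening", "improvement")) {
        delta <- if (kind == "worsening") edss[v] - ref_val else
          ref_val - edss[v]
        if (delta < thr(ref_val) - 1e-9) next
        for (cc in seq_len(n)) {
          if (cc <= v) next
          if (day[cc] - day[v] < conf_days) next
          if (excluded(day[cc])) next
          span <- (v + 1):cc
          sustain <- if (kind == "worsening") {
            all(edss[span] - ref_val >= thr(ref_val) - 1e-9)
          } else {
            all(ref_val - edss[span] >= thr(ref_val) - 1e-9)
          }
          if (sustain) {
            found <- list(v = v, cc = cc, kind = kind)
            break
          }
        }
        if (!is.null(found)) break
      }
      if (!is.null(found)) break
    }
    if (is.null(found)) break
    out[[length(out) + 1]] <- data.frame(
      kind = found$kind, onset_day = day[found$v],
      onset_value = edss[found$v], reference_day = ref_day,
      reference_value = ref_val, confirmation_day = day[found$cc],
      confirmation_value = edss[found$cc])
    ref_day <- day[found$cc]
    ref_val <- edss[found$cc]
    pos <- found$cc
  }
  if (length(out) == 0) {
    return(data.frame(kind = character(), onset_day = numeric(),
                      onset_value = numeric(), reference_day = numeric(),
                      reference_value = numeric(),
                      confirmation_day = numeric(),
                      confirmation_value = numeric()))
  }
  do.call(rbind, out)
}

# Random short trajectory on the half-point grid, with a handful of relapses.
random_trajectory <- function(max_visits = 10) {
  n <- sample(2:max_visits, 1)
  day <- sort(sample(0:600, n))
  day[1] <- 0
  day <- unique(day)
  edss <- cumsum(c(sample(seq(0, 6, 0.5), 1),
                   sample(seq(-1.5, 1.5, 0.5), length(day) - 1,
                          replace = TRUE)))
  edss <- pmin(10, pmax(0, edss))
  nrel <- sample(0:3, 1)
  rel <- if (nrel > 0) sort(sample(0:600, nrel)) else numeric()
  list(day = day, edss = edss, rel = rel)
}

as_visit_tbl <- function(traj, pid = "p1") {
  tibble::tibble(patient_id = pid, day = traj$day, edss = traj$edss)
}

as_relapse_tbl <- function(traj, pid = "p1") {
  tibble::tibble(patient_id = pid,
                 onset_day = if (length(traj$rel)) traj$rel else numeric())
}

# Efron partial log-likelihood for a single binary covariate, written from
# the definition (event-time by event-time), for the grid-search oracle.
efron_loglik <- function(beta, time, status, x) {
  ll <- 0
  for (t in sort(unique(time[status == 1]))) {
    d_idx <- which(time == t & status == 1)
    r_idx <- which(time >= t)
    d <- length(d_idx)
    sum_x_d <- sum(x[d_idx])
    risk <- sum(exp(beta * x[r_idx]))
    tied <- sum(exp(beta * x[d_idx]))
    ll <- ll + beta * sum_x_d
    for (l in seq_len(d) - 1) {
      ll <- ll - log(risk - l / d * tied)
    }
  }
  ll
}

# Shared full-scale study cells for the acceptance tests, computed once per
# test run. n 800/arm, 200 replicates, Standard1/Non-RAW/RIC where needed.
acceptance_cache <- new.env(parent = emptyenv())

acceptance_cell <- function(scenario = c("A", "B"), reduction,
                            definitions = "standard1",
                            n_replicates = 200L, master_seed = 20260925L) {
  scenario <- match.arg(scenario)
  key <- paste(scenario, reduction, paste(sort(definitions), collapse = "+"),
               n_replicates, sep = "|")
  if (!is.null(acceptance_cache[[key]])) return(acceptance_cache[[key]])
  spec <- scenario_spec(
    n_per_arm = 800L, true_pira_hr = if (scenario == "A") 0.75 else 1.00,
    relapse_reduction = reduction, n_replicates = n_replicates,
    master_seed = master_seed)
  res <- suppressMessages(run_study(spec, relapse_reductions = reduction,
                                    definitions = definitions,
                                    n_boot = 2000))
  acceptance_cache[[key]] <- res
  res
}
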