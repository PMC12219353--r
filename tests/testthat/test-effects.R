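pat_tbl <- function(n, arm = "control", prefix = "p") {
  tibble::tibble(patient_id = sprintf("%s%03d", prefix, seq_len(n)),
                 arm = arm)
}

test_that("time to first PIRA takes the earliest onset and censors the rest", {
  patients <- tibble::tibble(patient_id = c("a", "b", "c"),
                             arm = c("control", "treated", "treated"))
  events <- tibble::tibble(
    patient_id = c("a", "a", "b"), kind = "worsening",
    onset_day = c(252, 84, 100), classification = c("PIRA", "PIRA", "RAW"))
  rec <- time_to_first_pira(events, patients, 672)
  expect_equal(rec$time_days, c(84, 672, 672))
  expect_equal(rec$event, c(TRUE, FALSE, FALSE))
})

test_that("the Cox fit recovers a known exponential rate ratio", {
  set.seed(2026)
  n <- 2000
  t0 <- rexp(n, 1); t1 <- rexp(n, 0.5)
  cens <- 3
  rec <- tibble::tibble(
    patient_id = as.character(1:(2 * n)),
    arm = rep(c("control", "treated"), each = n),
    time_days = pmin(c(t0, t1), cens),
    event = c(t0, t1) < cens)
  hr <- estimate_hr(rec)
  expect_false(hr$degenerate)
  # within 3 standard errors of the design value, and close in absolute terms
  expect_lt(abs(log(hr$point) - log(0.5)), 3 * hr$log_se)
  expect_lt(abs(log(hr$point) - log(0.5)), 0.15)
})

test_that("mirrored arms give HR 1 and swapping labels inverts the estimate", {
  times <- c(10, 20, 30, 40, 200, 300)
  rec <- tibble::tibble(
    patient_id = as.character(1:12),
    arm = rep(c("control", "treated"), each = 6),
    time_days = c(times, times),
    event = rep(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE), 2))
  expect_equal(estimate_hr(rec)$point, 1, tolerance = 1e-8)

  set.seed(5)
  rec2 <- tibble::tibble(
    patient_id = as.character(1:60),
    arm = rep(c("control", "treated"), each = 30),
    time_days = sample(10:500, 60),
    event = runif(60) < 0.7)
  swapped <- rec2
  swapped$arm <- ifelse(rec2$arm == "control", "treated", "control")
  expect_equal(estimate_hr(swapped)$point, 1 / estimate_hr(rec2)$point,
               tolerance = 1e-6)
})

test_that("degenerate Cox cases are flagged", {
  rec <- tibble::tibble(
    patient_id = as.character(1:4),
    arm = c("control", "control", "treated", "treated"),
    time_days = c(10, 20, 400, 400), event = c(TRUE, TRUE, FALSE, FALSE))
  expect_true(estimate_hr(rec)$degenerate)
  none <- tibble::tibble(patient_id = c("a", "b"),
                         arm = c("control", "treated"),
                         time_days = c(100, 100), event = c(FALSE, FALSE))
  expect_warning(out <- estimate_hr(none), "no events")
  expect_true(out$degenerate)
})

test_that("estimate_hr matches a grid search on the Efron partial likelihood", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(8:20, 1)
    rec <- tibble::tibble(
      patient_id = as.character(seq_len(n)),
      arm = sample(c("control", "treated"), n, replace = TRUE),
      time_days = sample(1:15, n, replace = TRUE),
      event = runif(n) < 0.7)
    if (length(unique(rec$arm)) < 2 || sum(rec$event) == 0) next
    hr <- estimate_hr(rec)
    if (hr$degenerate) next
    x <- as.integer(rec$arm == "treated")
    opt <- stats::optimize(function(b) {
      efron_loglik(b, rec$time_days, as.integer(rec$event), x)
    }, c(-8, 8), maximum = TRUE)
    expect_lt(abs(log(hr$point) - opt$maximum), 1e-4)
  }
})

test_that("the risk ratio is the ratio of PIRA proportions with sane edge cases", {
  d <- tibble::tibble(arm = rep(c("treated", "control"), each = 100),
                      pira = c(rep(TRUE, 40), rep(FALSE, 60),
                               rep(TRUE, 50), rep(FALSE, 50)))
  rr <- estimate_rr(d)
  expect_equal(rr$point, 0.8)
  expect_true(rr$ci_low < 0.8 && rr$ci_high > 0.8)

  equal <- tibble::tibble(arm = rep(c("treated", "control"), each = 10),
                          pira = rep(c(TRUE, FALSE), 10))
  expect_equal(estimate_rr(equal)$point, 1)

  zero_treated <- tibble::tibble(arm = rep(c("treated", "control"), each = 10),
                                 pira = rep(c(FALSE, TRUE), each = 10))
  out <- estimate_rr(zero_treated)
  expect_equal(out$point, 0)
  expect_true(out$degenerate)

  zero_control <- tibble::tibble(arm = rep(c("treated", "control"), each = 10),
                                 pira = rep(c(TRUE, FALSE), each = 10))
  expect_error(estimate_rr(zero_control), "control")
})

test_that("replicate aggregation is a geometric mean with a percentile bootstrap", {
  const <- aggregate_replicates(rep(0.75, 20), n_boot = 200, seed = 1)
  expect_equal(const$point, 0.75)
  expect_equal(const$ci_low, 0.75)
  expect_equal(const$ci_high, 0.75)

  two <- aggregate_replicates(c(0.5, 2.0), n_boot = 100, seed = 1)
  expect_equal(two$point, 1.0)

  set.seed(77)
  x <- exp(rnorm(200, log(0.75), 0.1))
  agg <- aggregate_replicates(x, n_boot = 1000, seed = 2)
  mc_se <- 0.1 / sqrt(200)
  expect_lt(abs(log(agg$point) - log(0.75)), 2 * mc_se * 1.5)

  expect_message(
    aggregate_replicates(c(0.5, 1, NA, -1), n_boot = 50, seed = 1),
    "excluding 2")
})

test_that("bias is antisymmetric and its paired CI is computed on shared resamples", {
  est <- c(0.9, 1.0, 1.1, 0.95)
  tru <- c(0.7, 0.8, 0.75, 0.72)
  b1 <- estimate_bias(est, tru, n_boot = 500, seed = 3)
  b2 <- estimate_bias(tru, est, n_boot = 500, seed = 3)
  expect_equal(b1$bias, -b2$bias)
  # strongly correlated pairs: the paired CI must be narrower than the sum
  # of the marginal CI widths
  set.seed(4)
  shared <- exp(rnorm(100, 0, 0.2))
  est2 <- shared * exp(rnorm(100, log(1.1), 0.02))
  tru2 <- shared
  pb <- estimate_bias(est2, tru2, n_boot = 1000, seed = 5)
  ae <- aggregate_replicates(est2, n_boot = 1000, seed = 6)
  at <- aggregate_replicates(tru2, n_boot = 1000, seed = 7)
  expect_lt(pb$ci_high - pb$ci_low,
            (ae$ci_high - ae$ci_low) + (at$ci_high - at$ci_low))
})
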