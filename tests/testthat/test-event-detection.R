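test_that("a sustained 1-point increase is confirmed at the first visit 84+ days later", {
  v <- tibble::tibble(patient_id = "p1", day = c(0, 84, 168, 252),
                      edss = c(2, 3, 3, 3))
  ev <- detect_events(v)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "worsening")
  expect_equal(ev$onset_day, 84)
  expect_equal(ev$reference_day, 0)
  expect_equal(ev$reference_value, 2)
  expect_equal(ev$confirmation_day, 168)
})

test_that("a flat trajectory produces no events", {
  v <- tibble::tibble(patient_id = "p1", day = seq(0, 336, 84),
                      edss = rep(2, 5))
  expect_equal(nrow(detect_events(v)), 0)
})

test_that("a relapse-tainted confirmation visit is skipped; no later visit means no event", {
  v <- tibble::tibble(patient_id = "p1", day = c(0, 84, 168),
                      edss = c(2, 3, 3))
  r <- tibble::tibble(patient_id = "p1", onset_day = 150)
  expect_equal(nrow(detect_events(v, r)), 0)
  # with a later clean visit the event is confirmed there instead
  v2 <- tibble::tibble(patient_id = "p1", day = c(0, 84, 168, 252),
                       edss = c(2, 3, 3, 3))
  ev <- detect_events(v2, r)
  expect_equal(ev$confirmation_day, 252)
  expect_equal(ev$onset_day, 84)
})

test_that("a relapse onset on the visit day itself taints the visit (closed window)", {
  v <- tibble::tibble(patient_id = "p1", day = c(0, 84, 168),
                      edss = c(2, 3, 3))
  r <- tibble::tibble(patient_id = "p1", onset_day = 168)
  expect_equal(nrow(detect_events(v, r)), 0)
  r31 <- tibble::tibble(patient_id = "p1", onset_day = 137)
  expect_equal(nrow(detect_events(v, r31)), 1) # gap 31 > 30: eligible
})

test_that("intermediate visits must sustain the change", {
  v <- tibble::tibble(patient_id = "p1", day = c(0, 56, 84, 168),
                      edss = c(2, 3, 2.5, 3))
  # candidate at 56 dies at 84 (2.5 < 3); candidate at 168 has no later visit
  expect_equal(nrow(detect_events(v)), 0)
})

test_that("the roving baseline resets at the confirmation visit", {
  v <- tibble::tibble(patient_id = "p1",
                      day = c(0, 84, 168, 252, 336, 420),
                      edss = c(2, 3, 3, 4, 4, 4))
  ev <- detect_events(v)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$reference_value, c(2, 3))
  expect_equal(ev$reference_day, c(0, 168))
  st <- apply_roving_baseline(list(), ev[1, ])
  expect_equal(st$reference_day, 168)
  expect_equal(st$reference_value, 3)
})

test_that("confirmed improvements reset the baseline symmetrically", {
  v <- tibble::tibble(patient_id = "p1",
                      day = c(0, 84, 168, 252, 336),
                      edss = c(3, 1.5, 1.5, 2.5, 2.5))
  ev <- detect_events(v)
  expect_equal(ev$kind, c("improvement", "worsening"))
  expect_equal(ev$reference_value, c(3, 1.5))
})

test_that("relapse re-baseline resets to the first qualifying visit", {
  visits <- tibble::tibble(day = c(0, 110, 140), edss = c(2, 3, 2.5))
  st <- apply_relapse_rebaseline(visits,
                                 list(reference_day = 0,
                                      reference_value = 2), 100)
  expect_equal(st$reference_day, 140)
  expect_equal(st$reference_value, 2.5)
  # relapse at the very end: no qualifying visit, state unchanged
  st2 <- apply_relapse_rebaseline(visits,
                                  list(reference_day = 0,
                                       reference_value = 2), 140)
  expect_equal(st2$reference_day, 0)
  # all post-relapse visits below the original baseline: unchanged
  low <- tibble::tibble(day = c(0, 140, 200), edss = c(2, 1.5, 1.0))
  st3 <- apply_relapse_rebaseline(low,
                                  list(reference_day = 0,
                                       reference_value = 2), 100)
  expect_equal(st3$reference_value, 2)
})

test_that("the relapse_rebaseline scheme suppresses relapse-driven pseudo-worsening", {
  # relapse bump at day 100 settles at 3.0; under a pure roving baseline the
  # jump from 2.0 is a confirmed worsening, under relapse re-baseline the
  # reference moves to (140, 3.0) and no event remains
  v <- tibble::tibble(patient_id = "p1", day = c(0, 84, 140, 224, 308),
                      edss = c(2, 2, 3, 3, 3))
  r <- tibble::tibble(patient_id = "p1", onset_day = 100)
  roving <- detect_events(v, r, analysis_config())
  reb <- detect_events(v, r,
                       analysis_config(baseline_scheme = "relapse_rebaseline"))
  expect_equal(nrow(roving), 1)
  expect_equal(nrow(reb), 0)
})

test_that("detection is deterministic and confirmation separation always holds", {
  set.seed(41)
  for (i in 1:50) {
    tr <- random_trajectory()
    ev1 <- detect_events(as_visit_tbl(tr), as_relapse_tbl(tr))
    ev2 <- detect_events(as_visit_tbl(tr), as_relapse_tbl(tr))
    expect_identical(ev1, ev2)
    if (nrow(ev1) > 0) {
      expect_true(all(ev1$confirmation_day - ev1$onset_day >= 84))
    }
  }
})

test_that("detection matches the brute-force pair-enumeration oracle", {
  set.seed(42)
  n_checked <- 0
  for (i in 1:400) {
    tr <- random_trajectory()
    got <- detect_events(as_visit_tbl(tr), as_relapse_tbl(tr))
    want <- oracle_detect(tr$day, tr$edss, tr$rel)
    expect_equal(nrow(got), nrow(want),
                 info = sprintf("case %d: event counts differ", i))
    if (nrow(want) > 0) {
      expect_equal(got$onset_day, want$onset_day, info = paste("case", i))
      expect_equal(got$confirmation_day, want$confirmation_day,
                   info = paste("case", i))
      expect_equal(got$kind, want$kind, info = paste("case", i))
      expect_equal(got$reference_value, want$reference_value,
                   info = paste("case", i))
      n_checked <- n_checked + nrow(want)
    }
  }
  expect_gt(n_checked, 50) # the generator must actually exercise events
})

test_that("deleting a relapse whose only role is confirmation exclusion never removes events", {
  set.seed(43)
  for (i in 1:200) {
    tr <- random_trajectory()
    if (length(tr$rel) == 0) next
    with_rel <- detect_events(as_visit_tbl(tr), as_relapse_tbl(tr))
    without <- detect_events(as_visit_tbl(tr), NULL)
    expect_gte(nrow(without), nrow(with_rel))
  }
})
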