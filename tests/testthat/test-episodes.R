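test_that("candidate events cover the consecutive-rise, flanking and admission cases", {
  # admission event: SOFA 5 on day 0 against the virtual zero baseline
  ser <- series_from_totals("a1", c(`-1` = 0, `0` = 5, `1` = 5))
  ev <- detect_candidate_events(ser, escalation_days = 0L)
  expect_true(any(ev$onset_day == 0 & ev$baseline_sofa == 0))
  # rise on days 2 -> 3 with escalation on day 3 (consecutive-rise rule)
  ser2 <- series_from_totals("a1", c(`-1` = 0, `0` = 1, `1` = 2, `2` = 3,
                                     `3` = 6, `4` = 6))
  ev2 <- detect_candidate_events(ser2, escalation_days = 3L)
  expect_equal(ev2$rule, c("A_consecutive_rise", "B_flanking_rise"))
  expect_equal(ev2$onset_day, c(2L, 2L))
  expect_equal(ev2$baseline_sofa, c(3L, 3L))
  # flanking rule: escalation day 4, SOFA d3 = 4 and d5 = 7, middle irrelevant
  ser3 <- series_from_totals("a1", c(`-1` = 0, `0` = 3, `1` = 3, `2` = 3,
                                     `3` = 4, `4` = 2, `5` = 7, `6` = 7))
  ev3 <- detect_candidate_events(ser3, escalation_days = 4L)
  ruleB <- ev3[ev3$rule == "B_flanking_rise", ]
  expect_equal(ruleB$onset_day, 3L)
  expect_equal(ruleB$baseline_sofa, 4L)
  # the virtual day can never carry the escalation itself
  ser4 <- series_from_totals("a1", c(`-1` = 0, `0` = 5, `1` = 5))
  expect_equal(nrow(detect_candidate_events(ser4, integer(0))), 0)
  # a flexible-window rise needs no recorded escalation and is labelled C
  ev5 <- detect_candidate_events(ser2, integer(0), flexible_days = 1:4)
  expect_equal(ev5$rule[ev5$onset_day == 2], "C_sdd_flexible")
})

test_that("deduplication keeps onsets strictly more than 72 h apart and caps at day 15", {
  mk <- function(onsets) data.frame(
    admission_id = "a1", rule = "A_consecutive_rise",
    evidence_lo = onsets, evidence_hi = onsets + 1L,
    onset_day = onsets, baseline_sofa = 0L, escalation_day = onsets,
    stringsAsFactors = FALSE)
  expect_equal(deduplicate_and_cap(mk(c(0L, 2L)))$onset_day, 0L)
  expect_equal(deduplicate_and_cap(mk(c(0L, 4L)))$onset_day, c(0L, 4L))
  # exactly 72 h is not "more than 72 h"
  expect_equal(deduplicate_and_cap(mk(c(0L, 3L)))$onset_day, 0L)
  expect_equal(deduplicate_and_cap(mk(c(0L, 16L)))$onset_day, 0L)
  expect_equal(deduplicate_and_cap(mk(c(14L, 15L)))$onset_day, 14L)
})

test_that("septic shock needs a vasopressor plus lactate strictly above 2 in the evidence window", {
  adm <- adm_row("a1", stay_days = 3)
  ep <- data.frame(admission_id = "a1", evidence_lo = -1L, evidence_hi = 0L,
                   onset_day = 0L, baseline_sofa = 0L)
  nor <- drow("a1", "noradrenaline", class = "vasopressor", day = 0,
              dur_h = 12, rate = 0.2)
  lac <- function(v, day = 0) mrow("a1", "lactate_mmol_L", v, day)
  expect_true(classify_septic_shock(ep, nor, lac(2.5), adm))
  expect_false(classify_septic_shock(ep, nor, lac(2.0), adm))   # boundary
  expect_false(classify_septic_shock(ep, empty_drugs(), lac(5), adm))
  # lactate outside the evidence window does not count
  expect_false(classify_septic_shock(ep, nor, lac(5, day = 2), adm))
})

test_that("episode state persists while SOFA exceeds baseline on antibiotics", {
  adm <- adm_row("a1", stay_days = 6)
  meas <- do.call(rbind, mapply(function(d, t) sofa_meas_for_total("a1", d, t),
                                0:5, c(3, 6, 5, 5, 3, 3), SIMPLIFY = FALSE))
  drg <- do.call(rbind, lapply(1:4, function(d) drow("a1", "ceftriaxone",
                                                     day = d)))
  res <- detect_sepsis_episodes(adm, meas, drg, empty_cult())
  expect_equal(nrow(res$episodes), 1)
  ep <- res$episodes[1, ]
  expect_equal(ep$onset_day, 0L)
  expect_equal(ep$baseline_sofa, 3L)
  # days 1-3 are above baseline 3 on antibiotics; day 4 drops to baseline
  expect_equal(ep$end_day, 4L)
  st <- res$states[[1]]
  expect_equal(st$sepsis_active, c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  # an admission episode with virtual baseline 0 persists while SOFA > 0
  meas2 <- do.call(rbind, mapply(function(d, t) sofa_meas_for_total("a2", d, t),
                                 0:5, c(4, 2, 1, 0, 0, 0), SIMPLIFY = FALSE))
  adm2 <- adm_row("a2", stay_days = 6)
  drg2 <- do.call(rbind, lapply(0:5, function(d) drow("a2", "ceftriaxone",
                                                      day = d)))
  res2 <- detect_sepsis_episodes(adm2, meas2, drg2, empty_cult())
  ep2 <- res2$episodes[1, ]
  expect_equal(ep2$baseline_sofa, 0L)
  expect_equal(ep2$end_day, 3L)  # first day at SOFA 0 despite antibiotics
})

test_that("episode onsets match the brute-force enumerator on random series", {
  set.seed(47)
  cfg <- cohort_config()
  for (rep in 1:60) {
    stay <- sample(3:20, 1)
    totals <- c(0L, sample(0:14, stay, replace = TRUE))
    names(totals) <- as.character(-1:(stay - 1))
    esc <- sort(sample(0:(stay - 1), sample(0:3, 1)))
    flex <- if (stats::runif(1) < 0.3) 1:4 else integer(0)
    ser <- series_from_totals("r1", totals)
    got <- deduplicate_and_cap(
      detect_candidate_events(ser, esc, flex, cfg), cfg)$onset_day
    expect_equal(got, oracle_episode_onsets(totals, esc, flex))
  }
})
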