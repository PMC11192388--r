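test_that("component scorers apply the threshold table, with the ventilation cap", {
  expect_equal(score_respiration(450, FALSE), 0L)
  expect_equal(score_respiration(150, TRUE), 3L)
  expect_equal(score_respiration(150, FALSE), 2L)  # capped without ventilation
  expect_equal(score_respiration(80, TRUE), 4L)
  expect_true(is.na(score_respiration(NA)))

  expect_equal(score_coagulation(160), 0L)
  expect_equal(score_coagulation(19), 4L)
  expect_equal(score_cns(15), 0L)
  expect_equal(score_liver(32.5), 1L)   # between the score-1 and score-2 bounds
  expect_equal(score_liver(204.5), 4L)  # strictly above the score-4 bound
  expect_equal(score_renal(90, 150), 4L)  # urine branch dominates creatinine
  expect_equal(score_renal(440, NA), 3L)
  expect_true(is.na(score_renal(NA, NA)))
})

test_that("cardiovascular scoring takes the highest branch and honours the noradrenaline-duration rule", {
  vp <- function(drug, rate, hours) data.frame(
    drug_name = drug, rate_ug_kg_min = rate, hours = hours)
  expect_equal(as.integer(score_cardiovascular(80, NULL)), 0L)
  expect_equal(as.integer(score_cardiovascular(60,
    vp("noradrenaline", 0.2, 12))), 4L)
  # 6 h rule strips the short infusion, leaving the MAP branch
  expect_equal(as.integer(score_cardiovascular(60,
    vp("noradrenaline", 0.2, 3), norad_6h_rule = TRUE)), 1L)
  # the rule is inert for infusions longer than 6 h
  expect_equal(as.integer(score_cardiovascular(60,
    vp("noradrenaline", 0.2, 12), norad_6h_rule = TRUE)), 4L)
  expect_equal(as.integer(score_cardiovascular(80, vp("dopamine", 8, 10))), 3L)
  expect_equal(as.integer(score_cardiovascular(80, vp("dopamine", 16, 10))), 4L)
  expect_equal(as.integer(score_cardiovascular(80, vp("dobutamine", NA, 10))), 2L)
  # missing rate scores at the minimum qualifying level and is flagged
  s <- score_cardiovascular(80, vp("noradrenaline", NA, 10))
  expect_equal(as.integer(s), 3L)
  expect_true(attr(s, "rate_imputed"))
  # vasopressin is not scored by the standard table
  expect_equal(as.integer(score_cardiovascular(80, vp("vasopressin", 0.03, 10))), 0L)
  expect_true(is.na(score_cardiovascular(NA, NULL)))
})

test_that("daily scoring uses the worst value in each 24 h window", {
  adm <- adm_row("a1", stay_days = 2)
  meas <- rbind(mrow("a1", "platelets_10e9_L", 120, hour = 3),
                mrow("a1", "platelets_10e9_L", 40, hour = 20))
  row <- compute_daily_sofa(adm, meas, empty_drugs(), 0)
  expect_equal(row$coag, 3L)
  # no measurements at all: all components missing, total 0
  row2 <- compute_daily_sofa(adm, empty_meas(), empty_drugs(), 1)
  expect_equal(row2$n_missing, 6L)
  expect_equal(row2$total, 0)
  # all six present: total is the sum
  meas3 <- rbind(mrow("a1", "platelets_10e9_L", 70),   # 2
                 mrow("a1", "bilirubin_umol_L", 60),   # 2
                 mrow("a1", "creatinine_umol_L", 250), # 2
                 mrow("a1", "gcs_total", 11),          # 2
                 mrow("a1", "map_mmHg", 62),           # 1
                 mrow("a1", "fio2_fraction", 0.4),
                 mrow("a1", "pao2_mmHg", 100))         # PF 250 -> 2
  row3 <- compute_daily_sofa(adm, meas3, empty_drugs(), 0)
  expect_equal(row3$n_missing, 0L)
  expect_equal(row3$total, 11)
})

test_that("a measurement at a window boundary lands in exactly one day", {
  adm <- adm_row("a1", stay_days = 3)
  m <- mrow("a1", "platelets_10e9_L", 40, day = 1, hour = 0)  # exactly 24 h
  expect_true(is.na(compute_daily_sofa(adm, m, empty_drugs(), 0)$coag))
  expect_equal(compute_daily_sofa(adm, m, empty_drugs(), 1)$coag, 3L)
  expect_equal(day_index(c(DAY - 1, DAY, 2 * DAY - 1)), c(0L, 1L, 1L))
})

test_that("the series prepends a virtual zero day and imputes incomputable death days to 24", {
  adm <- adm_row("a1", stay_days = 4, died = TRUE)  # dies on day 3
  meas <- do.call(rbind, lapply(0:2, function(d)
    sofa_meas_for_total("a1", d, 3)))               # nothing on day 3
  ser <- sofa_series(adm, meas, empty_drugs())
  expect_equal(ser$day, -1:3)
  expect_true(ser$virtual[1])
  expect_equal(ser$total[1], 0)
  dd <- ser[ser$day == 3, ]
  expect_equal(dd$total, 24)
  expect_true(dd$death_day_imputed)
  # alive days with partial missingness just sum the present components
  adm2 <- adm_row("a2", stay_days = 2)
  meas2 <- rbind(mrow("a2", "platelets_10e9_L", 70),
                 mrow("a2", "bilirubin_umol_L", 60))
  ser2 <- sofa_series(adm2, meas2, empty_drugs())
  expect_equal(ser2$total[ser2$day == 0], 4)
  expect_false(any(ser2$death_day_imputed))
  # a partially computable death day is not imputed under the default mode
  adm3 <- adm_row("a3", stay_days = 2, died = TRUE)
  meas3 <- rbind(sofa_meas_for_total("a3", 0, 2),
                 mrow("a3", "platelets_10e9_L", 70, day = 1))
  ser3 <- sofa_series(adm3, meas3, empty_drugs())
  expect_equal(ser3$total[ser3$day == 1], 2)
  expect_false(any(ser3$death_day_imputed))
  # ... but is under the any_missing mode
  cfg <- cohort_config(death_day_impute = "any_missing")
  ser4 <- sofa_series(adm3, meas3, empty_drugs(), cfg)
  expect_equal(ser4$total[ser4$day == 1], 24)
})

test_that("component scores are monotone as physiology worsens", {
  set.seed(2024)
  for (i in 1:200) {
    p <- sort(stats::runif(2, 1, 400))   # platelets: lower is worse
    expect_gte(score_coagulation(p[1]), score_coagulation(p[2]))
    b <- sort(stats::runif(2, 1, 400))   # bilirubin: higher is worse
    expect_gte(score_liver(b[2]), score_liver(b[1]))
    cr <- sort(stats::runif(2, 20, 600))
    expect_gte(score_renal(cr[2]), score_renal(cr[1]))
    g <- sort(sample(3:15, 2, replace = TRUE))
    expect_gte(score_cns(g[1]), score_cns(g[2]))
    pf <- sort(stats::runif(2, 40, 500))
    for (v in c(TRUE, FALSE))
      expect_gte(score_respiration(pf[1], v), score_respiration(pf[2], v))
  }
})

test_that("daily scoring agrees with a literal brute-force oracle on random data", {
  set.seed(99)
  vars <- c("platelets_10e9_L", "bilirubin_umol_L", "creatinine_umol_L",
            "gcs_total", "map_mmHg", "pao2_mmHg", "fio2_fraction",
            "urine_mL", "ventilated", "lactate_mmol_L")
  for (rep in 1:40) {
    stay <- sample(2:6, 1)
    adm <- adm_row("r1", stay_days = stay)
    n <- sample(5:60, 1)
    var <- sample(vars, n, replace = TRUE)
    value <- vapply(var, function(v) switch(v,
      platelets_10e9_L = stats::runif(1, 5, 350),
      bilirubin_umol_L = stats::runif(1, 2, 300),
      creatinine_umol_L = stats::runif(1, 30, 600),
      gcs_total = sample(3:15, 1),
      map_mmHg = stats::runif(1, 30, 110),
      pao2_mmHg = stats::runif(1, 40, 150),
      fio2_fraction = stats::runif(1, 0.21, 1),
      urine_mL = stats::runif(1, 0, 1500),
      ventilated = sample(0:1, 1),
      lactate_mmol_L = stats::runif(1, 0.5, 6)), 1)
    meas <- data.frame(admission_id = "r1", variable = var, value = value,
                       time = stats::runif(n, 0, stay * DAY))
    drugs <- if (stats::runif(1) < 0.5) drow("r1", "noradrenaline",
      class = "vasopressor", day = sample(0:(stay - 1), 1),
      dur_h = stats::runif(1, 0.5, 30), rate = stats::runif(1, 0.02, 0.4))
      else empty_drugs()
    for (d in 0:(stay - 1)) {
      got <- compute_daily_sofa(adm, meas, drugs, d)
      exp <- oracle_daily_sofa(meas, drugs, d)
      expect_equal(unlist(got[1, c("resp", "coag", "liver", "cardio",
                                   "cns", "renal")], use.names = FALSE),
                   unname(exp$components))
      expect_equal(got$total, exp$total)
      expect_equal(got$n_missing, exp$n_missing)
    }
  }
})
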