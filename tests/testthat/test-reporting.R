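test_that("group assignment keys on admission-onset episodes", {
  reg_on <- data.frame(day = 0:3, n_drugs = c(1L, 1L, 0L, 0L))
  reg_off <- data.frame(day = 0:3, n_drugs = 0L)
  ep0 <- data.frame(onset_day = 0L, shock = TRUE)
  expect_equal(assign_admission_group(ep0, reg_on), "septic_shock")
  ep0$shock <- FALSE
  expect_equal(assign_admission_group(ep0, reg_on), "sepsis_without_shock")
  # a later-onset episode keys the admission as antibiotics-without-sepsis
  ep6 <- data.frame(onset_day = 6L, shock = FALSE)
  expect_equal(assign_admission_group(ep6, reg_on), "antibiotics_without_sepsis")
  none <- ep0[0, , drop = FALSE]
  expect_equal(assign_admission_group(none, reg_on), "antibiotics_without_sepsis")
  expect_equal(assign_admission_group(none, reg_off), "not_on_antibiotics")
})

test_that("antibiotic-duration classes partition admission-sepsis stays", {
  mk_reg <- function(iv_days, stay) data.frame(
    day = 0:(stay - 1),
    n_drugs = as.integer(0:(stay - 1) %in% iv_days),
    has_iv = 0:(stay - 1) %in% iv_days)
  # IV antibiotics on days 0-5, stay of 10 days
  expect_equal(classify_antibiotic_duration(adm_row("a", stay_days = 10),
                                            mk_reg(0:5, 10)), "ge4d_or_death")
  # antibiotics to discharge with a stay under 4 days
  expect_equal(classify_antibiotic_duration(adm_row("a", stay_days = 2),
                                            mk_reg(0:1, 2)),
               "until_discharge_lt4d")
  # stopped after 3 days despite a 9-day stay
  expect_equal(classify_antibiotic_duration(adm_row("a", stay_days = 9),
                                            mk_reg(0:2, 9)), "lt4d_los_ge4d")
  # short course but continuing until ICU death
  expect_equal(classify_antibiotic_duration(
    adm_row("a", stay_days = 3, died = TRUE), mk_reg(0:2, 3)),
    "ge4d_or_death")
})

test_that("the percentage formatter reproduces printed cohort-table ratios", {
  expect_equal(format_pct(4272, 9083), "47.0")
  expect_equal(format_pct(3696, 13650), "27.1")
  expect_equal(format_pct(4911, 6312), "77.8")
  expect_equal(round_half_up(0.25, 1), 0.3)   # halves go up, not to even
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_true(is.na(pct_value(0, 0)))
})

test_that("antibiotic courses are maximal runs of consecutive days", {
  adm <- adm_row("a1", stay_days = 8)
  mk_ph <- function(days) {
    drg <- do.call(rbind, lapply(days, function(d)
      drow("a1", "ceftriaxone", day = d)))
    meas <- sofa_meas_for_total("a1", 0, 0)
    phenotype_cohort(make_tables(adm, drugs = drg, measurements = meas))
  }
  u1 <- usage_table(mk_ph(0:2))
  expect_equal(u1$n_courses, 1L)
  expect_equal(u1$antibiotic_days, 3L)
  u2 <- usage_table(mk_ph(c(0, 1, 4, 5)))
  expect_equal(u2$n_courses, 2L)
  expect_equal(u2$antibiotic_days, 4L)
  expect_equal(u2$pct_courses, 100)
  # prophylactic administrations never reach the usage table
  drg <- rbind(drow("a1", "cefazoline", day = 1),
               drow("a1", "ceftriaxone", day = 1))
  ph <- phenotype_cohort(make_tables(adm, drugs = drg,
                                     measurements = sofa_meas_for_total("a1", 0, 0)))
  expect_equal(usage_table(ph)$drug_name, "ceftriaxone")
})

test_that("stratum summaries partition the cohort and keep counts consistent", {
  co <- generate_cohort(120, seed = 88)
  ph <- phenotype_cohort(validate_cohort_tables(co$tables))
  s <- summarize_strata(ph)
  n_by_group <- s$counts$n[s$counts$metric == "n_admissions"]
  names(n_by_group) <- s$counts$group[s$counts$metric == "n_admissions"]
  expect_equal(unname(n_by_group["overall"]),
               sum(n_by_group[names(n_by_group) != "overall"]))
  expect_equal(unname(n_by_group["overall"]), nrow(ph$admissions))
  # each categorical row sums to its column's n
  for (g in names(n_by_group)) {
    sub <- s$counts[s$counts$group == g, ]
    expect_equal(sum(sub$n[sub$metric == "age_band"]),
                 unname(n_by_group[g]), info = g)
    expect_equal(sum(sub$n[sub$metric == "admission_category"]),
                 unname(n_by_group[g]), info = g)
  }
  # a single-admission group gives a degenerate IQR
  one <- ph
  keep <- ph$groups$admission_id[ph$groups$group == "septic_shock"][1]
  one$covariates <- ph$covariates[ph$covariates$admission_id == keep, ]
  one$admissions <- ph$admissions[ph$admissions$admission_id == keep, ]
  one$groups <- ph$groups[ph$groups$admission_id == keep, ]
  s1 <- summarize_strata(one)
  q <- s1$physiology[s1$physiology$group == "septic_shock" &
                       s1$physiology$metric == "min_map", ]
  expect_equal(q$median, q$q1)
  expect_equal(q$median, q$q3)
})

test_that("SOFA trajectories align on onset and censor at discharge", {
  adm <- adm_row("a1", stay_days = 4)
  meas <- do.call(rbind, mapply(function(d, t) sofa_meas_for_total("a1", d, t),
                                0:3, c(1, 4, 4, 4), SIMPLIFY = FALSE))
  drg <- drow("a1", "ceftriaxone", day = 1)
  ph <- phenotype_cohort(make_tables(adm, drugs = drg, measurements = meas))
  expect_equal(ph$episodes$onset_day, 0L)
  tr <- sofa_trajectories(ph, "onset")
  # a 4-day stay with onset day 0 contributes offsets 0..3 only
  expect_equal(sort(unique(tr$rel_day)), 0:3)
  # components never measured appear as missing
  expect_true(any(tr$score == "missing" & tr$component == "resp"))
  coag0 <- tr[tr$rel_day == 0 & tr$component == "coag", ]
  expect_equal(coag0$score, "1")
  expect_equal(coag0$n, 1L)
})
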