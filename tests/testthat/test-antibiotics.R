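test_that("the rank table resolves the spectrum classes and rejects unknowns helpfully", {
  expect_equal(rank_of("Meropenem"), 4L)
  expect_equal(rank_of("Ceftriaxone"), 2L)
  expect_equal(rank_of("Metronidazole"), 1L)
  expect_equal(rank_of("vancomycin"), 3L)
  expect_error(rank_of("ceftriaxon"), "unknown antibiotic.*ceftriaxone")
  # the shipped CSV mirrors the built-in table
  csv <- antibiotic_rank_table(system.file("extdata", "antibiotic_ranks.csv",
                                           package = "icusepsis"))
  expect_equal(csv, antibiotic_rank_table())
})

test_that("the shipped YAML thresholds mirror the built-in defaults", {
  yml <- read_sofa_thresholds(system.file("extdata", "sofa_thresholds.yaml",
                                          package = "icusepsis"))
  def <- sofa_thresholds()
  for (comp in names(def)) expect_equal(yml[[comp]], def[[comp]],
                                        ignore_attr = TRUE)
})

test_that("prophylaxis rules strip exactly the prescribed administrations", {
  # SDD cefotaxime in the first four days
  adm <- adm_row("a1", stay_days = 8)
  px <- filter_prophylaxis(drow("a1", "cefotaxime", day = 2), adm)
  expect_equal(nrow(px$treatment), 0)
  expect_equal(px$removed$prophylaxis_rule, "sdd_cefotaxime")
  expect_false(px$extended_cefotaxime)
  # cefotaxime on day 4+ is treatment and flags the extended course
  drg <- do.call(rbind, lapply(0:6, function(d) drow("a1", "cefotaxime", day = d)))
  px2 <- filter_prophylaxis(drg, adm)
  expect_true(px2$extended_cefotaxime)
  expect_equal(day_index(px2$treatment$start_time), 4:6)
  # vancomycin any day after cardiac surgery
  cardiac <- adm_row("a2", cardiac = TRUE, stay_days = 8)
  px3 <- filter_prophylaxis(drow("a2", "vancomycin", day = 5), cardiac)
  expect_equal(nrow(px3$treatment), 0)
  # ... but kept without cardiac surgery
  px4 <- filter_prophylaxis(drow("a1", "vancomycin", day = 5), adm)
  expect_equal(nrow(px4$treatment), 1)
  # ceftriaxone on day 0 of an emergency medical admission is kept
  px5 <- filter_prophylaxis(drow("a1", "ceftriaxone", day = 0), adm)
  expect_equal(nrow(px5$treatment), 1)
  # ... and stripped on day 0 of an elective surgical admission
  elect <- adm_row("a3", urgency = "elective", category = "surgical")
  px6 <- filter_prophylaxis(drow("a3", "ceftriaxone", day = 0), elect)
  expect_equal(px6$removed$prophylaxis_rule, "elective_day0")
  # all cefazoline
  px7 <- filter_prophylaxis(drow("a1", "cefazoline", day = 3), adm)
  expect_equal(px7$removed$prophylaxis_rule, "cefazoline")
  # low-dose erythromycin: 250 mg four times a day is stripped ...
  ery4 <- do.call(rbind, lapply(c(0, 6, 12, 18), function(h)
    drow("a1", "erythromycin", day = 2, start_h = h, amount = 250)))
  px8 <- filter_prophylaxis(ery4, adm)
  expect_equal(nrow(px8$treatment), 0)
  # ... three administrations are conservatively kept as treatment
  px9 <- filter_prophylaxis(ery4[1:3, ], adm)
  expect_equal(nrow(px9$treatment), 3)
})

test_that("daily regimens attach drugs to every day their dose interval touches", {
  adm <- adm_row("a1", stay_days = 4)
  # infusion spanning the day-1/day-2 boundary appears on both days
  inf <- drow("a1", "ceftriaxone", start = 1 * DAY + 20 * HOUR,
              stop = 2 * DAY + 4 * HOUR)
  reg <- build_daily_regimens(inf, adm)
  expect_equal(reg$n_drugs, c(0L, 1L, 1L, 0L))
  # no antibiotics: max_rank 0
  reg0 <- build_daily_regimens(empty_drugs(), adm)
  expect_true(all(reg0$max_rank == 0L))
  # IV ceftriaxone + oral metronidazole on one day
  both <- rbind(drow("a1", "ceftriaxone", day = 1),
                drow("a1", "metronidazole", day = 1, route = "other"))
  reg2 <- build_daily_regimens(both, adm)
  d1 <- reg2[reg2$day == 1, ]
  expect_equal(d1$max_rank, 2L)
  expect_equal(d1$count_at_max, 1L)
  expect_true(d1$has_iv)
})

test_that("escalation days follow the new-course / rank-rise / count-rise rule", {
  adm <- adm_row("a1", stay_days = 5)
  esc_days <- function(doses) {
    r <- detect_escalations(build_daily_regimens(doses, adm))
    r$day[r$escalation]
  }
  # new IV course on day 1
  expect_equal(esc_days(drow("a1", "ceftriaxone", day = 1)), 1L)
  # count at the same max rank rises 1 -> 2
  expect_equal(esc_days(rbind(
    drow("a1", "ceftriaxone", day = 1),
    drow("a1", "ceftriaxone", day = 2),
    drow("a1", "ciprofloxacin", day = 2))), c(1L, 2L))
  # de-escalation in rank is not an escalation
  expect_equal(esc_days(rbind(
    drow("a1", "meropenem", day = 1),
    drow("a1", "ceftriaxone", day = 2))), 1L)
  # IV is required on the escalated day
  expect_equal(length(esc_days(drow("a1", "ceftriaxone", day = 1,
                                    route = "other"))), 0L)
  # a one-day gap resets to a new course on resumption
  expect_equal(esc_days(rbind(
    drow("a1", "ceftriaxone", day = 0),
    drow("a1", "ceftriaxone", day = 2))), c(0L, 2L))
})

test_that("escalation flags agree with a brute-force (max_rank, count) oracle on random regimens", {
  pool <- data.frame(
    name = c("meropenem", "vancomycin", "ceftriaxone", "ciprofloxacin",
             "metronidazole", "amoxicillin"),
    rank = c(4L, 3L, 2L, 2L, 1L, 1L), stringsAsFactors = FALSE)
  set.seed(31)
  for (rep in 1:60) {
    stay <- sample(2:8, 1)
    adm <- adm_row("r1", stay_days = stay)
    day_sets <- vector("list", stay)
    doses <- list()
    for (d in 0:(stay - 1)) {
      k <- sample(0:3, 1)
      idx <- sample(nrow(pool), k)
      iv <- sample(c(TRUE, FALSE), k, replace = TRUE)
      day_sets[[d + 1]] <- data.frame(rank = pool$rank[idx], iv = iv)
      for (j in seq_len(k))
        doses[[length(doses) + 1]] <- drow("r1", pool$name[idx[j]], day = d,
          route = if (iv[j]) "IV" else "other")
    }
    doses <- if (length(doses)) do.call(rbind, doses) else empty_drugs()
    got <- detect_escalations(build_daily_regimens(doses, adm))$escalation
    expect_equal(got, oracle_escalations(day_sets))
  }
})

test_that("escalations are monotone under adding and removing doses", {
  adm <- adm_row("a1", stay_days = 5)
  base <- rbind(drow("a1", "ceftriaxone", day = 1),
                drow("a1", "ceftriaxone", day = 2),
                drow("a1", "ciprofloxacin", day = 3))
  before <- detect_escalations(build_daily_regimens(base, adm))
  for (d in 0:4) {
    # adding a strictly higher-rank IV antibiotic never removes an existing
    # escalation on that day
    added <- detect_escalations(build_daily_regimens(
      rbind(base, drow("a1", "meropenem", day = d)), adm))
    expect_true(all(!before$escalation[before$day == d] |
                      added$escalation[added$day == d]))
  }
  for (i in seq_len(nrow(base))) {
    # removing a dose never creates an escalation on its own day
    d <- day_index(base$start_time[i])
    removed <- detect_escalations(build_daily_regimens(base[-i, ], adm))
    expect_true(all(!removed$escalation[removed$day == d] |
                      before$escalation[before$day == d]))
  }
})

test_that("the flexible SDD window opens only for extended cefotaxime courses", {
  expect_equal(extended_cefotaxime_windows(TRUE), 1:4)
  expect_equal(extended_cefotaxime_windows(FALSE), integer(0))
})
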