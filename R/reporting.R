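# Cohort reporting: infection-status groups, stratum summaries, antibiotic
# duration classes, the antibiotic usage table, and SOFA trajectory
# aggregates.

#' Assign an admission to an infection-status group
#'
#' Groups key on admission-onset (day 0) episodes: an admission whose day-0
#' episode met the shock criteria is `septic_shock`, one with a day-0
#' episode without shock is `sepsis_without_shock`; otherwise any treatment
#' antibiotic during the stay gives `antibiotics_without_sepsis` (this
#' includes admissions whose only episodes started later than day 0), and
#' `not_on_antibiotics` completes the partition.
#'
#' @param episodes Episode data.frame for one admission (may be empty).
#' @param regimens Daily regimens for the admission.
#' @return One of the four group labels.
#' @export
assign_admission_group <- function(episodes, regimens) {
  adm0 <- episodes[episodes$onset_day == 0L, , drop = FALSE]
  if (nrow(adm0)) {
    if (any(adm0$shock)) "septic_shock" else "sepsis_without_shock"
  } else if (any(regimens$n_drugs > 0)) {
    "antibiotics_without_sepsis"
  } else {
    "not_on_antibiotics"
  }
}

#' Antibiotic-duration class of an admission-onset sepsis admission
#'
#' Partitions admissions with sepsis on admission by how long the (IV,
#' treatment-only) antibiotics ran: at least 4 distinct days or continuing
#' until ICU death (`ge4d_or_death`); continuing until discharge with a
#' stay under 4 days (`until_discharge_lt4d`); or stopped before 4 days
#' despite a stay of 4 days or more (`lt4d_los_ge4d`).
#'
#' @param admission One-row admissions data.frame.
#' @param regimens Daily regimens for the admission.
#' @return One of the three class labels.
#' @export
classify_antibiotic_duration <- function(admission, regimens) {
  iv_days <- sum(regimens$has_iv & regimens$n_drugs > 0)
  last <- last_stay_day(admission)
  abx_to_end <- any(regimens$day == last & regimens$n_drugs > 0)
  los_days <- (admission$discharge_time - admission$admit_time) / MS_PER_DAY
  if (iv_days >= 4 || (isTRUE(admission$died_in_icu) && abx_to_end))
    "ge4d_or_death"
  else if (abx_to_end && los_days < 4)
    "until_discharge_lt4d"
  else
    "lt4d_los_ge4d"
}

# First-24h extrema and outcome covariates for one admission.
admission_covariates <- function(admission, measurements, regimens,
                                 day0_total) {
  admit <- admission$admit_time
  t_rel <- measurements$time - admit
  m0 <- measurements[t_rel >= 0 & t_rel < MS_PER_DAY, , drop = FALSE]
  grab <- function(var, fun) {
    v <- m0$value[m0$variable == var]
    if (!length(v)) NA_real_ else fun(v)
  }
  pao2 <- grab("pao2_mmHg", min)
  fio2 <- grab("fio2_fraction", max)
  iv_days <- sum(regimens$has_iv & regimens$n_drugs > 0)
  last <- last_stay_day(admission)
  abx_to_end <- any(regimens$day == last & regimens$n_drugs > 0)
  data.frame(
    admission_id = admission$admission_id,
    patient_id = admission$patient_id,
    max_heart_rate = grab("heart_rate_bpm", max),
    min_map = grab("map_mmHg", min),
    max_fio2 = fio2,
    min_spo2 = grab("spo2_fraction", min),
    min_pao2 = pao2,
    min_pf = if (is.na(pao2) || is.na(fio2)) NA_real_ else pao2 / fio2,
    min_gcs = grab("gcs_total", min),
    max_creatinine = grab("creatinine_umol_L", max),
    min_platelets = grab("platelets_10e9_L", min),
    max_bilirubin = grab("bilirubin_umol_L", max),
    max_sofa_day0 = day0_total,
    vasopressor_24h = NA,   # filled by caller (needs drug rows)
    ventilated_24h = any(m0$value[m0$variable == "ventilated"] != 0),
    escalation_24h = any(regimens$escalation[regimens$day == 0L]),
    iv_abx_ge4d = iv_days >= 4 || abx_to_end,
    los_hours = (admission$discharge_time - admit) / MS_PER_HOUR,
    died = isTRUE(admission$died_in_icu),
    stringsAsFactors = FALSE
  )
}

#' Stratum summaries by infection-status group
#'
#' Builds the cohort summary: per group (plus overall), admission and
#' patient counts, sex and age-band breakdowns, admission-category
#' breakdown, medians and interquartile ranges of first-24 h physiology
#' extrema, and outcome counts. Percentages use one decimal, halves up.
#'
#' @param phenotype Output of [phenotype_cohort()].
#' @return A list with `counts` (long data.frame: `group`, `metric`,
#'   `level`, `n`, `pct`) and `physiology` (long data.frame: `group`,
#'   `metric`, `median`, `q1`, `q3`).
#' @export
summarize_strata <- function(phenotype) {
  cov <- phenotype$covariates
  adm <- phenotype$admissions
  cov <- merge(cov, adm[, c("admission_id", "age_years", "sex", "urgency",
                            "category")], by = "admission_id")
  cov$group <- phenotype$groups$group[match(cov$admission_id,
                                            phenotype$groups$admission_id)]
  cov$age_band <- cut(cov$age_years, c(18, 40, 50, 60, 70, 80, Inf),
                      right = FALSE, labels = c("18-39", "40-49", "50-59",
                                                "60-69", "70-79", "80+"))
  cov$adm_cat <- ifelse(cov$urgency == "elective", "elective_surgical",
                        ifelse(cov$category == "surgical",
                               "emergency_surgical", "emergency_medical"))
  groups <- c("overall", "septic_shock", "sepsis_without_shock",
              "antibiotics_without_sepsis", "not_on_antibiotics")

  counts <- list()
  phys <- list()
  for (g in groups) {
    sub <- if (g == "overall") cov else cov[cov$group == g, , drop = FALSE]
    n <- nrow(sub)
    addc <- function(metric, level, k) {
      counts[[length(counts) + 1]] <<- data.frame(
        group = g, metric = metric, level = level, n = k,
        pct = pct_value(k, n), stringsAsFactors = FALSE)
    }
    counts[[length(counts) + 1]] <- data.frame(
      group = g, metric = "n_admissions", level = "", n = n, pct = NA_real_,
      stringsAsFactors = FALSE)
    counts[[length(counts) + 1]] <- data.frame(
      group = g, metric = "n_patients", level = "",
      n = length(unique(sub$patient_id)), pct = NA_real_,
      stringsAsFactors = FALSE)
    addc("sex", "female", sum(sub$sex == "female"))
    for (b in levels(cov$age_band)) addc("age_band", b,
                                         sum(sub$age_band == b, na.rm = TRUE))
    for (cat in c("elective_surgical", "emergency_surgical",
                  "emergency_medical")) addc("admission_category", cat,
                                             sum(sub$adm_cat == cat))
    addc("vasopressors_24h", "", sum(sub$vasopressor_24h, na.rm = TRUE))
    addc("ventilated_24h", "", sum(sub$ventilated_24h, na.rm = TRUE))
    addc("escalation_24h", "", sum(sub$escalation_24h, na.rm = TRUE))
    addc("iv_abx_ge4d", "", sum(sub$iv_abx_ge4d, na.rm = TRUE))
    addc("icu_mortality", "", sum(sub$died))

    for (v in c("max_heart_rate", "min_map", "max_fio2", "min_spo2",
                "min_pao2", "min_pf", "min_gcs", "max_creatinine",
                "min_platelets", "max_bilirubin", "max_sofa_day0",
                "los_hours")) {
      q <- stats::quantile(sub[[v]], c(0.25, 0.5, 0.75), na.rm = TRUE,
                           names = FALSE, type = 7)
      phys[[length(phys) + 1]] <- data.frame(
        group = g, metric = v, median = q[2], q1 = q[1], q3 = q[3],
        stringsAsFactors = FALSE)
    }
  }
  list(counts = do.call(rbind, counts), physiology = do.call(rbind, phys))
}

#' Antibiotic usage table (treatment-only)
#'
#' A course is a maximal run of consecutive calendar days on which a drug
#' was administered within one admission; antibiotic-days count distinct
#' (admission, drug, day) triples. Shares of all courses are given per drug
#' at one decimal.
#'
#' @param phenotype Output of [phenotype_cohort()].
#' @return data.frame: `drug_name`, `rank`, `n_courses`, `pct_courses`,
#'   `antibiotic_days`, ordered by rank (4 first) then courses, plus the
#'   rank-level aggregate in the `rank_summary` attribute.
#' @export
usage_table <- function(phenotype) {
  config <- phenotype$config
  triples <- list()
  for (id in names(phenotype$per_admission)) {
    pa <- phenotype$per_admission[[id]]
    reg <- pa$regimens
    for (i in seq_len(nrow(reg))) {
      for (drug in reg$drugs[[i]]) {
        triples[[length(triples) + 1]] <- data.frame(
          admission_id = id, drug_name = drug, day = reg$day[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(triples)) {
    out <- data.frame(drug_name = character(0), rank = integer(0),
                      n_courses = integer(0), pct_courses = numeric(0),
                      antibiotic_days = integer(0), stringsAsFactors = FALSE)
    attr(out, "rank_summary") <- data.frame(
      rank = integer(0), n_courses = integer(0), pct_courses = numeric(0))
    return(out)
  }
  tr <- unique(do.call(rbind, triples))
  key <- paste(tr$admission_id, tr$drug_name, sep = "\r")
  per <- split(tr$day, key)
  n_runs <- vapply(per, function(d) {
    d <- sort(unique(d))
    1L + sum(diff(d) > 1)
  }, 1L)
  drug_of <- vapply(strsplit(names(per), "\r"), `[`, "", 2)
  courses <- tapply(n_runs, drug_of, sum)
  days <- table(tr$drug_name)
  drugs <- sort(unique(tr$drug_name))
  out <- data.frame(
    drug_name = drugs,
    rank = rank_of(drugs, config$rank_table),
    n_courses = as.integer(courses[drugs]),
    antibiotic_days = as.integer(days[drugs]),
    stringsAsFactors = FALSE
  )
  total_courses <- sum(out$n_courses)
  out$pct_courses <- pct_value(out$n_courses, total_courses)
  out <- out[order(-out$rank, -out$n_courses, out$drug_name), ,
             drop = FALSE]
  out <- out[, c("drug_name", "rank", "n_courses", "pct_courses",
                 "antibiotic_days")]
  rownames(out) <- NULL
  rk <- stats::aggregate(n_courses ~ rank, out, sum)
  rk$pct_courses <- pct_value(rk$n_courses, total_courses)
  attr(out, "rank_summary") <- rk
  out
}

#' SOFA component trajectories around an anchor
#'
#' For each day relative to the anchor (episode onset, ICU discharge, or
#' ICU death), counts the distribution of each component score, including a
#' `"missing"` level for incomputable components. No imputation is applied
#' here, so the missing fraction reflects the raw data.
#'
#' @param phenotype Output of [phenotype_cohort()].
#' @param alignment `"onset"`, `"discharge"` or `"death"`.
#' @param max_offset Trim relative days beyond this absolute offset.
#' @return Long data.frame: `alignment`, `rel_day`, `component`, `score`
#'   (`"0"`..`"4"` or `"missing"`), `n`.
#' @export
sofa_trajectories <- function(phenotype, alignment = c("onset", "discharge",
                                                       "death"),
                              max_offset = 10) {
  alignment <- match.arg(alignment)
  comps <- c("resp", "coag", "liver", "cardio", "cns", "renal")
  rows <- list()
  for (id in names(phenotype$per_admission)) {
    pa <- phenotype$per_admission[[id]]
    adm <- phenotype$admissions[phenotype$admissions$admission_id == id, ,
                                drop = FALSE]
    anchors <- switch(alignment,
      onset = pa$episodes$onset_day,
      discharge = if (!isTRUE(adm$died_in_icu) && nrow(pa$episodes))
        last_stay_day(adm) else integer(0),
      death = if (isTRUE(adm$died_in_icu) && nrow(pa$episodes))
        day_index(adm$death_time, adm$admit_time) else integer(0))
    ser <- pa$series[!pa$series$virtual, , drop = FALSE]
    for (a in anchors) {
      rel <- ser$day - a
      keep <- abs(rel) <= max_offset
      for (ci in comps) {
        sc <- ser[[ci]][keep]
        rows[[length(rows) + 1]] <- data.frame(
          rel_day = rel[keep], component = ci,
          score = ifelse(is.na(sc), "missing", as.character(sc)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(data.frame(
    alignment = character(0), rel_day = integer(0), component = character(0),
    score = character(0), n = integer(0), stringsAsFactors = FALSE))
  long <- do.call(rbind, rows)
  agg <- stats::aggregate(list(n = rep(1L, nrow(long))),
                          long[, c("rel_day", "component", "score")], sum)
  agg$alignment <- alignment
  agg[order(agg$rel_day, agg$component, agg$score),
      c("alignment", "rel_day", "component", "score", "n")]
}
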