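# Daily SOFA scoring: component scorers, the per-window "worst value" rule,
# and the pre-ICU / death-day missing-data policies.

#' Respiration SOFA component
#'
#' Scores the PaO2:FiO2 ratio. Scores of 3-4 additionally require
#' ventilatory support; without it the component is capped (default 2).
#'
#' @param pf_ratio PaO2:FiO2 ratio, mmHg; `NA` gives a missing score.
#' @param ventilated Logical, ventilatory support in the window.
#' @param thr [sofa_thresholds()].
#' @return Integer score 0-4 or `NA`.
#' @export
score_respiration <- function(pf_ratio, ventilated = FALSE,
                              thr = sofa_thresholds()) {
  if (is.na(pf_ratio)) return(NA_integer_)
  s <- sum(pf_ratio < thr$respiration$pf_cutpoints)
  if (!isTRUE(ventilated)) s <- min(s, thr$respiration$cap_without_ventilation)
  as.integer(s)
}

#' Coagulation SOFA component
#' @param platelets Platelet count, 10^9/L; `NA` gives a missing score.
#' @param thr [sofa_thresholds()].
#' @return Integer score 0-4 or `NA`.
#' @export
score_coagulation <- function(platelets, thr = sofa_thresholds()) {
  if (is.na(platelets)) return(NA_integer_)
  as.integer(sum(platelets < thr$coagulation$platelet_cutpoints))
}

#' Liver SOFA component
#' @param bilirubin Total bilirubin, umol/L; `NA` gives a missing score.
#' @param thr [sofa_thresholds()].
#' @return Integer score 0-4 or `NA`.
#' @export
score_liver <- function(bilirubin, thr = sofa_thresholds()) {
  if (is.na(bilirubin)) return(NA_integer_)
  if (bilirubin > thr$liver$bilirubin_gt4) return(4L)
  as.integer(sum(bilirubin >= thr$liver$bilirubin_min))
}

#' Central nervous system SOFA component
#' @param gcs Glasgow Coma Scale total, 3-15; `NA` gives a missing score.
#' @param thr [sofa_thresholds()].
#' @return Integer score 0-4 or `NA`.
#' @export
score_cns <- function(gcs, thr = sofa_thresholds()) {
  if (is.na(gcs)) return(NA_integer_)
  if (gcs < thr$cns$gcs_lt4) return(4L)
  as.integer(sum(gcs <= thr$cns$gcs_le))
}

#' Renal SOFA component
#'
#' The worse of the creatinine-based and 24 h urine-output-based scores.
#'
#' @param creatinine Creatinine, umol/L, or `NA`.
#' @param urine_24h Urine output over the day, mL, or `NA`.
#' @param thr [sofa_thresholds()].
#' @return Integer score 0-4, or `NA` when both inputs are missing.
#' @export
score_renal <- function(creatinine, urine_24h = NA, thr = sofa_thresholds()) {
  s_cr <- if (is.na(creatinine)) NA_integer_ else {
    if (creatinine > thr$renal$creatinine_gt4) 4L
    else as.integer(sum(creatinine >= thr$renal$creatinine_min))
  }
  s_ur <- if (is.na(urine_24h)) NA_integer_ else {
    if (urine_24h < thr$renal$urine_lt4) 4L
    else if (urine_24h < thr$renal$urine_lt3) 3L
    else 0L
  }
  if (is.na(s_cr) && is.na(s_ur)) return(NA_integer_)
  max(s_cr, s_ur, na.rm = TRUE)
}

#' Cardiovascular SOFA component
#'
#' Highest applicable score among the mean-arterial-pressure branch and the
#' vasopressor branches (dopamine, dobutamine, adrenaline, noradrenaline;
#' rates in ug/kg/min). A vasopressor exposure with a missing rate is scored
#' at the drug's minimum qualifying level and flagged via the
#' `rate_imputed` attribute. When `norad_6h_rule` is on, noradrenaline
#' exposures totalling at most `norad_min_hours` in the window are ignored.
#'
#' @param map_min Minimum mean arterial pressure in the window, mmHg, or `NA`.
#' @param vasopressors data.frame with columns `drug_name`,
#'   `rate_ug_kg_min`, `hours` (in-window exposure). Zero rows for none.
#' @param norad_6h_rule Logical; the noradrenaline-duration sensitivity rule.
#' @param thr [sofa_thresholds()].
#' @param norad_min_hours Cumulative-hours threshold for the rule.
#' @return Integer score 0-4, or `NA` when there is neither a MAP value nor
#'   a scoring vasopressor.
#' @export
score_cardiovascular <- function(map_min, vasopressors = NULL,
                                 norad_6h_rule = FALSE,
                                 thr = sofa_thresholds(),
                                 norad_min_hours = 6) {
  cv <- thr$cardiovascular
  vp <- vasopressors
  if (is.null(vp)) vp <- data.frame(drug_name = character(0),
                                    rate_ug_kg_min = numeric(0),
                                    hours = numeric(0))
  vp$drug_name <- tolower(vp$drug_name)
  if (isTRUE(norad_6h_rule) && nrow(vp)) {
    is_nor <- vp$drug_name == "noradrenaline"
    if (any(is_nor) && sum(vp$hours[is_nor]) <= norad_min_hours)
      vp <- vp[!is_nor, , drop = FALSE]
  }

  scores <- integer(0)
  imputed <- FALSE
  if (!is.na(map_min) && map_min < cv$map_lt) scores <- c(scores, 1L)
  for (i in seq_len(nrow(vp))) {
    d <- vp$drug_name[i]
    r <- vp$rate_ug_kg_min[i]
    s <- switch(d,
      dobutamine = 2L,
      dopamine = {
        if (is.na(r)) { imputed <- TRUE; 2L }
        else if (r > cv$dopamine_high) 4L
        else if (r > cv$dopamine_mid) 3L
        else 2L
      },
      adrenaline = ,
      noradrenaline = {
        if (is.na(r)) { imputed <- TRUE; 3L }
        else if (r > cv$norad_high) 4L
        else 3L
      },
      NULL  # vasopressin, phenylephrine: not scored by the standard table
    )
    if (!is.null(s)) scores <- c(scores, s)
  }
  out <- if (length(scores)) max(scores) else if (is.na(map_min)) NA_integer_ else 0L
  attr(out, "rate_imputed") <- imputed
  out
}

# Worst (score-maximising) per-window extrema for one admission-day.
window_extrema <- function(measurements, day, admit = 0) {
  t_rel <- measurements$time - admit
  in_win <- t_rel >= day * MS_PER_DAY & t_rel < (day + 1) * MS_PER_DAY
  m <- measurements[in_win, , drop = FALSE]
  grab <- function(var, fun) {
    v <- m$value[m$variable == var]
    if (!length(v)) NA_real_ else fun(v)
  }
  list(
    platelets = grab("platelets_10e9_L", min),
    bilirubin = grab("bilirubin_umol_L", max),
    creatinine = grab("creatinine_umol_L", max),
    gcs = grab("gcs_total", min),
    map = grab("map_mmHg", min),
    pao2 = grab("pao2_mmHg", min),
    fio2 = grab("fio2_fraction", max),
    lactate = grab("lactate_mmol_L", max),
    urine = if (any(m$variable == "urine_mL"))
      sum(m$value[m$variable == "urine_mL"]) else NA_real_,
    ventilated = any(m$value[m$variable == "ventilated"] != 0)
  )
}

# In-window vasopressor exposures for one admission-day.
vasopressor_exposures <- function(drugs, day, config, admit = 0) {
  vp <- drugs[drugs$drug_class == "vasopressor" &
                tolower(drugs$drug_name) %in% config$vasopressor_names, ,
              drop = FALSE]
  if (!nrow(vp)) return(data.frame(drug_name = character(0),
                                   rate_ug_kg_min = numeric(0),
                                   hours = numeric(0)))
  on <- interval_on_day(vp$start_time - admit, vp$stop_time - admit, day)
  vp <- vp[on, , drop = FALSE]
  data.frame(
    drug_name = tolower(vp$drug_name),
    rate_ug_kg_min = vp$rate_ug_kg_min,
    hours = hours_on_day(vp$start_time - admit, vp$stop_time - admit, day),
    stringsAsFactors = FALSE
  )
}

#' Daily SOFA for one admission-day
#'
#' Each component is scored on the worst (score-maximising) value observed
#' in the 24 h window. The PF ratio is the worst-case pairing
#' min(PaO2)/max(FiO2); PaO2 without any FiO2 assumes room air. The total is
#' the sum of the non-missing components.
#'
#' @param admission One-row admissions data.frame.
#' @param measurements Measurement rows for this admission.
#' @param drugs Drug administration rows for this admission.
#' @param day Day index (0 = first 24 h).
#' @param config A [cohort_config()].
#' @return One-row data.frame: `admission_id`, `day`, the six component
#'   scores (`resp`, `coag`, `liver`, `cardio`, `cns`, `renal`), `total`,
#'   `n_missing`, `rate_imputed`, `death_day_imputed`.
#' @export
compute_daily_sofa <- function(admission, measurements, drugs, day,
                               config = cohort_config()) {
  admit <- admission$admit_time
  ex <- window_extrema(measurements, day, admit)
  thr <- config$thresholds
  pf <- if (is.na(ex$pao2)) NA_real_ else
    ex$pao2 / ifelse(is.na(ex$fio2), config$fio2_default, ex$fio2)
  vp <- vasopressor_exposures(drugs, day, config, admit)
  cardio <- score_cardiovascular(ex$map, vp,
                                 norad_6h_rule = config$variant == "norad_6h",
                                 thr = thr,
                                 norad_min_hours = config$norad_min_hours)
  comp <- c(
    resp = score_respiration(pf, ex$ventilated, thr),
    coag = score_coagulation(ex$platelets, thr),
    liver = score_liver(ex$bilirubin, thr),
    cardio = as.integer(cardio),
    cns = score_cns(ex$gcs, thr),
    renal = score_renal(ex$creatinine, ex$urine, thr)
  )
  data.frame(
    admission_id = admission$admission_id,
    day = as.integer(day),
    resp = comp[["resp"]], coag = comp[["coag"]], liver = comp[["liver"]],
    cardio = comp[["cardio"]], cns = comp[["cns"]], renal = comp[["renal"]],
    total = sum(comp, na.rm = TRUE),
    n_missing = sum(is.na(comp)),
    rate_imputed = isTRUE(attr(cardio, "rate_imputed")),
    death_day_imputed = FALSE,
    stringsAsFactors = FALSE
  )
}

# Last in-stay day index for an admission.
last_stay_day <- function(admission) {
  off <- admission$discharge_time - admission$admit_time
  max(0L, as.integer(ceiling(off / MS_PER_DAY) - 1))
}

#' Daily SOFA series for one admission
#'
#' Scores every in-stay day (0 to the last day touched by the stay) and
#' applies the missing-data policies: a virtual pre-admission day (day -1)
#' with SOFA 0 is prepended, reflecting the assumption that all components
#' are zero before ICU admission; and on the day of death, if the total
#' cannot be computed it is set to the maximum of 24.
#'
#' @param admission One-row admissions data.frame.
#' @param measurements,drugs Rows for this admission.
#' @param config A [cohort_config()].
#' @param virtual_day Prepend the virtual pre-admission day? (default TRUE)
#' @return data.frame of daily rows (see [compute_daily_sofa()]) with an
#'   extra logical column `virtual`; day -1 is the pre-admission row.
#' @export
sofa_series <- function(admission, measurements, drugs,
                        config = cohort_config(), virtual_day = TRUE) {
  days <- 0:last_stay_day(admission)
  rows <- lapply(days, function(d)
    compute_daily_sofa(admission, measurements, drugs, d, config))
  series <- do.call(rbind, rows)
  series$virtual <- FALSE
  series <- apply_missingness_policy(series, admission, config)
  if (virtual_day) {
    v <- series[1, , drop = FALSE]
    v$day <- -1L
    v[, c("resp", "coag", "liver", "cardio", "cns", "renal")] <- 0L
    v$total <- 0L
    v$n_missing <- 0L
    v$rate_imputed <- FALSE
    v$death_day_imputed <- FALSE
    v$virtual <- TRUE
    series <- rbind(v, series)
  }
  rownames(series) <- NULL
  series
}

#' Death-day SOFA imputation
#'
#' Among admissions that died in the ICU, a death-day total that could not
#' be calculated from the data is set to the maximum of 24. Under the
#' default `"all_missing"` mode this applies only when all six components
#' are missing; under `"any_missing"` whenever at least one is.
#'
#' @param series Daily SOFA data.frame (real days only), sorted by day.
#' @param admission One-row admissions data.frame.
#' @param config A [cohort_config()].
#' @return The series with `total`/`death_day_imputed` adjusted.
#' @export
apply_missingness_policy <- function(series, admission,
                                     config = cohort_config()) {
  if (isTRUE(admission$died_in_icu) && !is.na(admission$death_time)) {
    dday <- day_index(admission$death_time, admission$admit_time)
    i <- which(series$day == dday)
    if (length(i) == 1) {
      incomputable <- if (config$death_day_impute == "all_missing")
        series$n_missing[i] == 6L else series$n_missing[i] > 0L
      if (incomputable) {
        series$total[i] <- 24L
        series$death_day_imputed[i] <- TRUE
      }
    }
  }
  series
}

#' Number of missing day-0 SOFA components per admission
#'
#' Used by the inclusion flow; computed for every admission in the table.
#'
#' @param tables A `cohort_tables` list.
#' @param config A [cohort_config()].
#' @return Named integer vector keyed by `admission_id`.
#' @export
day0_missing_components <- function(tables, config = cohort_config()) {
  adm <- tables$admissions
  out <- integer(nrow(adm))
  names(out) <- adm$admission_id
  mes_by <- split(tables$measurements, tables$measurements$admission_id)
  drg_by <- split(tables$drugs, tables$drugs$admission_id)
  empty_mes <- tables$measurements[0, , drop = FALSE]
  empty_drg <- tables$drugs[0, , drop = FALSE]
  for (i in seq_len(nrow(adm))) {
    id <- adm$admission_id[i]
    row <- compute_daily_sofa(adm[i, , drop = FALSE],
                              mes_by[[id]] %||% empty_mes,
                              drg_by[[id]] %||% empty_drg, 0L, config)
    out[[id]] <- row$n_missing
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
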