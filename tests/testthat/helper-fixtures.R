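# Fixture builders and independent oracles. Oracles are written directly
# from the standard SOFA table / the escalation rule text, as a separate
# code path from the package implementation.

HOUR <- 3600 * 1000
DAY <- 24 * HOUR

adm_row <- function(id = "a1", stay_days = 6, age = 60, sex = "female",
                    unit = "ICU", urgency = "emergency",
                    category = "medical",
                    specialty = "General Internal Medicine",
                    cardiac = FALSE, died = FALSE, discharge = NULL,
                    death_time = NA_real_, patient = NULL) {
  if (is.null(discharge)) discharge <- stay_days * DAY - 2 * HOUR
  if (died && is.na(death_time)) death_time <- discharge
  data.frame(admission_id = id, patient_id = patient %||% paste0("p_", id),
             age_years = age, sex = sex, unit = unit, admit_time = 0,
             discharge_time = discharge, urgency = urgency,
             category = category, specialty = specialty,
             cardiac_surgery = cardiac, died_in_icu = died,
             death_time = death_time, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mrow <- function(id, var, value, day = 0, hour = 6) {
  data.frame(admission_id = id, variable = var, value = value,
             time = day * DAY + hour * HOUR, stringsAsFactors = FALSE)
}

drow <- function(id, name, class = "antibiotic", route = "IV", day = 0,
                 start_h = 8, dur_h = 0.5, amount = 1000, unit = "mg",
                 rate = NA_real_, start = NULL, stop = NULL) {
  s <- start %||% (day * DAY + start_h * HOUR)
  e <- stop %||% (s + dur_h * HOUR)
  data.frame(admission_id = id, drug_name = name, drug_class = class,
             route = route, dose_amount = amount, dose_unit = unit,
             rate_ug_kg_min = rate, start_time = s, stop_time = e,
             stringsAsFactors = FALSE)
}

crow <- function(id, specimen = "blood", time = 10 * HOUR) {
  data.frame(admission_id = id, specimen = specimen, time = time,
             stringsAsFactors = FALSE)
}

empty_drugs <- function() drow("x", "ceftriaxone")[0, , drop = FALSE]
empty_meas <- function() mrow("x", "map_mmHg", 80)[0, , drop = FALSE]
empty_cult <- function() crow("x")[0, , drop = FALSE]

make_tables <- function(admissions, drugs = NULL, measurements = NULL,
                        cultures = NULL) {
  list(admissions = admissions,
       drugs = drugs %||% empty_drugs(),
       measurements = measurements %||% empty_meas(),
       cultures = cultures %||% empty_cult())
}

# Measurements giving a chosen daily SOFA total via the coagulation /
# liver / CNS / renal components (value per target score).
sofa_meas_for_total <- function(id, day, total) {
  stopifnot(total >= 0, total <= 16)
  plate <- c(200, 120, 70, 30, 10)
  bili <- c(8, 25, 60, 150, 250)
  gcs <- c(15, 13, 11, 8, 4)
  creat <- c(80, 140, 250, 400, 500)
  s <- rep(0L, 4)
  rem <- total
  for (i in 1:4) { s[i] <- min(4L, rem); rem <- rem - s[i] }
  rbind(
    mrow(id, "platelets_10e9_L", plate[s[1] + 1], day),
    mrow(id, "bilirubin_umol_L", bili[s[2] + 1], day),
    mrow(id, "gcs_total", gcs[s[3] + 1], day),
    mrow(id, "creatinine_umol_L", creat[s[4] + 1], day)
  )
}

# ---- independent SOFA oracle (literal threshold table) ------------------

oracle_resp <- function(pf, vent) {
  if (is.na(pf)) return(NA_integer_)
  if (pf < 100 && vent) 4L else if (pf < 200 && vent) 3L
  else if (pf < 200) 2L  # capped without ventilation
  else if (pf < 300) 2L else if (pf < 400) 1L else 0L
}
oracle_coag <- function(p) {
  if (is.na(p)) return(NA_integer_)
  if (p < 20) 4L else if (p < 50) 3L else if (p < 100) 2L
  else if (p < 150) 1L else 0L
}
oracle_liver <- function(b) {
  if (is.na(b)) return(NA_integer_)
  if (b > 204) 4L else if (b >= 102) 3L else if (b >= 33) 2L
  else if (b >= 20) 1L else 0L
}
oracle_cns <- function(g) {
  if (is.na(g)) return(NA_integer_)
  if (g < 6) 4L else if (g <= 9) 3L else if (g <= 12) 2L
  else if (g <= 14) 1L else 0L
}
oracle_renal <- function(cr, ur) {
  s1 <- if (is.na(cr)) NA_integer_ else {
    if (cr > 440) 4L else if (cr >= 300) 3L else if (cr >= 171) 2L
    else if (cr >= 110) 1L else 0L
  }
  s2 <- if (is.na(ur)) NA_integer_ else {
    if (ur < 200) 4L else if (ur < 500) 3L else 0L
  }
  if (is.na(s1) && is.na(s2)) NA_integer_ else max(s1, s2, na.rm = TRUE)
}
oracle_cardio <- function(map, vps) {
  # vps: data.frame(drug_name, rate_ug_kg_min)
  best <- -1L
  if (!is.na(map) && map < 70) best <- max(best, 1L)
  for (i in seq_len(nrow(vps))) {
    d <- vps$drug_name[i]; r <- vps$rate_ug_kg_min[i]
    s <- if (d == "dobutamine") 2L
    else if (d == "dopamine") {
      if (is.na(r)) 2L else if (r > 15) 4L else if (r > 5) 3L else 2L
    } else if (d %in% c("adrenaline", "noradrenaline")) {
      if (is.na(r)) 3L else if (r > 0.1) 4L else 3L
    } else -1L
    best <- max(best, s)
  }
  if (best >= 0L) best else if (is.na(map)) NA_integer_ else 0L
}

# Literal per-window scoring from raw measurement rows.
oracle_daily_sofa <- function(meas, drugs, day) {
  w <- meas[meas$time >= day * DAY & meas$time < (day + 1) * DAY, ,
            drop = FALSE]
  v <- function(var) w$value[w$variable == var]
  worst <- function(var, fun) { x <- v(var); if (length(x)) fun(x) else NA }
  pao2 <- worst("pao2_mmHg", min)
  fio2 <- worst("fio2_fraction", max)
  pf <- if (is.na(pao2)) NA else pao2 / ifelse(is.na(fio2), 0.21, fio2)
  vent <- any(v("ventilated") != 0)
  vp <- drugs[drugs$drug_class == "vasopressor", , drop = FALSE]
  d0 <- day * DAY; d1 <- d0 + DAY
  on <- ifelse(vp$start_time == vp$stop_time,
               vp$start_time >= d0 & vp$start_time < d1,
               vp$start_time < d1 & vp$stop_time > d0)
  comp <- c(
    resp = oracle_resp(pf, vent),
    coag = oracle_coag(worst("platelets_10e9_L", min)),
    liver = oracle_liver(worst("bilirubin_umol_L", max)),
    cardio = oracle_cardio(worst("map_mmHg", min), vp[on, , drop = FALSE]),
    cns = oracle_cns(worst("gcs_total", min)),
    renal = oracle_renal(worst("creatinine_umol_L", max),
                         if (any(w$variable == "urine_mL"))
                           sum(v("urine_mL")) else NA)
  )
  list(components = comp, total = sum(comp, na.rm = TRUE),
       n_missing = sum(is.na(comp)))
}

# ---- independent escalation oracle --------------------------------------

# day_sets: list over days 0..D of data.frame(rank, iv); enumerates
# (max_rank, count_at_max) pairs day over day.
oracle_escalations <- function(day_sets) {
  stats <- lapply(day_sets, function(df) {
    if (!nrow(df)) return(c(mx = 0L, cnt = 0L, iv = 0L, n = 0L))
    mx <- max(df$rank)
    c(mx = mx, cnt = sum(df$rank == mx), iv = as.integer(any(df$iv)),
      n = nrow(df))
  })
  out <- logical(length(day_sets))
  for (d in seq_along(day_sets)) {
    cur <- stats[[d]]
    prev <- if (d == 1) c(mx = 0L, cnt = 0L, iv = 0L, n = 0L) else stats[[d - 1]]
    out[d] <- cur[["n"]] > 0 && cur[["iv"]] == 1L &&
      (prev[["n"]] == 0 || cur[["mx"]] > prev[["mx"]] ||
         (cur[["mx"]] == prev[["mx"]] && cur[["cnt"]] > prev[["cnt"]]))
  }
  out
}

# ---- independent episode oracle -----------------------------------------

# totals: named by day (may include "-1"); brute-force enumeration of all
# consecutive day pairs and flanking triples, then greedy dedup and the
# 15-day cap.
oracle_episode_onsets <- function(totals, esc_days, flex_days = integer(0),
                                  cap = 15, gap_days = 3) {
  days <- sort(as.integer(names(totals)))
  tot <- function(d) totals[[as.character(d)]]
  onsets <- integer(0)
  for (d in days) {
    if (!((d + 1) %in% days)) next
    if (tot(d + 1) - tot(d) >= 2 &&
          (any(c(d, d + 1) %in% esc_days) || any(c(d, d + 1) %in% flex_days)))
      onsets <- c(onsets, max(d, 0L))
  }
  for (e in esc_days) {
    if ((e - 1) %in% days && (e + 1) %in% days &&
          tot(e + 1) - tot(e - 1) >= 2)
      onsets <- c(onsets, max(e - 1, 0L))
  }
  onsets <- sort(unique(onsets))
  onsets <- onsets[onsets <= cap]
  kept <- integer(0)
  for (o in onsets) {
    if (!length(kept) || o - kept[length(kept)] > gap_days)
      kept <- c(kept, o)
  }
  kept
}

# Bare daily-total series (plus virtual day -1) in the shape
# detect_candidate_events() consumes.
series_from_totals <- function(id, totals_by_day) {
  data.frame(admission_id = id,
             day = as.integer(names(totals_by_day)),
             total = as.integer(unname(totals_by_day)),
             stringsAsFactors = FALSE)
}
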