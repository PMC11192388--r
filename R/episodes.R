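# Sepsis episode detection: candidate events from SOFA rises + escalation
# days, deduplication, septic shock classification, and episode tracking.

#' Candidate sepsis events for one admission
#'
#' Three ways a SOFA rise and an antibiotic escalation combine into a
#' candidate event:
#' * Rule A (consecutive rise): days `(d, d+1)` with
#'   `SOFA(d+1) - SOFA(d) >= 2` and an escalation on `d` or `d+1`. The
#'   virtual pre-admission day participates with SOFA 0 (it can supply the
#'   baseline but never the escalation), which is what makes
#'   admission-onset episodes possible.
#' * Rule B (flanking rise): an escalation on day `e` with
#'   `SOFA(e+1) - SOFA(e-1) >= 2`; the middle day's score is irrelevant.
#' * Rule C (extended-SDD flexible window): the days in `flexible_days`
#'   carry a virtual escalation, so a qualifying consecutive-day rise there
#'   forms an event with no recorded escalation.
#'
#' The onset is the earliest evidence day (clamped to day 0); the baseline
#' SOFA is the lower of the two evidence-day totals.
#'
#' @param series Daily SOFA data.frame including the virtual day -1
#'   (see [sofa_series()]).
#' @param escalation_days Integer days flagged by [detect_escalations()].
#' @param flexible_days Integer days from [extended_cefotaxime_windows()].
#' @param config A [cohort_config()].
#' @return data.frame of candidate events: `admission_id`, `rule`
#'   (`"A_consecutive_rise"`, `"B_flanking_rise"`, `"C_sdd_flexible"`),
#'   `evidence_lo`, `evidence_hi`, `onset_day`, `baseline_sofa`,
#'   `escalation_day` (`NA` for Rule C).
#' @export
detect_candidate_events <- function(series, escalation_days,
                                    flexible_days = integer(0),
                                    config = cohort_config()) {
  id <- series$admission_id[1]
  total <- stats::setNames(series$total, series$day)
  days <- sort(series$day)
  tot <- function(d) unname(total[as.character(d)])
  onset_of <- function(lo, hi) {
    if (config$onset_convention == "earliest") max(min(lo, hi), 0L)
    else max(lo, hi)
  }
  esc_all <- sort(unique(c(escalation_days, flexible_days)))
  ev <- list()
  add <- function(rule, lo, hi, esc_day) {
    ev[[length(ev) + 1]] <<- data.frame(
      admission_id = id, rule = rule,
      evidence_lo = as.integer(lo), evidence_hi = as.integer(hi),
      onset_day = as.integer(onset_of(lo, hi)),
      baseline_sofa = as.integer(min(tot(lo), tot(hi))),
      escalation_day = as.integer(esc_day),
      stringsAsFactors = FALSE)
  }

  # Rules A and C share the consecutive-day shape.
  for (d in days[-length(days)]) {
    if (!((d + 1) %in% days)) next
    if (tot(d + 1) - tot(d) < 2) next
    real <- intersect(c(d, d + 1), escalation_days)
    virt <- intersect(c(d, d + 1), flexible_days)
    if (length(real)) add("A_consecutive_rise", d, d + 1, min(real))
    else if (length(virt)) add("C_sdd_flexible", d, d + 1, NA)
  }
  # Rule B: flanking rise around a real escalation day.
  for (e in intersect(escalation_days, days)) {
    if (!((e - 1) %in% days) || !((e + 1) %in% days)) next
    if (tot(e + 1) - tot(e - 1) >= 2) add("B_flanking_rise", e - 1, e + 1, e)
  }

  if (!length(ev)) return(data.frame(
    admission_id = character(0), rule = character(0),
    evidence_lo = integer(0), evidence_hi = integer(0),
    onset_day = integer(0), baseline_sofa = integer(0),
    escalation_day = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, ev)
  rule_ord <- match(out$rule, c("A_consecutive_rise", "B_flanking_rise",
                                "C_sdd_flexible"))
  out[order(out$onset_day, rule_ord, out$evidence_lo), , drop = FALSE]
}

#' Deduplicate candidate events and cap the onset day
#'
#' Events with onset after `max_onset_day` (default 15) are dropped; a
#' greedy forward scan then keeps an event only when its onset lies
#' strictly more than `dedup_window_hours` (default 72 h) after the last
#' kept onset, onsets being whole days.
#'
#' @param events Candidate events sorted by onset (see
#'   [detect_candidate_events()]).
#' @param config A [cohort_config()].
#' @return The kept events, one row per episode.
#' @export
deduplicate_and_cap <- function(events, config = cohort_config()) {
  events <- events[events$onset_day <= config$max_onset_day, , drop = FALSE]
  if (!nrow(events)) return(events)
  keep <- logical(nrow(events))
  last_onset <- -Inf
  for (i in seq_len(nrow(events))) {
    if ((events$onset_day[i] - last_onset) * 24 > config$dedup_window_hours) {
      keep[i] <- TRUE
      last_onset <- events$onset_day[i]
    }
  }
  events[keep, , drop = FALSE]
}

#' Septic shock classification for one episode
#'
#' Shock requires, within the episode's evidence-day window, at least one
#' vasopressor administration intersecting the window and a maximum lactate
#' strictly above the configured threshold (2 mmol/L).
#'
#' @param episode One-row episode data.frame.
#' @param drugs,measurements Rows for the admission.
#' @param admission One-row admissions data.frame.
#' @param config A [cohort_config()].
#' @return Logical.
#' @export
classify_septic_shock <- function(episode, drugs, measurements, admission,
                                  config = cohort_config()) {
  admit <- admission$admit_time
  w0 <- max(0L, episode$evidence_lo)
  w1 <- episode$evidence_hi
  t0 <- w0 * MS_PER_DAY
  t1 <- (w1 + 1) * MS_PER_DAY
  vp <- drugs[drugs$drug_class == "vasopressor" &
                tolower(drugs$drug_name) %in% config$vasopressor_names, ,
              drop = FALSE]
  s <- vp$start_time - admit
  e <- vp$stop_time - admit
  vaso_on <- any(ifelse(s == e, s >= t0 & s < t1, s < t1 & e > t0))
  lac_t <- measurements$time - admit
  lac <- measurements$value[measurements$variable == "lactate_mmol_L" &
                              lac_t >= t0 & lac_t < t1]
  vaso_on && length(lac) > 0 && max(lac) > config$lactate_shock_threshold
}

#' Track an episode's state over subsequent days
#'
#' A sepsis episode persists on a day while the SOFA total remains strictly
#' above the episode baseline and the patient remains on (treatment)
#' antibiotics; the shock state persists while the day's maximum lactate
#' stays above threshold or a vasopressor is still running. The end day is
#' the first day the sepsis condition fails; episodes still active on the
#' last in-stay day are censored (open, `end_day = NA`).
#'
#' @param episode One-row episode data.frame (with `shock` filled in).
#' @param series Daily SOFA data.frame (virtual day included or not).
#' @param regimens Output of [build_daily_regimens()].
#' @param drugs,measurements Rows for the admission.
#' @param admission One-row admissions data.frame.
#' @param config A [cohort_config()].
#' @return List: `end_day` (integer or `NA` if censored), `states`
#'   (data.frame of `day`, `sepsis_active`, `shock_active`, `label`).
#' @export
track_episode_state <- function(episode, series, regimens, drugs,
                                measurements, admission,
                                config = cohort_config()) {
  admit <- admission$admit_time
  last <- last_stay_day(admission)
  days <- episode$onset_day:last
  total <- stats::setNames(series$total, series$day)
  on_abx <- stats::setNames(regimens$n_drugs > 0, regimens$day)
  vp <- drugs[drugs$drug_class == "vasopressor" &
                tolower(drugs$drug_name) %in% config$vasopressor_names, ,
              drop = FALSE]
  day_shock <- function(d) {
    t0 <- d * MS_PER_DAY; t1 <- t0 + MS_PER_DAY
    s <- vp$start_time - admit; e <- vp$stop_time - admit
    vaso <- any(ifelse(s == e, s >= t0 & s < t1, s < t1 & e > t0))
    lt <- measurements$time - admit
    lac <- measurements$value[measurements$variable == "lactate_mmol_L" &
                                lt >= t0 & lt < t1]
    vaso || (length(lac) > 0 && max(lac) > config$lactate_shock_threshold)
  }

  sepsis_active <- logical(length(days))
  shock_active <- logical(length(days))
  end_day <- NA_integer_
  for (k in seq_along(days)) {
    d <- days[k]
    if (k == 1) {
      sepsis_active[k] <- TRUE  # the onset day itself
    } else if (is.na(end_day)) {
      cont <- unname(total[as.character(d)]) > episode$baseline_sofa &&
        isTRUE(unname(on_abx[as.character(d)]))
      if (isTRUE(cont)) sepsis_active[k] <- TRUE else end_day <- d
    }
    shock_active[k] <- isTRUE(episode$shock) &&
      (k == 1 || shock_active[k - 1]) && day_shock(d)
  }
  label <- ifelse(sepsis_active & shock_active, "septic_shock",
                  ifelse(sepsis_active, "sepsis", "none"))
  list(end_day = end_day,
       states = data.frame(day = days, sepsis_active = sepsis_active,
                           shock_active = shock_active, label = label,
                           stringsAsFactors = FALSE))
}

#' Detect the sepsis episodes of one admission
#'
#' Runs the full per-admission chain: prophylaxis filtering, daily
#' regimens, escalation flags, candidate events, the sensitivity-variant
#' filters selected in the configuration, deduplication, shock
#' classification, and state tracking.
#'
#' @param admission One-row admissions data.frame.
#' @param measurements,drugs,cultures Rows for this admission.
#' @param config A [cohort_config()]; its `variant` field selects the
#'   main analysis or one of the three sensitivity variants.
#' @param series Optional precomputed [sofa_series()] (with virtual day).
#' @return List: `episodes` (data.frame with `shock`, `admission_onset`,
#'   `end_day` columns added), `regimens`, `candidates` (pre-dedup events),
#'   `escalation_days`, `flexible_days`, `states` (per-episode list of
#'   state frames), `series`.
#' @export
detect_sepsis_episodes <- function(admission, measurements, drugs, cultures,
                                   config = cohort_config(), series = NULL) {
  if (is.null(series))
    series <- sofa_series(admission, measurements, drugs, config)
  px <- filter_prophylaxis(drugs, admission, config)
  regimens <- detect_escalations(
    build_daily_regimens(px$treatment, admission, config))
  esc_days <- regimens$day[regimens$escalation]
  flex_days <- extended_cefotaxime_windows(px$extended_cefotaxime, config)

  if (config$variant == "culture_required") {
    esc_days <- Filter(function(e) escalation_has_culture(
      e, px$treatment, cultures, admission, config), esc_days)
    flex_days <- Filter(function(e) escalation_has_culture(
      e, drugs[tolower(drugs$drug_name) == "cefotaxime", , drop = FALSE],
      cultures, admission, config), flex_days)
    esc_days <- as.integer(esc_days)
    flex_days <- as.integer(flex_days)
  }

  cand <- detect_candidate_events(series, esc_days, flex_days, config)
  eps <- deduplicate_and_cap(cand, config)

  if (config$variant == "drop_single_day" && nrow(eps)) {
    keep <- vapply(seq_len(nrow(eps)), function(i)
      !single_day_regimen(eps[i, ], regimens, admission), TRUE)
    eps <- eps[keep, , drop = FALSE]
  }

  states <- list()
  if (nrow(eps)) {
    eps$shock <- vapply(seq_len(nrow(eps)), function(i)
      classify_septic_shock(eps[i, ], drugs, measurements, admission, config),
      TRUE)
    eps$admission_onset <- eps$onset_day == 0L
    eps$end_day <- NA_integer_
    for (i in seq_len(nrow(eps))) {
      tr <- track_episode_state(eps[i, ], series, regimens, drugs,
                                measurements, admission, config)
      eps$end_day[i] <- tr$end_day
      states[[i]] <- tr$states
    }
  } else {
    eps$shock <- logical(0)
    eps$admission_onset <- logical(0)
    eps$end_day <- integer(0)
  }
  list(episodes = eps, regimens = regimens, candidates = cand,
       escalation_days = regimens$day[regimens$escalation],
       flexible_days = flex_days, states = states, series = series)
}

# Variant b: does a culture fall within the configured window of the first
# dose given on escalation day `e`?
escalation_has_culture <- function(e, doses, cultures, admission, config) {
  if (!nrow(cultures)) return(FALSE)
  admit <- admission$admit_time
  on <- interval_on_day(doses$start_time - admit, doses$stop_time - admit, e)
  if (!any(on)) return(FALSE)
  anchor <- min(doses$start_time[on]) - admit
  win <- config$culture_window_hours * MS_PER_HOUR
  any(abs((cultures$time - admit) - anchor) <= win)
}

# Variant c: was the triggering escalated regimen given on a single calendar
# day with the stay continuing past the following day? Episodes triggered by
# the flexible SDD window (no recorded escalation) are never removed, and a
# course truncated by discharge or death is spared.
single_day_regimen <- function(episode, regimens, admission) {
  e <- episode$escalation_day
  if (is.na(e)) return(FALSE)
  last <- last_stay_day(admission)
  if (e + 1 > last) return(FALSE)                      # truncated by discharge
  next_n <- regimens$n_drugs[regimens$day == e + 1]
  length(next_n) == 1 && next_n == 0 && last >= e + 2
}
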