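# Prophylaxis filtering, daily antibiotic regimens, and escalation flags.

#' Strip prophylactic antibiotic administrations
#'
#' Applies five rules identifying prophylactic use, each toggleable in the
#' configuration:
#' * selective digestive decontamination: cefotaxime doses starting in the
#'   first `sdd_days` (default 4) days of the stay;
#' * all antibiotic doses in the first 24 h of an elective surgical
#'   admission;
#' * vancomycin on any day of a cardiac-surgery admission;
#' * low-dose erythromycin (250 mg given at least 4 times in one calendar
#'   day);
#' * all cefazoline.
#'
#' A cefotaxime prescription extending beyond the prophylactic course
#' (any dose touching day >= `sdd_days`) signals that an infection was
#' suspected during the course; this is returned as `extended_cefotaxime`
#' and later opens a flexible episode-matching window (see
#' [extended_cefotaxime_windows()]).
#'
#' @param drugs Drug administration rows for one admission.
#' @param admission One-row admissions data.frame.
#' @param config A [cohort_config()].
#' @return List: `treatment` (antibiotic rows kept as treatment),
#'   `removed` (rows stripped, with a `prophylaxis_rule` column),
#'   `extended_cefotaxime` (logical).
#' @export
filter_prophylaxis <- function(drugs, admission, config = cohort_config()) {
  abx <- drugs[drugs$drug_class == "antibiotic", , drop = FALSE]
  admit <- admission$admit_time
  px <- config$prophylaxis
  name <- tolower(abx$drug_name)
  start_day <- day_index(abx$start_time, admit)

  extended <- any(name == "cefotaxime" &
                    interval_beyond_day(abx$start_time - admit,
                                        abx$stop_time - admit,
                                        config$sdd_days))

  rule <- rep(NA_character_, nrow(abx))
  if (isTRUE(px$cefazoline))
    rule[is.na(rule) & name == "cefazoline"] <- "cefazoline"
  if (isTRUE(px$sdd_cefotaxime))
    rule[is.na(rule) & name == "cefotaxime" &
           start_day < config$sdd_days] <- "sdd_cefotaxime"
  if (isTRUE(px$elective_day0) && admission$urgency == "elective" &&
        admission$category == "surgical")
    rule[is.na(rule) & start_day == 0L] <- "elective_day0"
  if (isTRUE(px$cardiac_vancomycin) && isTRUE(admission$cardiac_surgery))
    rule[is.na(rule) & name == "vancomycin"] <- "cardiac_vancomycin"
  if (isTRUE(px$low_dose_erythromycin)) {
    ery <- which(name == "erythromycin" &
                   abx$dose_amount == px$erythromycin_low_dose_mg &
                   tolower(abx$dose_unit) == "mg")
    if (length(ery)) {
      per_day <- table(start_day[ery])
      low_days <- as.integer(names(per_day)[per_day >= px$erythromycin_min_daily])
      hit <- ery[start_day[ery] %in% low_days]
      rule[hit][is.na(rule[hit])] <- "low_dose_erythromycin"
    }
  }

  removed <- abx[!is.na(rule), , drop = FALSE]
  removed$prophylaxis_rule <- rule[!is.na(rule)]
  list(treatment = abx[is.na(rule), , drop = FALSE],
       removed = removed,
       extended_cefotaxime = extended)
}

# Does [start, stop] (relative ms) touch any day >= from_day?
interval_beyond_day <- function(start, stop, from_day) {
  limit <- from_day * MS_PER_DAY
  ifelse(start == stop, start >= limit, stop > limit)
}

#' Build the daily antibiotic regimens of one admission
#'
#' A drug is "on" a day if any of its dose intervals intersects the 24 h
#' window; infusions spanning midnight therefore appear on both days.
#'
#' @param treatment Treatment-only antibiotic rows (see
#'   [filter_prophylaxis()]).
#' @param admission One-row admissions data.frame.
#' @param config A [cohort_config()].
#' @return data.frame with one row per in-stay day: `admission_id`, `day`,
#'   `drugs` (list-column of drug names), `n_drugs`, `max_rank` (0 when no
#'   antibiotics), `count_at_max`, `has_iv`, and placeholder `escalation` /
#'   `new_course` flags (set by [detect_escalations()]).
#' @export
build_daily_regimens <- function(treatment, admission,
                                 config = cohort_config()) {
  admit <- admission$admit_time
  last <- last_stay_day(admission)
  days <- 0:last
  drug_sets <- rep(list(character(0)), length(days))
  iv_flags <- logical(length(days))
  for (i in seq_len(nrow(treatment))) {
    dd <- days_covered(treatment$start_time[i] - admit,
                       treatment$stop_time[i] - admit, last)
    for (d in dd) {
      j <- d + 1L
      drug_sets[[j]] <- union(drug_sets[[j]], tolower(treatment$drug_name[i]))
      if (treatment$route[i] == "IV") iv_flags[j] <- TRUE
    }
  }
  ranks <- lapply(drug_sets, function(ds)
    if (length(ds)) rank_of(ds, config$rank_table) else integer(0))
  max_rank <- vapply(ranks, function(r) if (length(r)) max(r) else 0L, 1L)
  count_at_max <- mapply(function(r, m) sum(r == m), ranks, max_rank)
  out <- data.frame(
    admission_id = admission$admission_id,
    day = as.integer(days),
    n_drugs = lengths(drug_sets),
    max_rank = as.integer(max_rank),
    count_at_max = as.integer(count_at_max),
    has_iv = iv_flags,
    escalation = NA,
    new_course = NA,
    stringsAsFactors = FALSE
  )
  out$drugs <- drug_sets
  out
}

#' Flag escalation days
#'
#' Day `d` is an escalation day iff the regimen is non-empty with at least
#' one IV antibiotic, and either no antibiotics were given the previous day
#' (a new course), the maximum spectrum rank rose relative to the previous
#' day, or the number of antibiotics at the unchanged maximum rank rose.
#' Day -1 (pre-admission) is treated as antibiotic-free.
#'
#' @param regimens Output of [build_daily_regimens()], consecutive by day.
#' @return The regimens with `escalation` and `new_course` filled in.
#' @export
detect_escalations <- function(regimens) {
  n <- nrow(regimens)
  prev_n <- c(0L, regimens$n_drugs[-n])
  prev_max <- c(0L, regimens$max_rank[-n])
  prev_cnt <- c(0L, regimens$count_at_max[-n])
  regimens$new_course <- regimens$n_drugs > 0 & prev_n == 0
  regimens$escalation <- regimens$has_iv & regimens$n_drugs > 0 & (
    prev_n == 0 |
      regimens$max_rank > prev_max |
      (regimens$max_rank == prev_max & regimens$count_at_max > prev_cnt)
  )
  regimens
}

#' Flexible episode-matching days for extended cefotaxime prescriptions
#'
#' When a prophylactic cefotaxime course runs past its intended length, an
#' infection is assumed to have arisen at an unknown point during the
#' course; days 1 to 4 of the stay then carry a virtual escalation so that
#' a qualifying SOFA rise on consecutive days anywhere in that window can
#' form an episode without a recorded escalation.
#'
#' @param extended_cefotaxime Logical from [filter_prophylaxis()].
#' @param config A [cohort_config()].
#' @return Integer vector of flexible days (`1:4` or empty).
#' @export
extended_cefotaxime_windows <- function(extended_cefotaxime,
                                        config = cohort_config()) {
  if (isTRUE(extended_cefotaxime)) 1:4 else integer(0)
}
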