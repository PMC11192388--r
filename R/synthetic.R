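# Synthetic ICU cohort generator. Emits the four input tables with planted,
# labelled sepsis/shock episodes so the whole pipeline can be validated
# end-to-end without access to a real critical-care database. Trajectories
# are constructed per day as a single worst value per SOFA component; this
# is deliberately simple (the scoring engine takes the worst value per
# window anyway) and makes planted labels exact at zero noise.

.archetypes <- c("admission_shock", "admission_sepsis", "late_sepsis",
                 "prophylaxis_only", "clean", "short_stay_excluded",
                 "missing_day0_excluded")

#' Scenario specification for one synthetic admission
#'
#' @param archetype One of `admission_shock`, `admission_sepsis`,
#'   `late_sepsis`, `prophylaxis_only`, `clean`, `short_stay_excluded`,
#'   `missing_day0_excluded`.
#' @param stay_days Length of stay in days; archetype default if `NULL`.
#' @param onset_day Planted episode onset (late_sepsis only; drawn 2-5 if
#'   `NULL`).
#' @param shock Plant septic shock? Defaults by archetype.
#' @param rise Planted SOFA rise across the evidence days (>= 2); the
#'   default 4 is robust, 2 exercises the decision boundary.
#' @param missingness Per-component per-day probability of dropping the
#'   measurement (0 keeps labels exact).
#' @param noise Relative jitter applied to generated lab values (0 keeps
#'   every value in its intended score band).
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(archetype, stay_days = NULL, onset_day = NULL,
                          shock = NULL, rise = 4, missingness = 0,
                          noise = 0) {
  archetype <- match.arg(archetype, .archetypes)
  fail_if(rise < 2, "planted rise must be >= 2 to be detectable")
  if (is.null(shock)) shock <- archetype == "admission_shock"
  structure(list(archetype = archetype, stay_days = stay_days,
                 onset_day = onset_day, shock = shock, rise = rise,
                 missingness = missingness, noise = noise),
            class = "scenario_spec")
}

# Worst-value generators: the centre of each score band for each component.
.value_for <- list(
  platelets = c(200, 120, 70, 30, 10),
  bilirubin = c(8, 25, 60, 150, 250),
  creatinine = c(80, 140, 250, 400, 500),
  gcs = c(15, 13, 11, 8, 4),
  pf = c(450, 350, 250, 150, 80),
  map = c(80, 62, NA, NA, NA)  # cardio > 1 is planted via vasopressors
)

# Half-widths keeping a jittered value inside its score band.
.band_halfwidth <- list(
  platelets = c(20, 15, 10, 8, 5),
  bilirubin = c(5, 4, 20, 20, 20),
  creatinine = c(15, 12, 20, 20, 20),
  gcs = c(0, 1, 1, 1, 1),
  pf = c(20, 20, 20, 20, 10),
  map = c(5, 3, NA, NA, NA)
)

# Split a daily total into six component scores. The cardiovascular score
# is fixed by the vasopressor/MAP plan; the remainder is spread over the
# other components (respiration capped at 2: no ventilation is planted).
decompose_total <- function(total, cardio) {
  rem <- total - cardio
  fail_if(rem < 0, "daily total %d below planted cardiovascular score %d",
          total, cardio)
  comps <- c(coag = 0L, liver = 0L, cns = 0L, renal = 0L, resp = 0L)
  caps <- c(coag = 4L, liver = 4L, cns = 4L, renal = 4L, resp = 2L)
  for (pass_cap in list(pmin(caps, 2L), caps)) {
    for (nm in names(comps)) {
      add <- min(pass_cap[[nm]] - comps[[nm]], rem)
      if (add > 0) { comps[[nm]] <- comps[[nm]] + add; rem <- rem - add }
    }
  }
  fail_if(rem > 0, "daily total %d exceeds plantable maximum", total)
  c(comps, cardio = as.integer(cardio))
}

#' Generate one synthetic admission
#'
#' Builds records for all four input tables plus a ground-truth label.
#' Sepsis archetypes get lab values chosen so the daily SOFA series rises
#' by `rise` across the planted consecutive days, together with a planted
#' new IV antibiotic course; shock archetypes add a 12 h noradrenaline
#' infusion and a lactate above threshold inside the evidence window;
#' `prophylaxis_only` emits only selective-digestive-decontamination
#' cefotaxime, cefazoline, post-cardiac-surgery vancomycin and low-dose
#' erythromycin patterns (plus a SOFA rise that must *not* become an
#' episode). Deterministic given `seed`.
#'
#' @param spec A [scenario_spec()].
#' @param seed Integer seed for this admission.
#' @param admission_id,patient_id Identifiers to use.
#' @return List: `admissions`, `drugs`, `measurements`, `cultures`
#'   (data.frames), `label` (one-row data.frame), `episode_labels`
#'   (data.frame of planted onsets/shock, possibly empty).
#' @export
generate_admission <- function(spec, seed, admission_id = "adm1",
                               patient_id = "pat1") {
  with_seed(seed, generate_admission_impl(spec, admission_id, patient_id))
}

generate_admission_impl <- function(spec, admission_id, patient_id) {
  a <- spec$archetype
  stay <- spec$stay_days
  onset <- spec$onset_day
  if (a == "late_sepsis" && is.null(onset)) onset <- sample(2:5, 1)
  fail_if(a == "late_sepsis" && onset < 1, "late onset must be >= 1")
  if (is.null(stay)) stay <- switch(a,
    admission_shock = 6L, admission_sepsis = 6L,
    late_sepsis = onset + 6L, prophylaxis_only = 6L, clean = 3L,
    short_stay_excluded = 1L, missing_day0_excluded = 2L)
  fail_if(!is.null(onset) && onset > stay - 2,
          "planted onset %d too close to discharge (stay %d days)",
          onset, stay)
  fail_if(!is.null(onset) && onset > 15,
          "planted onset beyond the 15-day cap is undetectable by design")

  # demographics and admission strata
  age <- sample(18:89, 1)
  sex <- sample(c("female", "male"), 1, prob = c(0.33, 0.67))
  sepsis_arch <- a %in% c("admission_shock", "admission_sepsis", "late_sepsis")
  if (a == "prophylaxis_only") {
    urgency <- "elective"; category <- "surgical"; cardiac <- TRUE
    specialty <- "Cardiothoracic surgery"
  } else if (sepsis_arch) {
    urgency <- "emergency"
    category <- sample(c("medical", "surgical"), 1, prob = c(0.87, 0.13))
    specialty <- if (category == "medical")
      sample(c("General Internal Medicine", "Cardiology", "Neurology",
               "Lung disease/surgery", "Haematology"), 1)
    else sample(c("Gastrointestinal surgery", "Trauma", "Vascular surgery"), 1)
    cardiac <- FALSE
  } else {
    urgency <- sample(c("elective", "emergency"), 1, prob = c(0.55, 0.45))
    category <- if (urgency == "elective") "surgical" else
      sample(c("medical", "surgical"), 1, prob = c(0.8, 0.2))
    specialty <- if (category == "surgical")
      sample(c("Cardiothoracic surgery", "Neurosurgery", "Vascular surgery"), 1)
    else sample(c("Cardiology", "General Internal Medicine", "Neurology"), 1)
    cardiac <- specialty == "Cardiothoracic surgery"
  }

  p_death <- switch(a, admission_shock = 0.38, admission_sepsis = 0.11,
                    late_sepsis = 0.15, prophylaxis_only = 0.02,
                    clean = 0.08, 0)
  died <- stats::runif(1) < p_death
  discharge <- if (a == "short_stay_excluded") 30 * 60 * 1000 else
    stay * MS_PER_DAY - 2 * MS_PER_HOUR
  death_time <- if (died) discharge else NA_real_

  adm <- data.frame(
    admission_id = admission_id, patient_id = patient_id,
    age_years = age, sex = sex, unit = "ICU",
    admit_time = 0, discharge_time = discharge,
    urgency = urgency, category = category, specialty = specialty,
    cardiac_surgery = cardiac, died_in_icu = died, death_time = death_time,
    stringsAsFactors = FALSE
  )

  last_day <- max(0L, as.integer(ceiling(discharge / MS_PER_DAY) - 1))
  days <- 0:last_day

  # --- planted daily totals and cardiovascular plan -----------------------
  base <- switch(a, clean = sample(0:2, 1), late_sepsis = 2L,
                 prophylaxis_only = 1L, missing_day0_excluded = 1L, 0L)
  totals <- rep(base, length(days))
  cardio <- rep(0L, length(days))
  shock_days <- integer(0)
  esc_day <- NA_integer_  # planted new-course day
  if (a %in% c("admission_shock", "admission_sepsis")) {
    onset <- 0L
    peak <- if (spec$shock) max(spec$rise, 4L) else spec$rise
    for (k in seq_along(days)) {
      d <- days[k]
      totals[k] <- if (died) peak else max(peak - d, 0L)
    }
    if (spec$shock) { cardio[1] <- 4L; shock_days <- 0L }
    esc_day <- 0L
  } else if (a == "late_sepsis") {
    peak <- base + spec$rise
    for (k in seq_along(days)) {
      d <- days[k]
      totals[k] <- if (d <= onset) base
      else if (d <= onset + 2 || died) peak
      else max(peak - (d - onset - 2), 0L)
    }
    esc_day <- onset + 1L
    if (spec$shock) { cardio[onset + 2] <- 4L; shock_days <- onset + 1L }
  } else if (a == "prophylaxis_only") {
    totals <- rep(1L, length(days))
    totals[pmin(3, length(totals))] <- 3L  # a rise with no real escalation
  } else if (a == "missing_day0_excluded") {
    totals <- rep(2L, length(days))
  }

  # --- measurements -------------------------------------------------------
  mes <- list()
  emit <- function(var, value, t) {
    mes[[length(mes) + 1]] <<- data.frame(
      admission_id = admission_id, variable = var, value = value, time = t,
      stringsAsFactors = FALSE)
  }
  jitter_in_band <- function(centre, half) {
    if (spec$noise <= 0 || is.na(half) || half == 0) return(centre)
    centre + stats::runif(1, -1, 1) * half * min(spec$noise, 1)
  }
  if (a != "short_stay_excluded") {
    for (k in seq_along(days)) {
      d <- days[k]
      t0 <- d * MS_PER_DAY + 6 * MS_PER_HOUR
      comps <- decompose_total(totals[k], cardio[k])
      if (a == "missing_day0_excluded" && d == 0) {
        # only two components measurable on day 0 (4 of 6 missing)
        emit("platelets_10e9_L",
             .value_for$platelets[comps[["coag"]] + 1], t0)
        emit("bilirubin_umol_L",
             .value_for$bilirubin[comps[["liver"]] + 1], t0)
        next
      }
      keep <- stats::runif(6) >= spec$missingness
      if (keep[1]) emit("platelets_10e9_L",
        jitter_in_band(.value_for$platelets[comps[["coag"]] + 1],
                       .band_halfwidth$platelets[comps[["coag"]] + 1]), t0)
      if (keep[2]) emit("bilirubin_umol_L",
        jitter_in_band(.value_for$bilirubin[comps[["liver"]] + 1],
                       .band_halfwidth$bilirubin[comps[["liver"]] + 1]), t0)
      if (keep[3]) emit("creatinine_umol_L",
        jitter_in_band(.value_for$creatinine[comps[["renal"]] + 1],
                       .band_halfwidth$creatinine[comps[["renal"]] + 1]), t0)
      if (keep[4]) emit("gcs_total",
        jitter_in_band(.value_for$gcs[comps[["cns"]] + 1],
                       .band_halfwidth$gcs[comps[["cns"]] + 1]), t0)
      if (keep[5]) {
        pf <- jitter_in_band(.value_for$pf[comps[["resp"]] + 1],
                             .band_halfwidth$pf[comps[["resp"]] + 1])
        emit("fio2_fraction", 0.4, t0)
        emit("pao2_mmHg", pf * 0.4, t0)
      }
      if (keep[6]) {
        map_score <- min(comps[["cardio"]], 1L)
        emit("map_mmHg",
             jitter_in_band(.value_for$map[map_score + 1],
                            .band_halfwidth$map[map_score + 1]), t0)
      }
      emit("lactate_mmol_L", if (d %in% shock_days) 3.5 else 1.2, t0)
    }
  }
  measurements <- if (length(mes)) do.call(rbind, mes) else
    data.frame(admission_id = character(0), variable = character(0),
               value = numeric(0), time = numeric(0), stringsAsFactors = FALSE)

  # --- drug administrations ----------------------------------------------
  drg <- list()
  dose <- function(name, class, route, day, amount = 1000, unit = "mg",
                   start_h = 8, dur_h = 0.5, rate = NA_real_) {
    s <- day * MS_PER_DAY + start_h * MS_PER_HOUR
    drg[[length(drg) + 1]] <<- data.frame(
      admission_id = admission_id, drug_name = name, drug_class = class,
      route = route, dose_amount = amount, dose_unit = unit,
      rate_ug_kg_min = rate, start_time = s, stop_time = s + dur_h * MS_PER_HOUR,
      stringsAsFactors = FALSE)
  }
  if (!is.na(esc_day)) {
    for (d in esc_day:min(esc_day + 3L, last_day))
      dose("ceftriaxone", "antibiotic", "IV", d, amount = 2000)
  }
  if (length(shock_days)) {
    dose("noradrenaline", "vasopressor", "IV", min(shock_days),
         amount = 5, unit = "mg", start_h = 2, dur_h = 12, rate = 0.25)
  }
  if (a == "prophylaxis_only") {
    for (d in 0:min(3L, last_day))
      dose("cefotaxime", "antibiotic", "IV", d)
    for (h in c(6, 12, 18)) dose("cefazoline", "antibiotic", "IV", 0,
                                 amount = 2000, start_h = h)
    if (last_day >= 2) dose("vancomycin", "antibiotic", "IV", 2)
    if (last_day >= 1)
      for (h in c(0, 6, 12, 18))
        dose("erythromycin", "antibiotic", "IV", 1, amount = 250, start_h = h)
  }
  drugs <- if (length(drg)) do.call(rbind, drg) else
    data.frame(admission_id = character(0), drug_name = character(0),
               drug_class = character(0), route = character(0),
               dose_amount = numeric(0), dose_unit = character(0),
               rate_ug_kg_min = numeric(0), start_time = numeric(0),
               stop_time = numeric(0), stringsAsFactors = FALSE)

  # --- cultures -----------------------------------------------------------
  cultures <- if (sepsis_arch && !is.na(esc_day)) {
    data.frame(admission_id = admission_id, specimen = "blood",
               time = esc_day * MS_PER_DAY + 10 * MS_PER_HOUR,
               stringsAsFactors = FALSE)
  } else data.frame(admission_id = character(0), specimen = character(0),
                    time = numeric(0), stringsAsFactors = FALSE)

  # --- ground truth -------------------------------------------------------
  excluded <- a %in% c("short_stay_excluded", "missing_day0_excluded")
  group <- if (excluded) NA_character_ else switch(a,
    admission_shock = "septic_shock",
    admission_sepsis = "sepsis_without_shock",
    late_sepsis = "antibiotics_without_sepsis",
    prophylaxis_only = "not_on_antibiotics",
    clean = "not_on_antibiotics")
  episode_labels <- if (sepsis_arch)
    data.frame(admission_id = admission_id, onset_day = as.integer(onset),
               shock = spec$shock, stringsAsFactors = FALSE)
  else data.frame(admission_id = character(0), onset_day = integer(0),
                  shock = logical(0), stringsAsFactors = FALSE)
  label <- data.frame(
    admission_id = admission_id, archetype = a,
    expected_excluded = excluded,
    exclusion_reason = if (a == "short_stay_excluded") "short_stay"
      else if (a == "missing_day0_excluded") "missing_day0"
      else NA_character_,
    expected_group = group,
    n_expected_episodes = nrow(episode_labels),
    stringsAsFactors = FALSE
  )

  list(admissions = adm, drugs = drugs, measurements = measurements,
       cultures = cultures, label = label, episode_labels = episode_labels)
}

#' Generate a synthetic cohort
#'
#' Samples `n` admissions from an archetype mix and binds their tables.
#' The default mix plants admission-onset sepsis in about 27% of
#' admissions with about a third of those in shock, a few percent of
#' later-onset episodes, and a block of purely prophylactic antibiotic
#' exposure, echoing the strata proportions of a mixed surgical-medical
#' tertiary ICU.
#'
#' @param n Number of admissions.
#' @param mix Named numeric vector of archetype proportions (must sum to 1).
#' @param seed Master seed; per-admission seeds derive from it, so the
#'   output is byte-identical across runs and platforms.
#' @param readmission_rate Fraction of admissions assigned to an existing
#'   patient.
#' @param rise,missingness,noise Passed to every [scenario_spec()].
#' @return List: `tables` (list of the four data.frames), `labels`
#'   (one row per admission), `episode_labels` (planted episodes).
#' @export
generate_cohort <- function(n,
                            mix = c(admission_shock = 0.09,
                                    admission_sepsis = 0.18,
                                    late_sepsis = 0.03,
                                    prophylaxis_only = 0.15,
                                    clean = 0.55),
                            seed = 1, readmission_rate = 0.05,
                            rise = 4, missingness = 0, noise = 0) {
  fail_if(n < 0, "n must be non-negative")
  fail_if(abs(sum(mix) - 1) > 1e-8, "mix proportions must sum to 1")
  fail_if(!all(names(mix) %in% .archetypes), "unknown archetype in mix")

  draws <- with_seed(seed, list(
    arch = sample(names(mix), n, replace = TRUE, prob = mix),
    seeds = sample.int(.Machine$integer.max - 1, max(n, 1)),
    readm = stats::runif(max(n, 1))
  ))
  wid <- max(4, nchar(n))
  parts <- vector("list", n)
  patient_pool <- character(0)
  for (i in seq_len(n)) {
    adm_id <- sprintf("adm%0*d", wid, i)
    pat_id <- if (i > 1 && draws$readm[i] < readmission_rate)
      patient_pool[((i * 7) %% (i - 1)) + 1] else sprintf("pat%0*d", wid, i)
    patient_pool <- c(patient_pool, pat_id)
    spec <- scenario_spec(draws$arch[i], rise = rise,
                          missingness = missingness, noise = noise)
    parts[[i]] <- generate_admission(spec, draws$seeds[i], adm_id, pat_id)
  }
  bind <- function(field) {
    dfs <- lapply(parts, `[[`, field)
    if (!length(dfs)) return(NULL)
    do.call(rbind, c(dfs, list(make.row.names = FALSE)))
  }
  if (n == 0) {
    z <- generate_admission(scenario_spec("clean"), 1)
    tables <- lapply(z[c("admissions", "drugs", "measurements", "cultures")],
                     function(df) df[0, , drop = FALSE])
    return(list(tables = tables,
                labels = z$label[0, , drop = FALSE],
                episode_labels = z$episode_labels[0, , drop = FALSE]))
  }
  list(
    tables = list(admissions = bind("admissions"), drugs = bind("drugs"),
                  measurements = bind("measurements"),
                  cultures = bind("cultures")),
    labels = bind("label"),
    episode_labels = bind("episode_labels")
  )
}

#' Write a synthetic cohort to CSV files
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$tables$admissions, file.path(dir, "admissions.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$tables$drugs, file.path(dir, "drugitems.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$tables$measurements,
                   file.path(dir, "numericitems.csv"), row.names = FALSE)
  utils::write.csv(cohort$tables$cultures, file.path(dir, "cultures.csv"),
                   row.names = FALSE)
  con <- file(file.path(dir, "labels.jsonl"), open = "wt")
  for (i in seq_len(nrow(cohort$labels)))
    writeLines(jsonlite::toJSON(as.list(cohort$labels[i, , drop = FALSE]),
                                auto_unbox = TRUE, na = "null"), con)
  close(con)
  invisible(dir)
}

#' Compare recovered episodes with planted labels
#'
#' Matches episodes to planted labels on admission and onset day; a match
#' also requires the shock flag to agree.
#'
#' @param phenotype Output of [phenotype_cohort()].
#' @param episode_labels Planted episode labels from [generate_cohort()].
#' @return List: `precision`, `recall`, `n_recovered`, `n_planted`.
#' @export
score_label_recovery <- function(phenotype, episode_labels) {
  rec <- phenotype$episodes
  key <- function(df) paste(df$admission_id, df$onset_day, df$shock)
  hits <- sum(key(rec) %in% key(episode_labels))
  list(
    precision = if (nrow(rec)) hits / nrow(rec) else NA_real_,
    recall = if (nrow(episode_labels)) hits / nrow(episode_labels) else NA_real_,
    n_recovered = nrow(rec),
    n_planted = nrow(episode_labels)
  )
}
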