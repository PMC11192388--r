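#' SOFA component thresholds
#'
#' Cut-points and co-conditions for the six Sequential Organ Failure
#' Assessment components. These follow the standard SOFA definition and are
#' deliberately configurable: a site can load a variant from a YAML file
#' (see [read_sofa_thresholds()]) without any code change.
#'
#' Units: PaO2:FiO2 in mmHg, platelets in 10^9/L, bilirubin and creatinine
#' in umol/L, vasopressor rates in ug/kg/min, urine output in mL/day.
#'
#' @param file Optional YAML file with the same structure; `NULL` uses the
#'   built-in defaults.
#' @return A list of class `sofa_thresholds`.
#' @export
sofa_thresholds <- function(file = NULL) {
  thr <- list(
    respiration = list(
      # PF below each cut-point (strict <) earns one more point; scores 3-4
      # additionally require ventilatory support, otherwise capped.
      pf_cutpoints = c(400, 300, 200, 100),
      cap_without_ventilation = 2
    ),
    coagulation = list(platelet_cutpoints = c(150, 100, 50, 20)), # strict <
    liver = list(
      bilirubin_min = c(20, 33, 102),   # inclusive lower bounds for 1..3
      bilirubin_gt4 = 204               # strict > for score 4
    ),
    cardiovascular = list(
      map_lt = 70,
      dopamine_mid = 5,    # dopamine <= mid -> 2, > mid -> 3
      dopamine_high = 15,  # dopamine > high -> 4
      norad_high = 0.1     # noradrenaline/adrenaline <= 0.1 -> 3, > -> 4
    ),
    cns = list(gcs_le = c(14, 12, 9), gcs_lt4 = 6),
    renal = list(
      creatinine_min = c(110, 171, 300), # inclusive lower bounds for 1..3
      creatinine_gt4 = 440,              # strict > for score 4
      urine_lt3 = 500,
      urine_lt4 = 200
    )
  )
  if (!is.null(file)) {
    loaded <- yaml::read_yaml(file)
    thr <- utils::modifyList(thr, loaded)
  }
  validate_sofa_thresholds(thr)
  structure(thr, class = "sofa_thresholds")
}

#' @rdname sofa_thresholds
#' @export
read_sofa_thresholds <- function(file) sofa_thresholds(file = file)

validate_sofa_thresholds <- function(thr) {
  ord_desc <- function(x) all(diff(x) < 0)
  ord_asc <- function(x) all(diff(x) > 0)
  fail_if(!ord_desc(thr$respiration$pf_cutpoints), "PF cut-points must be strictly decreasing")
  fail_if(!ord_desc(thr$coagulation$platelet_cutpoints), "platelet cut-points must be strictly decreasing")
  fail_if(!ord_asc(thr$liver$bilirubin_min), "bilirubin cut-points must be strictly increasing")
  fail_if(!ord_asc(thr$renal$creatinine_min), "creatinine cut-points must be strictly increasing")
  fail_if(!ord_desc(thr$cns$gcs_le), "GCS cut-points must be strictly decreasing")
  invisible(thr)
}

#' Antibiotic spectrum rank table
#'
#' Four-level spectrum classification of ICU antibiotics (1 narrow to
#' 4 restricted), used to define escalation of antibiotic therapy.
#' Cefazoline is carried in the table so that administrations of it validate
#' at ingest, but it is treated as prophylactic in its entirety and can
#' never appear in treatment-only output.
#'
#' @param file Optional CSV with columns `drug_name,rank` replacing the
#'   built-in table. A copy of the default table ships at
#'   `system.file("extdata", "antibiotic_ranks.csv", package = "icusepsis")`.
#' @return A data.frame with columns `drug_name` (lower case) and `rank`.
#' @export
antibiotic_rank_table <- function(file = NULL) {
  if (!is.null(file)) {
    tab <- utils::read.csv(file, stringsAsFactors = FALSE)
    fail_if(!all(c("drug_name", "rank") %in% names(tab)),
            "rank table needs columns drug_name, rank")
    tab$drug_name <- tolower(trimws(tab$drug_name))
    tab$rank <- as.integer(tab$rank)
    fail_if(!all(tab$rank %in% 1:4), "ranks must be in 1..4")
    fail_if(anyDuplicated(tab$drug_name) > 0, "duplicate drug names in rank table")
    return(tab[, c("drug_name", "rank")])
  }
  data.frame(
    drug_name = c(
      "imipenem", "meropenem", "colistin", "amikacin", "linezolid",
      "neomycin sulphate", "tigecycline", "daptomycin",
      "vancomycin", "gentamicin", "ceftazidime", "piperacillin",
      "ceftriaxone", "ciprofloxacin", "co-amoxiclav", "levofloxacin",
      "erythromycin", "cefuroxime", "clindamycin", "cefotaxime",
      "clarithromycin", "azithromycin", "norfloxacin", "moxifloxacin",
      "metronidazole", "co-trimoxazole", "amoxicillin", "tobramycin",
      "benzylpenicillin", "doxycycline", "feneticillin", "nitrofurantoin",
      "cefazoline"
    ),
    rank = c(rep(4L, 8), rep(3L, 4), rep(2L, 12), rep(1L, 8), 1L),
    stringsAsFactors = FALSE
  )
}

#' Spectrum rank of an antibiotic
#'
#' @param drug_name Antibiotic name (case-insensitive).
#' @param table Rank table, see [antibiotic_rank_table()].
#' @return Integer rank in 1..4.
#' @export
rank_of <- function(drug_name, table = antibiotic_rank_table()) {
  key <- tolower(trimws(drug_name))
  i <- match(key, table$drug_name)
  if (anyNA(i)) {
    bad <- unique(key[is.na(i)])
    near <- unlist(lapply(bad, function(b) {
      hits <- agrep(b, table$drug_name, max.distance = 0.3, value = TRUE)
      if (length(hits)) paste0(b, " (did you mean: ", paste(hits, collapse = ", "), "?)") else b
    }))
    stop("unknown antibiotic(s): ", paste(near, collapse = "; "), call. = FALSE)
  }
  table$rank[i]
}

#' Cohort phenotyping configuration
#'
#' Houses every threshold, drug list, window and toggle used by the
#' pipeline. Defaults encode the study conditions: adults (>= 18 y) with an
#' ICU stay of at least 1 hour, day-0 exclusion at >= 3 missing SOFA
#' components, a 2-point SOFA rise, a strict 72 h re-episode gap, a 15-day
#' onset cap, lactate > 2 mmol/L for shock, a 4-day selective digestive
#' decontamination cefotaxime course, and a 6 h noradrenaline minimum in the
#' corresponding sensitivity variant.
#'
#' @param min_age_years Minimum age for inclusion.
#' @param min_stay_hours Minimum ICU stay, hours.
#' @param day0_max_missing_components Exclude an admission when at least
#'   this many of the six day-0 SOFA components are missing.
#' @param thresholds A [sofa_thresholds()] object.
#' @param rank_table An [antibiotic_rank_table()] data.frame.
#' @param vasopressor_names Recognised vasopressor drug names.
#' @param dedup_window_hours Minimum gap (strict >) between episode onsets.
#' @param max_onset_day Episodes with onset after this day are discarded.
#' @param lactate_shock_threshold Lactate must exceed (strict >) this,
#'   mmol/L, for septic shock.
#' @param sdd_days Length of the prophylactic cefotaxime course, days.
#' @param prophylaxis Named list of rule toggles: `sdd_cefotaxime`,
#'   `elective_day0`, `cardiac_vancomycin`, `low_dose_erythromycin`,
#'   `cefazoline`, plus `erythromycin_low_dose_mg` and
#'   `erythromycin_min_daily` defining "low dose".
#' @param variant One of `"main"`, `"norad_6h"`, `"culture_required"`,
#'   `"drop_single_day"` selecting the sensitivity variant.
#' @param norad_min_hours Under variant `norad_6h`, noradrenaline exposures
#'   with at most this many cumulative in-window hours are ignored for the
#'   cardiovascular component.
#' @param culture_window_hours Under variant `culture_required`, half-width
#'   of the window around the first escalated dose in which a culture must
#'   fall.
#' @param onset_convention `"earliest"` (default) labels an episode with the
#'   first day of its evidence window; `"latest"` with the last.
#' @param death_day_impute `"all_missing"` imputes the death-day total to 24
#'   only when no component is computable; `"any_missing"` whenever at least
#'   one is missing.
#' @param fio2_default FiO2 assumed when PaO2 is recorded without FiO2
#'   (room air).
#' @param rng_seed Optional integer seed recorded in run manifests.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(min_age_years = 18,
                          min_stay_hours = 1,
                          day0_max_missing_components = 3,
                          thresholds = sofa_thresholds(),
                          rank_table = antibiotic_rank_table(),
                          vasopressor_names = c("noradrenaline", "adrenaline",
                                                "dopamine", "dobutamine",
                                                "vasopressin", "phenylephrine"),
                          dedup_window_hours = 72,
                          max_onset_day = 15,
                          lactate_shock_threshold = 2,
                          sdd_days = 4,
                          prophylaxis = list(),
                          variant = c("main", "norad_6h", "culture_required",
                                      "drop_single_day"),
                          norad_min_hours = 6,
                          culture_window_hours = 24,
                          onset_convention = c("earliest", "latest"),
                          death_day_impute = c("all_missing", "any_missing"),
                          fio2_default = 0.21,
                          rng_seed = NULL) {
  variant <- match.arg(variant)
  onset_convention <- match.arg(onset_convention)
  death_day_impute <- match.arg(death_day_impute)
  prophylaxis <- utils::modifyList(list(
    sdd_cefotaxime = TRUE,
    elective_day0 = TRUE,
    cardiac_vancomycin = TRUE,
    low_dose_erythromycin = TRUE,
    cefazoline = TRUE,
    erythromycin_low_dose_mg = 250,
    erythromycin_min_daily = 4
  ), prophylaxis)

  fail_if(min_stay_hours <= 0, "min_stay_hours must be positive")
  fail_if(dedup_window_hours <= 0, "dedup_window_hours must be positive")
  fail_if(max_onset_day <= 0, "max_onset_day must be positive")
  fail_if(norad_min_hours <= 0, "norad_min_hours must be positive")
  fail_if(culture_window_hours <= 0, "culture_window_hours must be positive")
  fail_if(sdd_days <= 0, "sdd_days must be positive")
  fail_if(day0_max_missing_components < 1 || day0_max_missing_components > 6,
          "day0_max_missing_components must be in 1..6")

  structure(list(
    min_age_years = min_age_years,
    min_stay_hours = min_stay_hours,
    day0_max_missing_components = as.integer(day0_max_missing_components),
    thresholds = thresholds,
    rank_table = rank_table,
    vasopressor_names = tolower(vasopressor_names),
    dedup_window_hours = dedup_window_hours,
    max_onset_day = as.integer(max_onset_day),
    lactate_shock_threshold = lactate_shock_threshold,
    sdd_days = as.integer(sdd_days),
    prophylaxis = prophylaxis,
    variant = variant,
    norad_min_hours = norad_min_hours,
    culture_window_hours = culture_window_hours,
    onset_convention = onset_convention,
    death_day_impute = death_day_impute,
    fio2_default = fio2_default,
    rng_seed = rng_seed
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  variant:", x$variant, "\n")
  cat("  inclusion: age >=", x$min_age_years, "y; stay >=", x$min_stay_hours,
      "h; exclude if >=", x$day0_max_missing_components,
      "missing day-0 SOFA components\n")
  cat("  episodes: rise >= 2; dedup >", x$dedup_window_hours,
      "h; onset <= day", x$max_onset_day, "\n")
  cat("  shock: vasopressor + lactate >", x$lactate_shock_threshold, "mmol/L\n")
  invisible(x)
}
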