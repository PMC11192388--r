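# Ingest and validation of the four cohort tables, plus the admission
# inclusion/exclusion flow.

.admission_cols <- c("admission_id", "patient_id", "age_years", "sex", "unit",
                     "admit_time", "discharge_time", "urgency", "category",
                     "specialty", "cardiac_surgery", "died_in_icu", "death_time")
.drug_cols <- c("admission_id", "drug_name", "drug_class", "route",
                "dose_amount", "dose_unit", "rate_ug_kg_min",
                "start_time", "stop_time")
.measurement_cols <- c("admission_id", "variable", "value", "time")
.culture_cols <- c("admission_id", "specimen", "time")

.measurement_vars <- c("platelets_10e9_L", "bilirubin_umol_L",
                       "creatinine_umol_L", "lactate_mmol_L", "pao2_mmHg",
                       "fio2_fraction", "map_mmHg", "gcs_total", "urine_mL",
                       "ventilated", "heart_rate_bpm", "spo2_fraction")
.culture_specimens <- c("blood", "urine", "wound", "catheter", "faecal",
                        "drain", "throat", "nasal", "rectal", "perineum")

#' Read and validate the four cohort input tables
#'
#' Reads `admissions`, `drugitems`, `numericitems` and `cultures` CSV files,
#' applies type and range validation row by row, and cross-checks
#' referential integrity. Rows that violate an invariant (for example an
#' FiO2 above 1, an antibiotic absent from the rank table, or an
#' elective-medical admission) are dropped and reported in the `rejected`
#' element with a per-row diagnostic; structural problems (missing columns,
#' records referencing an unknown admission) raise errors.
#'
#' @param paths Named list or vector with elements `admissions`,
#'   `drugitems`, `numericitems`, `cultures` giving file paths; or a single
#'   directory containing files with those names plus `.csv`.
#' @param config A [cohort_config()].
#' @return A list of class `cohort_tables` with elements `admissions`,
#'   `drugs`, `measurements`, `cultures` (validated data.frames) and
#'   `rejected` (data.frame of dropped rows: `table`, `row`, `reason`).
#' @export
read_cohort_tables <- function(paths, config = cohort_config()) {
  if (length(paths) == 1 && is.character(paths) && dir.exists(paths)) {
    paths <- file.path(paths, c(admissions = "admissions.csv",
                                drugitems = "drugitems.csv",
                                numericitems = "numericitems.csv",
                                cultures = "cultures.csv"))
    names(paths) <- c("admissions", "drugitems", "numericitems", "cultures")
  }
  need <- c("admissions", "drugitems", "numericitems", "cultures")
  fail_if(!all(need %in% names(paths)), "paths must name %s",
          paste(need, collapse = ", "))
  for (p in unlist(paths[need])) fail_if(!file.exists(p), "file not found: %s", p)

  rd <- function(p) utils::read.csv(p, stringsAsFactors = FALSE)
  validate_cohort_tables(list(
    admissions = rd(paths[["admissions"]]),
    drugs = rd(paths[["drugitems"]]),
    measurements = rd(paths[["numericitems"]]),
    cultures = rd(paths[["cultures"]])
  ), config)
}

#' Validate in-memory cohort tables
#'
#' The same validation as [read_cohort_tables()] applied to data.frames
#' already in memory (as produced by [generate_cohort()]).
#'
#' @param tables List with `admissions`, `drugs`, `measurements`, `cultures`.
#' @param config A [cohort_config()].
#' @return A `cohort_tables` list; see [read_cohort_tables()].
#' @export
validate_cohort_tables <- function(tables, config = cohort_config()) {
  adm <- tables$admissions
  drg <- tables$drugs
  mes <- tables$measurements
  cul <- tables$cultures

  chk_cols <- function(df, cols, what) {
    missing <- setdiff(cols, names(df))
    fail_if(length(missing) > 0, "%s: missing required column(s): %s",
            what, paste(missing, collapse = ", "))
  }
  chk_cols(adm, .admission_cols, "admissions")
  chk_cols(drg, .drug_cols, "drugitems")
  chk_cols(mes, .measurement_cols, "numericitems")
  chk_cols(cul, .culture_cols, "cultures")

  rejected <- list()
  note <- function(table, rows, reason) {
    if (length(rows)) rejected[[length(rejected) + 1]] <<- data.frame(
      table = table, row = rows, reason = reason, stringsAsFactors = FALSE)
  }

  # --- admissions ---------------------------------------------------------
  adm$cardiac_surgery <- as.logical(adm$cardiac_surgery)
  adm$died_in_icu <- as.logical(adm$died_in_icu)
  for (col in c("age_years", "admit_time", "discharge_time", "death_time"))
    adm[[col]] <- suppressWarnings(as.numeric(adm[[col]]))
  bad <- which(is.na(adm$admit_time) | is.na(adm$discharge_time) |
                 is.na(adm$age_years) | adm$age_years < 0)
  note("admissions", bad, "unparseable or negative age/time")
  ok <- setdiff(seq_len(nrow(adm)), bad)
  bad2 <- ok[adm$discharge_time[ok] < adm$admit_time[ok]]
  note("admissions", bad2, "discharge before admission")
  bad3 <- ok[adm$urgency[ok] == "elective" & adm$category[ok] == "medical"]
  note("admissions", bad3, "elective medical admission is not a valid stratum")
  bad4 <- ok[!adm$sex[ok] %in% c("female", "male", "unknown") |
               !adm$unit[ok] %in% c("ICU", "MCU") |
               !adm$urgency[ok] %in% c("elective", "emergency") |
               !adm$category[ok] %in% c("surgical", "medical")]
  note("admissions", bad4, "invalid sex/unit/urgency/category code")
  died <- ok[adm$died_in_icu[ok] %in% TRUE]
  bad5 <- died[is.na(adm$death_time[died]) |
                 adm$death_time[died] < adm$admit_time[died] |
                 adm$death_time[died] > adm$discharge_time[died]]
  note("admissions", bad5, "died_in_icu without valid in-stay death_time")
  drop <- unique(c(bad, bad2, bad3, bad4, bad5))
  if (length(drop)) adm <- adm[-drop, , drop = FALSE]
  fail_if(anyDuplicated(adm$admission_id) > 0, "duplicate admission_id values")

  known_ids <- adm$admission_id
  ref_check <- function(df, what) {
    unknown <- setdiff(unique(df$admission_id), known_ids)
    fail_if(length(unknown) > 0,
            "%s references admission_id(s) absent from admissions: %s",
            what, paste(utils::head(unknown, 5), collapse = ", "))
  }

  # --- drug administrations ----------------------------------------------
  for (col in c("dose_amount", "rate_ug_kg_min", "start_time", "stop_time"))
    drg[[col]] <- suppressWarnings(as.numeric(drg[[col]]))
  drg$drug_name <- tolower(trimws(drg$drug_name))
  bad <- which(is.na(drg$start_time) | is.na(drg$stop_time) |
                 drg$stop_time < drg$start_time)
  note("drugitems", bad, "missing or inverted start/stop times")
  ok <- setdiff(seq_len(nrow(drg)), bad)
  is_abx <- ok[drg$drug_class[ok] == "antibiotic"]
  unknown_abx <- is_abx[!drg$drug_name[is_abx] %in% config$rank_table$drug_name]
  note("drugitems", unknown_abx,
       paste0("antibiotic not in rank table: ",
              drg$drug_name[unknown_abx]))
  is_vp <- ok[drg$drug_class[ok] == "vasopressor"]
  unknown_vp <- is_vp[!drg$drug_name[is_vp] %in% config$vasopressor_names]
  note("drugitems", unknown_vp, "vasopressor not in configured list")
  bad_rate <- ok[!is.na(drg$rate_ug_kg_min[ok]) & drg$rate_ug_kg_min[ok] < 0]
  note("drugitems", bad_rate, "negative infusion rate")
  drop <- unique(c(bad, unknown_abx, unknown_vp, bad_rate))
  if (length(drop)) drg <- drg[-drop, , drop = FALSE]
  ref_check(drg, "drugitems")

  # --- measurements -------------------------------------------------------
  mes$value <- suppressWarnings(as.numeric(mes$value))
  mes$time <- suppressWarnings(as.numeric(mes$time))
  bad <- which(is.na(mes$value) | is.na(mes$time) | mes$value < 0)
  note("numericitems", bad, "unparseable or negative value/time")
  ok <- setdiff(seq_len(nrow(mes)), bad)
  bad_var <- ok[!mes$variable[ok] %in% .measurement_vars]
  note("numericitems", bad_var, "unknown measurement variable")
  ok <- setdiff(ok, bad_var)
  bad_fio2 <- ok[mes$variable[ok] %in% c("fio2_fraction", "spo2_fraction") &
                   (mes$value[ok] <= 0 | mes$value[ok] > 1)]
  note("numericitems", bad_fio2, "fraction outside (0, 1]")
  bad_gcs <- ok[mes$variable[ok] == "gcs_total" &
                  (mes$value[ok] < 3 | mes$value[ok] > 15)]
  note("numericitems", bad_gcs, "GCS outside [3, 15]")
  drop <- unique(c(bad, bad_var, bad_fio2, bad_gcs))
  if (length(drop)) mes <- mes[-drop, , drop = FALSE]
  ref_check(mes, "numericitems")

  # --- cultures -----------------------------------------------------------
  cul$time <- suppressWarnings(as.numeric(cul$time))
  bad <- which(is.na(cul$time) | !cul$specimen %in% .culture_specimens)
  note("cultures", bad, "unknown specimen or unparseable time")
  if (length(bad)) cul <- cul[-bad, , drop = FALSE]
  ref_check(cul, "cultures")

  rejected <- if (length(rejected)) do.call(rbind, rejected) else
    data.frame(table = character(0), row = integer(0), reason = character(0),
               stringsAsFactors = FALSE)
  structure(list(admissions = adm, drugs = drg, measurements = mes,
                 cultures = cul, rejected = rejected),
            class = "cohort_tables")
}

#' Apply the admission inclusion/exclusion flow
#'
#' Exclusion reasons are assessed in a fixed order so that every admission
#' carries exactly one reason: unit (MCU), stay length (< 1 h), day-0 SOFA
#' missingness (>= 3 of 6 components missing), then age (< 18 y).
#'
#' @param admissions Validated admissions data.frame.
#' @param day0_missing Named integer vector: number of missing day-0 SOFA
#'   components per `admission_id` (see [day0_missing_components()]).
#' @param config A [cohort_config()].
#' @return List with `included` (admissions data.frame) and `flow`
#'   (a `flow_counts` list: `n_input`, `n_excluded_mcu`,
#'   `n_excluded_short_stay`, `n_excluded_missing_day0`, `n_excluded_age`,
#'   `n_final`).
#' @export
apply_inclusion_criteria <- function(admissions, day0_missing,
                                     config = cohort_config()) {
  n_input <- nrow(admissions)
  stay_h <- (admissions$discharge_time - admissions$admit_time) / MS_PER_HOUR
  miss <- day0_missing[match(admissions$admission_id, names(day0_missing))]
  miss[is.na(miss)] <- 6L  # no day-0 data at all

  reason <- rep(NA_character_, n_input)
  reason[is.na(reason) & admissions$unit == "MCU"] <- "mcu"
  reason[is.na(reason) & stay_h < config$min_stay_hours] <- "short_stay"
  reason[is.na(reason) & miss >= config$day0_max_missing_components] <- "missing_day0"
  reason[is.na(reason) & admissions$age_years < config$min_age_years] <- "age"

  flow <- structure(list(
    n_input = n_input,
    n_excluded_mcu = sum(reason == "mcu", na.rm = TRUE),
    n_excluded_short_stay = sum(reason == "short_stay", na.rm = TRUE),
    n_excluded_missing_day0 = sum(reason == "missing_day0", na.rm = TRUE),
    n_excluded_age = sum(reason == "age", na.rm = TRUE),
    n_final = sum(is.na(reason))
  ), class = "flow_counts")

  included <- admissions[is.na(reason), , drop = FALSE]
  excluded <- admissions[!is.na(reason), , drop = FALSE]
  excluded$exclusion_reason <- reason[!is.na(reason)]
  list(included = included, excluded = excluded, flow = flow)
}

#' @export
print.flow_counts <- function(x, ...) {
  cat("Admission flow:\n")
  cat("  input              ", x$n_input, "\n")
  cat("  - MCU              ", x$n_excluded_mcu, "\n")
  cat("  - stay < minimum   ", x$n_excluded_short_stay, "\n")
  cat("  - day-0 missingness", x$n_excluded_missing_day0, "\n")
  cat("  - under age        ", x$n_excluded_age, "\n")
  cat("  final              ", x$n_final, "\n")
  invisible(x)
}
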