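# Cohort-level orchestration: ingest -> inclusion -> SOFA -> escalation ->
# episodes -> groups, plus the file-based pipeline entry point.

#' Phenotype a whole cohort
#'
#' Runs the per-admission chain over validated tables: day-0 missingness,
#' the inclusion flow, daily SOFA series, prophylaxis filtering, regimens
#' and escalations, episode detection under the configured variant, shock
#' classification, and infection-status group assignment. Each admission's
#' phenotype depends only on its own records.
#'
#' @param tables A `cohort_tables` list (see [read_cohort_tables()] /
#'   [validate_cohort_tables()]).
#' @param config A [cohort_config()].
#' @return A list of class `cohort_phenotype`: `admissions` (included),
#'   `excluded`, `flow`, `episodes` (cohort-level data.frame), `groups`,
#'   `daily_sofa`, `regimen_days`, `covariates`, `per_admission` (named
#'   list of [detect_sepsis_episodes()] results), `config`, `counts`
#'   (stage counts).
#' @export
phenotype_cohort <- function(tables, config = cohort_config()) {
  if (!inherits(tables, "cohort_tables"))
    tables <- validate_cohort_tables(tables, config)
  day0 <- day0_missing_components(tables, config)
  incl <- apply_inclusion_criteria(tables$admissions, day0, config)
  adm <- incl$included

  mes_by <- split(tables$measurements, tables$measurements$admission_id)
  drg_by <- split(tables$drugs, tables$drugs$admission_id)
  cul_by <- split(tables$cultures, tables$cultures$admission_id)
  empty_mes <- tables$measurements[0, , drop = FALSE]
  empty_drg <- tables$drugs[0, , drop = FALSE]
  empty_cul <- tables$cultures[0, , drop = FALSE]

  per <- list()
  covs <- list()
  for (i in seq_len(nrow(adm))) {
    a <- adm[i, , drop = FALSE]
    id <- a$admission_id
    mes <- mes_by[[id]] %||% empty_mes
    drg <- drg_by[[id]] %||% empty_drg
    cul <- cul_by[[id]] %||% empty_cul
    res <- detect_sepsis_episodes(a, mes, drg, cul, config)
    per[[id]] <- res
    cov <- admission_covariates(a, mes, res$regimens,
                                res$series$total[res$series$day == 0L])
    vp <- drg[drg$drug_class == "vasopressor" &
                tolower(drg$drug_name) %in% config$vasopressor_names, ,
              drop = FALSE]
    cov$vasopressor_24h <- any(interval_on_day(vp$start_time - a$admit_time,
                                               vp$stop_time - a$admit_time, 0L))
    covs[[id]] <- cov
  }

  bind0 <- function(dfs, proto) {
    if (!length(dfs)) return(proto)
    do.call(rbind, c(dfs, list(make.row.names = FALSE)))
  }
  ep_proto <- data.frame(admission_id = character(0), rule = character(0),
                         evidence_lo = integer(0), evidence_hi = integer(0),
                         onset_day = integer(0), baseline_sofa = integer(0),
                         escalation_day = integer(0), shock = logical(0),
                         admission_onset = logical(0), end_day = integer(0),
                         stringsAsFactors = FALSE)
  sofa_proto <- data.frame(admission_id = character(0), day = integer(0),
                           resp = integer(0), coag = integer(0),
                           liver = integer(0), cardio = integer(0),
                           cns = integer(0), renal = integer(0),
                           total = integer(0), n_missing = integer(0),
                           rate_imputed = logical(0),
                           death_day_imputed = logical(0),
                           virtual = logical(0), stringsAsFactors = FALSE)
  reg_proto <- data.frame(admission_id = character(0), day = integer(0),
                          n_drugs = integer(0), max_rank = integer(0),
                          count_at_max = integer(0), has_iv = logical(0),
                          escalation = logical(0), new_course = logical(0),
                          drugs = character(0), stringsAsFactors = FALSE)
  episodes <- bind0(lapply(per, function(x) x$episodes), ep_proto)
  if (!nrow(episodes)) episodes <- ep_proto
  groups <- data.frame(
    admission_id = adm$admission_id,
    group = vapply(adm$admission_id, function(id)
      assign_admission_group(per[[id]]$episodes, per[[id]]$regimens), ""),
    stringsAsFactors = FALSE
  )
  daily_sofa <- bind0(lapply(per, function(x)
    x$series[!x$series$virtual, , drop = FALSE]), sofa_proto)
  regimen_days <- bind0(lapply(per, function(x) {
    r <- x$regimens
    r$drugs <- vapply(r$drugs, paste, "", collapse = ";")
    r
  }), reg_proto)

  counts <- list(
    n_input = incl$flow$n_input,
    n_included = incl$flow$n_final,
    n_escalation_days = sum(vapply(per, function(x)
      sum(x$regimens$escalation), 0L)),
    n_candidate_events = sum(vapply(per, function(x)
      nrow(x$candidates), 0L)),
    n_episodes = nrow(episodes),
    n_shock = sum(episodes$shock)
  )

  structure(list(
    admissions = adm, excluded = incl$excluded, flow = incl$flow,
    episodes = episodes, groups = groups, daily_sofa = daily_sofa,
    regimen_days = regimen_days,
    covariates = bind0(covs, data.frame(
      admission_id = character(0), patient_id = character(0),
      max_heart_rate = numeric(0), min_map = numeric(0),
      max_fio2 = numeric(0), min_spo2 = numeric(0), min_pao2 = numeric(0),
      min_pf = numeric(0), min_gcs = numeric(0), max_creatinine = numeric(0),
      min_platelets = numeric(0), max_bilirubin = numeric(0),
      max_sofa_day0 = integer(0), vasopressor_24h = logical(0),
      ventilated_24h = logical(0), escalation_24h = logical(0),
      iv_abx_ge4d = logical(0), los_hours = numeric(0), died = logical(0),
      stringsAsFactors = FALSE)),
    per_admission = per, config = config, counts = counts
  ), class = "cohort_phenotype")
}

#' @export
print.cohort_phenotype <- function(x, ...) {
  cat("<cohort_phenotype>", x$counts$n_included, "included admissions;",
      x$counts$n_episodes, "sepsis episodes (", x$counts$n_shock,
      "with shock ), variant:", x$config$variant, "\n")
  invisible(x)
}

#' Run the full pipeline against files
#'
#' Reads the four CSV inputs, phenotypes the cohort under the configured
#' variant, writes all stage outputs (daily SOFA and regimens as CSV,
#' episodes and flow counts as JSON Lines, group assignments and summary
#' tables as CSV), and writes a run manifest recording input digests, a
#' configuration hash, and per-stage counts. Reruns with identical inputs
#' and configuration are bitwise identical.
#'
#' @param input Directory containing `admissions.csv`, `drugitems.csv`,
#'   `numericitems.csv`, `cultures.csv`, or a named list of paths.
#' @param out_dir Output directory (created if needed).
#' @param config A [cohort_config()]; its `variant` field selects the run.
#' @return The run manifest (list), invisibly; also written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(input, out_dir, config = cohort_config()) {
  tables <- read_cohort_tables(input, config)
  ph <- phenotype_cohort(tables, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  w <- function(df, name) utils::write.csv(
    df, file.path(out_dir, name), row.names = FALSE)
  w(ph$daily_sofa, "daily_sofa.csv")
  w(ph$regimen_days, "regimens.csv")
  w(ph$groups, "groups.csv")
  summ <- summarize_strata(ph)
  w(summ$counts, "summary_counts.csv")
  w(summ$physiology, "summary_physiology.csv")
  w(usage_table(ph), "antibiotic_usage.csv")

  ep_path <- file.path(out_dir, "episodes.jsonl")
  con <- file(ep_path, open = "wt")
  if (nrow(ph$episodes)) {
    for (i in seq_len(nrow(ph$episodes))) {
      writeLines(jsonlite::toJSON(as.list(ph$episodes[i, , drop = FALSE]),
                                  auto_unbox = TRUE, na = "null", digits = NA),
                 con)
    }
  }
  close(con)
  writeLines(jsonlite::toJSON(unclass(ph$flow), auto_unbox = TRUE),
             file.path(out_dir, "flow_counts.json"))

  in_paths <- if (length(input) == 1 && dir.exists(input))
    file.path(input, c("admissions.csv", "drugitems.csv", "numericitems.csv",
                       "cultures.csv")) else unlist(input)
  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    variant = config$variant,
    inputs = stats::setNames(
      vapply(in_paths, function(p) rlang::hash(readLines(p)), ""),
      basename(in_paths)),
    counts = c(list(flow = unclass(ph$flow)), ph$counts),
    outputs = list(dir = out_dir,
                   files = c("daily_sofa.csv", "regimens.csv", "groups.csv",
                             "summary_counts.csv", "summary_physiology.csv",
                             "antibiotic_usage.csv", "episodes.jsonl",
                             "flow_counts.json"))
  )
  # write atomically: render to a temp file, then rename
  tmp <- file.path(out_dir, ".manifest.json.tmp")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             tmp)
  file.rename(tmp, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
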