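# The three pre-specified sensitivity analyses, expressed as configuration
# transforms over the main pipeline.

#' Configuration for a sensitivity variant
#'
#' Returns the given configuration with its `variant` field switched:
#' * `norad_6h`: the cardiovascular SOFA component ignores noradrenaline
#'   infusions of at most 6 cumulative hours in a day window;
#' * `culture_required`: an escalation day counts as suspected infection
#'   only when a microbial culture was sampled within 24 h of the first
#'   dose of the escalated regimen;
#' * `drop_single_day`: episodes whose escalated regimen lasted a single
#'   calendar day (with the stay continuing) are not classified as sepsis.
#'
#' @param config A [cohort_config()].
#' @param id `"main"`, `"norad_6h"`, `"culture_required"` or
#'   `"drop_single_day"`.
#' @return The modified configuration.
#' @export
variant_config <- function(config = cohort_config(),
                           id = c("main", "norad_6h", "culture_required",
                                  "drop_single_day")) {
  id <- match.arg(id)
  config$variant <- id
  config
}

#' Phenotype a cohort under every analysis variant
#'
#' Convenience wrapper running the main analysis and the three sensitivity
#' variants over the same tables.
#'
#' @param tables A `cohort_tables` list.
#' @param config Base [cohort_config()].
#' @param variants Character vector of variant ids to run.
#' @return Named list of [phenotype_cohort()] results.
#' @export
phenotype_all_variants <- function(tables, config = cohort_config(),
                                   variants = c("main", "norad_6h",
                                                "culture_required",
                                                "drop_single_day")) {
  stats::setNames(lapply(variants, function(v)
    phenotype_cohort(tables, variant_config(config, v))), variants)
}
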