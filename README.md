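# icusepsis

Sepsis-3 phenotyping of ICU electronic health records in R.

Sepsis epidemiology depends on how you define sepsis. The 2016 Sepsis-3
consensus defines it as life-threatening organ dysfunction caused by a
dysregulated host response to infection, operationalised as a rise in the
Sequential Organ Failure Assessment (SOFA) score of **ΔSOFA ≥ 2** together
with suspected infection. `icusepsis` implements a complete, testable
version of this phenotype for tabular ICU extracts (admissions, drug
administrations, lab/vital measurements, microbial cultures), for
researchers characterising septic cohorts in de-identified critical-care
databases.

The pipeline:

1. **Cohort ingest and inclusion** — schema and range validation of the
   four CSV tables; exclusion of medium-care (MCU) admissions, stays
   < 1 h, admissions with ≥ 3 of 6 SOFA components missing on day 0, and
   patients under 18, each counted once in a fixed order.
2. **Daily SOFA scoring** — six components (respiration PaO₂:FiO₂ with a
   ventilation requirement for scores 3–4, coagulation, liver,
   cardiovascular MAP/vasopressor branches, CNS, renal
   creatinine/urine), each scored on the worst value per 24 h window.
   Pre-ICU SOFA is assumed 0 (a virtual pre-admission day), and an
   incomputable total on the day of death is set to the maximum of 24.
3. **Suspected infection** — antibiotic spectrum ranks 1 (narrow) to
   4 (restricted); an escalation day is a new IV course, a rise in maximum
   rank day-over-day, or more agents at the unchanged maximum rank.
   Prophylaxis is stripped first: selective-digestive-decontamination
   cefotaxime (days 0–3), elective-surgery day-0 antibiotics,
   post-cardiac-surgery vancomycin, low-dose (250 mg × 4/day)
   erythromycin, and all cefazoline. A cefotaxime course running past
   day 3 opens a flexible episode-matching window on days 1–4.
4. **Episodes** — a sepsis episode is a consecutive-day SOFA rise ≥ 2 with
   escalation on either day, or a rise ≥ 2 across the days flanking an
   escalation. Repeat episodes must start strictly more than 72 h after
   the previous onset; onsets after day 15 are discarded. Septic shock
   additionally requires a vasopressor in the evidence window and lactate
   > 2 mmol/L.
5. **Sensitivity variants** — (a) ≥ 6 h of noradrenaline for the
   cardiovascular component, (b) a culture within 24 h of the escalated
   regimen's first dose, (c) dropping single-day escalated regimens.
6. **Reporting** — infection-status groups (septic shock / sepsis without
   shock / antibiotics without sepsis / not on antibiotics), stratum
   summary tables, antibiotic course/usage accounting, and SOFA-component
   trajectories aligned on onset, discharge or death.
7. **Synthetic cohorts** — `generate_cohort()` plants labelled episodes
   (admission sepsis/shock, late sepsis, prophylaxis-only, clean, and
   excluded archetypes) so every stage is verifiable end to end.

## Worked example

```r
library(icusepsis)

cohort <- generate_cohort(200, seed = 42)          # synthetic, labelled
tables <- validate_cohort_tables(cohort$tables)
ph     <- phenotype_cohort(tables)                  # main analysis
ph
#> <cohort_phenotype> 200 included admissions; 64 sepsis episodes ( 22 with shock ), variant: main

table(ph$groups$group)
#> antibiotics_without_sepsis         not_on_antibiotics
#>                          5                        136
#>       sepsis_without_shock               septic_shock
#>                         37                         22

ph$episodes[1:3, c("admission_id", "rule", "onset_day", "baseline_sofa",
                   "shock", "end_day")]
#>   admission_id               rule onset_day baseline_sofa shock end_day
#> 1      adm0001 A_consecutive_rise         0             0  TRUE       4
#> 2      adm0002 A_consecutive_rise         0             0  TRUE       4
#> 3      adm0005 A_consecutive_rise         0             0 FALSE       4

score_label_recovery(ph, cohort$episode_labels)[c("precision", "recall")]
#> $precision
#> [1] 1
#> $recall
#> [1] 1
```

Each episode row gives the detection rule (`A_consecutive_rise`,
`B_flanking_rise`, or `C_sdd_flexible`), the onset day (0 = sepsis on ICU
admission, enabled by the assumed pre-ICU SOFA of 0), the baseline SOFA
(the lower of the two evidence-day totals), the shock flag, and the day
the episode ended (SOFA back at baseline or antibiotics stopped; `NA`
when censored at discharge). On a noiseless synthetic cohort the planted
episodes are recovered with precision = recall = 1.

A file-based run (`run_pipeline("inputs/", "out/")`) writes daily SOFA
scores, regimens, episodes (JSON Lines), group assignments, summary
tables and a deterministic run manifest; a thin CLI with `simulate` and
`phenotype` subcommands ships in `inst/scripts/icusepsis-cli.R`.

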