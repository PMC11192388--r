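---
title: "Sepsis-3 phenotyping of ICU admissions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sepsis-3 phenotyping of ICU admissions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icusepsis)
```

`icusepsis` turns four tabular ICU extracts — admissions, drug
administrations, numeric measurements, and microbial cultures — into
sepsis and septic-shock episodes under the Sepsis-3 consensus definition,
together with the cohort tables an epidemiological description needs.
This vignette explains the model the package implements, the parameters
that matter, the missing-data policies, and the design decisions taken
where the underlying methodology is genuinely open. It reports no
empirical result beyond what the package's own tests and acceptance
script compute.

## The phenotype

Sepsis-3 defines sepsis as life-threatening organ dysfunction caused by a
dysregulated host response to infection. The package operationalises the
two halves as:

* **Organ dysfunction**: a rise of at least 2 points in the total SOFA
  score between consecutive 24 h windows, or across the two days flanking
  an antibiotic escalation. SOFA components are assumed zero before ICU
  admission, so a day-0 total of 2 or more already qualifies against the
  virtual pre-admission baseline — this is what makes "sepsis on ICU
  admission" detectable at all in a dataset with no pre-ICU record.
* **Suspected infection**: a new course of antibiotics (one or more doses
  in a patient not already receiving antibiotics) or an escalation of
  therapy, with at least one antibiotic given intravenously that day.
  Escalation is judged on a four-level spectrum ranking (1 narrow to
  4 restricted): the maximum rank rises day-over-day, or the number of
  agents at the unchanged maximum rank rises.

**Septic shock** additionally requires a vasopressor administration
intersecting the episode's evidence window and a lactate strictly above
2 mmol/L in that window. Repeat episodes must begin strictly more than
72 h after the previous onset; onsets after day 15 of the stay are
discarded as likely nosocomial processes outside the admission phenotype.

### Time model

All event times are integer milliseconds on the axis of each admission's
admit time (the convention of de-identified critical-care extracts). Day
`d` is the half-open window `[d·24 h, (d+1)·24 h)` from admission, so
windows partition the stay exhaustively and without overlap; a point dose
at an exact boundary belongs to the later window, while a nonzero
infusion interval contributes to every window it overlaps.

## Daily SOFA scoring

Each component is scored on its *worst* (score-maximising) value in the
window: minimum platelets, maximum bilirubin and creatinine, minimum GCS,
minimum MAP, and the worst-case oxygenation pairing min(PaO₂)/max(FiO₂).
The cut-points follow the standard SOFA table and ship as an editable
YAML configuration (`inst/extdata/sofa_thresholds.yaml`), so a site can
substitute variants without code change. Choices the standard leaves
open, resolved here and configurable where noted:

* **Respiration without ventilatory support** is capped at 2: the
  standard couples scores 3–4 to ventilation. A window with no recorded
  ventilation event is treated as not ventilated.
* **PaO₂ without FiO₂** assumes room air (FiO₂ 0.21).
* **Renal** takes the worse of the creatinine branch and the 24 h
  urine-output branch (urine volumes are summed per window).
* **Vasopressors**: dopamine, dobutamine, adrenaline and noradrenaline
  follow the standard rate branches (μg/kg/min, patient weight assumed
  already folded in by the data producer). Vasopressin and phenylephrine
  count as vasopressors for the shock criterion but have no branch in the
  standard cardiovascular table and so do not score. An exposure with a
  missing rate scores at the drug's minimum qualifying level
  (noradrenaline/adrenaline 3, dopamine/dobutamine 2) and is flagged
  `rate_imputed` for audit.

### Missing data

Missingness in routinely collected ICU data is non-random and cannot be
imputed away; the package makes three explicit, auditable choices:

* **Pre-ICU**: a virtual day −1 with SOFA 0 is prepended. It can supply
  the baseline of an admission episode but can never carry an escalation.
* **Within the stay**: a day's total is the sum of its non-missing
  components (missing contributes 0). Admissions with ≥ 3 of 6 components
  missing on day 0 are excluded (`day0_max_missing_components`; the
  threshold is configurable because "fewer than 3 components calculated"
  and "3 or more missing" differ with six components, and both readings
  should be reachable).
* **Day of death**: a death-day total that cannot be computed is set to
  the maximum of 24. By default this applies only when *all* six
  components are missing (`death_day_impute = "all_missing"`); the
  stricter `"any_missing"` mode imputes whenever any component is absent.
  Totals never exceed 24 and imputation can only occur on a death day —
  both are asserted by the test suite on every synthetic cohort.

The consequence of summing present components is that heavily missing
days bias totals downward, so rises can be missed; the trajectory
reporting therefore exposes the per-day fraction of incomputable
components rather than hiding it.

## Prophylaxis and the flexible SDD window

Escalation status must ignore prophylactic antibiotics. Five rules,
individually toggleable in `cohort_config()`:
cefotaxime doses starting on days 0–3 (selective digestive
decontamination), all antibiotics in the first 24 h of elective surgical
admissions, vancomycin on any day of a cardiac-surgery admission,
erythromycin at 250 mg given ≥ 4 times in a calendar day (fewer
administrations are conservatively kept as treatment), and all
cefazoline. "Prescribed" is operationalised as *administered* — the data
model records administrations, not orders.

A cefotaxime course that runs past day 3 implies an infection was
suspected during the prophylactic course (the local practice would
otherwise have switched to ceftriaxone). Because the timing within the
course is unknowable, days 1–4 then carry a *virtual* escalation: a
qualifying SOFA rise on consecutive days anywhere in that window forms an
episode with no recorded escalation (rule `C_sdd_flexible`). The flanking
rule only ever uses real escalation days. The asymmetry — removal keyed
on days 0–3, flexibility on days 1–4 — is deliberate and matches the
phenotype's published framing.

## Episodes: onset, baseline, deduplication, tracking

The onset is the **earliest** evidence day, clamped to day 0
(`onset_convention = "earliest"`, switchable to `"latest"`); the early
convention is what labels admission events as day 0. The baseline SOFA is
the lower of the two evidence-day totals (0 whenever the virtual day is
in evidence). Candidate events are deduplicated by a greedy forward scan
keeping onsets strictly more than 72 h apart, in whole-day units since no
finer onset timestamp exists; events after day 15 are dropped first.

An episode then persists while the daily total remains strictly above its
baseline *and* the patient remains on treatment antibiotics; the shock
state persists while the day's lactate stays above 2 mmol/L or a
vasopressor is still running. The end day is the first day the sepsis
condition fails, censored (`NA`) at discharge or death.

The shock assessment window is the episode's evidence days, not the whole
stay — a stated design choice (`shock` is about the episode, and a
vasopressor three weeks later should not reclassify it).

## Sensitivity variants

Three pre-specified variants are configuration transforms over the same
pipeline (`variant_config()`, `phenotype_all_variants()`):

* **`norad_6h`**: noradrenaline exposures totalling ≤ 6 h in a window are
  ignored for the cardiovascular component only — the shock vasopressor
  criterion is deliberately untouched, since the variant is scoped to
  SOFA calculation.
* **`culture_required`**: an escalation day counts as suspected infection
  only if a culture was sampled within ±24 h of the first dose of that
  day's escalated regimen (for virtual SDD days, the first cefotaxime
  dose of the day). The window is symmetric because only "within a
  24 hour period" is specified.
* **`drop_single_day`**: an episode whose escalated regimen was given on
  exactly one calendar day, with the stay continuing past the following
  day, is not classified as sepsis. Courses truncated by discharge or
  death are spared — stopping because the patient left is not evidence of
  a non-infectious diagnosis. The filter runs after deduplication, so it
  can only remove episodes; each variant's episode set is asserted to be
  a subset of the main analysis on every synthetic cohort.

## Cohort reporting

Admissions are partitioned into four infection-status groups keyed on
**admission-onset (day 0) episodes**: `septic_shock`,
`sepsis_without_shock`, then `antibiotics_without_sepsis` (any treatment
antibiotic during the stay — including admissions whose only episodes
began after day 0), and `not_on_antibiotics`. Keying on day 0 is
surprising but intentional: the group columns of an admission-level
summary table describe the state in which the patient *arrived*, and
later-onset episodes are reported in the episode table instead.

Percentages print at one decimal with halves rounded away from zero
(base R's `round()` rounds half to even, which does not reproduce
clinical-table formatting). An antibiotic *course* is a maximal run of
consecutive calendar days on which a drug was administered within one
admission; antibiotic-days count distinct (admission, drug, day) triples.

## The synthetic cohort generator

`generate_cohort()` emits the four input tables with planted ground
truth. Archetypes: `admission_shock`, `admission_sepsis`, `late_sepsis`,
`prophylaxis_only` (SDD cefotaxime, cefazoline, post-cardiac vancomycin,
low-dose erythromycin, plus a SOFA rise that must *not* become an
episode), `clean`, and two exclusion archetypes (`short_stay_excluded`,
`missing_day0_excluded`). Labs are generated as one worst value per
component per day at the centre of the intended score band; optional
noise jitters values within the band and optional missingness drops
components, so labels are exact at zero noise and degrade monotonically
with missingness — both properties are under test.

Defaults are fixed once and not tuned: the archetype mix (9% admission
shock, 18% admission sepsis, 3% late sepsis, 15% prophylaxis-only, 55%
clean) plants admission-onset sepsis in about 27% of admissions with
about a third in shock, the proportions of a mixed surgical-medical
tertiary ICU; planted rises default to 4 points with a boundary-tight
2-point option; per-archetype death probabilities give an overall ICU
mortality near 10%. What the generator does **not** emulate: realistic
physiological autocorrelation, inter-component correlation, hourly
dynamics, informative missingness tied to severity, or real marginal
distributions. Passing tests therefore demonstrate that the *detector*
implements its rules exactly, not that the rules recover sepsis in real
data.

## Numerical and degenerate-input choices

* Day windows are half-open; a zero-length dose exactly at a boundary
  belongs to the later day.
* Totals are integer sums; no floating-point comparisons enter the
  ≥ 2-rise rule.
* An empty cohort, an admission with no measurements (all components
  missing, total 0), and an admission with no antibiotics (max rank 0)
  are all valid inputs with defined outputs.
* Ties at thresholds are spelled out everywhere: lactate exactly 2.0 is
  *not* shock, an onset exactly 72 h after the previous one is *not* a
  new episode, GCS 15 scores 0, bilirubin 204 scores 3.
* Problem sizes in the test and acceptance runs (cohorts of 120–500
  admissions, 200 random series for the brute-force comparison) were
  chosen as the smallest sizes at which every archetype and rule path is
  exercised repeatedly.

## Known limitations

* Hourly-resolution phenotyping (the original culture-window framing of
  suspected infection) is out of scope; everything is daily.
* GCS is taken at face value (no sedation correction), and SpO₂-based
  oxygenation surrogates are not scored.
* Antibiotic route inference, dose-appropriateness, antifungals and
  antivirals are out of scope.
* The reporting layer emits per-admission tables suitable for survival
  modelling, but Cox/Kaplan–Meier estimation itself is left to standard
  tools (`survival`), and between-group hypothesis tests to base R.
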