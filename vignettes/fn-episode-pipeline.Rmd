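---
title: "Building febrile-neutropenia episodes from administrative claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building febrile-neutropenia episodes from administrative claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fncohort)
```

## The problem

Febrile neutropenia (FN) — fever or documented infection arising during
chemotherapy-induced neutropenia — is a medical emergency that usually ends in
hospitalization. Estimating what an FN episode costs, and who bears the risk,
requires turning raw administrative claims (diagnosis and procedure codes,
pharmacy fills, enrollment spans) into well-defined *episodes of care*. That
construction is the heart of this package: an episode-of-care algorithm with
explicit inclusion, exclusion, termination and washout rules, followed by
treatment classification and cost attribution.

Everything clinical is code-list driven. The package ships placeholder
ICD-10-CM/HCPCS-style code lists (`load_codesets()`); a deployment against real
claims replaces the YAML file and nothing else.

## Episode construction

**Case definition.** A candidate index event is a (member, date) pair where
either definition holds:

1. *Inpatient*: the member's inpatient claims of that date together carry a
   neutropenia diagnosis and a fever, bacterial-infection or fungal-infection
   diagnosis.
2. *Outpatient*: the same same-day diagnosis combination on outpatient claims,
   plus same-day evidence of an NCCN-recommended antibiotic — a pharmacy fill
   satisfying a configured oral combination rule (ciprofloxacin with
   amoxicillin/clavulanate or clindamycin; levofloxacin; moxifloxacin) or a
   parenteral-antibiotic procedure code.

We evaluate the diagnosis combination over the *union* of same-day claims
within the setting class rather than requiring a single claim to carry both
codes: claims systems routinely split one encounter across claim lines, and
the date — not the claim row — is the clinical unit of the definition. When
both definitions fire on one date the candidate is recorded as inpatient;
hospitalization status is computed independently later, so the label only
disambiguates bookkeeping.

**Qualification.** A candidate becomes an episode only if, in this fixed
order: (a) a chemotherapy/biologic claim exists in the 30 days before index
(`[index-30, index-1]`; chemotherapy *on* the index date is excluded by
default because it would conflate treatment with trigger — `fn_config()`
exposes the switch); (b) enrollment, after merging spans separated by at most
one day, covers `[index-180, index]` without a gap; (c) no
neutropenia/infection/fever diagnosis appears in the 180-day pre-episode
window; (d) no bone-marrow/stem-cell transplant or CAR-T procedure and (e) no
ALL/AML/CML/MDS diagnosis appears in that window; (f) no COVID-19 diagnosis
appears in the window or on the index date. The fixed order makes the
attrition log reproducible; each rejected candidate records the first
criterion it failed.

**Termination.** The provisional end is the earlier of the next chemotherapy
administration strictly after index and `index + 60` days. If an FN-related
inpatient stay admitted inside the provisional window discharges later, the
episode extends to the discharge date so the whole stay is costed. We apply
the extension relative to the provisional end whichever rule produced it (cap
or next-chemotherapy); the extension is the only way an episode exceeds the
cap.

**Lengths are counted inclusively**: `end - index + 1`, so an uncut capped
episode has length 61 and a one-day episode has length 1. The convention is a
deliberate choice — reported minimum episode lengths of 1 day imply the index
day itself counts — and it is asserted throughout the tests.

**Washout.** A member's first qualified episode is retained. A later episode
is retained only if at least 30 consecutive days free of
neutropenia/infection/fever diagnoses separate the previous episode's end
from the new index. For these subsequent episodes the washout gap *replaces*
the full 180-day clean-period rule: applied verbatim, criterion (c) would
make second episodes impossible (the first episode's own diagnoses sit in the
window), contradicting the fact that a small share of patients do have
multiple qualifying episodes. `fn_config(subsequent_episode_rule =
"full_clean_period")` restores the verbatim reading for sensitivity analyses.

## Classification

**Chemotherapy FN risk.** Drugs observed in the 30-day treatment period are
matched against a configured regimen dictionary labelled high / intermediate;
an episode showing drugs of several regimens takes the *highest* matching
risk, and unmatched drugs are low/undefined. Context-dependent rules are
configuration, not code: a regimen may require a cancer diagnosis in the
pre-episode window (docetaxel, topotecan) or a minimum number of distinct
administration dates over 180 days (dose-dense doxorubicin/cyclophosphamide).

**Prophylaxis vs treatment.** A GCSF or antimicrobial utilization in the
treatment period is prophylactic iff it falls on the date of, or within 4
days after, the *first* chemotherapy administration of the period — a closed
window `[first chemo, first chemo + 4]`, so day +4 is prophylactic and day +5
is treatment. Any other utilization in the period (including one preceding
the first chemotherapy date) counts as treatment. The categories are not
mutually exclusive. GCSF is further split short- vs long-acting by codeset.

**Comorbidity.** The NCI adaptation of the Charlson index is a weighted sum:
each configured condition contributes its weight once if any qualifying
diagnosis appears in the lookback window. The shipped weights are the
published NCI comorbidity-index weights, which are non-integer — this is what
makes the three reporting categories 0, (0, 2), and ≥ 2 all reachable, and it
is the only reading under which those categories partition. The lookback
excludes the index date by default (consistent with the clean-pre-period
convention); `fn_config(include_index_in_lookback = TRUE)` includes it.

**Risk factors and cancer groups.** The six NCCN risk factors are assessed
independently; older age means 65 or more years on the index date, computed
from birth year. Cancer-group membership (NHL, CLL, other hematologic,
breast, lung, colorectal, prostate, other solid) is a *set* of flags from
pre-episode diagnoses — groups may overlap, and an episode with no cancer
diagnosis belongs to none of them. No primary-vs-metastatic disambiguation is
attempted; claims carry no staging.

## Utilization and costs

Claims dated inside `[index, end]` (index inclusive) are bucketed by setting
into inpatient, emergency room, physician office, other outpatient and
pharmacy. Inpatient *visits* are distinct stays — maximal unions of
overlapping admission spans — because claims often split one stay across
rows; LOS defaults to `discharge - admission + 1` with a floor of one day
(switchable to the plain difference). A medical claim is FN-related if it
carries a neutropenia/infection/fever diagnosis or a GCSF/antimicrobial
administration code; a pharmacy claim is FN-related iff its drug is a GCSF or
antimicrobial. FN-related records are therefore a subset of all-cause ones,
category by category — a conservation property the tests assert across seeds.

Costs stay in nominal dollars of the service year until a single adjustment
point: `adjust_to_2021()` multiplies by the ratio of the 2021 medical-care
CPI to the service-year value, using an annual year-to-index table supplied
as configuration (no month-level adjustment — the index, not its granularity,
is the contract). Summary statistics are computed *among users*: episodes
with no claim in a category do not enter that category's cost mean, SD
(sample, n−1) or median.

## The synthetic-claims generator

No public FN claims dataset exists, so the generator is first-class, tested
code: it emits members, enrollment, medical and pharmacy claims *and a
ground-truth ledger* recording, per planted episode, the intended index and
end dates, hospitalization flag, planted FN-related cost, treatment flags,
risk-factor/comorbidity/cancer labels, and any planted qualification
violation with the criterion it must fail. Tests treat the ledger as the
oracle and never re-derive intent from the claims.

Default parameters are the study conditions the package is built around:
91.2% of episodes hospitalized; 2.9% of members with a second episode; the
FN-related episode cost drawn from a single lognormal moment-matched to mean
\$25,176 and SD \$39,943 in 2021 USD (claims costs are heavy-tailed with
SD > mean, which a lognormal captures and a normal cannot); age N(55.4, 15)
truncated to [1, 90]; and the published category mixes for sex, payer,
region, chemotherapy risk, GCSF/antimicrobial use, risk factors and cancer
groups. One distribution drives FN cost regardless of hospitalization status;
episode-type cost contrasts are an analysis output here, not a generator
input. Planted costs are drawn in 2021 dollars and *deflated* to nominal
dollars of the service year with the same CPI table the pipeline uses, so
cost recovery through the inflation adjustment is exact to rounding cents.

What the generator does **not** emulate: real code frequencies and coding
noise, payer-mix dynamics, regional pricing, miscoded or missing claims, and
hospitalization-dependent cost structure. Passing tests therefore demonstrate
algorithmic correctness — the rules fire exactly where the definitions say —
not real-world phenotype validity, which requires chart review against real
data.

## Numerical and degenerate-input choices

* Dates are whole calendar days; all windows are closed intervals.
* Percentages render half-up to one decimal (not banker's rounding), dollars
  round to whole units in human-readable tables; JSON output keeps full
  precision.
* Ties where both case definitions fire on one date resolve to the inpatient
  label; ties among regimens resolve to the highest risk.
* Empty inputs flow through: an empty dataset yields a zero-episode cohort,
  an all-zero attrition log, and renderable (empty) report tables. Undefined
  statistics (SD of one value, mean over no users, percent of zero
  denominator) are `NA`/`"--"`, never `NaN` or 0.
* A stay admitted and discharged the same day has LOS 1 under the default
  convention, 0 under `"difference"`.

## Problem sizes

The test suite runs its oracle-equivalence checks on cohorts of at most ten
members against a deliberately naive day-by-day reference implementation, its
parameter-recovery checks on a 5,000-episode cohort (4,859 members at the
default second-episode rate), and its invariant sweeps on twenty seeded
30-member cohorts. The acceptance script regenerates the 5,000-episode cohort
from the supplied seed and reports the measured quantities; these sizes give
3-standard-error recovery bands of about ±1.2 percentage points on the
hospitalization share and about ±\$1,700 on the FN-cost mean.

## Known limitations

* Settings come from an explicit `setting` column; mapping from
  place-of-service codes in any particular claims warehouse is out of scope.
* The shipped code lists are placeholders, adequate for the synthetic data
  and for testing the machinery, not for inference on real claims.
* Whether "number of visits" for inpatient care should count admissions or
  claim rows is unspecified in the field; we count admissions (merged stays)
  and document it.
* No statistical inference is produced — the reports are descriptive, as is
  conventional for this study type.

## A worked example

```{r example, eval = FALSE}
library(fncohort)

codesets <- load_codesets()
syn <- generate_synthetic_claims(synth_config(n_members = 500, seed = 7), codesets)

cohort <- build_cohort(syn$dataset, codesets)
cohort$attrition

cls <- classify_episodes(cohort$episodes, syn$dataset, codesets)
rec <- attribute_claims(cohort$episodes, syn$dataset, codesets)
strata <- stratify_episodes(cohort$episodes, cls)
summarize_costs(rec, strata)

report <- build_report(cohort, cls, syn$dataset, codesets)
render_report(report, "fn-report")
```
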