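---
title: "Classifying intermittent oral corticosteroid use: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying intermittent oral corticosteroid use: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocspatterns)
library(data.table)
```

## The problem

Oral corticosteroids (OCS) in asthma are used two ways that look similar in
prescribing records: short acute courses ("bursts") for exacerbations, and
continuous low-dose maintenance therapy for severe disease. Separating the
two from raw prescription tables is the precondition for studying the
burden of *intermittent* use — how often bursts recur, and whether the
spacing between them tightens over time. `ocspatterns` implements a
prescription-level classification algorithm and a patient-level gap
sequencer for that purpose, together with cohort construction, stratified
summaries and a ground-truth-bearing synthetic data generator.

## The stepwise classifier

Every OCS script receives exactly one label, `intermittent` or `long_term`,
from a chain of four steps ordered from most to least definitive. The first
step that resolves the label wins and is recorded as `decision_step`, so
the provenance of every label is auditable.

1. **Instruction step.** The free-text dosing instruction is matched
   against an ordered rulebook (`default_rulebook()`, an editable CSV).
   Maintenance phrases deliberately rank *before* course phrases so that
   conflicting wording resolves toward `long_term`; this is the
   specificity-maximising posture of the whole chain — a script is only
   called intermittent when nothing about it suggests maintenance use.
2. **Dose step.** The daily dose is derived from the instruction (explicit
   mg/day, else units/day × tablet strength, else dispensed quantity over a
   parsed course duration) and converted to prednisolone equivalents via
   the bundled WHO ATC/DDD ratios. Two thresholds then apply:
   `dose_high_mg` (default 20 mg/day; at or above ⇒ intermittent) and
   `dose_low_mg` (default 10 mg/day; at or below ⇒ long_term). Doses
   strictly between are undecided. The defaults follow UK clinical
   convention — acute adult courses are typically 40–50 mg/day while
   maintenance sits at or below ~10 mg/day — and sit far from both typical
   regimens, so moderate misparsing does not flip labels. They are exposed
   in configuration and echoed into every pipeline log precisely because
   they are a convention, not a universal constant.
3. **Concurrent-event step.** An LRTI or exacerbation event within ±14 days
   (`event_window_days`) of the script marks it intermittent. The window is
   symmetric: a burst may be prescribed a few days before the coded
   consultation or after it. 14 days is the span in which a coded
   respiratory event and the course treating it plausibly co-occur while
   staying well below the 90-day "frequent" gap boundary.
4. **Annual-count step.** For the residue, each script is compared against
   the count of residual scripts in its trailing 365-day window (including
   itself): at most `annual_nonintermittent_max` (default 2, the
   "repeated ≥ 2/year acute courses" reading of intermittency) keeps the
   script intermittent; more implies maintenance. A *rolling* window is
   used rather than calendar years to avoid year-boundary artifacts; this
   was an open choice and is therefore a config knob.

Scripts whose substance is not in the DDD table, or whose dose cannot be
parsed, skip the dose step rather than erroring — the chain is a
fall-through by design. A patient is `intermittent_only` iff every script
is intermittent; one maintenance script makes them `any_long_term` and
removes them from pattern sequencing.

### Whether the dose step uses one or two thresholds

Only the thresholds' existence, not their values, is pinned by the source
material for this design, and a single cut-point would force every
mid-range dose (say 15 mg/day) to a label. We use two thresholds with an
undecided middle band so that mid-range doses defer to the later,
contextual steps; this is the more conservative reading and the one
consistent with maximizing specificity.

## Gap sequencing

Within an intermittent-only patient, one script is one course; same-day
scripts merge; courses have no modelled duration (only start dates are
reliably present in dispensing records), so gaps are differences between
consecutive start dates. Gap categories partition the positive integers:
frequent < 90 days, moderately frequent 90–181, infrequent 182–364,
sporadic ≥ 365 — the boundaries are asserted exhaustively over 1…1000 in
the tests. Where an illustrative "≥ 2 courses within four weeks" phrasing
conflicts with the < 90-day rule, the < 90-day rule governs and the
four-week wording is treated as an example. Gaps are between individual
courses, not between clusters of courses.

The 16 detailed labels are exactly the once-only row plus the 15 non-empty
subsets of the four categories, named longest-gap-first ("Sporadic,
infrequent and frequent"); the sporadic-only label is simply "Sporadic",
and "Frequent only" closes its group, mirroring the published table layout
so outputs join against it. The simplified collapse is: `once_only` (one
course ever), `frequent` (any gap < 90 days, i.e. the frequent category
appears anywhere in follow-up), else `less_frequent`. One published
description of the simplified grouping says "moderately infrequent" where
the detailed taxonomy has "moderately frequent"; we read it as a typo for
the latter and note it here rather than silently ignoring it.

## Cohort construction

Index date is the first OCS prescription. Inclusion requires age ≥ 4
completed years at index, an asthma event — coded diagnosis/consultation
*or* an asthma-therapy prescription — within ±91 days of index, and
registration starting ≥ 365 days before index. "Three months" is
implemented as 91 days and "12 months" as 365 days (config keys): month
lengths are never well-defined in gap arithmetic, so both are pinned to
whole days.

Chronic conditions commonly treated with long-term OCS (ankylosing
spondylitis through respiratory cancer; `exclusion_conditions()`) make OCS
scripts unattributable to asthma. Adults are excluded when such a condition
appears *anywhere* in their record — the condition list is already
restricted to OCS-treated diseases, so an "ever" reading is the defensible
default, with a stricter concurrency mode available by configuration.
Minors are excluded only when the diagnosis is concurrent (±91 days) with
an OCS prescription.

Rules apply in a fixed order (age → concurrent asthma event → baseline →
exclusion conditions) and the attrition log reports removals per rule in
that order; the order is a reporting convention, not a claim about the
source analysis, and eligibility itself is order-free (shuffling input rows
never changes any patient's eligibility — a property test). The non-OCS arm
(no OCS ever) is constructed and labelled, with its baseline reference date
defaulting to `registration_start + 365` days, but no pattern analysis
applies to it.

## Stratifiers and summaries

GINA 2020 step is assigned from the therapy classes dispensed in the 365
days before index by a highest-matching-step rule (biologic ⇒ 5; LAMA
add-on to high-dose ICS-LABA ⇒ 5; medium/high ICS-LABA ⇒ 4; low ICS-LABA or
ICS+LTRA ⇒ 3; ICS or LTRA alone ⇒ 2; reliever-only ⇒ 1; nothing ⇒ none).
The product-to-dose-band mapping is a bundled editable CSV
(`ics_dose_bands()`) because no canonical code mapping is published; any
reanalysis against real records must substitute its own product list. SABA
fills in the same window band to 0 / 1–2 / ≥ 3; age bands are half-open
(4–<12, 12–<18, ≥ 18).

Summary tables report n, percent, mean (SD) and median (IQR) of
per-patient prescription counts per detailed label, with "Any …" super-rows
grouping patients by the most severe (shortest-gap) category present.
Numerical conventions, pinned and used everywhere:

* **Percentages** round half *away from zero* to one decimal
  (base R `round()` is round-half-even). One published percentage cell is
  not reproducible under any common rounding of its printed numerator and
  denominator (31.57% printed as 31.5); we report the computed value.
* **Quantiles** use linear interpolation at `(n+1)p` (type 6). The choice
  is visible: for counts {2, 2, 3} it gives IQR (2, 3) where R's default
  type 7 would give (2, 2.5).
* **Chi-square** is Pearson's without continuity correction,
  `df = (r−1)(c−1)`, zero-margin rows/columns dropped with a warning.
  Column percentages sum to 100 within each pattern column.

## The synthetic generator

Real primary-care OCS records are access-restricted, so validation runs on
generated cohorts with known ground truth. The generator's defaults *are*
the study conditions: the 16-label pattern mixture equals the published
detailed breakdown's proportions (`reference_pattern_counts()`), the
GINA-step mixture (13.8% none, 25.1/32.0/18.4/8.7/2.0% steps 1–5), SABA
bands (23.8/44.9/31.4%) and age bands (16.2/7.6/76.2%) match the published
stratifier distributions, and the sex split is 44.3% male. Planted
violations (under-age, no concurrent asthma event, short baseline, adult
and minor exclusion conditions) and a non-OCS arm exercise every attrition
rule.

Each script is planted to be decided at a chosen step, with attributes
strictly inside the decisive region: instruction-step scripts carry rulebook
phrases, dose-step scripts imply 40 mg/day (including a dexamethasone
variant exercising DDD conversion) or 10 mg/day for maintenance,
event-step scripts get an LRTI/exacerbation within ±5 days, and at most two
annual-count scripts are planted per patient so their ground-truth label is
intermittent *by construction* — the generator never re-implements the
classifier's sliding window, keeping truth independent of the code it
validates. The annual-count ⇒ long_term branch is covered by hand-counted
unit fixtures instead. In strict mode gaps avoid category boundaries and
frequent-category gaps are drawn from 30–88 days so a planted event can
never sit within the ±14-day window of a neighbouring script; a non-strict
mode samples boundary values to exercise tie handling.

What passing recovery tests show — and what they do not: they demonstrate
that the implementation is internally exact (every rule fires exactly where
it is defined to fire), not that the algorithm correctly classifies real
prescriptions. Real free text is messier than the rulebook's phrases, real
dosing is not bimodal, and coded events are incomplete; recovery on
synthetic data is a correctness check, not a validation study.

A hand-written boundary cohort (`make_boundary_fixtures()`) pins every edge
exactly once: gaps 89/90/181/182/364/365, same-day duplicates, ages
3/4/11/12/17/18, an asthma event exactly at (and just past) the 91-day
edge, each exclusion condition, and a minor with a distant vs concurrent
condition.

## Degenerate inputs and tie-breaks

* A patient with zero OCS scripts has no defined `patient_use`; asking for
  one is an error, as is sequencing an empty course list.
* Thresholds are inclusive on the decisive side: dose exactly 20 ⇒
  intermittent, exactly 10 ⇒ long_term; an event exactly 14 days away
  counts; a gap of exactly 90 days is moderately frequent, 365 sporadic; an
  asthma event exactly 91 days from index satisfies inclusion.
* Unknown substances are never guessed: conversion errors for the caller,
  while the classifier routes such scripts past the dose step.
* Rows failing type coercion on read are collected into a rejects table
  with reasons; accepted + rejected always equals input rows.

## Problem sizes

Tests run the generator at 10–400 patients per case, the acceptance
recovery at 2,000 patients, and the invariance suites over 100 seeds at 25
patients each — sizes chosen so the full suite exercises every rule many
times over while remaining quick to run routinely.

## Known limitations

* Prescriptions are not ingestion: stockpiling and non-adherence are
  invisible, and one dispensed script may cover several self-managed
  bursts.
* The pattern labels are not an exacerbation proxy and are not intended as
  one.
* Specificity-first labelling will miscall some true intermittent use as
  long-term (by design).
* GINA step inference from dispensing data is approximate and depends
  entirely on the supplied product/dose-band table.
* Course durations are ignored; two scripts 89 days apart count as a
  frequent pair even if the first course lasted two weeks.
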