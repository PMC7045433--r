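---
title: "Identifying youth mental health problems from linked administrative data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying youth mental health problems from linked administrative data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhcasefind)
```

## The problem

Surveys of child and youth mental health are expensive, infrequent and
small; administrative health collections are large, continuous and
population-wide, but none of them was designed to measure prevalence.
Specialist mental-health services see only the most severe cases;
hospital discharges record mental health mostly as secondary diagnoses;
pharmaceutical dispensings reach into primary care but carry no
diagnosis, only a chemical ID; disability-support referral diagnoses are
of uncertain provenance; and the mortality collection contributes only
deaths by suicide. `mhcasefind` implements a case-identification method
that pools all five coded streams into one set of per-person dichotomous
indicators across 13 problem categories, under explicit, auditable
mapping rules.

The output is a *service-contact phenotype*, not a prevalence estimate
of disorder: people treated solely in primary care without medication,
or not treated at all, are invisible to every source, so identified
prevalence is a lower bound. The package makes that undercount
measurable on synthetic data (see below).

## The procedure

1. **Codebook.** A rule maps (code system, code or ICD prefix, source,
   age range) to one category. Validation (`validate_ruleset()`)
   enforces: ages within 0–24 with `min <= max`; each source admits the
   rule's code system (e.g. only Pharms carries chemical IDs); the
   (category, source) pair is ticked in the support matrix
   (`category_source_matrix()`); and no two rules can resolve the same
   (system, code, source, age) to different categories.
2. **Ingest.** `read_events()` reads each source table, skipping
   malformed rows (logged by row number) and rows outside the source's
   best-quality window: hospital discharges before 1994, dispensings
   before 2007, disability referrals before 2010, specialist diagnoses
   outside July 2008–December 2016, activity outside July 2008–June
   2018, deaths after 2015. All window bounds are arguments.
3. **Denominator.** `build_population()` keeps roster persons aged 0–24
   (completed years) at the reference date, excluding deaths before the
   window and persons overseas for the entire window.
4. **Identification.** `identify()` matches every in-window event at the
   person's age *on the event date* and ORs the results per person and
   category, recording which sources contributed. Duplicate events are
   harmless by construction ("at least one code").
5. **Precedence.** `apply_precedence()` zeroes the residual
   `mh_not_defined` indicator for anyone who also has a specific
   problem-group indicator, self-harm excluded.
6. **Tabulation.** `count_table()` counts unique persons per (category,
   source) and per category; `render()` produces the releasable twin
   with base-3 random rounding and small-cell suppression.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| fiscal year | `"2014/15"` | label | NZ reporting year, 1 July–30 June |
| reference date | window start | date | one fixed date makes ages, strata and denominators unambiguous; configurable to end/midpoint |
| precedence knock-out set | 10 specific groups + `other_mh` | categories | the rule exempts only self-harm by name; whether `other_mh` participates is genuinely open, so it is a switch with the inclusive default |
| suppression threshold | 6 | persons | cells with raw counts 1–5 release as `S` |
| RR3 probabilities | 2/3 nearer, 1/3 farther | — | the graduated unbiased convention; configurable |
| denominator ages | substance/psychosis 10–24, bipolar 15–24, personality 18–24, else 0–24 | years | category-specific reporting denominators; configurable map |

## Numerical and tie-break choices

* **Code resolution.** Exact match beats any wildcard; among wildcard
  (prefix) rules the longest matching prefix wins, reflecting ICD
  hierarchy. A tie between categories at equal specificity raises an
  integrity error rather than picking silently — validation makes this
  unreachable for a valid codebook. Chemical IDs, DSM-IV, activity and
  team codes never prefix-match: they are flat vocabularies.
* **Ages** are completed years by the birthday-anniversary convention;
  rule matching uses age at the event date (a person dispensed
  amitriptyline the day before their 20th birthday does not count toward
  depression; the day after, they do).
* **Suppression is decided on raw counts** and applied after rounding,
  so rounding can never lift a sub-threshold cell above the line.
* **Rates are computed from raw totals**, not rounded ones
  (configurable): rounding noise of ±2 on a numerator is disclosure
  protection, not information, and should not propagate into rates.
* **Persons dying during the window stay in the denominator**, so that
  suicide deaths identified from the mortality collection have a
  denominator; deaths before the window are excluded. Whether the
  original population method kept within-year deaths is not documented,
  so this is the package's own documented choice.
* **Degenerate inputs.** An empty codebook loads with a warning and
  identifies nobody; an empty event stream yields an all-zero table;
  an age-restricted denominator with no members yields a blank rate
  rather than a division by zero.

## What the synthetic generator emulates — and what it does not

`scenario_config()` + `generate()` draw, per person: an age (uniform
over 0–24 by default), a date of birth consistent with that age at the
reference date, and true category statuses from per-category prevalences
with optional pairwise comorbidity odds multipliers (applied
sequentially in canonical category order — simple, documented, and
sufficient for testing that indicators are independent bits). Each true
(person, category) is then captured independently by each permitted
source with probability p<sub>cs</sub>; a captured source emits a
geometric number of events (mean 2, minimum 1) with codes drawn from the
codebook's rules for that cell and dates uniform over the part of the
fiscal year where the sampled rule's age restriction holds. A person
whose age matches no rule of a source is uncapturable by that source.
Optional noise injects unmapped codes and out-of-window dispensings to
exercise the ingest drop paths.

Default prevalences follow published per-100,000 identification rates
for the 13 categories, and default capture probabilities (Pharms 0.70,
PRIMHD 0.35, NMDS 0.12, Socrates 0.03, Mortality 0.02; NMDS 0.90 for
self-harm) are fixed once so that the pharmaceutical collection is the
largest identification source and hospital data dominate self-harm,
mirroring the qualitative structure of real applications. Death and
overseas rates default to zero in scenarios; the exclusion logic is
exercised by dedicated roster fixtures instead.

Under independent captures the identified prevalence of a category has
the closed form π·(1−∏<sub>s</sub>(1−p<sub>cs</sub>)), which the test
suite and `scripts/acceptance.R` verify to within binomial error at
n = 20,000.

The generator does **not** emulate: realistic clinical coding
distributions, within-person correlation of capture across sources
(captures are independent by default, the known weak point of
capture–recapture undercount estimation), seasonality, service pathways,
or linkage error (person IDs arrive pre-linked). Passing tests therefore
show the *pipeline* is correct under the stated model, not that any
particular codebook is clinically complete.

## Problem sizes

The test suite runs scenarios of 200–20,000 persons; the oracle
equivalence check (a naive per-(person, event, rule) triple loop)
uses 1,000 persons; RR3 calibration uses 10⁵ draws and an analytic check
over every count 0–1000. These sizes give 3-standard-error resolution on
every stochastic assertion while keeping a full run under a minute.

## Known limitations

* The shipped codebook is an exemplar: every category–source cell is
  populated and the stated medication rules are encoded exactly, but the
  full clinical code lists of a production analysis must be supplied by
  the user, and their clinical correctness is out of scope.
* The support matrix is reconstructed from the method's documented
  source usage; it is a configurable constant, not a clinical claim.
* Identified prevalence is a service-use lower bound on true prevalence;
  the package quantifies undercount only under its own synthetic model.
* One category per code per age per source: codes with genuinely mixed
  indications belong in `mh_not_defined` (as risperidone does), not in
  two lists.
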