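---
title: "Needs-based cancer-control resource planning with oncocap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Needs-based cancer-control resource planning with oncocap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncocap)
```

## The model

Cancer-control planning in settings without registries starts from a simple
chain of deterministic conversions:

1. **Incidence.** National annual new-case counts by cancer site (typically
   GLOBOCAN estimates) are extrapolated to a state or city by population
   share: every per-site count and the all-cancers total are multiplied by
   `share` and rounded half-up to whole cases. The all-cancers total is
   scaled independently of the listed sites because published tables list
   only the most common sites; the remainder is "other" cancers.

2. **Treatment demand.** Per site, a fraction of incident patients requires
   surgery, chemotherapy and/or radiotherapy. Demand per site and modality
   is `round_half_up(cases * pct / 100)` — whole patients. Each treated
   patient is admitted for the modality's average length of stay (ALOS, in
   days), giving annual bed-days; the steady-state daily bed requirement is
   `ceiling(total bed-days / 365)`.

3. **Capacity.** Demand converts to whole-unit requirements by *ceiling*
   rules: specialists at a rate per 1000 patients
   (`ceiling(patients * rate / 1000)`); surgical oncologists by annual
   theatre throughput (2 surgeries/day x 5 days/week x 48 weeks = 480
   operations/surgeon/year); ward staff in exact multiples of 24-bed wards
   (15 nurses, 4 oncopharmacists, 6 pharmacy technicians per ward);
   radiotherapy staff and equipment per 1000 radiotherapy patients (12
   technicians, 4 physicists, 1 linac engineer, 4 RT nurses; one of each
   major equipment item per block, with megavoltage teletherapy doubled
   unless a single unit may run nearly non-stop). Cities additionally floor
   every staff category at two, so that a single departure does not
   interrupt coverage; states never: state needs are computed from state
   totals, not by summing floored city values.

4. **Gap analysis.** Requirements meet a surveyed availability inventory
   category by category: `shortage = max(0, needed - available)` and
   `surplus = max(0, available - needed)`; exactly one of the two is
   nonzero and a surplus never offsets a deficit elsewhere. Categories with
   no local specialization are carried as zero with an explanatory flag,
   and adjacent specialties can be pooled explicitly
   (`merge_available_categories()`), never silently.

## Rounding and numerical choices

Two distinct rounding rules are deliberate. Demand uses **half-up**
rounding: it is a point estimate of a patient count, and half-up is the
unbiased whole-patient convention. Capacity uses **ceiling**: a fraction of
a workload still needs a whole specialist, bed or machine. Ceiling is also
the only rule consistent with the reference results this package
reproduces (801.48 oncologists become 802; 24.05 hematologist-oncologists
become 25; 120.5 wards become 121); half-up would fail several of these.

Growth projection between two published national totals interpolates
**linearly in the factor** and refuses to extrapolate beyond the horizon
year. Linearity is a choice: the reference discussion quotes "about 20%"
growth by the fifth of eight years, which no simple scheme reproduces
exactly (linear gives ~17.9%); we treat the quote as an approximation and
keep the transparent rule.

## Published totals as explicit overrides

The reference assessment's state-level modality totals (74,860 requiring
surgery; 117,172 chemotherapy; 94,808 radiotherapy) and bed requirement
(2,892) exceed what its published site-group tables recompute to (68,212;
101,434; 83,839 patients; 3,394 beds from the bed-day formula). The
original computation evidently used finer-grained subtype inputs that were
not published. The package never conflates the two: `compute_demand()`
reports the arithmetic answer, `override_totals()` substitutes externally
supplied totals for the downstream capacity stages while preserving the
computed ones, and `totals_source` records which is in force. Subtype-level
computation is supported when the user supplies subtype case counts and the
explicit subtype-to-group mapping (`oncocap_site_groups()`); no subtype
shares are imputed.

Similarly excluded from exact reproduction, and documented rather than
forced: the published 157 surgical oncologists (the throughput formula
gives `ceiling(74860/480) = 156`), the urologic (20) and neurologic (26)
subspecialist cells (the 2-per-1000 rule on the published site counts gives
15 and 8), and the bed shortage of 2,018 (the inventory arithmetic gives
2,892 − 875 = 2,017). The package reports the arithmetic values.

## Tunable parameters

All conversion constants live in one `capacity_norms()` object and are
overridable individually, in code or from a YAML/JSON file
(`read_norms()`); omitted fields keep the defaults listed above, which are
the reference assessment's IAEA-informed values. Units: rates are per 1000
patients per year; throughput constants are per surgeon per year; ward
constants are per 24-bed ward; `city_minimum` is professionals per
category per city. `nonstop_allowed` (default `FALSE`) controls the
teletherapy doubling; the reference state table used two units per block,
while its city rows are consistent with single-unit operation, so the flag
is per-call rather than global.

## What the synthetic generator emulates — and what it does not

`generate_scenario()` produces the data *shapes* the pipeline consumes: a
country/state/city hierarchy (country population fixed at six times the
state's, the approximate state-to-country ratio of the reference setting),
a national site-by-sex incidence table, and sparse availability
inventories. Site proportions come from a symmetric Dirichlet draw; the
listed sites carry 85% of the national total (the listed share in the
reference table is ~84.5%); integer counts are reconciled by
largest-remainder apportionment so totals are exact; per-site sex splits
are uniform in a configurable range with men + women reconciled exactly;
availability counts are small Poisson draws zeroed with a configurable
sparsity probability, mirroring surveys in which whole specializations are
absent. City populations default to 0.5–2.8 million with ten cities —
deliberately far below the state population, as in the reference setting
where the ten cities held under a tenth of the state.

The generator does **not** emulate age structure, registry-quality
incidence, stage distributions, referral flows between cities, or
correlations between availability categories. Passing tests on synthetic
scenarios therefore demonstrates arithmetic and structural correctness of
the pipeline (sex-sum consistency, ceiling and ward-multiple invariants,
gap identities, determinism under a seed), not epidemiological realism of
any particular scenario.

`perturb_norms()` supports one-at-a-time sensitivity analysis by jittering
every norm within a relative range under a seed; perturbed norms are
re-rounded to whole units of at least 1.

## Degenerate inputs and tie-breaks

Zero cases, zero beds and zero radiotherapy patients all yield zero
requirements (never a spurious ceiling of 1). A site with zero cases may
lack a fraction record; a site with cases and no record is a configuration
error naming the site. Validation violations (negative counts, broken sex
sums, an all-cancers total below the listed sum) are returned as data, one
readable message per failure, not thrown. Shares outside (0, 1] and growth
queries outside the projection window are refused. Largest-remainder ties
are broken by first occurrence, which makes generation deterministic.

## Problem sizes

The whole reference reproduction is desk-scale arithmetic: 14 sites, 21
gap categories, 11 geographies. The test suite's property checks sweep
patients 0–5000 for the block-filling oracle, ~20-seed loops for the
stochastic and structural properties, and scenarios with 2–10 cities;
everything completes in seconds on one CPU.

## Limitations

The model is a static, deterministic needs calculator: no queueing or
utilization, no treatment sequencing or re-treatment, no workforce
attrition or training-pipeline dynamics, no costing or siting. Availability
inventories are taken at face value (possible double-counting of staff
across institutions is unknowable from a survey). Population-proportional
extrapolation assumes the sub-national case mix equals the national one,
which is exactly the assumption a local registry would replace.
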