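# oncocap

Needs-based estimation of the human resources, oncology beds and
radiotherapy equipment required for cancer control — and of the gap
between what is required and what is available.

Decision makers in low- and middle-income settings rarely have cancer
registries or staffing guidelines to plan against. `oncocap` implements a
transparent planning chain that works from publicly available inputs:

1. **Incidence extrapolation** — national annual new-case counts by site
   (e.g. GLOBOCAN) scaled to a state or city by population share,
   `cases_target = round(share × cases_national)`;
2. **Treatment demand** — per-site fractions requiring surgery,
   chemotherapy and radiotherapy, `demand = round(cases × pct/100)`, with
   in-patient bed-days from average lengths of stay and beds =
   `⌈bed-days/365⌉`;
3. **Capacity requirements** — ceiling-based whole-unit conversions:
   specialists per 1000 patients (`⌈patients × rate/1000⌉`), surgeons by
   annual theatre throughput (480 operations/surgeon/year), ward staff in
   exact multiples of 24-bed wards (15 nurses, 4 oncopharmacists, 6
   pharmacy technicians per ward), radiotherapy staff and equipment per
   1000 RT patients, a two-per-city staffing floor;
4. **Gap analysis** — per category, `shortage = max(0, needed −
   available)`, `surplus = max(0, available − needed)`, rendered as CSV,
   JSON or text tables.

The packaged reference tables transcribe a published needs assessment for
Uttar Pradesh, India (160,296 estimated new cancer cases in 2008, ten
cities with radiotherapy centres), so the published state-level results
can be reproduced end-to-end. A seeded synthetic-scenario generator
(`generate_scenario()`) exercises every stage without any download.

## Worked example

```r
library(oncocap)

rep <- up_state_assessment()   # full pipeline on the packaged tables
subset(rep$rows, shortage > 0,
       select = c(category, needed, available, shortage))
```

```
                         category needed available shortage
1  radiation_clinical_oncologists    802        87      715
2                    pathologists    321       179      142
3     palliative_care_specialists    321         8      313
4            surgical_oncologists    156        42      114
5         gynecologic_oncologists     58        24       34
8        hematologist_oncologists     25         7       18
9                 oncology_nurses   1815       233     1582
10                oncopharmacists    484         0      484
11           pharmacy_technicians    726         0      726
12                 rt_technicians   1138        83     1055
13             medical_physicists    380        38      342
14                linac_engineers     95         0       95
15                      rt_nurses    380         0      380
16                    teletherapy    190        26      164
17                  brachytherapy     95        17       78
18                   ct_simulator     95        11       84
19                            tps     95        19       76
20                   dosimetry_qa     95         0       95
21                           beds   2892       875     2017
```

Reading: from 160,296 annual new cases the state needs 802 combined
radiation/clinical oncologists (5 per 1000 cases) but has 87 — a shortage
of 715. The 2,892 beds needed imply 121 wards of 24 beds, hence 1,815
oncology nurses against 233 available. Oncopharmacists, pharmacy
technicians, RT nurses and linac engineers are specializations that do not
exist locally (available 0, flagged in the report). The published modality
totals driving the capacity stage (74,860 surgery / 117,172 chemo /
94,808 RT patients) enter as explicit overrides via `override_totals()`;
the group-level recomputation from the packaged tables (68,212 / 101,434 /
83,839) remains available as `computed_totals` — see the methods vignette
(`vignettes/resource-planning.Rmd`) for why the two differ.

Lower-level pieces compose freely:

```r
ratio_staff_need(160296, 5)          # 802
ward_staffing(2892)$nurses           # 1815
rt_equipment_need(94808)             # teletherapy 190, others 95 each
growth_factor(growth_projection(2008, 948858, 2016, 1220000), 2016)
# 1.285756  -> ~29% more resources needed by 2016
```

A thin CLI wraps the same functions:

```sh
Rscript scripts/oncocap.R gaps --format text     # packaged reference run
Rscript scripts/oncocap.R simulate --seed 7 --out scenario/
```

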