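---
title: "Benchmarking resident clinical experience from EHR encounter exports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking resident clinical experience from EHR encounter exports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caselogr)
library(dplyr)
```

## The measurement problem

Residency programs need objective evidence of what their trainees have
actually seen. In nonprocedural specialties there are no mandated case
minimums, and needs assessments after disruptions (a pandemic, a site
closure, an extended leave) are usually built on recall. Yet the
electronic health record already knows: every visit note a resident
authors carries ICD-10 visit diagnoses. `caselogr` turns a flat-file
export of those notes into per-trainee experience profiles benchmarked
against two internal references — the trainee's own class and the
program's recent graduates.

The measurement model is deliberately simple. A curated set of
diagnostic groups $g = 1,\dots,G$ is defined by ICD-10 code patterns.
For resident $r$ with enrollment window $W_r$ (clipped at the
extraction date), the **volume** in group $g$ is

$$ V_{rg} = \#\{\, e : \text{author}(e)=r,\ \text{date}(e) \in W_r,\
\exists\, c \in \text{dx}(e): c \in g \,\} $$

— the number of *unique visits* carrying at least one diagnosis in the
group. One encounter with two codes from the same group counts once for
that group; an encounter with codes in two groups counts once in each.
**Variety** is $\#\{g : V_{rg} \ge 1\}$. Benchmarks are arithmetic
means over cohorts, *including* members with zero counts: the class
average $\bar V_{\cdot g}^{(\text{class})}$ and the graduate benchmark
$\bar V_{\cdot g}^{(\text{grad})}$, the latter over each graduate's
complete training window. Because groups live on wildly different
scales (hundreds of well checks, a handful of autism diagnoses), every
display quantity is normalized to the graduate benchmark:

$$ P_{rg} = 100 \times V_{rg} \,/\, \bar V_{\cdot g}^{(\text{grad})}. $$

The radar chart plots $P_{rg}$ on one axis per group, with the
graduate reference as the 100% ring.

## The code-set grammar

Group definitions use three token forms, compiled by `parse_pattern()`:

* **exact** codes (`"R62.51"`, `"N39"`) match by string equality after
  normalization (uppercase, dot removed);
* **prefix** tokens written with a wildcard (`"K59.xx"`) match every
  subcode of the category;
* **ranges** (`"D50-D64"`, `"Z68.51-Z68.54"`) match any code whose
  truncation to each endpoint's length falls inside the endpoints
  lexicographically, so a range of categories includes all their
  subcodes.

Three parsing choices deserve a note, because curated code lists are
written by clinicians, not parsers. First, a bare category token
without a wildcard (`"N39"`) is treated as an *exact* code: the
curators wrote `.xx` explicitly wherever subcodes were intended, and
silently widening `N39` to the whole N39.x family would change the
urinary-tract-infection group's meaning. `validate_group_set()` exists
so curators can audit such decisions. Second, a range endpoint written
without its letter (`"F90.0‐90.2"`) inherits the letter of the first
endpoint. Third, both the ASCII hyphen and typographic dashes are
accepted as range separators, since real-world lists mix them.

The matcher is verified, pattern by pattern, against a brute-force
oracle that enumerates every grammar-valid code of length $\le 5$ over
the pattern's letter and the digits, and decides membership by
independent case analysis. The shipped pediatric set (22 groups, 68
patterns) shows no overlaps on its own enumerated universe and every
group is reachable.

```{r groups}
gs <- default_group_set()
tidy(gs) |> count(kind)
assign_groups(c("Z00129", "D509", "J069"), gs)
```

An unmatched code (like the J06.9 upper respiratory infection above) is
not an error: curated sets deliberately exclude common self-limited
conditions so reports stay actionable. The pipeline tallies unmapped
codes per run and otherwise ignores them.

## Cohort logic

Classes are labelled by graduation year on a July 1 – June 30 academic
calendar (configurable via `academic_calendar()`). `pgy_level()` maps a
class year and a date to PGY1…PGYn, `GRADUATED`, or `PRE_ENROLLMENT`;
`enrollment_window()` spans the class's full residency;
`applicable_reports()` counts which semiannual report dates fall inside
a class's window, inclusive of the first day. With the reference
schedule (April 2019, September 2019, April 2020) the classes of 2020
and 2021 receive three reports and the class of 2022 two — the class of
2022 enrolls in July 2019, after the first report date.

```{r cohorts}
applicable_reports(2022, c("2019-04-01", "2019-09-01", "2020-04-01"))
```

The graduate benchmark cohort is explicit configuration, not inference:
which classes count as "recent graduates" is a program-level judgement
that shifts over time, so `cohort_config()` takes it as input and only
checks that every benchmark class has graduated by the as-of date.

## The synthetic encounter generator

Protected health data cannot ship with a package, so `caselogr`
includes a generator whose defaults reproduce the study conditions the
pipeline was designed around: seven classes of sizes 8, 15, 18, 11, 18,
19, 13 (102 residents; the first four classes, 52 residents, fully
graduated), extraction as of 2020-04-01, and per-group annual visit
rates calibrated so expected cumulative counts match the published
PGY1 / PGY2 / graduate benchmark columns by successive differencing
(well check: 150, 304, 409 per year).

Counts are Poisson: for resident $r$ in PGY year $y$ and group $g$,
$N_{ryg} \sim \text{Pois}(\lambda_{gy} f_{ry})$ where $f_{ry}$ is the
elapsed fraction of the academic year at the extraction date. Poisson
is the minimal count model and makes standard errors for recovery tests
analytic ($\text{SE} = \sqrt{\mu/n}$); true overdispersion and
within-class variance in real programs are unpublished, so no attempt
is made to model them. Visit dates are uniform within the academic
year. Each qualifying visit carries one code enumerated from the
group's own patterns (restricted to codes mapping back to exactly that
group); with probability 0.2 a non-well-check diagnosis is instead
attached to an existing well-check encounter of the same resident-year,
exercising the multi-group-visit counting rule the way real well-child
visits accumulate comorbid codes. A further 20% of qualifying volume
appears as encounters with deliberately unmapped codes. Both values are
package defaults chosen to make the multi-diagnosis and unmapped paths
unmissable in testing while leaving expected per-group counts
essentially unchanged; neither is an empirical estimate.

One calibration wrinkle: the published congenital-nongenetic row is
non-monotone (class means 3, 10 against a graduate mean of 4 — the
columns average *different cohorts*), which would difference to a
negative PGY3 rate. Rates are clamped at zero, so that group's
configured graduate expectation telescopes to 10 rather than its
printed 4; the recovery harness compares estimates against configured
expectations, keeping it well-posed.

The generator writes a truth file of realized per-resident per-group
unique-visit counts from its own bookkeeping; `count_volumes()` must
reproduce it *exactly*, which pins the entire
normalize–match–attribute–deduplicate chain. `recover_parameters()`
then checks cohort means against configured expectations with Poisson
z-scores. What passing these tests does **not** show: robustness to
coding behavior (under-coding of counseling-only diagnoses),
overdispersed or seasonally clustered visits, panel effects, or
off-cycle residents — real data will be messier than this generator.

```{r sim}
cfg <- sim_config(seed = 42,
                  class_sizes = tibble(class_year = c(2018L, 2019L, 2021L),
                                       n = c(5L, 5L, 4L)),
                  group_rates = default_group_rates() |>
                    mutate(rate = rate / 10))
sim <- simulate_encounters(cfg)
sim
recover_parameters(sim) |> filter(cohort == "graduate") |> head(4)
```

## Reports and the radar chart

`build_benchmarks()` holds full-precision means; display rounding
(half-up, matching how such tables are conventionally printed) happens
only in `tidy()`. `build_individual_report()` refuses graduated
residents — individual reports exist to steer *remaining* training.
Radar categories are placed in a seeded random order, identical across
every chart of a batch, rather than sorted by value: sorted axes draw
the eye to the extremes, and the point of the chart is that readers
scan every axis. Values above 100% are drawn at true scale (capping at
100 is available as an option but off by default, since a cap hides
over-exposure); cells with a zero graduate benchmark are undefined and
render as gaps, never as zeros. The numbers serialized next to each
chart are exactly the benchmark-table values — the image is
presentation only.

## Numerical and degenerate-input choices

* Dates are ISO 8601 only; a malformed date is a hard error with a row
  number. Silent month/day swaps corrupt windows invisibly.
* Duplicate `encounter_id` rows are merged by set-union of diagnoses
  (source systems differ on one-row-per-visit vs one-row-per-diagnosis);
  the merge is idempotent and order-independent.
* An encounter is attributed wholly to its single authoring resident;
  preceptor co-signature creates no additional attribution.
* Zero-benchmark percent cells are `NA` with a defined meaning, never
  `Inf`; `percent_of_benchmark(0, x)` is exactly 0.
* Off-roster encounter authors are a hard error in strict mode and a
  counted drop in lenient mode.
* Problem sizes in the test suite: the full 102-resident configuration
  is exercised once for self-consistency; the recovery study runs 20
  seeds of the 52-graduate configuration; unit tests use a scaled-down
  (rates / 10) three-class configuration.

## Known limitations

The pipeline measures *coded exposure*, not competence: diagnoses that
were discussed but not coded are invisible, and exposure in other
settings (emergency department, inpatient) is out of frame unless those
encounters are exported too. Class averages assume classmates have had
comparable rotation schedules, which is most defensible in spring
reports. No statistical testing, risk adjustment or severity weighting
is performed, by design. Off-cycle and extended-leave residents are not
specially handled: their windows are the standard class windows.
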