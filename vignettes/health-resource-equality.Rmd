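---
title: "Measuring allocation equality of public health resources with the Theil index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring allocation equality of public health resources with the Theil index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healtheil)
```

## The problem

China's public health system — centers for disease control, maternal and
child health hospitals, specialist prevention hospitals, health education
centers, emergency aid centers, blood centers and health inspection
institutions — is monitored through yearbook panels that record, per
province and year, four resource counts: institutions, technical personnel,
beds, and equipment (devices above 10,000 yuan). Two questions recur:
how dense are these resources relative to the population they serve
(per 10,000 capita) and the territory they cover (per km²), and how
*unequal* is the allocation — overall, inside each of the three
macro-regions (western, middle, eastern), and between them?

`healtheil` implements that analysis as a reusable, tested pipeline:
validated CSV ingestion, density indicators, and the Theil decomposition
with contribution rates, plus a seeded synthetic-panel generator so every
stage can be exercised without the yearbook files.

## The model

Let province $i$ hold population share $p_i$ and resource share $y_i$
(both summing to 1). The package measures inequality with the
population-weighted mean-log-deviation Theil form

$$T \;=\; \sum_i p_i \ln\!\frac{p_i}{y_i},$$

the Kullback–Leibler divergence of the population-share distribution from
the resource-share distribution. $T = 0$ exactly when every province's
resource share matches its population share; it grows with
disproportionality and is **unbounded above** (a common misconception pins
it to $[0,1]$; the implementation does not clamp). Units are nats
(natural log).

With provinces partitioned into regions $j$ holding aggregate shares
$P_j = \sum_{i \in j} p_i$ and $Y_j = \sum_{i \in j} y_i$, the index is
additively decomposable:

$$T_T \;=\; T_\omega + T_B
  \;=\; \Big[\sum_j P_j T_j\Big] + \Big[\sum_j P_j \ln\frac{P_j}{Y_j}\Big],$$

where $T_j$ is the Theil index of region $j$'s provinces with shares
renormalized by the region totals. The identity is exact — the grouped
total always equals the ungrouped province-level Theil value, which the
test suite verifies against an independent brute-force evaluation on
randomized panels (observed gaps at machine precision, $\sim 10^{-16}$).
Region $j$'s *contribution rate* is $P_j T_j / T_T$, the between-region
rate is $T_B / T_T$, and the rates sum to 1. When $T_T = 0$ there is no
inequality to attribute and the rates are reported as `NA` with a warning
rather than as an arbitrary split.

Only this orientation (population shares weighting $\ln(p/y)$) is
implemented; the resource-weighted alternative ("Theil-T") answers a
different question and is out of scope.

### Zero resource shares

A province with people but none of a resource makes $\ln(p_i/y_i)$
infinite. Silent infinities would corrupt every downstream trend series, so
the default policy is `zero_policy = "error"`, naming the offending unit;
`"drop"` excludes the unit, renormalizes both share vectors and warns. The
same policy applies at region level inside the decomposition.

## Indicators and rounding conventions

Densities are `count / population` (population in 10,000-person units, the
yearbook convention; a `population_unit` column of raw `persons` is
converted on read) and `count / area` (km²). Three numerical conventions
matter and are deliberate:

* **Half-away-from-zero rounding** (`round_half_up()`): printed statistical
  tables use commercial rounding, not R's round-half-to-even.
* **`percent_change(mode = "table_rounded")`** first rounds both densities
  to 2 decimals and then differences. This is the convention under which
  the published 2013–2018 changes (+8.72% personnel, +24.68% beds, +50.28%
  equipment, −43.48% institutions) are exactly reproducible from the printed
  2-decimal densities; whether the original analysis rounded before or after
  differencing is not stated, but only before-rounding reproduces its
  figures, so that is the fixture-matching default. `mode = "raw"` uses
  unrounded densities (giving e.g. −43.56% for institutions).
* **Ratios on printed precision.** The packaged 2018 provincial table
  stores the 3-decimal densities as printed; quoted comparisons (Shanghai
  vs Tibet per-km² personnel: $1.403/0.001 = 1403$) are computed on those
  stored values, documented as such.

`extremes()` reports the min/max province (alphabetical tie-break, for
determinism) and the max/min ratio, with a zero minimum yielding an `NA`
marker instead of infinity. One data inconsistency is worth knowing: for
per-capita technical personnel in 2018 the provincial table's maximum is
Guangxi (7.333), while the accompanying narrative compares Hainan (6.301)
to Anhui (2.709) as if Hainan were the maximum — the same source's
discussion section itself names Guangxi as the highest. `extremes()`
reports the honest maximum; `density_ratio()` reproduces the printed
pairwise comparison ($6.301/2.709 \approx 2.3$).

National `TOTAL` rows are aggregated by summing counts and populations
*before* dividing, i.e. the TOTAL density is the population-weighted mean
of province densities (tested to $10^{-9}$).

## The packaged tables

* `paper_fixture("totals_2013_2018")`: six national-total records with raw
  counts — supports the full pipeline.
* `paper_fixture("provinces_2018")`: 31 provinces with printed per-10k and
  per-km² densities for institutions, personnel and beds. The source prints
  densities, not counts, so the panel is flagged `values_are = "densities"`
  and count-requiring operations (Theil, `density_table()`) refuse it with
  a message pointing to `as_density_table()`; equipment is absent from the
  provincial table and therefore from this fixture.

The partition is the standard 12 western / 8 middle / 11 eastern grouping.
The romanization collision between Shaanxi and Shanxi (both spelled
"Shanxi" in the source lists, once in the western and once in the middle
group) is resolved by keeping distinct canonical names and letting
`canonicalize_province()` disambiguate by region label; matching is
case- and whitespace-insensitive and unmatched names are errors, never
guesses.

## The synthetic generator

`simulate_panel()` emulates the statistical structure the analysis assumes:
three regions (12/8/11 provinces), years 2013–2018, and for each province a
fixed population and area plus per-resource per-capita densities, with
counts formed as `round(density × population)`. Draws come from one seeded
generator in a fixed order (populations, areas, then base densities), so a
seed fully determines the panel and re-runs are bit-identical.

Modeling choices, made once:

* **Log-normal laws** for population, area and densities: all three are
  positive and right-skewed in the real tables (the 2018 provincial table
  spans ~12× per capita and ~1400× per km²). This is a modeling choice of
  this package, not a claim about the source data's law.
* **Level and scale defaults from the published tables**: density log-means
  sit at the 2018 provincial medians (institutions ≈ 0.13 per 10k,
  personnel ≈ 4.8, beds ≈ 1.7, equipment ≈ 5.3); drift factors are the
  5-year geometric mean changes of the national per-capita series
  (institutions 0.896 — the consolidation-driven decline — personnel
  1.022, beds 1.050, equipment 1.091); populations and areas use yearbook
  magnitudes (western provinces: fewer people, much larger areas).
  Density dispersion is higher in the west by default (log-scale 0.45 vs
  0.30/0.35), consistent with the wider western spread in the provincial
  table.
* **Zero floor**: rounded counts of 0 are bumped to 1 so default panels
  satisfy the `"error"` zero policy; `zero_floor = FALSE` produces true
  zeros for exercising `"drop"`.

What the generator does *not* emulate: spatial autocorrelation between
neighbouring provinces, province-specific drift, measurement revisions
between yearbook editions, and any calibration to the real panels beyond
the level/drift magnitudes above. Passing tests on synthetic panels
therefore demonstrate the correctness of the arithmetic and the qualitative
recoverability of dispersion differences — not that the generator's numbers
match any province's actual series.

```{r example}
panel <- simulate_panel(simulation_config(seed = 7))
contribution_rates(theil_decompose(panel, "beds", 2018))
```

## Design choices in genuinely open spots

* **Which share vector the published formula weights by** is taken
  literally: population shares weight $\ln(P_j/y_j)$, inside groups as well
  as between them.
* **Trend series on ragged panels**: a year with no counts for the
  requested resource is skipped with a warning rather than interpolated.
* **Reports**: `run_report()` stores the exact module outputs (no
  recomputation), serializes to JSON as the canonical representation
  (timestamps excluded, numbers at full precision), and round-trips
  losslessly — re-running on identical input gives byte-identical files.
  On a densities-only panel the count-requiring stages are skipped with
  explicit warnings recorded in the report.
* **Tolerances**: share-sum validation $10^{-9}$; the decomposition
  identity and rate-sum checks $10^{-12}$; both configurable where they
  appear.

## Problem sizes used in the tests

The suite runs entirely on packaged tables, hand-built 4-province cases
with hand-worked decompositions, and generated data: 300–1000 randomized
panels (4–40 provinces, 2–4 groups) for the algebraic properties, and 200
seeded simulations for the dispersion-recovery check (a western log-scale
of 0.6 against 0.1 elsewhere, equal means, is recovered as the top
contributing region in essentially every run). These sizes make the
properties sharp while keeping the default test run to well under a minute.

## Known limitations

* The real yearbook province-year panels are not shipped; published
  per-year Theil values that depend on them are not reproduced here, only
  the structure of those series on synthetic data.
* The provincial fixture stores printed 3-decimal densities, so ratios on
  it inherit printing precision (e.g. Tibet's 0.001 per-km² personnel makes
  the 1403 ratio exact only at printed precision).
* Equipment exists only in the national series, not the provincial table.
* The Theil index is population-weighted; no resource-weighted variant,
  Gini, Atkinson or dissimilarity index, and no bootstrap intervals.
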