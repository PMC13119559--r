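---
title: "Stratified Intensity Analysis of land-cover change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified Intensity Analysis of land-cover change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcintensity)
```

## The problem and the model

Net land-cover change numbers hide turnover: a forest area that loses
100,000 km² to cropland while regrowing 95,000 km² elsewhere looks almost
stable in a net budget. Intensity Analysis (the Aldwaik–Pontius hierarchy)
works on the full area cross-tabulation matrix of each time interval and
asks three nested questions, each against a *uniform* baseline:

1. **Interval level.** For interval $t$ of duration $\Delta Y_t$ with
   transition areas $C_{tij}$, the annual change intensity is
   $$S_t = \frac{\sum_{j}\sum_{i \ne j} C_{tij} / \Delta Y_t}
                {\sum_{j}\sum_{i} C_{tij}} \times 100\,\%.$$
   The uniform intensity $U$ spreads all change evenly over the study span;
   we compute it as $\sum_t \mathrm{gross}_t \,/\, \sum_t \Delta Y_t\,
   \mathrm{total}_t \times 100$, which reduces to the textbook single-total
   formula when map totals are constant but stays well-defined under small
   nodata drift. $S_t > U$ makes interval $t$ *fast*, $S_t < U$ *slow*.

2. **Category level.** Gain intensity $G_{tj}$ divides a category's annual
   gross gain by its end size $C_{t\cdot j}$; loss intensity $L_{ti}$
   divides its annual gross loss by its start size $C_{ti\cdot}$. A category
   is an *active* gainer (loser) when $G_{tj} > S_t$ ($L_{ti} > S_t$),
   *dormant* otherwise.

3. **Transition level** (gain perspective). For a gaining category $n$,
   $R_{tmn} = C_{tmn}/(\Delta Y_t\, C_{tm\cdot}) \times 100$ measures how
   hard $n$ draws from each losing category $m$, and
   $W_{tn} = \sum_{i\ne n} C_{tin} / (\Delta Y_t \sum_{i\ne n}
   C_{ti\cdot}) \times 100$ is the rate if $n$ gained uniformly from all
   available non-$n$ area. $R > W$ marks the transition *targeted*,
   $R < W$ *avoided*. $W_{tn}$ is algebraically the start-size-weighted
   mean of the $R_{tmn}$, which the test suite asserts on random matrices.

The stratified extension decomposes every one of these budgets into spatial
sub-regions (strata): the contribution of stratum $k$ to an interval's gross
change, to a category's gross gain/loss, or to a specific transition's area
is the stratum's area divided by the sum over strata, times 100. All
contributions are defined on areas, not intensities; when the denominator is
zero they are reported as undefined rather than zero. Repeating the
targeted/avoided classification across all intervals yields the
*stationarity* table, and pairs that are targeted persistently while moving
substantial first-to-last area become *dominant transition pathways*
(deforestation, forest degradation, agricultural expansion, wetland
expansion, shrub degradation, desertification in the default ten-class
configuration).

## Worked example

A three-category matrix over a 5-year interval (areas in km²):

```{r}
labs <- c("A", "B", "C")
m <- transition_matrix(matrix(c(75, 15, 10,
                                 5, 90,  5,
                                 0,  0, 100), 3, 3, byrow = TRUE,
                              dimnames = list(labs, labs)),
                       1985, 1990)
interval_intensity(m)
category_intensities(m)
transition_profile(m, "B")
```

35 of 300 km² changed (11.7 % of the map, 2.33 %/yr). Category A is an
active loser (5 %/yr > 2.33), B an active gainer. B draws from A at
3 %/yr against a uniform expectation of 1.5 %/yr: A→B is targeted, C→B
avoided.

## Classification conventions

- **Strict inequalities, explicit ties.** fast/active/targeted require a
  strict `>`; exact equality gets status `"equal"` rather than being forced
  to either side. With real-valued areas ties are measure-zero, but they
  occur in degenerate fixtures (all-zero gains) and deserve their own label.
- **Undefined, not zero.** A zero denominator — a category absent at the
  relevant date, a transition with no available source area — yields an
  `NA` intensity with status `"undefined"`. Undefined entries are excluded
  from the weighted-mean identities and from classification; forcing them to
  0 would fabricate "dormant"/"avoided" judgements about absent categories.
- **Full precision internally.** Intensities are carried as doubles and
  rounded only for display; the cross-level identities are asserted at
  relative tolerance 1e-10 in the tests.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_targeted_frac` | 0.5 | fraction of intervals a pair must be targeted in to count as a dominant transition |
| `min_area_km2` | top decile | minimum first-to-last transition area; the default is the 90th percentile of positive pair areas |
| `area_drift_tol` | 1e-6 | relative per-stratum total-area drift above which `validate_series()` warns |
| `targeted_only` (network) | `TRUE` | sum edge areas over targeted intervals only, or over all intervals |

The dominance thresholds are genuinely free parameters — "persistently
targeted" and "substantial area" are qualitative criteria — so both are
exposed, and `select_dominant_transitions()` is monotone in both (raising a
threshold never adds a pair). The network sums edge areas over targeted
intervals by default because the network is a summary *of targeted
transitions*; the all-intervals variant is one flag away since either
reading is defensible.

With matrix-only input there is no per-cell first-vs-last cross-tabulation,
so the first-to-last matrix used for area ranking is chained from the
interval matrices (`chained_first_last()`): each interval matrix is
row-normalised into conditional proportions and the chain is composed. This
is exact only if aggregate flows are Markovian; with map input the direct
`crosstab()` of the first and last maps is preferred and
`label_trajectories()` uses maps only. Trajectory maps compare first and
last dates only — intermediate reversals are invisible by design.

## The synthetic landscape generator

`simulate_series()` generates what the analysis assumes: per-stratum grids
whose cells evolve independently under an annual row-stochastic Markov
kernel, compounded to `K^ΔY` over each interval. This deliberately exercises
the framework's duration normalisation through the unequal final interval
(2020–2022, 2 years, against 5-year steps). The landscape is closed, so
per-stratum totals are exactly constant — the cleanest case for the
conservation invariants. Design choices:

- **No spatial autocorrelation.** Intensity Analysis consumes only the
  matrices, which are invariant to spatial arrangement, so patch structure
  would add cost without adding test power. Consequently passing tests say
  nothing about spatial pattern realism, georeferencing edge cases, or
  classification noise ("flicker") in real products — only about the
  statistics downstream of the cross-tabulation.
- **Neutral null kernel.** `availability_kernel(shares, rate)` sets
  $K[m,n] = \text{rate} \cdot s_n$ for $m \ne n$: every losing category
  feeds a gaining category at the same per-area rate, so $R = W$ in
  expectation for every pair and targeted/avoided flags are coin flips.
  (Renormalising each row's off-diagonal mass would re-introduce a
  systematic $1/(1-s_m)$ dependence on the loser — that variant is *not*
  neutral.)
- **Ground truth by injection.** `inject_target()` multiplies one kernel
  entry and repairs the row sum on the diagonal, creating a transition that
  must be recovered as targeted in every interval, ranked first, and
  attributed to the boosted stratum.
- **Determinism.** One global seed; per-stratum substreams are derived from
  it, so per-stratum results do not depend on evaluation order.
- **Exact oracle.** `expected_matrix()` returns
  $\mathrm{diag}(\text{start areas}) \cdot K^{\Delta Y}$ with start areas
  propagated analytically — the reference that seed-averaged empirical
  matrices must approach within three standard errors.

The default configuration (`default_sim_config()`) emulates a continental
multi-decadal design: ten Level-1 classes, five strata (EAF, MED, SAF, SAH,
WAF), nine time points 1985–2022. Initial compositions make the vegetated
classes dominant and the minor classes (tundra, snow/ice) rare-to-absent by
stratum, and annual change rates are graded 0.003–0.016 so the southern
stratum is most dynamic and the arid strata near-stagnant; the resulting
continental uniform intensity is of order 0.6 %/yr, the magnitude at which
the framework is typically applied. These defaults were fixed once as the
package's reference conditions and are not tuned per analysis. Problem
sizes used by the tests and the acceptance script — 120×120 cells per
stratum for the reference landscape, 200×200 × 3 strata for recovery
checks, 120 seed replicates for convergence — keep each run in seconds
while leaving multi-sigma margins on every recovery criterion.

## Degenerate inputs and numerical notes

- A matrix with zero total area is an error at the interval level; a
  stratum with no analyzable cells is an error at cross-tabulation.
- Cells nodata at *either* date are excluded from that interval's matrix
  entirely, keeping row/column sums interpretable as start/end sizes.
  `validate_series()` reports the resulting per-stratum area drift as a
  warning, not an error, since real products rarely have perfectly stable
  masks.
- Dominant-stratum ties are broken by stratum declaration order —
  deterministic and order-reportable, at the cost of being arbitrary for
  exact ties.
- `sum_strata()` is associative and permutation-invariant, so continental
  statistics do not depend on stratum ordering (asserted in tests).

## Limitations

- The loss-perspective transition statistics of the original framework
  (how a losing category distributes its losses) are not implemented; only
  the gain perspective is.
- Raster I/O is plain-text ESRI ASCII grid with JSON sidecars; there is no
  GeoTIFF reader/writer, no reprojection, and grids are compared by
  identity, not alignment.
- The chained first-to-last matrix is an approximation whenever aggregate
  flows are non-Markovian; prefer map input for trajectory work.
- Contribution percentages are area shares; intensity-based regional shares
  are intentionally out of scope.
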