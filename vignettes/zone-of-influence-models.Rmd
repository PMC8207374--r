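---
title: "Spatially extended neighborhood models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially extended neighborhood models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crownzoi)
```

## The model

Classical neighborhood competition models treat trees as points: the
influence of a neighbor on a focal tree is its basal area
(ba = gbh²/4π, cm²) weighted by the inverse of the stem-to-stem distance,
summed over all larger surviving neighbors within a radius *r*. `crownzoi`
implements the *spatially extended* alternative, in which each tree's zone
of influence is a disc of crown radius

cr = a + b·√gbh

(defaults a = −1.003 m, b = 0.523 m·cm^−1/2^, a pooled multi-species
allometry; a rounded variant a = −1.0, b = 0.52 is provided for worked
examples). The disc is filled with randomly placed points that partition
the tree's basal area:

* **equal** — a fixed density of 10 points per m² of crown area;
* **larsm** — as many points as the tree's basal area in cm², so larger
  trees get disproportionally denser crowns and the total point count of a
  plot equals its total basal area.

In both modes every point carries weight ba/N, so summed weights equal ba
exactly; this is the convention we adopt for "equal" filling, where the
mapping of points to basal area is otherwise under-determined.

**Crown plasticity.** A point of a smaller tree is *shaded* when a point
of a strictly larger tree lies within a tolerance Δd, applied separately
for conspecific (Δd_CON) and heterospecific (Δd_HET) neighbors on the grid
0.0, 0.2, …, 1.2 m (49 combinations). Shaded points are either *removed*
(pruning: the tree's effective basal area shrinks) or *relocated* into the
outermost (lowest positive density) contour of the tree's unshaded points,
mimicking growth toward light. Adjustment is hierarchical from the largest
tree down ([A → B] → C): each tree is flagged against the
*already-adjusted* clouds of all larger trees. At Δd = 0 nothing is
flagged, because exact coincidence of two independently placed points has
probability zero. A fully flagged tree vanishes as a neighbor.

**Predictors and regressions.** For each focal tree (those 10–<100 cm gbh,
alive at the period start, ≥20 m from every plot edge) the CON/HET/ALL
predictors are decayed point-weight sums over radii 1–20 m in 1-m steps;
1 cm² is added before the log transform so empty neighborhoods map to
zero. Growth (ln of annual basal-area increment) is modeled by least
squares and survival by logistic regression:

ln(agr) = intercept + α·ln(ba_t1) + β·ln ΣbaCON + γ·ln ΣbaHET + ε

Per species and period, a fit is produced for every grid cell
(r_CON, r_HET, Δd_CON, Δd_HET) — 19,600 cells for the full spatial
two-term scan, 400 nonspatially — and coefficients are averaged,
unweighted, over all fits within 2 AICc of the best cell. Growth effect
sizes are signed squared partial correlations t²/(t² + df); survival
effects are raw logistic coefficients, with (exp(β) − 1)·100 the percent
change in odds.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| allometry variant | published17 (−1.003, 0.523) | crown radius from √gbh; "rounded" only for worked tables |
| fill mode, density | larsm; 10 m⁻² for equal | crown point allocation |
| Δd grid | 0–1.2 m by 0.2 | overlap tolerance (CON and HET separately) |
| radii | 1–20 m by 1 | neighborhood radii for CON and HET |
| decay | linear (1/d) | none and squared (1/d²) available |
| distance floor | 0.1 m | decay distances are floored at the coordinate resolution, bounding weights |
| size class | [10, 100) cm gbh | half-open focal interval |
| border | 20 m | closed test (a tree exactly on the line is focal) |
| agr floor | 0.01 cm²·y⁻¹ | non-positive growth before ln (dropping is an option) |
| AICc band | 2 | model-averaging window; |ΔAICc| > 7 marks a strong difference from the reference model |

`agr` is defined on basal area (cm²·y⁻¹): the growth model regresses
against ln(ba) and sums basal areas, so a basal-area increment keeps the
response and predictors on one scale; a gbh-based rate (cm·y⁻¹) is
available via `growth_rate(basis = "gbh")`.

## Numerical choices

* **Point counts** round half-away-from-zero and are floored at 1; weights
  are ba/N rather than exactly 1 cm² per larsm point, keeping
  Σweights = ba exact for every tree.
* **Seeding.** One master seed; each tree derives a 31-bit substream from
  a string hash of (seed, tree_id, purpose), so filling and relocation are
  independent of iteration order and reproducible tree-by-tree.
* **Shading queries** prune candidate neighbors by bounding boxes in R and
  run an early-exit brute-force distance check in C++; results are
  identical to the all-pairs check (tested).
* **Relocation contour.** 2-D normal-kernel density of the unshaded
  points (normal-reference bandwidth per axis, 25 × 25 grid padded by one
  bandwidth); the target region is the contour at the smallest positive
  grid density, which may extend beyond the original disc. Points are
  placed by rejection sampling; with fewer than three non-collinear
  unshaded points, relocated points fall on jittered copies of unshaded
  points (sd = 5% of cr).
* **Ties.** Equal-gbh trees never shade each other; neighbor inclusion
  uses gbh ≥ focal gbh (excluding the focal itself). Ties are
  measure-zero for continuous sizes.
* **Closed boundaries.** A neighbor (or point) exactly at distance r is
  inside; contributions are summed in (distance, id) order so the
  spatial machinery with cr = 0 reproduces nonspatial sums bit-for-bit —
  a correctness check run in the test suite.
* **Degenerate fits.** Rank-deficient designs, one-class survival
  outcomes, non-convergence, and logistic SEs above 100 are flagged and
  excluded from averaging, never silently dropped; grid scans record
  failures and continue.
* **Adjusted pseudo-R².** R²_L = 100(L₀ − L_p)/L₀ is df-adjusted with the
  linear-regression formula 1 − (1 − R²)(n − 1)/(n − p), the natural
  reading of "adjusted as in least squares".

## The synthetic forest

`synthetic_spec()` describes the emulated study system: two
100 × 400 m plots with 20 m analysis borders, censuses spanning periods of
10.00 and 11.07 years, ~20 species with log-series rank abundances,
Thomas-process clustering (2 parents·ha⁻¹ per species, 10 m cluster sd),
2000 stems·ha⁻¹ at ≥10 cm gbh with truncated-exponential girths
(rate 0.05 cm⁻¹ above 10 cm, capped at 300 cm — about 21 m²·ha⁻¹ of basal
area), and growth/survival drawn from the package's own regression
equations (defaults: growth intercept 0.2, α 0.5, β_CON −0.2, γ_HET −0.1,
σ 0.6; survival intercept 3.0, α 0.3, β_CON −0.3, γ_HET −0.1; true radii
10 m; Δd 0; linear decay). Survival is drawn from the largest tree down so
each tree's probability depends only on already-decided larger survivors —
making the generative neighbor set identical to the one the fitted models
use; growth then uses the surviving larger-or-equal neighbors. Because agr
is lognormal it is positive by construction (no shrinkage), and dead trees
keep their last measured gbh.

The generator emulates plot geometry, clustering, size structure and the
response equations. It does not emulate measurement error, recruitment,
climate-driven period differences (coefficients may simply be changed
between periods), crown asymmetry, or species-specific allometries — so
green tests demonstrate that the estimation machinery recovers known
parameters under the stated model, not that the model is adequate for any
particular forest.

**Problem sizes.** The test suite validates on single plots of 0.6–2 ha
at 400–900 stems·ha⁻¹: parameter recovery uses 20 stands of ~1800 trees
(~500 focal) fitted over a reduced radius grid {6, 10, 14} m containing
the true radius, and the randomization null uses a 1.4 ha neutral forest
with 20 randomized layouts. These sizes give Monte-Carlo errors well below
the effects being tested while keeping the default suite quick.

## Randomization nulls

`randomize_positions()` re-places every tree uniformly, largest first,
subject to minimum nearest-neighbor distances by gbh size class (six
classes with bounds 10/30/60/120/240/480 cm; defaults 1 m within and
0.5 m between classes, all configurable — the exact field rules come from
unpublished prior-study material, so the defaults are documented
assumptions). Species, sizes and statuses are untouched, so per-species
size structure is preserved exactly. Observed effects are classified
against mean ± 3 SE of the effect across randomized layouts, where SE is
the *standard deviation across runs* (the standard error of a single
randomized estimate): under a neutral forest this gives the expected
~99.7% coverage, whereas sd/√n′ would reject almost everything.
Departures |observed − null mean| are banded as moderate (0.06–<0.1
growth, 0.6–<1.0 survival) or large (≥0.1, ≥1.0).

## Design decisions that were genuinely open

* **Flagging against adjusted clouds.** Whether a smaller tree is flagged
  against the larger tree's original or adjusted cloud is ambiguous; we
  flag against the adjusted cloud, the only reading under which
  hierarchical adjustment leaves no residual overlap (re-checked in the
  suite for removal mode).
* **"Equal" weights.** Only the larsm mode has a stated basal-area
  identity; we give equal-mode points weight ba/N so both modes conserve
  ba (the alternative, unit weights, would decouple the predictor scale
  from basal area).
* **Survival neighbors.** The surviving-neighbor condition is stated for
  growth; we apply it to survival models too, for consistency of the
  predictor definition (and the generator draws survival top-down to keep
  that definition self-consistent).
* **Plot basal area per species** (community regressions) is computed at
  the period-start census over all stems ≥ 10 cm gbh, whole plot.
* **Borders** are applied per plot; multi-plot studies run the pipeline
  per plot and pool the per-species tables.

## Limitations

Crowns are circular at fill time and 2-D throughout (no height or crown
depth); point filling happens once per configuration rather than being
averaged over refills; relocation after adjustment can in principle place
points near larger crowns again (only removal guarantees zero residual
overlap); the Procrustes comparison and other community analyses assume
matched species sets; and the location randomization preserves size
structure but not habitat association or dispersal topography.
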