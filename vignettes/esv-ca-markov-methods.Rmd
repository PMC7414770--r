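---
title: "Methods: CA-Markov land-change simulation and equivalent-factor ESV accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CA-Markov land-change simulation and equivalent-factor ESV accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esvca)
```

This vignette is the package's own account of the methods it implements:
the models, the tunable parameters, the numerical conventions, and the
limits of what the synthetic tests demonstrate.

## The problem

Land-use/land-cover change (LUCC) reshapes the flow of ecosystem services —
water regulation, soil retention, food, habitat. The package couples the two
standard workhorse methods used to study this at regional scale:

1. **CA-Markov simulation** of the categorical land-cover map: a Markov
   chain decides *how much* area each class gains or loses, a cellular
   automaton decides *where* on the lattice those changes land.
2. **Equivalent-factor (benefit-transfer) valuation**: each class carries a
   per-area annual value coefficient for each of nine ecosystem-service
   functions, so the ecosystem-service value (ESV) of a landscape is a
   bilinear form in areas and coefficients.

The bundled case study is the Northern Tianshan Mountain Economic Zone
(NTMEZ), an arid economic corridor in Xinjiang, China: a six-class
classification (forestland, grassland, cropland, water body, built-up land,
unutilized land), per-class areas for six snapshot years (1980–2030, the
last two simulated), and a 9 × 6 coefficient table in yuan·hm⁻²·a⁻¹ built
from a regional equivalent factor of 1,304.86 yuan/hm².

## Markov area projection

Given two dated maps, `cross_tabulate()` counts the area A_ij moving from
class i to class j. `estimate_probabilities()` row-normalises these counts
into the transition-probability matrix A, and areas are projected as
S(t+1) = S(t) · A. Two conventions are fixed here:

* **Zero rows.** A class absent at the first date yields a zero row, which
  has no maximum-likelihood estimate. We substitute the identity row — an
  absent class persists trivially — because it is the only choice that keeps
  A row-stochastic without inventing transitions no data support.
* **Period handling.** A matrix calibrated on a d-year interval is applied
  once per d-year step, with no implicit rescaling. `rescale_period()`
  exposes integer matrix powers explicitly (nearest power, flagged, for
  non-integer multiples); embedding a fractional power via a matrix
  logarithm is out of scope because it can produce negative "probabilities"
  and is not identifiable from two dates.

Row-stochasticity makes total area an exact invariant of projection; the
tests assert it at machine precision.

## Cellular-automaton allocation

The CA's transition rule needs a notion of local suitability. With no
ancillary layers (elevation, roads, climate) in scope, suitability is
**contiguity only**: the suitability of class c at a pixel is the fraction
of class-c pixels in the surrounding (2r+1) × (2r+1) window, the classical
CA-Markov contiguity filter. The default `kernel_radius = 2` (a 5 × 5
window) is the conventional choice; windows are edge-truncated so
suitabilities remain window fractions that sum to one.

Each projection step then:

1. projects current class pixel counts one step with A;
2. rounds the real-valued targets to integer quotas by the
   **largest-remainder method**, so quotas sum exactly to the landscape
   size;
3. scores every (pixel, class) pair as `A[i, j] × suitability_j` (i the
   pixel's current class) plus a seeded uniform jitter of amplitude 1e-9 —
   far below any genuine score difference, so it only breaks exact ties —
   and assigns greedily in descending score under the hard quotas.

The greedy pass provably fills every quota exactly (quotas sum to the pixel
count, and a pixel can only remain unassigned if some quota stayed open,
which contradicts the pair having been visited), so realized areas equal the
Markov marginals by construction; the seed is the only stochastic element,
and two runs with the same seed are pixel-identical. `iterations` (default
1) repeats the allocation pass with suitability recomputed on the evolving
map; one pass per 5-year step is the default because nothing in the method
constrains a higher count, and more passes only sharpen contiguity.

## Validation

`kappa_agreement()` computes the confusion matrix of a simulated against an
observed map and Cohen's Kappa, (P0 − Pc)/(1 − Pc), with P0 the observed
and Pc the chance proportion agreement from the marginals. Two maps that
are the same single class have Pc = 1; we report Kappa = 1 with a
`degenerate` flag rather than NaN, since agreement is perfect even though
chance correction is undefined. The conventional 0.70 acceptance threshold
is exposed via `agreement_pass()` as a configurable flag, not hard-wired.
Only overall Kappa is implemented; per-class Kappa and quantity/allocation
disagreement components are out of scope.

## Equivalent-factor valuation

The equivalent factor E_a is one seventh of the economic value of the
average annual grain yield of one hectare of cropland,
E_a = (1/7) Σ_i M_i p_i q_i / M over the staple crops (`equivalent_factor()`).
The 1/7 convention is fixed; the bundled NTMEZ coefficient table is already
expressed in these units, so E_a enters the package as documentation and as
an operation, not as a runtime input of the valuation.

Valuation itself is bilinear: per-class value A_i × VC_i
(`compute_esv()`), per-function value Σ_i A_i × VC_if
(`esv_by_function()`), per-zone value via masked area tabulation
(`esv_by_zone()`). Additivity — functions, classes and zones all summing to
the same total — is asserted at 1e-12 relative tolerance in the tests.

### Unit convention

The NTMEZ reference tables carry areas in km² and coefficients per hm², yet
their reported 10⁸-yuan values equal (area in km²) × (coefficient) / 10⁸ —
the km²→hm² factor of 100 is absent from the reported scale. The package
therefore declares an explicit `unit_convention`:

* `"tabulated"` (default): multiply km² areas by the per-hm² coefficients
  directly. Reproduces the reference report tables digit for digit.
* `"si"`: convert km² to hm² first; every value is exactly 100 × larger.

The conventions differ by a global factor only, so shares, change rates and
elasticities are identical under both.

### Coefficient totals

The reference coefficient table prints a per-class "Total" row that differs
from its own column sums by up to 0.02 yuan·hm⁻²·a⁻¹ (last-digit rounding
of the printed entries). `esv_coefficient_table()` checks the printed row
against the exact column sums (tolerance 0.05) and then discards it: all
computations use the exact column sums, which is what makes the additivity
identities exact. We verified that every reported per-class value, total
and change rate still reproduces identically at two decimals under either
choice.

### Rounding of report tables

Reported values are rounded **half away from zero** (`round_half_up()`),
the convention of the reference tables; base R's round-half-to-even would
differ on boundary cells. One genuine quirk of the reference tables is
documented here because the acceptance tests encode it: the per-class table
was rounded once to two decimals, while the per-function table was
evidently rounded to three decimals first and then to two. Under single
rounding, four per-function cells (and that table's 1990/2000 totals, which
disagree with the per-class table's totals for the same quantity) differ by
one unit in the last digit; under the two-stage chain, every cell of the
per-function table reproduces exactly. `report_table()` takes an optional
`intermediate_digits` argument so either chain can be requested explicitly;
the package default is the standard single rounding.

## Coefficient sensitivity (elasticity)

`coefficient_sensitivity()` scales one class's entire coefficient column by
(1 + δ) (default δ = 0.5, the conventional ±50 % test), recomputes the
total, and reports the elasticity
CS_k = (relative change of total ESV) / (relative change of VC_k). The
elasticity is written with the coefficient's relative change in the
denominator — the standard economic form; a form with ESV in both numerator
and denominator is dimensionally circular. Because the valuation is linear,
CS_k equals class k's signed share of the total, is independent of δ, and
is strictly below 1 whenever at least two classes carry positive value —
the structural sense in which equivalent-factor ESV estimates are robust
(inelastic) to coefficient uncertainty. The sensitivity table reported for
the NTMEZ case study in the literature is not reproducible under any
normalization of this definition we could identify and is deliberately not
a test target; the package reports the elasticity as defined.

## Synthetic landscapes

`landscape_spec()` + `generate_initial()` + `evolve()` emulate the inputs
the real workflow would take from classified satellite imagery:

* the initial map is an i.i.d. categorical field with prescribed class
  proportions (defaults approximate the case study's 1980 mix at 30 m
  cells), optionally majority-filtered to create contiguous patches;
* subsequent dates resample each pixel independently from its row of a
  prescribed transition matrix, so expected areas follow the Markov
  projection exactly and `estimate_probabilities()` is consistent for the
  generating matrix;
* zones are near-square rectangular tiles, a stand-in for administrative
  regions in zonal accounting.

This is an idealisation. Real land change is spatially autocorrelated in
its *transitions* (not just its states), classification error is not
independent noise, and real suitability is driven by covariates the
contiguity filter cannot see. Passing tests therefore demonstrate the
estimator and the allocator are correct *under the stated sampling model*,
not that the CA reproduces any particular real landscape; the case study's
own simulated-map agreement cannot be re-derived without its rasters.

## Problem sizes and numerical tolerances

The test suite exercises: transition-matrix recovery and null-Kappa checks
on 250 × 400 (10⁵-pixel) synthetic maps, with recovery asserted below 0.02
max-absolute error (three-seed median) and null Kappa within ±0.02 —
three-standard-error bounds under the generators' multinomial sampling;
quota exactness on 100 × 100 maps (tolerance zero, by construction);
byte-identical pipeline reruns on 200 × 200 end-to-end simulations with two
calibration dates, two horizons and zonal accounting, chosen as a
realistically patchy landscape that keeps the whole suite fast; and exact
two-decimal reproduction of the bundled case-study report tables.
Cross-table additivity is asserted at 1e-12 relative tolerance, stochastic
conservation identities at machine precision.

## Known limitations

* Suitability is contiguity-only; multi-criteria potentials (terrain,
  accessibility, zoning, logistic/neural transition models) are out of
  scope.
* The equivalent-factor method is static benefit transfer: coefficients do
  not respond to ecosystem condition, prices, or supply-demand context, and
  negative externalities beyond the built-up class's two cost terms are not
  modelled.
* Period rescaling is restricted to integer matrix powers.
* Rasters are exchanged as ESRI ASCII grids; pixel lattices are assumed
  square-celled and co-registered, and georeferencing passes through
  untouched rather than being interpreted.
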