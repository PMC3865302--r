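---
title: "Methods: geographically weighted analysis of burned area and population density"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geographically weighted analysis of burned area and population density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popfire)
```

## The scientific problem

The relationship between human population density and fire is not one
relationship: people ignite fires, produce and fragment fuel, and suppress
fire, and the balance of those effects differs from region to region. A
single global regression of burned area on population density therefore
averages away most of the signal. `popfire` implements the toolchain for
studying that spatial variation on a lon/lat grid of cells carrying mean
annual burned area (km² yr⁻¹, the response) and population density
(persons km⁻², the predictor), both decimal-log transformed because both
are strongly skewed toward small values.

## Data model and preprocessing

A cell record carries centroid coordinates, burned area, population density,
a combustibility flag, an optional major-anthrome label, an optional
continent label, and the cell's area. Cell areas use the spherical latitude
correction `(R·d)·(R·d·cos(lat))` with `d` the resolution in radians and
`R = 6371` km; a spherical rather than ellipsoidal model is used because the
sub-percent difference is irrelevant next to the kernel scale, and summed
areas over a full globe agree with `4πR²` to better than 0.5% at any
resolution. Non-combustible cells (water, ice, artificial surfaces in real
data) are removed before fitting.

Zeros are undefined under the decimal log. The default policy drops cells
with zero burned area or zero population rather than flooring them at an
arbitrary constant, because a floor constant shared by many cells acts as a
high-leverage cluster in log space and can dominate local fits; a
`floor(eps)` policy is available where retention matters more. Distances are
great-circle (haversine) on the `R = 6371` km sphere: at continental extents
planar degree distances are badly anisotropic.

Aggregation to coarser resolutions (for sensitivity analyses) sums burned
area over child cells, averages population density with cell-area weights,
takes anthrome and continent by majority area, marks a parent combustible if
any child is, and re-applies the transforms and mask afterwards.

## The local regression model

At each cell `i` the model is

y_j = β₀(u_i, v_i) + β₁(u_i, v_i) · x_j + ε,  ε ~ N(0, σ²),

fitted by weighted least squares with weights
`w_ij = exp(-½ (d_ij / b_i)²)`. The kernel is adaptive: `b_i` is the
distance to the `k`-th nearest neighbour of cell `i`, so the kernel widens
where cells are sparse (coastlines, masked regions). The Gaussian is left
untruncated; with two regression parameters per cell the whole fit reduces
to vectorised 2×2 normal equations, so truncation buys nothing here.

Writing `S` for the hat matrix that maps `y` to the GWR fitted values, the
model's effective number of parameters is `p_eff = 2·tr(S) − tr(SᵀS)`, the
definition used by the classical GWR software lineage. `tr(S)` is also
exposed: where a complexity measure is needed the package defaults to
`p_eff` but the choice is explicit in the code. Residual variance is
`RSS/(n − p_eff)` and feeds the per-cell standard errors
`Var(β̂_i) = σ̂² (XᵀW_iX)⁻¹ XᵀW_i²X (XᵀW_iX)⁻¹`.

### Bandwidth selection

`k` is chosen by minimising the corrected AIC

AICc = 2n·ln(σ̂_ML) + n·ln(2π) + n(n + tr S)/(n − 2 − tr S),

with `σ̂_ML = sqrt(RSS/n)`. At `tr S = 2` this reduces exactly to the
small-sample AICc of a straight-line Gaussian model, and the `n·ln(2π)`
constant is kept in both the GWR AICc and the OLS AIC so the two are
directly comparable. The search is golden-section over integer `k` with a
final exhaustive sweep of ±2 around the incumbent, ties broken toward larger
`k` (the smoother model); an exhaustive mode exists as an audit oracle and
the two agree on seeded test worlds. The default search range is
`[max(16, 0.01n), 0.25n]`: below ~16 neighbours a 2-parameter local fit is
noisy even in clean data, and optima in strongly nonstationary data sit well
below 25% of `n`. The selected fraction `k/n` is always reported, never
imposed.

## Inference

**Per-cell t-tests.** Each local coefficient is tested against zero with
`t = β̂/se` and `n − p_eff` reference degrees of freedom (consistent with the
residual-variance denominator). Because thousands of cells are tested, the
family-wise rate `ξ₀` (default 0.05) is converted to a per-test level by
dividing by the effective number of independent tests: `α = ξ₀ · p / p_eff`,
which reduces to `ξ₀` when `p_eff = p`. The correction is a pluggable
function argument, since several variants exist in the local-statistics
literature; the default is the one with the stated semantics and the two
limits above.

**Nonstationarity permutation test.** Whether the coefficients vary in space
more than chance allows is tested by Monte Carlo permutation: the (x, y)
pairs are shuffled across the fixed cell locations — preserving the x–y
relationship, destroying its spatial arrangement, which is exactly the
hypothesis at issue — the GWR is refitted at the same `k`, and the spatial
variance of each local coefficient is recorded. With `n_perm = 99`,
`p = (1 + #{null ≥ observed})/(n_perm + 1)`. The kernel is held fixed across
permutations (the test conditions on the chosen bandwidth), which keeps the
test exact and fast. Maps are gated by the t-tests; the permutation p-value
is reported alongside as the global nonstationarity check.

**Sign classification.** Significant cells are classed by the sign of the
slope and of the intercept, giving four joint classes: a positive intercept
marks landscapes that burn even at negligible population (fire-prone), and
the slope sign says whether people amplify or suppress fire there.

## Population-density thresholds

The package fits continuous piecewise-linear ("broken stick") conditional
quantiles of log burned area against log population density at chosen levels
(default 50th and 90th percentiles). For each candidate breakpoint set `c`
on a grid spanning the central 90% of the x-range (default 101 candidates
per break, 1 or 2 breaks), the hinge basis `{1, x, (x−c)₊, …}` is fitted by
check-loss minimisation and the lowest-loss candidate wins, ties toward the
smallest breakpoint. Grid search is used deliberately: the optimal loss is
piecewise linear in `c`, so a grid is exactly auditable against brute force,
whereas smooth optimisers stall on the kinks. Candidates leaving fewer than
10 points in a segment are skipped.

The check-loss minimiser itself is iteratively reweighted least squares (a
majorise–minimise scheme with weights `|τ − 1[r<0]| / max(|r|, δ)`) followed
by a vertex polish: the optimum of this linear program interpolates `p` data
points, so the lowest-|residual| points after IRLS are enumerated as exact
interpolating bases and scored by exact check loss. On small samples this
reproduces a brute-force pair-enumeration oracle to 10⁻⁸. Breakpoints are
reported both on the log10 axis and back-transformed to persons km⁻².

## The synthetic world generator

Because the real rasters are external and large, every stage is exercised on
generated worlds with known truth. The generator follows the model's own
generative reading: a log-normal population field (log10 density
`N(0.5, 0.6)`, smoothed by a 3×3 moving average and rescaled, so the
predictor carries spatial autocorrelation as real population does), true
coefficient surfaces evaluated at cell centroids, and homoskedastic Gaussian
noise (default sd 0.3 in log10 units — comparable to the scatter the
log–log fire–population relation shows in practice). The default 50×50 grid
at 0.5° has a tanh-sigmoid slope surface crossing zero mid-grid, so positive
and negative regimes coexist as they do on real continents, and an intercept
surface varying linearly with latitude; 10% of cells are masked as
non-combustible holes. Amplitudes are chosen so `10^y` stays below the cell
area (caps are counted and are zero under the defaults).

The broken-stick generator plants a breakpoint at 7 persons km⁻²
(log10 ≈ 0.845) with slopes +0.8 then −0.5, noise sd 0.2, n = 2000, x
uniform on [−1, 2.5] — the rise–peak–decline shape. A location-scale noise
option (sd growing linearly in x) makes the 90th-percentile slopes differ
from the median's. Anthrome mosaics come as latitude bands or seeded Voronoi
blocks (convex, hence contiguous patches).

What the generator does **not** emulate: the actual spatial autocorrelation
spectrum of satellite burned area, its zero-inflation structure, anisotropic
coastlines, or measurement error in the population rasters. Passing tests
demonstrate the estimator's correctness and calibration under the stated
model, not the field accuracy of any real-data conclusion.

## Problem sizes and numerical choices

The test and acceptance runs use: 50×50 cells for surface recovery (slope
surface correlation ≥ 0.90; GWR beats OLS on adjusted R² and AIC), 200-cell
worlds for the OLS-limit and bandwidth-oracle checks, 100 stationary and 100
nonstationary 400-cell worlds with 99 permutations each for the test's size
(nominal 0.05, accepted within [0.02, 0.09]) and power (p ≤ 0.01 in ≥ 95
runs), and 50–100 replicates of the n = 2000 broken-stick scenario
(breakpoint within ±0.10 log10 units of the truth in ≥ 90%). These sizes
make the whole suite run in minutes on one core while keeping Monte Carlo
error well inside the acceptance bands.

Other numerical choices: singular local fits abort with the cell index
rather than being silently regularised; duplicate coordinates fall back to
the smallest positive neighbour distance with a warning; permutations that
produce singular fits are redrawn and counted; the IRLS loss tolerance is
10⁻¹⁰ relative with at most 60 iterations; all randomness flows from one
root seed through a documented linear splitting scheme, so identical
configurations give byte-identical CSV outputs.

## Known limitations

- One predictor only: no multi-predictor or semi-parametric (mixed) GWR.
- Only the adaptive Gaussian kernel; no bisquare/tricube variants.
- No spatially corrected standard errors beyond the hat-matrix framework;
  no false-discovery-rate alternative to the family-wise correction.
- No confidence intervals on quantile-regression breakpoints (a bootstrap
  hook is the natural extension).
- Grid I/O is CSV; raster formats are out of scope for this package.
- Continent membership is an input label, not computed from polygons.
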