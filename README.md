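# popfire

Geographically weighted analysis of the relationship between burned area and
human population density.

## The problem

People change fire regimes in opposite directions at once: they ignite fires
and produce fuel, but they also fragment landscapes and suppress burning.
A single global regression of burned area on population density therefore
explains almost nothing — the relationship differs in sign and strength from
region to region. `popfire` is a toolkit for analysts who want to map that
spatial variation on a gridded world of cells carrying mean annual burned
area (km² yr⁻¹), population density (persons km⁻²), a combustibility mask,
and optional anthrome (anthropogenic biome) and continent labels. Both
variables are decimal-log transformed before analysis.

## What it implements

**Geographically weighted regression (GWR).** At every grid cell `i` a local
model

    y_j = β₀(u_i, v_i) + β₁(u_i, v_i)·x_j + ε,   ε ~ N(0, σ²)

is fitted by weighted least squares with adaptive Gaussian kernel weights
`w_ij = exp(−½ (d_ij/b_i)²)`, where `d_ij` is great-circle distance and the
per-cell bandwidth `b_i` is the distance to the k-th nearest neighbour. The
neighbour count `k` is selected by minimising the corrected AIC

    AICc = 2n·ln(σ̂) + n·ln(2π) + n(n + tr S)/(n − 2 − tr S),

with `S` the hat matrix. The fit reports per-cell coefficients, standard
errors, t-statistics, local R², and the global effective number of
parameters `p_eff = 2·tr(S) − tr(SᵀS)`, plus a global OLS baseline on a
comparable AIC scale.

**Inference.** Per-cell two-sided t-tests with `n − p_eff` degrees of
freedom, at a per-test level `α = ξ₀·p/p_eff` derived from the family-wise
error rate `ξ₀` (default 0.05); a Monte Carlo permutation test of
coefficient nonstationarity (attribute pairs shuffled across fixed
locations); and classification of significant cells into the four
slope-sign × intercept-sign classes.

**Thresholds.** Continuous piecewise-linear ("broken stick") quantile
regression: for quantile level τ the hinge basis `{1, x, (x−c)₊}` is fitted
by check-loss minimisation over a grid of candidate breakpoints `c`,
locating the population density at which the fire response changes
direction. Breakpoints are reported in persons km⁻².

**Support machinery.** Latitude-corrected cell areas on the 6371-km sphere,
zero-handling policies for the decimal log, resolution aggregation with
area-weighted rules, anthrome cross-tabulations of significant slope signs,
a per-continent pipeline with reproducible CSV artifacts, a CSV grid format,
and a synthetic-world generator with known coefficient surfaces so every
stage is testable without external rasters.

## Worked example

```r
library(popfire)

scenario <- gwr_scenario(n_lon = 30, n_lat = 30, noise_sd = 0.3, seed = 42)
world <- simulate_gwr_world(scenario)
world$data <- assign_anthromes(world$data, layout = "blocks", seed = 42)
world$data
#> fire_grid: 810 cells at 0.5 deg (90 masked, 0 zero-dropped)
#>   y = log10(burned area km^2): [-3.13, 2.88]
#>   x = log10(pop density p/km^2): [-1.44, 2.67]

bw  <- select_bandwidth(world$data)
fit <- fit_gwr(world$data, gwr_kernel(k = bw$k))
ols <- fit_ols(world$data)
fit
#> fire_gwr: n = 810, k = 16 (2.0% of n)
#>   trS = 51.19, p_eff = 72.46, AICc = 448.87, adj R^2 = 0.892
ols
#> fire_ols: n = 810, slope = -0.1409, AIC = 2211.73, adj R^2 = 0.007
cor(world$truth$beta1, fit$cells$beta1_hat)
#> 0.992
```

The global OLS slope (−0.14, adjusted R² 0.007) says almost nothing: the
planted slope surface crosses zero mid-grid, so positive and negative
regimes cancel. The local model recovers that surface (correlation 0.992
with the truth) and explains 89% of the variance at a far lower AIC.

```r
alpha <- corrected_alpha(0.05, p_e = fit$p_eff, p = 2, n = fit$n)
tests <- local_t_tests(fit, alpha)
map   <- classify_cells(fit, tests)
summarize_run(fit, map, ols, label = "synthetic")
#>       label   n pct_significant_slopes pct_positive_slopes aic_ols  aic_gwr
#> 1 synthetic 810               92.22222            49.26372 2211.73 448.8706

d  <- simulate_broken_stick(broken_stick_scenario(seed = 42))
bs <- fit_broken_stick(d$x, d$y, tau = 0.5)
bs
#> fire_bstick: tau = 0.50, breakpoints (log10) = 0.844 (= 6.99 p/km^2)
#>   segment slopes: 0.806, -0.51; check loss = 159.7106
```

92% of cells have a significant local slope at the corrected level, split
almost evenly between positive and negative — the planted mosaic. The
broken-stick median regression recovers the planted threshold (7 persons
km⁻²): burned area rises with population density up to ~7 p/km² and declines
beyond it.

The same chain runs end to end per continent with
`run_continent(run_config(seed = 1, output_dir = "out"), dataset, "Africa")`,
or from a shell via `inst/cli/popfire.R` (subcommands `simulate`, `fit`,
`sensitivity`, `thresholds`, `crosstab`).

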