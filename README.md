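# stwreg

Global and space-time weighted regression for city-by-week air-pollutant
panels.

`stwreg` models a PM2.5 response against the five other criteria pollutants
(SO2, NO2, PM10, O3 in µg/m³; CO in mg/m³) observed on a spatial panel —
S cities at planar coordinates, T weekly periods — and implements the
five-model comparison used to separate spatial from temporal heterogeneity
in that relationship:

| model | heterogeneity handled | engine |
|-------|----------------------|--------|
| OLS   | none (benchmark)     | global least squares |
| LMM   | city random effects + AR(1) serial errors | REML, variance components `G = diag(σ₁²…σ₆²)`, AR(1) blocks `R[i,j] = σ²·r^|i−j|` |
| GWR   | spatial              | locally weighted LS, weights in spatial distance |
| TWR   | temporal             | locally weighted LS, weights in week distance |
| GTWR  | both                 | combined distance `d² = λ·d_S² + μ·d_T²` |

The local family solves `β̂(uᵢ, vᵢ, tᵢ) = (XᵀWᵢX)⁻¹XᵀWᵢY` at every record,
with adaptive bandwidths (distance to the k-th nearest record) and
neighbour counts selected by minimizing the smoother AICc

```
AICc = 2n·ln(σ̂) + n·ln(2π) + n·(n + tr(S))/(n − 2 − tr(S)),
```

where tr(S) is the hat-matrix trace. Shared diagnostics: adjusted and
conditional R², RMSE/MAE, residual Z scores, and Moran's I of residuals
over k-nearest-neighbour weights profiled against the neighbour count,
with randomization and permutation inference.

Because the monitoring data behind the emulated 13-city × 210-week design
were never deposited, the package ships a synthetic generator
(`simulate_panel()`) that reproduces the design's structure — seasonal
pollutant cycles driven by a shared heating-season factor, the reported
correlation sign pattern, city random effects, AR(1) errors with r = 0.552
— together with the generative ground truth for parameter-recovery tests.

## Worked example

```r
library(stwreg)

sim <- simulate_panel(sim_config(seed = 1))        # 13 x 210 mixed-mode panel
n_records(sim$ds)
#> [1] 2730

round(corr_matrix(sim$ds)["pm25", ], 3)
#>    so2    no2   pm10     co     o3   pm25
#>  0.548  0.516  0.667  0.618 -0.571  1.000

lmm <- fit_lmm(sim$ds)
lmm$ar1_r                                          # truth: 0.552
#> [1] 0.5508
round(c(ols_ra2 = fit_ols(sim$ds)$ra2, lmm_rc2 = lmm$rc2), 3)
#> ols_ra2 lmm_rc2
#>   0.518   0.860
```

The generated PM2.5 correlates positively with PM10/NO2/CO/SO2 and
negatively with O3; the mixed model recovers the AR(1) correlation it was
generated with and explains far more variance than the pooled OLS, because
it absorbs the city-level coefficient heterogeneity OLS averages over.

On a panel with space-time-varying coefficients the local models take
over (from `analysis/03_local_models.R` / `05_compare.R`, seed 1):

```
  model neighbors  aicc    r2  rmse   mae rmse_reduction_pct
1   ols        NA 22840 0.536 15.83 12.82                0.0
2   gwr       841 22642 0.574 15.07 12.36                4.8
3   twr        66 20360 0.829  9.21  7.32               41.8
4  gtwr       54 20199 0.846  8.59  6.82               45.7
```

TWR/GTWR cut RMSE roughly in half while GWR barely improves on OLS — with
13 distinct city locations there is little spatial information to borrow,
and the temporal signal dominates. The Moran profiles
(`analysis/04_diagnostics.R`) show the OLS residuals strongly clustered at
small neighbour counts (I = 0.65, p ≈ 0 at k = 12) while the LMM and GWR
residuals are statistically indistinguishable from random.

## The analysis workflow

Numbered drivers under `analysis/` run the full study pipeline on the
synthetic panels and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R --seed 1   # panels + correlation matrix
Rscript analysis/02_global_models.R       # OLS + LMM, per-city models
Rscript analysis/03_local_models.R        # GWR/TWR/GTWR with AICc selection
Rscript analysis/04_diagnostics.R         # Moran bandwidth profiles
Rscript analysis/05_compare.R             # five-model comparison tables
```

Stages must run in order (later stages read earlier outputs).

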