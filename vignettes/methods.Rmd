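---
title: "Models and methods: global and space-time weighted regression for pollutant panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stwreg)
```

## The problem

Regional PM2.5 is routinely modelled against the other criteria pollutants
(SO2, NO2, PM10, CO in a positive direction; O3, which is photochemical and
peaks in summer, in a negative one) on city-by-week panels. A single global
regression assumes one constant relationship across all cities and weeks;
on real panels that assumption fails in two distinct ways — city-level
heterogeneity (each city's emission mix shifts the coefficients) and
temporal heterogeneity (heating seasons change the relationship through the
year) — and its violation shows up as spatially and temporally
autocorrelated residuals. `stwreg` implements the five-model ladder used to
quantify this: OLS as benchmark, a linear mixed model (LMM) that absorbs
city heterogeneity and serial correlation globally, and the local family
GWR / TWR / GTWR that lets every coefficient vary over space, time, or
both.

## The models

**OLS.** `fit_ols()` fits
\(Y_i = \beta_0 + \sum_k \beta_k X_{ik} + \varepsilon_i\)
by QR, with classical standard errors, two-sided t tests on \(n - p\)
degrees of freedom, standardized estimates
\(\hat\beta_k\,\mathrm{sd}(X_k)/\mathrm{sd}(Y)\), the adjusted
\(R^2_a = 1 - (n-1)(1-R^2)/(n-p)\) and the corrected AIC below.

**LMM.** `fit_lmm()` fits \(Y = X\beta + Z\gamma + \varepsilon\) with one
random effect per city on the intercept and all five slopes. The
random-effect covariance \(G\) is diagonal (variance components
\(\sigma_1^2 \dots \sigma_6^2\)); the within-city error covariance \(R\) is
AR(1), \(\sigma^2 r^{|i-j|}\), so the marginal covariance
\(V = ZGZ' + R\) is block-diagonal by city. Estimation is REML: the
objective (`reml_objective()`) is \(-2\) times the restricted
log-likelihood,
\(\log|V| + \log|X'V^{-1}X| + r'V^{-1}r + (n-p)\log 2\pi\),
evaluated per city with the AR(1) precision in its tridiagonal Markov form
and a Woodbury identity for the rank-6 random-effect update, so no matrix
larger than 6 x 6 is ever factorized. The optimizer is BFGS on
\((\log\sigma_1^2, \dots, \log\sigma_6^2, \operatorname{artanh} r,
\log\sigma^2)\) — the transform enforces positivity and \(|r|<1\) — from
three deterministic starts (an OLS-residual-based start whose AR(1) start
value is the pooled lag-1 residual autocorrelation, a small-variance start,
and a moderate-variance start). Fixed effects and BLUPs come from
generalized least squares at the optimum; `city_models()` returns
\(\hat\beta + \hat\gamma_s\) per city. Convergence is declared when the
numerical gradient of the objective falls below 0.5 (the objective is on
the \(-2\log L\) scale of a panel with thousands of records, where a
gradient that small is far inside statistical noise); the multi-start trace
is kept on the fit object.

Fixed-effect p-values use a t reference with \(S - 1\) denominator degrees
of freedom (S = number of cities), a deliberately conservative containment
choice for a model whose slopes vary at the city level. The conditional
\(R_c^2\) (`conditional_r2()`) is
\((\sigma_f^2 + \sigma_r^2)/(\sigma_f^2 + \sigma_r^2 + \sigma_\epsilon^2)\)
with \(\sigma_f^2\) the variance of \(X\hat\beta\) over records,
\(\sigma_r^2\) the record-average of \(z_i'\hat G z_i\), and
\(\sigma_\epsilon^2\) the marginal residual variance.

**GWR / TWR / GTWR.** `fit_stwr()` solves, at every focal record \(i\),
\(\hat\beta(u_i, v_i, t_i) = (X'W_iX)^{-1}X'W_iY\) by QR on the
square-root-weighted design. Weights come from a kernel evaluated at the
combined distance
\(d_{ij}^2 = \lambda\,[(u_i-u_j)^2 + (v_i-v_j)^2] + \mu\,(t_i-t_j)^2\):
spatial mode (\(\mu = 0\)) is GWR, temporal mode (\(\lambda = 0\)) is TWR,
and the spatiotemporal mode is GTWR. This squared-distance definition is
the one under which the Gaussian spatiotemporal weight factorizes exactly
into a spatial and a temporal Gaussian
(\(w = e^{-d_S^2/h_S^2} e^{-d_T^2/h_T^2}\) with \(h_S^2 = h^2/\lambda\),
\(h_T^2 = h^2/\mu\)), and it makes GWR and TWR exact special cases of GTWR
— both identities are tested to 1e-10. Only the ratio
\(\tau = \mu/\lambda\) is identifiable jointly with an adaptive bandwidth,
so \(\lambda\) is fixed at 1 and \(\tau\) searched on a log grid (default
\(10^{-2} \dots 10^2\), 9 points).

Bandwidths are adaptive: \(h_i\) is the distance to the k-th nearest
record, the focal record itself counted, so k is comparable to a
"number of neighbours" axis. Records tied at the k-th distance sit on the
bandwidth, where the bi-square kernel \([1-(d/h)^2]^2\) vanishes anyway —
this tie rule is what makes TWR well-defined on a panel where all same-week
records are at temporal distance zero, without jitter. If the k nearest
records all coincide with the focal one the bandwidth is degenerate and
the fit refuses with an instruction to raise k (on an S-city panel,
spatial-mode k must exceed the per-city record count). Kernel defaults
follow the distinct descriptions given for the two model families:
bi-square in spatial mode, Gaussian in temporal/spatiotemporal mode; both
are overridable, plus an exponential and a boxcar kernel (the boxcar with
k = n reproduces OLS exactly, which the tests use as the uniform-weight
limit).

`select_bandwidth()` minimizes the AICc over a coarse log-spaced grid of
at most 25 integer k values, then refines by integer golden-section search
between the coarse minimum's grid neighbours. The AICc of a smoother with
hat matrix \(S\) is
\(2n\ln\hat\sigma + n\ln 2\pi + n(n + \mathrm{tr}\,S)/(n - 2 -
\mathrm{tr}\,S)\) with \(\hat\sigma^2 = \mathrm{RSS}/n\); tr(S) is
accumulated from the focal hat diagonals
\(w_{ii}x_i'(X'W_iX)^{-1}x_i\). For an unweighted fit tr(S) = p and this
equals the classical small-sample AICc with p + 1 parameters, which is the
sense in which AICc values are comparable across the global and local
models; the LMM's AICc is computed from the ML log-likelihood evaluated at
the REML-optimal variance parameters with p + 8 parameters, the ML-based
convention that keeps it on the same footing. The adjusted \(R^2\) of a
local model uses \(p_\mathrm{eff} = \mathrm{tr}(S)\) by default (the
standard local-smoother convention, consistent with the AICc's use of
tr(S)); `ra2_method = "p"` switches to the raw coefficient count since the
convention behind published local-model \(R_a^2\) values is not always
stated.

## Diagnostics

`fit_metrics()` implements \(R_a^2\), RMSE and MAE; `z_scores()` the
residual Z score \((y_i - \hat y_i)/\mathrm{sd}(\hat y)\), using the
sample (n - 1) standard deviation of the fitted values — the reference
does not fix the denominator, and at panel sizes in the thousands the
choice is immaterial. For an OLS fit with an intercept the Z scores
average to exactly zero.

`morans_i()` computes Moran's I of residuals over binary k-nearest-
neighbour spatial weights (`knn_binary_weights()`): \(w_{ij} = 1\) when j
is among the k nearest records to i by planar distance, self excluded,
ties broken deterministically by (city, week) order, no symmetrization or
row-standardization. On a panel whose records stack on a handful of city
coordinates, ties are massive; the deterministic rule keeps every run
reproducible, and because the normal approximation is dubious under such
ties a permutation test is provided alongside the analytic one. The
analytic method uses the randomization (fourth-moment) variance; the
expectation is \(-1/(n-1)\) exactly. `moran_curve()` profiles I and its
p-value across a neighbour-count grid, the diagnostic that shows OLS
residual clustering dissolving as local structure is absorbed by the
richer models.

## The synthetic generator

The monitoring data behind the emulated study design are not public, so
`simulate_panel()` generates panels with the structure the analysis
assumes, plus the exact generative truth needed for recovery tests.

*Predictors.* Each pollutant is mean level + signed loading x a shared
"heating season" factor (a 52-week sinusoid perturbed by AR(1) noise per
city) + a city offset + idiosyncratic AR(1) noise, floored at a small
positive constant. The shared factor loads positively on SO2, NO2, PM10
and CO and negatively on O3; a single shared factor is the simplest
mechanism that reproduces the reported correlation sign pattern, including
the \(\rho(\mathrm{PM2.5}, \mathrm{PM10}) > 0.5\) bound, which the
defaults were calibrated to meet. Mean levels default to the study's
descriptive means (SO2 16.48, NO2 22.95, PM10 58.67, O3 72.16 ug/m3; CO
0.72 mg/m3); loadings and noise scales were chosen once to give marginal
spreads of the right order.

*Mixed-mode response* (`gen_response_mixed()`): \(y = X\beta + Z\gamma +
\varepsilon\) with \(\gamma\) drawn per city from the diagonal G and
\(\varepsilon\) an independent AR(1) series per city (no cross-city error
correlation, matching the block-diagonal R of the fitted model) with
marginal sd `resid_sd`. Defaults: \(\beta\) at the study's global OLS
estimates (the signs are the reproducible claim; the magnitudes merely
keep the scale realistic), random-effect sds at the square roots of its
reported variance components, r = 0.552, residual sd \(\sqrt{75.11}\).

*Varying-mode response* (`gen_response_varying()`): each coefficient is
modulated multiplicatively, \(\beta_k(u, v, t) = \beta_k(1 +
a_s\,g(u,v) + a_t\,h(t))\) with g a centred linear surface and h a centred
sinusoid, plus white noise. Defaults \(a_s = 0.3\), \(a_t = 0.5\) encode
the study system's temporal-dominant heterogeneity — chosen once as the
regime in which TWR/GTWR should, and in the tests do, beat GWR.

*What the generator does not emulate:* the 56 sub-city monitoring sites
and within-week aggregation noise, the heavy right tails of the reported
marginals (only means are matched), any cross-city error correlation, and
real geography (cities are uniform on a unit square; coordinates are
treated as planar throughout, projection being the caller's
responsibility). Passing recovery tests on these panels therefore shows
the estimators work under the model's own assumptions, not that the
published coefficient values are reproduced — the published tables came
from data that were never deposited, and the package makes no attempt to
match their numbers.

## Numerical choices and degenerate inputs

* All linear solves are QR or Cholesky; printed inverse formulas are
  notation only. Local designs with condition number above 1e10 raise a
  singularity error naming the record.
* The REML objective returns `+Inf` (never an error) on overflow, so the
  optimizer can probe freely; variances are bounded away from illegality
  by the log/artanh parameterization.
* AR(1) whitening uses the Markov factorization keyed on the actual week
  gaps, so panels with dropped weeks remain exact.
* Missing records are dropped and counted (`validate_panel()`), never
  imputed; a panel must retain at least p + 2 complete records.
* A constant response leaves \(R_a^2\) undefined (NA) but local fits still
  return, reproducing the constant exactly — the hat rows sum to 1.
* Quartiles in coefficient summaries use the linear-interpolation
  convention (R type 7).

## Problem sizes in the tests

The packaged experiments run at the emulated study scale (13 x 210 = 2730
records) where the claim concerns that design — panel shape, correlation
structure, AR(1) recovery (20 seeds), LMM-vs-OLS fit ordering — and at
smaller designs chosen to exercise the same contrasts cleanly elsewhere:
8 x 60 for coefficient-recovery and model-ordering experiments (20 seeds),
6 x 40 for bandwidth-selection behaviour, 5 x 30 for the exact reduction
identities. Monte-Carlo acceptance bands (e.g. "in at least 18 of 20
seeds") are property checks on orderings, not reproductions of any
published number.

## Known limitations

* GWR on a 13-city panel has only 13 distinct spatial points; its k is
  bounded below by the per-city record count, exactly the regime in which
  the study found GWR's improvement marginal.
* No local-coefficient significance testing, semi-parametric (mixed) GWR,
  prediction at unobserved locations, or fixed distance-unit bandwidths.
* The LMM supports exactly the VC + AR(1) covariance pair; it is not a
  general mixed-model engine.
* Analytic Moran inference leans on a normal approximation that massive
  distance ties strain; use the permutation method when it matters.
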