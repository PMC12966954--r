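---
title: "Range versus occurrence distributions: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Range versus occurrence distributions: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvo)
```

## The movement processes

`rvo` treats a telemetry track as a discrete sample from a continuous-time
stochastic process $R_t = (x_t, y_t)$. Five Gaussian process families are
supported, distinguished by three capabilities — positional autocorrelation,
velocity autocorrelation, and range residency (finite long-run coverage
areas, visible as a variogram asymptote):

| kind | position autocorr. | velocity autocorr. | range-resident |
|------|--------------------|--------------------|----------------|
| IID  | no                 | no                 | yes            |
| BM   | yes                | no                 | no             |
| OU   | yes                | no                 | yes            |
| IOU  | yes                | yes                | no             |
| OUF  | yes                | yes                | yes            |

The OUF (Ornstein–Uhlenbeck foraging) process is the workhorse: a
stationary Gaussian process with positional autocovariance
$$\gamma(\tau) = \sigma^2\,
\frac{\tau_p e^{-\tau/\tau_p} - \tau_v e^{-\tau/\tau_v}}{\tau_p - \tau_v},$$
where $\sigma^2$ is the stationary per-axis variance (m²), $\tau_p$ the
positional autocorrelation timescale (days; the home-range crossing time)
and $\tau_v$ the velocity timescale (days; path smoothness). OU is its
$\tau_v \to 0$ limit, BM the $\tau_p \to \infty$ limit of OU, and IOU the
$\tau_p \to \infty$ limit of OUF; constructors accept an infinite `tau_p`
and coerce the kind, requiring the finite diffusion rate $D$ (m²/day,
the increment-variance rate) directly since $\sigma^2$ diverges in that
limit. The two axes are modeled as independent with shared parameters
(isotropic process); the *estimated* range covariance may still be a full
2×2 matrix (below). Units are fixed internally to days and meters.

Every kind has an exact discrete-time transition law (`transition()`). For
the velocity-correlated kinds the per-axis state is (position, velocity)
with state matrix $e^{\Delta t A}$, $A$ the companion matrix with
eigenvalues $-1/\tau_p, -1/\tau_v$, and noise covariance from the discrete
Lyapunov relation $Q = S - \Phi S \Phi'$ with
$S = \mathrm{diag}(\sigma^2, \sigma^2/(\tau_p\tau_v))$ the stationary state
covariance. This single primitive drives exact simulation, the O(n)
likelihood filter, and the Kriging smoother, which is why all three agree
with dense-kernel oracles to machine precision in the test suite.

## Likelihood, fitting and diagnostics

The joint Gaussian likelihood of a track is computed by a per-axis Kalman
filter over the transition recursion (O(n) in the number of locations,
compiled). Uncorrelated location error with known variance `error_var`
enters as the observation noise. For the diffusive kinds the likelihood is
conditional on the first observation (diffuse position prior; IOU
velocities start from their stationary law) — a marginal likelihood does
not exist for processes without a stationary distribution.

`fit_ml()` maximizes this likelihood with:

- the mean $\mu$ profiled out by GLS at every evaluation, computed inside
  the filter by also filtering a constant-ones series (innovations are
  linear in the observations, so $\hat\mu$ is a ratio of weighted innovation
  sums — no dense matrices);
- the overall scale ($\sigma^2$ or $D$) profiled analytically whenever
  `error_var = 0`, since every innovation variance is then proportional to
  it — this reduces OUF fitting to a 2-dimensional search;
- timescales optimized in log space within
  $[10^{-3}\,\mathrm{median}\,\Delta t,\; 10\,\mathrm{duration}]$, with a
  17-point log-spaced scan plus Brent refinement in one dimension and 6
  Nelder–Mead starts (5 timescale grid points plus one low
  $\tau_v/\tau_p$ start) in two; the OUF constraint $\tau_p > \tau_v$ is
  enforced by parameterizing the ratio through a logistic link. A
  degenerate $\tau_p \approx \tau_v$ switches to the analytic limit kernel
  $\sigma^2(1+\tau/\tau_p)e^{-\tau/\tau_p}$ when the timescales agree to
  within $10^{-6}$ relative, stabilizing the $1/(\tau_p-\tau_v)$
  denominator.

Model selection uses AICc, $-2\ell + 2kn/(n-k-1)$, on the nominal number of
locations $n$, with $k = 3, 4, 5$ for IID/OU/OUF (mean 2, variance 1, plus
timescales) and $k = 1, 2$ for BM/IOU (no mean under origin conditioning).
Standard errors come from the numerical Hessian of the negative
log-likelihood in log-parameters at the optimum (delta method), a choice
made for the parameter-recovery tests; profile intervals are not provided.
Plain ML is used throughout, not the perturbative hybrid REML used in parts
of the field: the small-`n_eff` downward bias this induces in variance
estimates is the known bias pattern visible at short durations in the
duration sweep, and no bootstrap debiasing is applied.

Two derived quantities recur. The **effective sample size**
`n_eff = duration / tau_p` approximates the number of home-range crossings
in the data (the information that actually bounds range-estimation
accuracy); for IID fits `n_eff = n`, and it is undefined for the
non-resident kinds. The **effective sampling rate** is
$\tau_p / \mathrm{median}\,\Delta t$, fixes per range crossing. Neither has
a canonical closed form in the literature this package follows; these
definitions are package conventions, chosen for transparency, and are used
consistently in the experiment tables.

`range_residency_check()` gates range estimation on three verdicts: the
selected kind is range-resident; `n_eff >= 5` crossings (default — below
that, coverage-area uncertainty is dominated by the handful of independent
excursions); and the mean of the last third of the empirical variogram bins
lies within ±50% of the fitted asymptote $\sigma^2 +$ `error_var`. The
variogram accumulates half the mean squared per-axis displacement of all
pairs into log-spaced lag bins.

## Range estimators

The primary estimator is autocorrelated Gaussian density estimation:
center = GLS mean under the fitted correlation, covariance = ML 2×2
stationary covariance estimated through the same whitening filter
($\hat\Sigma = \sigma^2_{\mathrm{fit}}\, n^{-1}\sum_i e_i e_i' / S_i$ over
the mean-profiled innovations; denominator $n$, so on IID data it reduces
exactly to the ML sample covariance). The full 2×2 covariance is the
default — it is what the IID reduction requires — with `isotropic = TRUE`
available where an isotropic region is preferred. Coverage ellipses have
the closed-form area $\pi\,\chi^2_2(q)\sqrt{\det\hat\Sigma}$, which makes
the 50%:95% area ratio exactly $\ln 0.5 / \ln 0.05$ for every fit.

Coverage-area confidence intervals treat the estimated area as a scaled
chi-square variate with $\nu = 2(n_\mathrm{eff}-1)$ degrees of freedom.
This is deliberately simple and slightly anticonservative: it propagates
the variance-estimation uncertainty at the effective sample size but not
the timescale-estimation uncertainty, and in the package's own calibration
test (60 OUF replicates at $n_\mathrm{eff} \approx 32$) the nominal-95%
interval covers the true area at a rate measurably below nominal (the test
asserts the band [0.70, 0.97]). Users needing exact coverage should widen
the level accordingly.

AKDE is provided for non-Gaussian ranges: a Gaussian-kernel KDE whose
reference-rule bandwidth uses the effective sample size,
$H = \hat\Sigma\, n_\mathrm{eff}^{-1/3}$ (the $d=2$ reference exponent).
Two consequences are documented rather than corrected: reference-rule
smoothing inflates the 95% HDR area by roughly $n_\mathrm{eff}^{-1/3}$
(about 15–20% at $n_\mathrm{eff} = 64$ in the module tests), and no
bootstrap debiasing is applied. The contrast estimator `conventional_kde()`
uses the nominal $n$ in the same rule and therefore undersmooths
autocorrelated tracks — its areas are systematically smaller than AKDE's on
the same data, the classic underestimation of IID-assuming estimators.
`mcp_area()` gives the minimum-convex-polygon baseline with
farthest-from-centroid peeling for percentage MCPs.

## Occurrence estimator

`krige_at()`/`krige_path()` return the exact conditional Gaussian of the
position at any in-window time given the whole track, via a fixed-interval
two-pass (RTS) smoother over the same state recursion; it equals dense
Gaussian-process regression but in O(n). At an observation time with no
location error the law collapses onto the observation; with error it
retains an error-variance floor. IID fits are refused — without detectable
autocorrelation, interpolation carries no information. Extrapolation
outside $[t_1, t_n]$ is refused likewise.

`occurrence_density()` averages these conditional Gaussians uniformly over
a time grid and rasterizes by exact per-cell mass integration (`pnorm`
differences, separable because the per-axis conditional is axis-aligned),
each component evaluated only within ±6 of its conditional standard
deviations. Two tuning choices, both fixed after a doubling check in the
test grids: **query density** of 10 query times per observation interval
(halving or doubling moves 95% HDR areas by well under 1% at the default
resolution), and the **gap rule** — query times strictly inside any
observation gap longer than 3× the median sampling interval are dropped
from the average, since effectively unconditioned predictions inside long
gaps oversmooth the estimate toward the range distribution. Gap endpoints
(the observations themselves) are retained; partial weighting of bridge
segments touching a gap was considered and rejected in favor of the simpler
whole-query-time exclusion. `bbmm_variance()` exposes the Brownian-bridge
special case, which `krige_at()` under a BM fit reproduces exactly.

## Rasters and coverage areas

Density grids use square cells of $\hat\sigma/50$ covering the range center
±5$\hat\sigma$ (default), which keeps the discretization error of a
rasterized Gaussian's 95% HDR area under 2% (asserted in the tests at the
default resolution). HDR areas accumulate cells in decreasing density order
until the mass reaches $q$, ties broken by cell index so regions are
deterministic; this is the smallest-cell-set convention, which on an exactly
uniform density keeps exactly the requested mass fraction rather than every
tied cell. Point-in-region scoring maps points to cells; points off the
raster count as uncovered.

## Cross-validation protocols

The two estimator families calibrate against different test sets:

- **Range (extrapolation)**: `crossval_range()` fits on the first
  $\lceil n/2 \rceil$ locations and scores the fraction of *future*
  (second-half) locations inside the nominal-$q$ ellipse. The contiguous
  half split mirrors the empirical protocol the estimator family is used
  with; an optional burn gap between halves for strict train/test
  independence was considered and left at 0 — with hundreds of range
  crossings per half the correlation across the boundary is negligible.
- **Occurrence (interpolation)**: `crossval_occurrence()` withholds every
  second location (preserving window span and sampling balance — the
  holdout rule is a package convention), fits on the rest, queries the
  occurrence density at exactly the held-out epochs, and scores the
  held-out locations against the $q$ HDR.

The acceptance script and test suite verify both calibrations at the
package's standard operating point, and also the misuse contrast: an
occurrence region scored against *future* locations under-covers its
nominal level, increasingly so at high sampling rates.

## The synthetic-data generator and what it does (not) show

All tests and experiments run on simulated OUF tracks with $\sigma^2 =
1$ km² per axis, $\tau_p = 1$ day and $\tau_v = 0.1$ day, no location
error unless stated. Daily range crossings match the simulation design the
estimators are contrasted under; $\tau_v$ is deliberately an order of
magnitude below $\tau_p$ so that the OUF kernel is far from its degenerate
limit while velocity correlation remains detectable at multi-fix-per-day
rates (the generating $\tau_v$ is not pinned by the study design, so this
is a package default, config-overridable). The generator draws the exact
finite-dimensional law of the process — initialization from the stationary
distribution, exact transitions, optional i.i.d. Gaussian location error —
so simulation error is purely Monte Carlo, and replicate $r$ of any
experiment uses seed `base_seed + r`, making every result table
reproducible bit for bit.

What passing these tests shows: the estimators are calibrated and the
collapse/convergence phenomena hold *when the model family is correctly
specified and the home range is Gaussian*. What they cannot show: behavior
under model misspecification (non-Gaussian ranges, behavioral switching,
autocorrelated measurement error, migration/drift), which real tracking
data exhibit; the generator deliberately does not emulate these. Schedule
irregularity and gaps are supported (half-open gap intervals
$[\mathrm{start}, \mathrm{end})$, so a fix exactly at a gap start is
removed and one at its end kept — a fixed convention for reproducible
schedules) but the calibration suites use regular schedules.

## Experiment pipelines and problem sizes

`run_rate_sweep()` (rates at fixed 256-day duration),
`run_duration_sweep()` (durations at fixed 8/day rate), `run_ratio_scan()`
(rate × duration cross) and `run_crossval_study()` (both CV protocols at
50% and 95%) emit tidy long tables with per-replicate areas and ratios
against the generating model's analytic truth; per-replicate fit failures
are logged and recorded as `NA`, never crashing a sweep. Bias is measured
against the analytic true area (known exactly for the generating OUF
model), and occurrence areas use the *fitted* model, mirroring the
estimation workflow rather than the truth. Whether to re-fit all OUF
parameters per replicate or fix the timescales was an open choice; the
sweeps re-fit everything, since that is what an analyst of real data must
do. The default configuration is the full study grid (1–128 fixes/day,
4–4096 days, 400 replicates) and is cluster-scale; the package's own test
and acceptance runs use the reduced grids quoted in their code (25
replicates, rates {1, 4, 16, 64}, durations {16, 64, 256}; 100 tracks for
the range-CV ensemble, 50 for the occurrence-CV ensemble, 100,000 draws
for the true-ellipse check), chosen so Monte-Carlo error sits comfortably
inside the asserted tolerances.

## Known limitations

- Plain ML (not phREML) biases $\hat\sigma^2$ and hence areas downward at
  small `n_eff`; no bootstrap debiasing.
- The area CI is an approximation that ignores timescale uncertainty and
  under-covers modestly (measured above).
- AKDE uses the uncorrected reference-rule bandwidth; its areas carry a
  positive $O(n_\mathrm{eff}^{-1/3})$ smoothing bias.
- Isotropic process kernels only; anisotropy enters only through the
  estimated range covariance.
- `error_var` is user-supplied, not estimated; location error is modeled
  as uncorrelated Gaussian only.
- The Movebank reader uses a local tangent-plane projection about the mean
  location — adequate for home-range-scale extents, not for continental
  tracks.
- Occurrence rasters inherit cell-size quantization: once conditional
  standard deviations fall below the cell size (very high sampling rates),
  HDR areas floor at the set of path-occupied cells.
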