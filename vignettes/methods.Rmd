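---
title: "Methods: region-specific ARIMAX forecasting of fire emissions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-specific ARIMAX forecasting of fire emissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fires2s` builds subseasonal-to-seasonal (1–6 month) forecasts of monthly
fire carbon emissions. Fire activity is too heterogeneous for one global
model, so the system works region by region: it partitions the gridded
emission record into *fire cohesive regions* (FCRs), transforms each
region's monthly series into a bounded anomaly, selects lagged climate
predictors for each region and lead time, and fits a separate ARIMAX model
per region. Forecast skill is judged by walk-forward cross-validation
against persistence and climatology baselines. This vignette records the
modelling choices, their defaults, and what the synthetic test bed does and
does not establish.

## Fire cohesive regions

The unit of prediction is the summed emission series of an FCR. Regions are
derived from the development-period record alone, iterating from 1° cells
up through 2°, 4° and 8° blocks (grids aligned so a coarser cell contains
exactly four finer cells; the northernmost 8° band is truncated to 4° and
holds two 4° children when the row count is not a multiple of 8). A
candidate block becomes a region when its summed series passes three
criteria:

* **magnitude** — mean annual emissions at or above a threshold `e_min`.
  By default `e_min` is the cutoff for the top 2% of burning land cells
  (nearest-rank rule: the k-th largest mean annual cell total with
  `k = ceiling(0.02 n)`); on the production data that cutoff is
  1.33 Tg C yr⁻¹, and the same absolute threshold is applied to aggregated
  candidates at every level;
* **continuity** — nonzero emissions in at least 90% of years (17 of 18 in
  an 18-year window), because a linear model is a poor description of a
  series that is mostly zeros;
* **variability** — coefficient of variation below 2, so that a few
  anomalous years cannot dominate the fit.

Criteria 2–3 are evaluated on calendar-year totals by default (configurable
to monthly): monthly CV routinely exceeds 2 for strongly seasonal regimes,
and the continuity criterion is phrased per year. Cells claimed at a finer
level are excluded from coarser candidates. A passing block spanning
several countries is split into one region per country — fire management is
organized nationally — each fragment keeping the level label, without
re-testing; fragments are ordered by ascending country code. After level 8,
leftover 8° blocks averaging more than 0.12 Tg C yr⁻¹ enter as a relaxed
level `8r`. Remaining cells are treated as fire-free and excluded. Ids are
assigned level by level in row-major order from the south-west corner, so
they are reproducible and contiguous per level.

Regional emissions are member-cell sums (missing cells count as zero, as
the production data report zeros); regional VPD is a cosine-latitude
area-weighted mean (missing cells excluded).

## Anomaly transform

Fire emissions are strongly seasonal and right-skewed. Each regional series
is standardized per calendar month against the development-window
climatology (sample, n−1, standard deviation) and passed through a scaled
hyperbolic tangent:

y' = 2 · tanh((y − ȳ_m) / (2 σ_m)),

which bounds anomalies to [−2, 2] and tames extreme months. The inverse
map clips the tanh argument to magnitude 1 − 10⁻⁶ (the forward map
saturates, so the inverse must be bounded) and floors emissions at zero.
Months with zero climatological variance map to zero anomaly in both
directions; they only arise for constant (usually zero) months. VPD is
only standardized, not tanh-transformed — its marginal distribution is
close to normal.

## Exogenous predictors

Two predictors per region: one of a set of ocean climate indices (OCIs,
monthly SST-anomaly indices; indices used only to define composites can be
marked unusable and are never selected) and the region's vapor pressure
deficit, computed from 2 m temperature, specific humidity and surface
pressure as e_s(T) − e_a(Qv, Ps) with e_s = 6.112·exp(17.67 T/(T+243.5))
hPa and e_a = Qv·Ps/0.622.

For diagnostics, lagged Pearson cross-correlations are scanned over lags
0–11 months; for operational selection at lead L only lags in [L, 11] are
admissible, so every selected predictor value is observed on or before the
forecast origin. Per region and lead, the OCI entry maximizes |r| jointly
over (usable index, lag) and the VPD entry maximizes |r| over lag; signed
correlations are stored. Ties break to the smaller lag, then to the earlier
index in the canonical order — a rule chosen here for determinism.
Correlations are computed on the transformed anomalies (the fitted target),
and the lookup is frozen from the development window; it is never updated
during walk-forward forecasting.

## The ARIMAX engine

The forecast model is regression with ARIMA(p, d, q) errors: intercept plus
exogenous terms, with the residual following an ARMA process on the
d-differenced scale, fit by Gaussian maximum likelihood through the Kalman
filter (`stats::arima`). This is the model family the reference
state-space implementations fit when given exogenous regressors; the
literal formulation with regressors entering the differenced equation is
nearly equivalent and not implemented separately. The intercept is always
estimated: under d = 1 it becomes a drift term, implemented as a linear
time column appended to the regressor matrix.

Orders are selected per region and lead by minimizing AIC
(2k − 2 log L, with the innovation variance counted in k) over the grid
p ∈ {0, 1, 2}, d ∈ {0, 1}, q ∈ {0, 1, 2} on development-window data, then
frozen. Three numerical safeguards:

* candidates that fail to converge or return a non-finite likelihood are
  discarded;
* candidates whose fitted AR or MA polynomial has a root with modulus
  below 1.001 are discarded as degenerate boundary fits — on near-white
  series the optimizer otherwise drifts into AR–MA common-factor
  configurations on the invertibility boundary whose AIC is spuriously
  low; this is the admissibility screen automatic ARIMA selection tools
  customarily apply;
* exact AIC ties break to the smaller p + d + q, then smaller p, then
  smaller q.

If every candidate fails, the fallback order is (0, 0, 0). Constant
(singular) exogenous columns are dropped with a warning. Fitting is
deterministic — no random starts.

## Walk-forward forecasting

Every month of the prediction window is a forecast origin. At each origin
the regression coefficients are re-optimized on all data available up to
that month (development data included), with the exogenous columns shifted
by the frozen lookup lags; hyperparameters (orders, predictor choices,
climatology) stay frozen from the development window. The fitted model is
iterated 1–6 steps ahead through the Kalman recursions; exogenous values
needed at target months are observed values at (target − lag), available
because lag ≥ lead. Predicted anomalies are clipped to [−2, 2] and mapped
back to emissions with the development-period climatology. Origins whose
target month falls beyond the observed record are still forecast but
flagged unverifiable and excluded from scores. If the frozen order fails to
converge at some origin, the engine falls back to (0, 0, 0) there and
flags the record.

Estimation methods: the reference fit contract and order selection use full
maximum likelihood (CSS-ML); the per-origin refits inside the walk-forward
sweep use conditional sum of squares (CSS), the standard fast estimator for
repeated refits of a fixed specification. Predictions always go through
the exact Kalman forecast recursions regardless of how coefficients were
estimated.

Seven variants isolate the contribution of each component: the full model
(OCIVPDAR), single-predictor reductions (OCIAR, VPDAR), autoregression
only (ARonly), pure lagged regression with orders forced to zero (Xonly),
and two baselines — Clim (zero anomaly, i.e. the monthly climatological
mean) and Persistence (the origin anomaly carried unchanged to every
lead). Variants with "optimal" orders get their own order lookup, selected
with their own exogenous structure.

## Verification

Skill is reported per variant, lead and scope (per region, and globally on
the sum over regions). Observed anomalies are always measured against the
development-period climatology, including during the prediction window, so
baseline and model errors are on a common footing. Scores are the Pearson
anomaly correlation, RMSE (Tg C/month), and the percent RMSE change
relative to the Clim variant (negative = better than climatology); every
score carries its record count, and zero-variance cases (e.g. the Clim
variant's anomalies) are flagged undefined rather than reported as
numbers. Global-sum months missing any region are dropped. The best-model
table picks the RMSE-minimizing variant per region, ties resolved in the
canonical variant order. Diagnostics include OLS trend slopes on annual
totals, KPSS level- and trend-stationarity statistics (Bartlett/Newey–West
long-run variance at bandwidth ⌊4(T/100)^0.25⌋, 5% critical values 0.463
and 0.146), and ACF/PACF of deseasonalized series.

## Synthetic test bed

The generator plants exactly the structure the pipeline is designed to
recover, with one root seed and independent per-cell substreams (so
enlarging the grid never reshuffles existing cells):

* a seasonal cycle per cell — a cosine bump raised to a concentration
  power, renormalized to mean 1, peaking at a configurable month;
* multiplicative log-scale AR(1) noise (marginal sd 0.3, lag-1
  autocorrelation 0.5 by default) — the autoregressive memory the AR part
  of the model should exploit;
* optional linear trends, zero inflation, and coupling
  `exp(coef · OCI[t − lag])` to one AR(1) OCI (lag-1 autocorrelation 0.8,
  as teleconnection indices are strongly persistent) per cell block;
* a VPD field equal to a seasonal cycle plus the cell's standardized
  emission anomaly shifted so VPD *leads* emissions by one month, plus
  noise, floored at 0 hPa.

Defaults mirror the production setup: an 18-year development window
followed by a 4-year prediction window, leads 1–6, all seven variants. The
end-to-end checks in the test suite run 50 level-1 regions (an 8×8 grid
with 14 low-fire cells) for five seeds; the predictor-recovery check uses
a 10×10 grid with a planted lag-3 coupling at signal-to-noise ratio 2.8.
These sizes were chosen so the full suite runs comfortably on one CPU
while still averaging over enough regions for stable rank orderings.

What passing these tests shows: the pipeline recovers planted lags,
indices, trends and autoregressive structure, respects the no-look-ahead
contract, and ranks the full model above the baselines at short leads with
skill decaying toward climatology as lead grows — the qualitative pattern
expected of the production system. What it does not show: skill on real
data. The generator makes no attempt to mimic the spatial texture of real
burned area, regime shifts, fire-season length changes, observational
error in reanalysis meteorology, or the latency of operational index
production. Numbers obtained on synthetic data say nothing quantitative
about production forecast skill.

## Known limitations

* One OCI per region; no multi-index combinations or SST-field learning.
* No seasonal (period-12) ARMA terms: seasonality is handled entirely by
  the climatology transform.
* The seasonal cycle is assumed stationary; regime shifts (policy changes,
  fire-season lengthening) violate the transform's premise.
* Country splitting can produce fragments whose own emissions would not
  pass the criteria; they are retained by design.
* KPSS decisions use asymptotic critical values; at 18 years the test is
  indicative, not sharp.
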