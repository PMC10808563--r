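---
title: "Kriged daily precipitation and lagged mosquito trap outcomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kriged daily precipitation and lagged mosquito trap outcomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kriglag)
```

## The scientific problem

*Aedes aegypti*, the container-breeding vector of dengue, Zika, chikungunya
and yellow fever, is abundant in desert metropolitan areas where rainfall
seems far too scarce to sustain it.  Whether precipitation limits the
mosquito at all — and how much of the population is instead supported by
anthropogenic water (irrigation runoff, storm drains, ornamental features) —
can be addressed by connecting *daily, highly local* precipitation to the
outcome of every trap collection in a surveillance network.  Regional
averages cannot do this: adult *Ae. aegypti* rarely disperse beyond a few
hundred meters, and the precipitation that matters is the rain that fell at
the trap's location on specific days of the preceding egg-to-adult window.

`kriglag` implements that analysis chain end to end:

1. **Daily precipitation surfaces** interpolated between weather stations by
   kriging with an elevation drift.
2. **Lag realignment**: for every trap collection, the interpolated
   precipitation at the trap location on each of the 20 days before
   collection, plus 10- and 20-day cumulative sums.
3. **Per-lag screening**: an independent logistic slope (presence) and a
   correlation (abundance) for each single day's precipitation.
4. **Model comparison**: L1-regularized logistic and Poisson regressions over
   four predictor sets, scored by held-out AUC-ROC and count-scale RMSE, with
   bootstrap coefficient intervals.
5. **Spatial autocorrelation** of aggregated trap counts (global Moran's I).
6. **Effort summaries** and a **low-precipitation threshold** that bounds the
   precipitation-independent fraction of the trapped population from below.
7. A **seeded synthetic-data generator** that emulates the statistical
   structure of such a study so every stage is testable without downloads.

## Kriging with an elevation drift

Station coordinates are projected to a local planar system centered on the
study box (east axis scaled by the cosine of the central latitude); at county
scale the planar/geodesic discrepancy is negligible relative to station
spacing.  Spatial dependence is summarized by the semivariogram
$\gamma(h) = \tfrac12 \mathrm{E}[(Z(s) - Z(s+h))^2]$, estimated by binning
point pairs up to a cutoff (default: one third of the bounding-box diagonal,
15 bins) and fit automatically by weighted least squares with weights
$N_j / h_j^2$ over four candidate families — spherical, exponential,
Gaussian, Matérn (smoothness searched over $\{0.5, 1, 2\}$, since a free
smoothness is nearly unidentifiable from binned data).  The automatic
initialization is: initial sill = mean of the maximum and median binned
semivariance; initial range = 0.1 × the diagonal of the data bounding box;
initial nugget = the minimum semivariance.  Optimization runs on a rescaled
parameterization (semivariances divided by their maximum, log range) with
three range starts; any finite minimum is accepted because "false
convergence" codes are routine on the flat portions of these surfaces.

Prediction uses kriging with external drift: the mean model is an intercept
plus a linear term in elevation, and the weights solve the augmented system

$$
\begin{pmatrix} \Gamma & \mathbf{1} & \mathbf{e} \\
\mathbf{1}' & 0 & 0 \\ \mathbf{e}' & 0 & 0 \end{pmatrix}
\begin{pmatrix} \lambda \\ \mu_0 \\ \mu_1 \end{pmatrix}
 = \begin{pmatrix} \gamma_0 \\ 1 \\ e_0 \end{pmatrix},
$$

where $\Gamma_{ij} = \gamma(h_{ij})$ with a zero diagonal (the nugget is a
discontinuity at the origin, so kriging interpolates observations exactly),
$\mathbf{e}$ is station elevation and $e_0$ the target's.  The intercept
constraint forces $\sum_i \lambda_i = 1$ (unbiasedness), which the tests
check to $10^{-10}$; agreement with an independently coded dense solve is
checked to $10^{-8}$.  If elevation is spatially constant its column is
collinear with the intercept, and the solver drops to ordinary kriging.
Duplicated station locations are averaged per day rather than dropped.  A
nearest-neighbor cap (default 64 stations) bounds the cost of dense days;
below the cap the system is solved once for all targets.

Interpolated values can be slightly negative or vanishingly small; every
prediction passes through the measurability rule: values below 0.01 inches
(the threshold of measurable precipitation in U.S. forecast practice),
including all negatives, are set to exactly zero.  The rule is idempotent and
applied again at extraction time, so analysis never sees sub-measurable
precipitation.

Days on which every reporting station records zero short-circuit to an
all-zero surface without solving any system; days with fewer than three
reporting stations produce an all-missing surface with a warning rather than
a pretend interpolation.  Whether the variogram is refit per day (default) or
a single pooled model is reused is a policy choice (`vgm_policy`); the
precipitation is kriged untransformed, with the model hook left open — a
log-type transform changes little at these magnitudes and complicates
back-transformation of the variance.

## Lag realignment and thinning

Day $k$ means the calendar date exactly $k$ days before collection, for
$k = 1, \dots, 20$; the collection day itself is not a predictor.  Values are
read from the surface cell containing the trap (point-in-cell, no smoothing —
the surface is already an interpolation).  `cum10` and `cum20` are the row
sums of days 1–10 and 1–20.

Weekly service of the same trap makes consecutive 20-day windows overlap,
which would imprint a spurious 7-day autocorrelation on the lag matrix —
coincidentally the approximate egg-to-adult time at summer temperatures, the
worst possible artifact.  Thinning therefore keeps one event per trap per
calendar year-month: the earliest-dated event of the group, ties broken by
trap id then input order.  "Earliest in the month" is the deterministic
reading of selecting events from early in the month; the operation is
idempotent and order-stable.

## Screening and the model comparison

Screens are deliberately univariate: for each day an intercept + slope
logistic fit against presence (Wald 95% CI), and a Pearson correlation
(Fisher-z 95% CI) against female counts — Spearman and a positive-counts-only
scope are available, since zeros dominate these networks.  Screens establish
that different days act in different directions; they are not the inference.

The comparison proper fits, per outcome, four specifications — intercept-only
null, all 20 daily lags, daily + cum10, daily + cum20 (cumulative-only
variants are also available) — with whole *sites* split 75/25 into training
and testing so no trap contributes to both.  The L1 penalty is chosen by
5-fold cross-validation on the training set; a presence model keeps the
penalty only when it beats the near-unpenalized end of the path by more than
one cross-validation standard error, and otherwise falls back to the
unpenalized fit (on these inch-scale, low-variance predictors an
unstandardized penalty otherwise silently deletes genuinely active days).
Abundance models are Poisson with predictors normalized to unit variance so
coefficients are comparable, and always use the CV-selected penalty.
Presence is scored by AUC-ROC on the held-out sites — the rank
implementation equals exhaustive pairwise concordance exactly, and an
intercept-only model scores exactly 0.5 — and abundance by RMSE on the count
scale.  In an unpenalized fit the cumulative sums are exact linear
combinations of the daily lags; aliased terms are reported as eliminated.

Coefficient uncertainty comes from a case-resampling bootstrap (default 1000
replicates, percentile 2.5/97.5 intervals) at the penalty chosen once on the
full data; rows are resampled by default, whole sites by flag.  Full-data
coefficients (not training-only) are the default reporting choice, with a
flag to restrict.

## Spatial statistics

Because busier traps would otherwise dominate, the spatial analysis first
equalizes effort: traps with fewer than 60 events are dropped, traps with
more are down-sampled to exactly 60 (seeded, without replacement), and female
counts are summed per trap.  Global Moran's I uses inverse Euclidean distance
weights with a zero diagonal and no row standardization by default (the
scheme is recorded in the result object); expectation $-1/(n-1)$, with the
standard deviation and p-value from the analytic normal approximation under
either the normality or the randomization (kurtosis-adjusted) assumption, or
from ≥999 seeded permutations.  Median trap spacing is the median
nearest-neighbor distance after collapsing duplicated coordinates.

## The low-precipitation threshold

Let $M(t)$ be the maximum female count among events whose 20-day cumulative
precipitation is at most $t$.  Where $M$ is flat, additional precipitation is
not changing what a trap can produce, so those mosquitoes must have developed
in anthropogenic water.  The threshold is the largest candidate $t^*$ (grid
default 0.01–0.50 in steps of 0.01 in) such that $M$ stays within a 5%
relative tolerance of its value at the smallest populated candidate over the
whole prefix $(0, t^*]$; tolerance 0 demands exact equality, honoring
"approximately or actually equal".  Reported alongside are the share of
*all* trapping events at or below $t^*$ and the share of *all* trapped
females caught in them — the latter is the lower bound on the
precipitation-independent fraction of the population.  Both denominators are
deliberate and logged: the event share is out of all events, the female share
out of all females.

Effort summaries group events by year and trap type (distinct traps, surveys,
surveys with any mosquito, total mosquitoes, females) with percentages
re-derived from each row's own integers and rounded half-away-from-zero to
one decimal; grand totals count unique traps across years.  BG-Sentinel
events are read but excluded from analyses by a default-on filter, since such
traps were deployed only marginally and sample differently.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes, not
mosquito biology — there are no egg/larva/pupa compartments.  Its defaults
describe an arid-metropolitan surveillance study: 355 stations clustered
(Gaussian mixture) over a ~29 × 31 mile urban core; a smooth elevation
surface (low-order trend + sinusoidal relief, ~300–750 m); wet days with
probability 0.15 and a wet-day field drawn from an exponential-variogram
Gaussian random field (partial sill 0.009 in², nugget 10⁻⁴ in², range 15 km)
around a 0.12 in mean plus 0.05 in/km of elevation, truncated at zero —
truncation doubles as natural zero inflation within wet days and yields
roughly 7 in/yr, two-rainy-season-like totals.  The covariance over all
requested points is factorized once and reused across days.  Station
observations add independent nugget noise to the true field (none when the
nugget is zero), so the true field stays available as an oracle.

Traps sit on a one-per-square-mile grid, serviced weekly with a per-trap
jittered weekday, over 390 days by default — a full annual cycle plus the
20-day burn-in.  The horizon matters: after thinning, each lag column's
values come from roughly seven distinct calendar days per month, so short
horizons can leave a lag column all-zero by chance, which the model stage
correctly rejects as degenerate.  Counts follow a hurdle: presence is
Bernoulli with logit $\beta_0 + \sum_k \beta_k \cdot \text{lag}_k$ (+
optional cumulative terms); positive counts are 1 + negative binomial with a
log-mean linear in the same lags (Poisson is the large-dispersion limit);
males are an independent draw at 46% of the female mean.  Default planted
effects mirror the qualitative structure such studies report — strong
suppression by rain 2 days before collection ($\beta_2 = -6$ per inch),
weaker suppression at day 8 ($-3$), enhancement at days 10 and 15 ($+5$,
$+3$), intercepts $-1.86$ (≈13.5% baseline presence) and $\log 4.3$ (≈5.3
females per positive trap) — chosen once as detectable-but-noisy at the
n = 2000 recovery scale.  Everything is a pure function of the configuration
seed.

What passing recovery tests on this generator does **not** show about real
data: fields are stationary and isotropic, wet days are temporally
independent (no storm persistence), effects are log/logit-linear without
temperature or humidity confounding, and traps never miss service.  Real
performance therefore degrades in ways the synthetic suite cannot certify;
the suite certifies the *machinery* — that the estimator recovers what the
generating process actually contains.

## Numerical choices and test scales

Degenerate inputs are contracts, not crashes: single-class outcomes,
zero-variance lags, all-identical station locations, missing surface dates,
empty candidate grids and constant Moran values all raise descriptive errors
or flagged NA rows.  Complete separation in a screen returns an
infinite-slope sentinel.  Correlation CIs are clipped so the estimate lies
inside its own interval at the |r| = 1 floating-point edge.  Kriging variance
is clamped at zero.  JSON artifacts are written with fixed formatting so
identical seeds give byte-identical results end to end.

The test suite exercises the pipeline at deliberately small problem sizes —
stations in the tens, grids of 10–20 cells per side, two to twelve simulated
months, 500–2000 thinned events, 20 recovery seeds — chosen so the complete
suite runs in well under a minute while leaving every statistical check
comfortably powered.  One honest caveat is recorded for variogram *family*
identification: a single realization's binned variogram fluctuates enough
that the generating family wins only a clear plurality (roughly 70–80% of
seeds), although parameter recovery from noiseless curves is exact to under
1%; the corresponding test asserts the plurality, and multi-day pooling is
the practical remedy on real data.

## Known limitations

Temperature and humidity — the other microclimate drivers of development
rate and survival — are out of scope, as are co-kriging, local Moran/LISA
statistics, mechanistic life-cycle simulation, and map rendering.  The
anthropogenic-water bound is a minimum: it counts only females trapped after
effectively rain-free 20-day windows, and says nothing about how much of the
rest of the population also depends on human water.
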