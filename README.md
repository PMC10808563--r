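# kriglag

Links kriged daily precipitation to *Aedes aegypti* trap outcomes in arid
urban landscapes.

Container-breeding mosquitoes like *Ae. aegypti* thrive in desert cities
where rainfall alone seems insufficient to sustain them. Deciding whether
precipitation limits the population — and how much of it is instead carried
by anthropogenic water (irrigation, storm drains, ornamental features) —
requires daily, trap-local precipitation, not regional averages: the adults
barely disperse, and what matters is the rain that fell at each trap on
specific days of the preceding egg-to-adult window.

`kriglag` is for vector-surveillance analysts and spatial ecologists who have
(a) daily weather-station precipitation tables, (b) an elevation grid, and
(c) trap-collection records, and want the full analysis chain:

1. **Daily precipitation surfaces** by kriging with external drift
   (elevation), with automatic variogram fitting over spherical /
   exponential / Gaussian / Matérn families. Initialization: sill₀ =
   (max + median)/2 of the binned semivariances, range₀ = 0.1 × the data
   bounding-box diagonal, nugget₀ = the minimum semivariance; weighted least
   squares with weights N/h². Interpolated values below the 0.01-in
   measurability threshold (including small negatives) are zeroed.
2. **Lag realignment**: each trap event joined to γ̂(s, t−k) for k = 1…20 at
   its own location, plus 10- and 20-day cumulative sums; thinning to one
   event per trap-month removes the overlap-induced 7-day artifact.
3. **Per-lag screens**: independent logistic slopes (presence) and
   correlations (abundance) per day.
4. **Model comparison**: LASSO logistic and Poisson regressions over
   {null, daily, daily+cum10, daily+cum20}, site-level 75/25 split, scored by
   AUC-ROC / count-scale RMSE, with 1000-replicate bootstrap coefficient CIs.
5. **Global Moran's I** of female counts at equally sampled traps
   (I = (n/S₀)·Σ wᵢⱼ zᵢ zⱼ / Σ zᵢ²; E[I] = −1/(n−1)).
6. **Effort summaries** and a **low-precipitation threshold**: the largest
   cum20 value below which the maximum trap count is flat, bounding the
   precipitation-independent ("anthropogenic-water") fraction from below.
7. A **seeded synthetic generator** (stations, elevation, zero-inflated
   spatially correlated rain fields, trap grids, counts with known planted
   lag effects) so the whole pipeline is testable offline.

## Worked example

```r
library(kriglag)

cfg <- synthetic_config(seed = 42, bbox = c(-112.25, 33.30, -112.05, 33.45),
                        n_stations = 60, n_days = 120, elev_grid_dims = c(20, 20))
study <- gen_study(cfg)            # 1573 events at 110 traps

## krige one wet day onto a 20 x 20 grid
wet <- which(study$fields$wet)[3]
day <- data.frame(lon = study$stations$lon, lat = study$stations$lat,
                  elevation_m = study$stations$elevation_m,
                  precip_in = study$fields$station_obs[, wet])
grid <- grid_spec(cfg$bbox, 20, 20)
make_daily_surface(day, study$elevation, grid, study$fields$dates[wet])
#> precip_surface 2014-06-06: 20 x 20 cells, mean 0.0894 in (+variance layer)

## realign, thin, screen, compare
lagmat <- build_lag_matrix(thin_events(study$truth))   # 440 thinned rows
head(per_lag_presence_screen(lagmat)[, 1:5], 3)
#>   lag_day    effect     ci_low   ci_high   n
#> 1       1 -1.718535  -8.346476 4.9094063 440
#> 2       2 -6.510134 -13.470113 0.4498446 440
#> 3       3  1.348872  -2.788630 5.4863737 440
fit_model_suite(lagmat, "presence", seed = 1)
#> model_comparison (presence, AUC-ROC): n_train=332, n_test=108
#>         spec  metric  estimate lambda n_nonzero
#>         null AUC-ROC 0.5000000      0         0
#>        daily AUC-ROC 0.5283951      0        20
#>  daily_cum10 AUC-ROC 0.5283951      0        20
#>  daily_cum20 AUC-ROC 0.5283951      0        20

## spatial autocorrelation and the anthropogenic-water bound
agg <- equal_sample(study$events, min_events = 12, seed = 1)
morans_i(agg$female_total, project_local(agg$lon, agg$lat))
#> Global Moran's I: I_obs=-0.0142, I_exp=-0.0092, sd=0.0095, p=0.601 (n=110, invdist weights)
find_low_precip_threshold(lagmat, candidate_grid = seq(0.02, 1.5, by = 0.02))
#> low-precipitation threshold: 0.14 in (3.2% of events, 4.8% of females, max count 11)
```

Reading the output: the intercept-only model scores AUC exactly 0.5 (all
pairs tie); the day-2 screen slope is negative, reflecting the generator's
planted suppression of presence by rain two days before collection; at this
small example scale the daily and cumulative specifications tie because the
unpenalized fits alias the cumulative sums. Moran's I near its expectation
says the generator (unlike real surveillance counts) plants no spatial
clustering in trap productivity. The threshold line reads: below 0.14 in of
20-day precipitation the maximum count is flat, those events are 3.2% of all
events and hold 4.8% of all trapped females — the minimum share of the
population not attributable to rain.

`run_pipeline(pipeline_config(...))` sequences all stages (simulation or CSV
inputs → surfaces → lag matrix → screens → models → Moran → summaries →
threshold) and writes each stage's artifact plus a manifest with the seeds
and a configuration digest; identical seeds give byte-identical JSON.

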