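# trawlindex

Abundance indices and effort-reduction diagnostics for fixed-station trawl
surveys.

Long-term midwater trawl surveys measure the relative abundance of epipelagic
forage taxa — young-of-the-year (YOY) rockfish, anchovy, sanddabs,
myctophids, market squid, krill — as catch-per-unit-effort (CPUE) per
standardized 15-minute tow, and feed those indices into stock assessments and
ecosystem status reports. When a survey year is curtailed (few trawls,
inshore-biased stations, a late season), the people maintaining those indices
need to know *how wrong* the degraded year can be, *how fast* precision decays
with effort, and *what else* can corroborate the estimate. `trawlindex` is a
toolkit for exactly that situation.

## What it implements

**Delta-GLM (hurdle) standardization.** Catches are zero-inflated and skewed,
so the index multiplies two submodels fit separately — a binomial GLM for
occurrence over all hauls and a lognormal model for positive catches:

    x_y = p̂_y · exp(μ̂_y)

with year a fixed factor in both parts and spatial covariates (station,
region, depth stratum, region×depth, optional Julian-day bins) chosen per
submodel by AIC. Indices are reported with log(x+1) transforms, z-score
anomalies, and bootstrap or asymptotic-posterior uncertainty.

**Effort-reduction simulation.** Reduce any past year to the last trawl at
each of the 15 inshore-biased stations, recompute the index, and measure the
relative bias (x_sub − x_all)/x_all; extrapolate observed SEs to other
sample sizes with SE = SD/√n; validate the scaling law by randomly excluding
trawls (purely at random, or consecutive trawls from random nights).

**Seabird diet calibration.** OLS regression of the log abundance index on
the mean proportion of a prey group in seabird chick diet, inverted to
predict the index — with 95% prediction intervals — in years the survey
could not sample well, plus an agreement report against the trawl estimate.

**Krill species distribution model.** Gradient-boosted regression trees
(learning rate 0.01, depth 3, bag fraction 0.5, tree count by year-blocked
CV) relating station-level ln(CPUE+1) to depth, distance to shore and two
ocean-state proxies; gridded predictions, climatological anomalies (mean
over a baseline period, masked to 150 km from shore), a station-mean series
comparable to the delta-GLM index, and patchiness diagnostics.

**Synthetic survey generator.** Stratified station grids, hurdle-structured
catches with known year effects and habitat associations, linked diet
series, and smooth environmental response surfaces — every estimator above
is tested against this known ground truth.

## Worked example

Simulate an 11-year survey whose final year is reduced to 15 inshore
stations, standardize anchovy CPUE, and ask what the SE would have been at
other effort levels:

```r
library(trawlindex)

cfg <- scenario_config(seed = 1, years = 2010:2020, n_stations = 35,
                       taxa = default_taxa(2010:2020, seed = 3))
sim <- simulate_scenario(cfg)

fit <- fit_delta_glm(sim$hauls, sim$stations, "anchovy")
fit
#> Delta-GLM fit for 'anchovy': 11 years, 635 hauls (515 positive)
#>   binomial covariates: depth_stratum
#>   positive covariates: depth_stratum
#>   residual sigma (log scale): 1.073

idx <- estimate_uncertainty(fit, method = "posterior", n_draws = 500, seed = 2)
head(idx[, c("year", "point_index", "log_index", "se_log", "z_score")], 4)
#>   year point_index log_index se_log z_score
#> 1 2010      17.740     2.931  0.157   1.232
#> 2 2011      16.538     2.864  0.159   1.011
#> 3 2012      11.307     2.510  0.167  -0.165
#> 4 2013      15.368     2.795  0.155   0.782

se_extrapolation(idx, 2019, n_grid = c(15, 40, 62, 90), reference_n = 62)
#> SE extrapolation (anchovy, year 2019): n_obs = 62, se_obs = 0.1644, implied SD = 1.2942
#>   n predicted_se pct_change_vs_ref
#>  15    0.3341649         103.30601
#>  40    0.2046334          24.49900
#>  62    0.1643655           0.00000
#>  90    0.1364222         -17.00067
```

Reading the numbers: the 2010 index is 17.7 anchovy per standardized tow
(log-scale SE 0.157, about one standard deviation above the 11-year mean as
a z-score), and the scaling curve says that cutting a 62-trawl year to 40
trawls inflates the index SE by ~24.5%, while cutting it to the 15-station
reduced year roughly doubles it.

Other entry points: `run_bias_simulation()` (naive vs model-based bias under
inshore-only resampling), `fit_calibration()` / `predict_index()` (diet
calibration), `train_sdm()` / `predict_anomaly()` /
`station_series_compare()` (krill SDM and consensus diagnostics),
`run_scenario()` (end-to-end pipeline with CSV artifacts and a provenance
hash). The methods vignette (`vignettes/survey-effort-methods.Rmd`) explains
the models, default parameters and design choices.

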