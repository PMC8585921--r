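---
title: "Standardized survey indices under reduced effort: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardized survey indices under reduced effort: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trawlindex)
```

## The problem

Fixed-station midwater trawl surveys turn haul-level catch-per-unit-effort
(CPUE, organisms per standardized 15-minute tow) into annual relative
abundance indices for forage taxa — young-of-the-year (YOY) rockfish,
anchovy, sanddabs, myctophids, market squid, krill. When a survey year is
curtailed — a fraction of the usual trawls, spatially biased toward inshore
shallow stations, shifted late in the season — three questions arise:

1. Is the degraded year's index biased, and can model-based standardization
   remove the bias?
2. How much precision is lost at reduced effort, and how does the standard
   error scale with the number of trawls?
3. Can auxiliary data streams — predator diets observed at a seabird colony,
   a species distribution model trained on past environmental covariates —
   corroborate or replace the trawl-based estimate?

`trawlindex` implements the estimators for all three questions together with
a synthetic survey generator whose ground truth is known, so every claim the
package makes is testable end to end.

## The delta-GLM (hurdle) index

Trawl catches are zero-inflated and highly skewed, so the standardization
uses a two-part (delta, or hurdle) model. With hauls indexed by $i$ in year
$y(i)$:

* **occurrence**: $\Pr(C_i > 0) = \mathrm{logit}^{-1}(\alpha_{y(i)} +
  \mathbf{x}_i'\boldsymbol\beta)$, a binomial GLM over all hauls;
* **positive catch**: $\log C_i \mid C_i > 0 \sim \mathrm{N}(\mu_{y(i)} +
  \mathbf{x}_i'\boldsymbol\gamma,\ \sigma^2)$, a lognormal model over
  positive hauls only.

Year enters both parts as a fixed factor. The candidate spatial covariates
are station, region, depth stratum and the region-by-depth interaction
(plus 10-day Julian-day bins for taxa with strongly seasonal availability),
and each submodel's covariate set is chosen independently by minimum AIC.
The annual index multiplies the back-transformed year profiles,

$$x_y = \hat p_y \, e^{\hat\mu_y},$$

and is reported with its $\log(x_y + 1)$ transform and z-score anomalies
over a baseline period, the convention used for ecosystem status reporting.

Design choices worth making explicit:

* **Reference levels.** Back-transforming year coefficients requires fixing
  the non-year covariates somewhere. We evaluate each year's linear
  predictor at the *effort-weighted average* of the non-year contributions
  over the observed hauls. This makes the yearly indices comparable,
  invariant to covariate coding, and — with year as the only covariate —
  reduces the estimator exactly to the closed forms $\hat p_y$ = observed
  proportion positive and $\hat\mu_y$ = mean log positive catch, which the
  test suite exploits as an oracle.
* **No lognormal bias correction.** The index uses $e^{\hat\mu_y}$, not
  $e^{\hat\mu_y + \sigma^2/2}$. Under homoscedastic $\sigma$ the correction
  is a constant multiplier that cancels in a relative index; it is exposed
  as `bias_correct = TRUE` in `compute_index()`.
* **Zero-positive years** index at 0, carry a low-information flag, and are
  excluded from log-scale SE summaries (which are computed excluding zeros
  and *not* adding 1).
* **AIC ties** resolve to the smaller covariate set.
* **z-scores** are computed on the $\log(x+1)$ scale. One consequence: they
  are exactly invariant to CPUE rescaling only in the large-index limit;
  the index itself is exactly scale-equivariant.

### Uncertainty

Two samplers share one summary convention (`se_log` = SD of log-scale index
draws excluding zeros; interval = 2.5/97.5 percentiles of $\log(x+1)$
draws):

* `method = "bootstrap"` (default): nonparametric resampling of hauls
  stratified by year, refitting both submodels with the already-selected
  covariates. Resamples that fail to fit are dropped and counted; more than
  20% dropped is an error.
* `method = "posterior"`: multivariate-normal draws of each submodel's
  coefficients about the MLE — the large-sample stand-in for a vague-prior
  Bayesian fit, and roughly two orders of magnitude faster. The coverage
  simulations in the test suite use this sampler; at the simulated sample
  sizes the two agree closely.

## Effort reduction: bias and precision

`subset_focal_year()` reduces a past year to the *last* trawl at each of the
15 flagged inshore stations ("last" resolved by Julian day, then haul id —
the tie rule is ours). `run_bias_simulation()` then recomputes the focal
year's index, model-based refits keeping complete data for all other years,
and reports the relative bias $(x_{\mathrm{sub}} - x_{\mathrm{all}}) /
x_{\mathrm{all}}$. Both estimators enter that formula on their reporting
scale — the naive index *is* a mean of $\log(\mathrm{CPUE}+1)$, and the
model-based index enters as $\log(\hat x + 1)$ — with an arithmetic-scale
variant behind `scale = "arithmetic"` (on which the model-based index is
exactly scale-invariant). Cells with $x_{\mathrm{all}} = 0$ are flagged NA
and excluded from the boxplot summaries, with a logged count.

At the default 31-year scenario the naive estimator shows the expected
habitat-association signature — median bias positive for nearshore taxa,
negative for offshore taxa — while the model-based estimator is unbiased.
With 30 focal years the *per-taxon* median has a Monte-Carlo standard error
of roughly 0.05 for the noisier taxa, so the package's acceptance check
bounds the estimator-level median pooled across taxa (120 cells) at 0.05
and asserts per-taxon sign patterns only for the naive estimator.

Precision follows the standard scaling law $\mathrm{SE} = \mathrm{SD} /
\sqrt{n}$: `se_extrapolation()` anchors the implied SD at an observed
(year, SE, $n$) triple and predicts the SE at any effort level — dropping
from 62 to 40 trawls raises the relative error by just under 25%, dropping
to 15 trawls essentially doubles it, and adding trawls up to 90 buys only a
~17% reduction. `random_exclusion_experiment()` validates the law by
actually subsampling a past year, either purely at random or as consecutive
trawls from randomly selected nights (the operationally realistic pattern);
on hurdle-simulated data the log–log slope of SE against $n$ is $-0.5$ and
the two exclusion modes agree within Monte-Carlo error.

## Seabird diet calibration

Seabird chick diet varies with the relative abundance of prey in the
surrounding ecosystem, so the mean proportion of a prey group in the diet
is an auxiliary abundance indicator. `fit_calibration()` regresses the
trawl-based log index on the diet proportion by ordinary least squares;
`predict_index()` inverts it for a survey-poor year with a 95% *prediction*
interval (coefficient + residual variance; a confidence band for the fitted
line is also exposed, since plots and new-year predictions need different
bands). Direction matters: the log index is the response, so prediction in
a data-poor year is direct rather than inverse regression. Proportions
enter untransformed — linear fits describe these series well — with a logit
option off by default. The pairing window is configurable because some prey
series begin later than others (e.g. counts unstandardized in early years).
`assess_agreement()` reports signed discrepancy, interval overlap, and
mutual point-in-interval containment between the diet-based and trawl-based
estimates.

## Krill species distribution model

Krill are patchy, swarm-forming taxa whose trawl CPUE is measured at fixed
stations. The SDM relates station-level $\ln(\mathrm{CPUE}+1)$ to static
geomorphic covariates (depth, distance to shore) and two dynamic
ocean-state proxies (winter preconditioning, spring conditions) with
gradient-boosted regression trees at conventional settings: learning rate
0.01, interaction depth 3, bag fraction 0.5, tree count chosen by
cross-validation with early stopping. CV folds are **blocked by year**,
because predicting years outside the training set is the model's use case;
row-wise folds would flatter it. Permutation importances and partial
dependence summarize the fitted response.

`predict_anomaly()` maps predictions on the full grid, floors them at 0
(negative $\ln(\mathrm{CPUE}+1)$ is uninterpretable; flooring is logged in
the returned object by construction), computes the per-cell climatology
over a baseline period, and reports anomalies that sum exactly to zero over
the baseline. Reporting is masked to cells within 150 km of shore. A
station-subset mean prediction series makes the SDM directly comparable to
the delta-GLM index: `station_series_compare()` standardizes both and
reports the Pearson correlation plus per-year sign-disagreement flags, and
`patchiness_diagnostics()` compares observed and predicted among-station
CVs — a smooth SDM cannot capture swarm-scale patchiness, so its CV sits
below the observed CV whenever patchiness noise is present.

## The synthetic survey generator

The generator exists so that every estimator above can be tested against
known truth. It emulates the statistical structure of a core-area survey,
not any particular ocean:

* **Design**: ~35 stations over shelf (<200 m), slope (200–1500 m) and deep
  (>1500 m) strata, with the 15 shallowest flagged as the reduced-year
  subset — a reduced year is therefore always inshore-biased.
* **Catches**: Bernoulli occurrence × lognormal positive catch. Year
  effects follow smoothed random walks (multi-year persistence); the depth
  association acts on both hurdle parts through stratum scores (shelf $+1$,
  slope $-0.5$, deep $-1$), so a depth-stratum covariate is the exactly
  correct spatial model — deliberate, since the estimators' unbiasedness
  claims are about correctly specified covariates. Catches are generated
  continuous, then rounded to counts (rounded zeros are hurdle zeros); the
  `round_counts = FALSE` switch keeps the positive part exactly lognormal
  for moment and coverage tests. Station-by-year lognormal patch effects
  add swarm-scale variability where wanted.
* **Effort history**: 31 years (a 1990–2020 analogue) at 62 hauls/year,
  the final year reduced to one haul at each flagged station, shifted late
  in the season (days 160–177 against the usual 121–180); hauls group ~3
  per night so night-based exclusion is meaningful. The ~35-station count
  is a scenario choice, not an observed value.
* **Diet link**: per-year diet proportion = linear function of the log
  index + Gaussian noise, clamped to [0, 1].
* **Environment and krill**: a coastal grid whose depth deepens offshore
  with independent cell-level relief (canyons and banks — this also keeps
  depth and distance from being perfectly collinear, which matters for
  partial dependence); dynamic covariates are a yearly level plus a smooth
  spatial gradient. Each krill-like species has a Gaussian dome in
  distance-to-shore — the neritic species peaking at 12 km, the offshore
  species at 45 km, over the design's slope stations, encoding its
  outer-slope association — plus linear responses to the two dynamic
  covariates and a small interannual term. Station samples multiply the
  truth by mean-one lognormal patchiness noise.

What the generator does *not* emulate: real oceanography, heatwave
dynamics, species interactions, gear effects, or observation error beyond
the stated noise models. Passing tests therefore demonstrate that the
estimators do what they claim *under their own assumptions*, not that any
particular real-world index is correct.

### The consensus-flag scenario

One acceptance-level scenario deserves its own explanation. When the final
year is sampled only at the inshore stations, a standardization whose
spatial covariates capture the cross-shore gradient (station or stratum
terms) largely *corrects* the bias — that is the point of model-based
indices, and the bias simulation asserts it. The situation the consensus
diagnostic exists for is the opposite one: covariates too coarse for the
gradient, as happens for strongly offshore, patchy taxa. The flag scenario
therefore evaluates the worst case — a year-only delta-GLM — against an SDM
that never saw the final year's observations, in a scenario with a
*designed* (evenly spread, deterministic) covariate history and a mildly
favourable final year. The designed history fixes the series against which
z-scores are standardized, so the diagnostic's outcome reflects the
sampling-bias mechanism rather than the luck of a random covariate draw;
across generator seeds the reduced year is flagged consistently (SDM
z-score positive, survey-index z-score negative).

## Problem sizes and numerical choices

The shipped tests and the acceptance script use deliberately compact
problem sizes — 31 × 62 hauls for the bias simulation (30 focal years, 4
taxa), 200 simulated datasets × 300 posterior draws for year-effect
coverage, 300 replicates for calibration recovery, a 24 × 8 grid × 19 years
for the SDM — chosen so the whole suite runs in well under a minute while
keeping Monte-Carlo error comfortably inside the asserted bounds. Other
numerical conventions: AIC comparisons use a 1e-8 tie tolerance; bootstrap
resamples that lose all positives in a year contribute a zero draw for that
year; the posterior sampler drops aliased coefficients; `xgboost` runs
single-threaded with an explicit seed for reproducibility.

## Known limitations

* The positive model assumes lognormality; heavy-tailed alternatives
  (gamma, Tweedie) are not implemented.
* The bootstrap resamples hauls, not nights; within-night correlation is
  represented in the generator but not propagated into the default
  uncertainty estimate.
* The calibration treats diet proportions as error-free predictors; a
  latent-variable formulation observing both trawls and diets would be the
  next step.
* The SDM's anomaly floor at 0 is applied before the climatology, so in
  principle a floor-heavy region can shrink anomaly amplitude there.
* Real-data connectors (survey databases, assimilative ocean models) are
  out of scope; all inputs arrive as plain CSV.
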