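---
title: "Hindcasting species richness with observer effects: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hindcasting species richness with observer effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(richcast)
```

## The problem

Large roadside breeding-bird surveys produce long panels of route-level
species richness, one observation per site and year, recorded by human
observers who turn over every few years. Two features of such data
dominate any attempt to forecast richness: most of the variance lies
*between* sites, and a substantial share of the rest is attributable to
*who* did the counting rather than to the birds. `richcast` implements a
forecasting workflow built around those two facts: a hierarchical
observer model whose posterior uncertainty is propagated into every
downstream forecaster, six forecasting models spanning site-history and
environmental information, and a verification suite for hindcast
evaluation.

Because the package must be testable without any survey download, it
ships a synthetic-data module that generates panels with the statistical
structure the analysis assumes. The generator is first-class, tested
code: every pipeline stage can be exercised, and parameter-recovery
tests are possible because the generating effects are returned alongside
the data.

## The observer model

For observed richness $y_{s,t}$ at site $s$ in year $t$ surveyed by
observer $o(s,t)$:

$$y_{s,t} = \mu + a_s + b_{o(s,t)} + \varepsilon_{s,t}, \qquad
a_s \sim N(0, \sigma_{site}^2),\;
b_o \sim N(0, \sigma_{obs}^2),\;
\varepsilon \sim N(0, \sigma_{resid}^2).$$

Site-level random effects are essential: without them, consistent
differences between sites would be soaked up by whichever observers
happen to work there, and "observer effects" would be site effects in
disguise. Identification requires observer turnover within sites; a
design in which each site has exactly one observer is flagged as
confounded.

`fit_observer_model()` samples the posterior with a blocked Gibbs
sampler in the centered parameterization:

* conjugate normal updates for $\mu$, all $a_s$, and all $b_o$;
* slice-sampler updates for $\sigma_{site}$ and $\sigma_{obs}$ under
  half-Normal$(0, 25^2)$ priors (species units; essentially flat over
  the plausible range, proper enough to handle degenerate designs);
* a conjugate inverse-gamma$(0.01, 0.01)$ update for
  $\sigma_{resid}^2$;
* two *location-interweaving* moves per sweep that shift mass between
  $\mu$ and the mean of $a$ (respectively $b$) along the direction in
  which the likelihood is flat. Without these moves the grand mean and
  the effect means random-walk against each other and the scale
  parameters mix an order of magnitude more slowly; with them the
  split-chain $\hat R$ of all three SDs sits near 1 at 500 warmup +
  500 retained draws (asserted in the tests).

The default of 500 retained draws matches the Monte-Carlo ensemble size
used throughout the package for uncertainty propagation; tests run with
fewer. A split-chain scale-reduction diagnostic is reported for each
variance parameter.

`variance_partition()` converts the draws to variance fractions
$\sigma_k^2 / \sum_j \sigma_j^2$ per draw and averages; the fractions
sum to one by construction. `corrected_richness_draws()` produces, for
each posterior draw $d$, the panel $y - b^{(d)}_{o}$ — the richness a
typical (zero-effect) observer would have recorded. Observers absent
from the training period (e.g. future observers) receive effect 0, the
same convention used when archiving forecasts for years that have not
happened yet.

## The synthetic-data generator

`sim_config()` defaults encode the study conditions the analysis
assumes:

| parameter | default | why |
|---|---|---|
| `global_mean_richness` | 51 | typical route-level richness |
| `sigma_resid` | 3.6 | residual SD, species |
| `sigma_site` | $\sqrt{0.70 \cdot 144} \approx 10.04$ | site share of variance 70% |
| `sigma_obs` | $\sqrt{0.21 \cdot 144} \approx 5.50$ | observer share 21% |
| `resid_ar1` | 0.114 | lag-1 residual $R^2 \approx 0.114^2 \approx 1.3\%$ |
| `mean_stint_years` | 8 | multi-year observer tenure |
| `obs_prob` | 0.9 | missing-visit rate, exercises the completeness filter |
| `years` | 1982–2013 | 22 training + 10 test years at the 2003 split |

The three SDs follow from fixing the residual SD at 3.6 species and
requiring the 70/21/9 partition, which implies a total variance of
$3.6^2/0.09 = 144$. With these values site means span roughly 20–80
species, consistent with the 8–91 range of real route richness.

Observer tenure is geometric with mean 8 years — the true tenure
distribution of volunteer observers is not documented, and the
geometric choice is the simplest memoryless model of "observers tend to
repeatedly sample the same site". Observers are never shared across
sites, which is simpler than reality (rarely, observers run several
routes) and makes the site/observer decomposition cleanly nested.

Site means are driven by a smooth nonlinear function of two synthetic
environmental gradients plus an unmeasured site term
(`env_effect_scale`, default 0.7, is the fraction of site variance the
gradients explain). Environmental models therefore have recoverable
signal but cannot fully separate sites with identical covariates —
mirroring the structural limitation of covariate-only models.

In richness mode the response is real-valued (the generating model is
Gaussian, matching the evaluation's Gaussian error convention); in
community mode (`simulate_community_panel()`) richness is the integer
row sum of per-species Bernoulli detections, with occupancy logits
$\alpha_i + \beta_i' x + \lambda_i' u_s$ driven by covariates and
`n_latent` shared site-level factors, and detection shifted by the
observer effect on the logit scale. The paired richness panel satisfies
the row-sum identity exactly, and the latent factors induce
over-dispersion of richness relative to the independent-Bernoulli
variance — the property the JSDM is meant to capture.

What the generator does *not* emulate: spatial autocorrelation between
sites, species phenology, the 50-stop substructure of real routes,
observer learning curves (first-year effects), and any directional
climate trend. Passing recovery tests on these panels therefore shows
that the estimators are correct under the stated model, not that the
model is adequate for any particular real survey.

## Environmental features

`compute_bioclim()` derives eight bioclim-style variables from monthly
weather over the 12 months *preceding* each survey (July of the prior
calendar year through June of the survey year — birds are surveyed in
early summer, so the relevant climate window is not the calendar year).
Conventions the implementation fixes (and the tests' oracles assume):

* "Quarters" are the 10 non-wrapping 3-month windows of the July–June
  sequence; ties between equally wet/dry/warm quarters go to the
  earliest window.
* Monthly mean temperature is the midpoint $(t_{max}+t_{min})/2$.
* Precipitation seasonality (bio15) is
  $100 \cdot \mathrm{SD}(prec) / (1 + \overline{prec})$; the $+1$
  guards zero-precipitation climates.
* Isothermality (bio3) is $100 \cdot bio2 / (bio5 - \min t_{min})$,
  defined as 100 when the annual range is zero.

Seasonal NDVI summaries average April–June (summer) and December of the
previous year plus January–February (winter). `filter_complete_sites()`
retains sites observed in at least `ceiling(0.7 * 22) = 16` training
years under the defaults, and `split_train_test()` partitions at the
split year (training years inclusive).

## The six forecasters

**average** — $y_t = \mu + \epsilon_t$: the training mean with a
horizon-invariant SD. In observer-corrected mode the predictive SD is
the observer model's residual SD rather than the raw sample SD, since
the raw spread includes observer turnover noise.

**naive** — ARIMA(0,1,0): the last observed value with SD
$\sigma_{step}\sqrt{h}$, where $\sigma_{step}$ is the sample SD of
first differences taken only across consecutive observed years. No
drift term: the model says the world stays where it was last seen.

**auto-ARIMA** — `select_arima()` chooses $d$ by repeated KPSS tests
(Bartlett-kernel long-run variance, truncation
$\lfloor 4(n/100)^{1/4}\rfloor$, 5% critical value 0.463) and then runs
a stepwise search over $(p, q) \le (5, 5)$ and the constant/drift term,
minimizing AICc $= \mathrm{AIC} + 2k(k+1)/(n-k-1)$. The search and the
KPSS test are implemented in-package on top of `stats::arima`; the
procedure is deterministic given the series. Series shorter than 10
observations fall back to the average model. On stationary series the
winner is usually the intercept-only model — time-series flexibility
buys little when richness is near-stationary.

**richness GBM** — gradient-boosted trees (squared-error loss,
interaction depth 5, shrinkage 0.015, up to 10,000 trees) on the
covariates only, with the tree count selected by 5-fold
cross-validation and a homoscedastic predictive SD equal to the
training-residual SD. Boosting is delegated to `xgboost`, which has no
out-of-bag improvement estimator, hence the cross-validated tree count;
the uncertainty construction is the package's own choice, as boosted
trees carry no native predictive variance.

**stacked SDM** — one classification random forest per species
(`ranger`, minimum node size 5; probability = fraction of trees voting
presence), richness as the Bernoulli sum: mean $\sum_i p_i$, variance
$\sum_i p_i (1 - p_i)$. The independence assumption behind that
variance is exactly what makes stacked SDMs overconfident about
community sums when species co-vary. In corrected mode each tree is fit
with a different posterior draw of the observer effects as an extra
predictor (one single-tree forest per draw), so ensemble spread carries
observer uncertainty.

**JSDM** — a latent-factor logistic joint model:
$\mathrm{logit}\, p_{i,s,t} = \alpha_i + \beta_i' x_{s,t} +
\lambda_i' u_s$ with $u_s \sim N(0, I_k)$ shared across species
($k$ = `n_latent`, default 2). This is a deliberate simplification of
neural-network JSDMs: it keeps the probabilistic contract (shared
latent variables inducing inter-species dependence and over-dispersed
richness) while remaining estimable and testable. Fitting is
Monte-Carlo EM: latent factors are importance-sampled from their prior
per site, and species-wise weighted logistic regressions update the
coefficients and loadings. With `n_latent = 0` the fit reduces exactly
to independent per-species logistic regressions (a test pins this to
`glm`). Prediction samples the latent factors, draws Bernoulli
communities, and summarizes the sampled richness as a Gaussian; zero
loadings reproduce the stacked formula up to Monte-Carlo error, and
nonzero loadings strictly widen the intervals.

Loadings are identified only up to rotation and sign; recovery tests
therefore check sign-agnostic correlation with the generating loading
vector. In corrected mode the posterior-mean observer effect enters as
a predictor column — a single-draw simplification of the per-draw
scheme used by the forest ensemble, chosen to keep the EM loop to one
fit.

## Uncertainty propagation

When a model is fit once per posterior draw of the observer effects,
`combine_draw_forecasts()` merges the per-draw Gaussian forecasts by
the law of total variance:

$$\hat y = \overline{m_d}, \qquad
\widehat{\mathrm{Var}} = \mathrm{Var}(m_d) + \overline{v_d},$$

with the *unbiased* ($n-1$ denominator) variance across draws — at 500
draws the bias distinction is invisible, but the tests fix the
convention. Single-site models are refit per corrected draw;
the GBM is refit per draw (capped at 20 draws in `run_experiment()` to
bound cost); forests carry draws per tree; the JSDM uses the
posterior-mean effect.

## Verification

* `rmse()` — accuracy of point forecasts.
* `coverage()` — share of observations inside the central Gaussian
  interval; `sd = 0` rows count as covered only on exact hits.
* `mean_deviance()` — $-2\times$ Gaussian log-likelihood per forecast,
  $\log(2\pi\sigma^2) + (y-\hat y)^2/\sigma^2$, averaged; a variance
  floor (default $10^{-6}$, logged when triggered) guards degenerate
  forecasts. Deviance is reported as a per-forecast mean rather than a
  sum, so values are comparable across strata of different size.
* `skill_vs_baseline()` — per-forecast differences in absolute error
  and deviance against a baseline on matched (site, year) keys, so the
  same forecast is compared like for like; a baseline against itself is
  identically zero.
* `decompose_mse()` — within each site the squared error splits into a
  site-level term $(\bar p_s - \bar y_s)^2$ and an annual term
  $\overline{((p-\bar p_s)-(y-\bar y_s))^2}$; the cross term cancels
  within sites, and weighting sites by their number of test years makes
  the two components add to the pooled MSE to machine precision
  (tested at $10^{-9}$ relative).
* `metrics_by_horizon()` — all metrics within each horizon stratum;
  stratum sizes sum to the pooled count.

`run_experiment()` wires the stages together: simulate or read inputs,
filter, split, fit the observer model, forecast with every requested
model in both correction modes (paired runs share seeds so
before/after comparisons are matched), and evaluate. The stage graph
never exposes test-period richness to any model — a property asserted
in the tests by poisoning test-year values and checking that forecasts
are byte-identical. Environmental forecasters see test-year covariates
under the hindcast convention ("future" environments are known); a
configuration flag substitutes training-period climatology to mimic
true forecasting. `forecast_archive()` serializes forecasts with
config-hash, seed and training-period metadata, and
`evaluate_archive()` refuses in-sample evaluation unless explicitly
acknowledged.

## Numerical choices and degenerate inputs

* Sample statistics use $n-1$ denominators throughout.
* The naive model needs three observations for a nonzero step SD; with
  two it returns step SD 0 and a constant-width (zero) interval.
* ARIMA candidates that fail to converge are skipped silently within
  the search; if no candidate converges the selection errors.
* Species observed in only one class get a constant forecast
  probability and are flagged; species never seen in training are
  excluded from richness sums.
* Richness draws are clamped at 0 in the generator (at the default
  mean of 51 and total SD 12 the truncation probability is ~1e-5).
* The coverage test of a `sd = 0` forecast treats an exact hit as
  covered, so a perfect deterministic forecaster scores 1, not 0.

## Problem sizes used in the shipped checks

The recovery experiments run at 300 sites x 32 years (about 6,000
training observations after the completeness filter) with 500 warmup
and 500 retained draws, replicated six times with fresh seeds and
averaged. The calibration experiment uses 500 sites (about 4,500 test
forecasts). At these sizes the finite-panel Monte-Carlo wobble of the
generated variance components dominates posterior uncertainty — the
delta method puts the sampling SD of the site fraction of a 300-site
draw near 1.8 percentage points, several times the posterior SD —
which is why the checks compare against combined Monte-Carlo plus
posterior standard errors. Two estimator-level effects are worth
knowing about: the lag-1 residual correlation (1.3% of variance),
which the iid observer model does not represent, lets observer stints
absorb a small slice of residual variance, tilting the recovered
residual fraction slightly low — restricted-maximum-likelihood fits
show the same tilt, so it is a property of the estimand, not of the
sampler; and pooled coverage of per-site intervals is a clustered
statistic, so binomial standard errors modestly understate its
sampling variability.

## Known limitations

* The observer model is Gaussian; count likelihoods are out of scope
  (route richness is underdispersed relative to Poisson, making the
  Gaussian a reasonable working choice at mean ~51).
* No spatial random fields, no observer-experience covariates, no
  detection-probability modelling.
* The JSDM's latent factors are site-constant: community composition
  may drift over decades in ways a static factor cannot track.
* The stepwise ARIMA search explores a neighbourhood, not the full
  $(p,d,q)$ lattice; like any stepwise procedure it can settle on a
  local AICc minimum.
* Forecast quality on these synthetic panels says nothing about model
  rankings on real surveys; the package's claim is that the machinery
  is correct, calibrated where it should be, and honestly evaluated.
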