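---
title: "Small-area estimation of county obesity and physical-activity prevalence: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area estimation of county obesity and physical-activity prevalence: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The estimation problem

State-based telephone surveys of health behaviors collect enough interviews
nationally to support precise state estimates, but most counties contribute
too few respondents for direct county estimates to be usable. `countyprev`
implements a small-area estimation pipeline for three binary outcomes —
obesity (BMI ≥ 30 kg/m²), any leisure-time physical activity, and sufficient
physical activity — that borrows strength across counties, years, and
demographic cells through a hierarchical logistic model, and corrects the
well-known self-report bias in height and weight against an examination
survey in which both are measured.

The pipeline has six stages, each an exported function family:

1. **Self-report calibration** (`cell_means()`, `fit_calibration()`,
   `apply_calibration()`): mean reported BMI is computed by sex and age group
   for every two-year cycle, matched to measured cell means from an
   examination survey, and measured means are regressed on reported means by
   ordinary least squares, separately for males and females. Each
   respondent's BMI is then corrected as `intercept + slope × reported BMI`
   before the ≥ 30 threshold is applied.
2. **Outcome definitions** (`add_outcomes()`, `classify_sufficient()`):
   sufficient activity means at least 150 weekly moderate-equivalent minutes,
   one vigorous minute counting as two moderate minutes. The same definition
   is applied to every survey year; both the threshold and the multiplier are
   configuration values so alternate definitions are one argument away.
3. **Model fitting** (`fit_variant()`): four logistic model variants with a
   Gaussian county random intercept, fitted separately by sex on every
   five-year moving window of survey years.
4. **Poststratification** (`aggregate_race()`, `age_standardize()`,
   `simulate_uncertainty()`, `estimate_prevalence()`): cell-level predictions
   are collapsed to all-race, age-standardized county prevalences with
   simulated 95% intervals.
5. **Validation** (`run_validation()`, `select_model()`): counties with at
   least 900 pooled respondents serve as gold standards; they are repeatedly
   down-sampled to 10, 50, and 100 respondents, all four variants are refit,
   and agreement with the direct gold proportions is scored by Lin's
   concordance correlation coefficient, mean relative error, and RMSE.
6. **Change analysis** (`compute_changes()`, `ecological_regression()`):
   county-level percentage-point changes between two years, with draw-wise
   paired intervals, and an ecological OLS of change in obesity on change in
   physical activity with county-level controls.

# The four model variants

For respondent $i$ in county $c$ with outcome $y_{ic}$, all variants share

$$\mathrm{logit}\, P(y_{ic}=1) = \alpha + \beta_{\text{race}(i)} +
\gamma_{\text{age}(i)} + \delta \,(t_i - \bar t_w) + \dots + u_c,\qquad
u_c \sim N(0, \sigma_u^2),$$

with race reference *white*, age reference *20–34*, and the year index
centered at the window midpoint $\bar t_w$ (a pure reparameterization that
decorrelates intercept and slope; predictions are unchanged).

- **Naive**: only the terms above.
- **Covariate**: adds county-level covariates — poverty, unemployment,
  percent rural, percent with a high-school diploma, and PM2.5 for the
  physical-activity outcomes, plus the doctors/dentists rate per 100,000 for
  obesity — and the county's racial-composition shares, so both individual
  race effects and contextual composition effects are represented.
- **Geospatial**: the naive model plus a *geospatial term*: for each county,
  the arithmetic mean of the empirical-Bayes posterior county-effect means of
  all adjacent counties, computed from a first-stage naive fit and entered as
  a fixed covariate in a second fit. The two-stage computation runs exactly
  once; there is no iteration to a fixed point.
- **Full**: the covariate model plus a geospatial term computed from a
  first-stage covariate fit.

Counties with no data in a window keep the prior mean $u_c = 0$ with variance
$\sigma_u^2$ (the empirical-Bayes prior), so every county receives a
prediction, with honestly inflated uncertainty. A county with no neighbors
has geospatial term 0. A constant geospatial term (for example when every
first-stage posterior mean is 0) carries no between-county information and is
confounded with the intercept; the fit then reduces to the base model and the
geospatial coefficient is reported as 0.

Fitting maximizes the Laplace-approximate marginal likelihood via
`lme4::glmer`; the approximation used is recorded in the fit's `method`
field. `fit_control(nAGQ = 0)` switches to the penalized-least-squares-only
approximation, which we recommend for large designs (tens of thousands of
rows): in our recovery experiments it changed county-prevalence estimates by
less than 10⁻³ while reducing fit time by two orders of magnitude. The
optimizer is bobyqa for both of lme4's stages, which is robust when
$\hat\sigma_u^2$ sits at its boundary of 0. A design with a single county
collapses to ordinary logistic regression (the random intercept is
unidentifiable), with $\sigma_u^2 = 0$. County covariates enter the linear
predictor rescaled (PM2.5 in tens, rates per 100,000 in thousands) so the
optimizer sees comparably scaled columns; fitting and prediction share the
scaling, so predictions are unaffected.

Rank-deficient fixed-effect designs (for example county covariates that are
constant across counties) are rejected with an error naming the inestimable
columns rather than silently dropped.

# Moving windows and annual estimates

Each model is fit on every span of five adjacent survey years. An annual
estimate is the unweighted mean of the predictions from all windows covering
that year (`combine_windows()`), applied elementwise to simulation draws as
well, so the combination preserves the (0, 1) bounds and the draw pairing.
The source text does not state how its overlapping windows map to annual
estimates; the unweighted average is this package's documented choice. For
sufficient activity, only years in which the detailed minutes questions exist
(odd years, plus 2011) contribute rows to a window; the time trend remains
linear in calendar year.

# Poststratification, age standardization, and uncertainty

Model predictions are race-specific; all-race county estimates weight them by
the county's race-specific populations pooled over the study period. Age
standardization then applies fixed standard-population weights over the six
age groups. The shipped `age_standard_2000()` weights approximate the 2000 US
census adult age distribution; the standard is injected as data and any
`standard_population()` can be substituted.

Uncertainty comes from simulation: fixed effects are drawn from
$N(\hat\beta, \widehat{\mathrm{Var}}(\hat\beta))$ and county effects from
their empirical-Bayes posteriors $N(\hat u_c, \widehat{\mathrm{var}}(u_c))$,
independently across counties and of $\beta$ — a Gaussian approximation to
the joint posterior that is this package's documented choice. Every draw is
pushed through prediction, race aggregation, and age standardization, and
each county-year is summarized by the draw mean and the 2.5th/97.5th
percentiles (percentile rather than normal-theory intervals, matching the
asymmetry of prevalence intervals near 0 or 1). The same draw indices are
used across counties and years, so draw-wise differences — used by
`compute_changes()` — carry the right correlation. Draws from different
windows are averaged draw-wise; the fits are treated as independent across
windows. `n_draws` defaults to 1000. A non-positive-definite covariance is
repaired by flooring negative eigenvalues at zero, with a warning (or an
error when `repair = FALSE`).

In our calibration experiment (20 independent 5×5-county worlds, 60
respondents per county-year, naive fits, 400 draws), nominal 95% intervals
covered the true age-standardized county prevalence for 96–98% of
county-worlds — acceptably close to nominal given the Gaussian and
independence approximations.

# Validation by down-sampling

Gold-standard counties are those with at least 900 respondents carrying a
non-missing outcome in 2001–2005; their pooled direct proportion is the
benchmark. Each replicate draws a simple random sample of size
$m \in \{10, 50, 100\}$ from every gold county (deterministically in
`(seed, replicate, county, m)`), refits all four variants with all other
counties untouched, and scores each variant's prediction of the gold
counties' crude pooled prevalence — the average of fitted cell probabilities
over each county's full respondent composition, so like is compared with
like. The selection rule is highest mean CCC across sample sizes, ties broken
by lower RMSE, then lower absolute mean relative error. We score crude pooled
prevalence rather than an age-standardized quantity because the gold standard
itself is a crude proportion; this choice is recorded here rather than
asserted as the source's.

The signed mean relative error is reported by default so systematic shrinkage
toward the grand mean (the signature failure mode of over-regularized
small-area estimators) is visible; an absolute variant is available.

# The synthetic-data generator

The generator is first-class, tested code: it produces the study conditions
under which every downstream claim is checked.

* **County structure**: a rows × cols lattice with rook adjacency stands in
  for the county adjacency map. Covariates are drawn per county (poverty,
  unemployment, and diploma shares from logit-normal distributions;
  percent rural uniform; PM2.5 log-normal around 10; doctors/dentists gamma
  around 200 per 100,000) with small linear drifts over years; race
  compositions come from a Dirichlet centred on a white-majority mix, and
  county populations from a log-normal.
* **Truth surface**: each outcome has a logit-linear surface with age, race,
  and sex offsets, a linear calendar-time slope, county-covariate effects
  acting on deviations from reference covariate levels, and a county effect
  $u_c$ built as the convex spatial mixture
  $\rho \cdot \overline{z}_{\mathcal N(c)} + (1-\rho) z_c$ of i.i.d. normal
  draws, rescaled to the requested standard deviation. With $\rho > 0$ the
  effects are positively autocorrelated (assertable via `morans_i()`).
* **Effect sizes** follow an explicit variance budget: the county covariates
  jointly contribute about 0.35 SD on the county logit scale against a
  county-effect SD of 0.5. The budget matters: a world where covariates carry
  negligible county-level signal makes the covariate and full variants pay a
  pure variance cost for their extra parameters and can never reproduce the
  intended model ranking; a world where covariates explain everything makes
  the geospatial term irrelevant. The defaults sit deliberately between those
  degenerate regimes and produce realistic national prevalences (roughly 30%
  obesity, 75% any activity, 50% sufficient activity).
* **Respondents** are drawn per county-year from the county race composition
  and a near-uniform age/sex table (`default_age_sex_distribution()`; the
  respondent age/race joint distribution is exposed as a parameter rather
  than asserted as faithful). Outcomes are Bernoulli draws from the truth
  surface. True BMI is `30·exp(±s|Z|)` with the sign set by the drawn obesity
  status — a two-sided log-normal around the threshold whose conditional
  means are available in closed form, which the examination-cell generator
  and its tests exploit. True height is sex-specific log-normal; weight
  follows from BMI and height.
* **Self-report distortion** is affine in weight and additive in height, each
  with optional Gaussian noise. Note one structural fact the tests rely on:
  only the multiplicative weight component induces a BMI distortion that is
  affine *per individual* (`reported BMI = scale × true BMI`), which is the
  case a linear calibration can undo exactly. Additive weight or height
  shifts make reported BMI non-affine in true BMI, so calibration then
  removes bias only approximately — a property of regression calibration
  itself, not of this implementation. The exact-recovery tests therefore use
  scale-only bias and noiseless measured cells.
* **Activity minutes** are generated consistently with the drawn sufficiency
  outcome (moderate-equivalent minutes above or below 150, split between
  moderate and vigorous so the reconstruction is exact in floating point),
  and blanked in even years before 2011 to emulate the odd-year-only detailed
  questionnaire. The three outcomes are drawn independently given the truth
  surfaces; real respondents' outcomes are correlated (sufficient activity
  implies any activity), which per-outcome models never exploit, so the
  simplification does not affect what the tests can show.
* **Determinism**: every generator function takes one explicit seed; child
  streams are derived arithmetically per stage, and the caller's RNG state is
  restored afterwards. Fixing the seed fixes every generated byte.

What passing tests on this generator do *not* show about real data:
telephone-frame selection, raking weights, nonresponse, the 2011 methodology
change, sentinel-coded item nonresponse, and spatially correlated covariate
fields are all absent. The package's claims are about the estimator
machinery, not about survey operations.

# Problem sizes used in the shipped experiments

The test suite and the acceptance script run scaled-down versions of the
analyses: a 10×10 grid with 80 respondents per county-year for parameter
recovery (full-variant county prevalence correlates with truth above 0.9, and
the fitted time slope falls within three standard errors of the generative
slope); an 8×8 grid with 21 gold counties of 2,000 pooled respondents each,
25 replicates, and $m \in \{10, 50, 100\}$ for the validation ranking (the
full variant attains the best mean concordance in the large majority of
generated worlds; in occasional worlds the realized covariate field is
uninformative by chance and a sibling variant edges it out); and twenty
independent 5×5 worlds for interval calibration. These sizes were chosen so
the entire suite documents the method's behavior at desk scale; the
estimator code is size-agnostic.

# Known limitations

- The geospatial term is a neighbor mean of posterior effects, not a joint
  CAR/ICAR prior; uncertainty in the first-stage posterior means is not
  propagated into the second stage.
- Survey weights are not used inside the models; representativeness is
  handled by race/age poststratification only.
- The Gaussian draw scheme ignores posterior dependence between fixed effects
  and county effects, and between counties; the interval-calibration
  experiment bounds the practical consequence.
- The per-sex calibration pools all cycles into one fit; time-varying or
  county-specific misreporting is out of scope. Because the calibration is a
  regression on cell *means*, sampling noise in the reported cell means
  attenuates the fitted slope (classical errors-in-variables); with
  survey-scale cell counts the attenuation is negligible, but desk-scale
  demonstrations should compute reported cells from a generously sized draw.
- The ecological regression describes area-level association only; nothing in
  it identifies individual-level causation.
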