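# Shared synthetic fixtures, built in code and memoized so several test
# files can reuse the same small study without regenerating it.

.fixture_env <- new.env(parent = emptyenv())

make_study <- function(rows = 4, cols = 4, years = 2001:2005, n = 30,
                       seed = 42, params = truth_params(),
                       bias = list(weight_scale = 1, weight_shift = 0,
                                   height_shift = 0)) {
  counties <- populate_county_data(make_county_grid(rows, cols), years,
                                   seed = seed)
  truth <- simulate_truth(counties, years, params, seed = seed)
  records <- simulate_survey(truth, counties, n, reporting_bias = bias,
                             seed = seed)
  list(counties = counties, truth = truth, records = records)
}

# default 4x4 study with identity reporting, outcomes attached
cached_study <- function() {
  if (is.null(.fixture_env$study)) {
    st <- make_study()
    st$records <- add_outcomes(st$records, calibration = NULL)
    .fixture_env$study <- st
  }
  .fixture_env$study
}

# truth parameters with every effect switched off except the intercept
flat_params <- function(intercept = 0.4, ...) {
  truth_params(
    age_effects = setNames(rep(0, 6), age_groups),
    race_effects = setNames(rep(0, 5), race_groups),
    sex_effect = c(male = 0, female = 0),
    time_slope = 0,
    covariate_coefs = setNames(rep(0, 6), county_covariates),
    sigma_u = 0, rho = 0,
    outcomes = list(obesity = list(intercept = intercept),
                    any_pa = list(intercept = intercept),
                    sufficient_pa = list(intercept = intercept)),
    ...)
}

# hand-built calibration model with given per-sex lines
fake_calibration <- function(intercept, slope) {
  structure(list(coefficients = list(
    male = list(intercept = intercept, slope = slope),
    female = list(intercept = intercept, slope = slope)),
    cells = NULL, weighted = FALSE), class = "calibration_model")
}

# minimal sae_fit whose linear predictor is intercept-only, for closed-form
# checks of the simulation machinery
fake_intercept_fit <- function(beta0, sd_beta0, counties,
                               window = 2001:2005) {
  spec <- model_spec("naive", "obesity", "female", window)
  p <- c("(Intercept)", paste0("race", race_groups[-1]),
         paste0("age_group", age_groups[-1]), "year_c")
  beta <- setNames(rep(0, length(p)), p)
  beta[1] <- beta0
  V <- matrix(0, length(p), length(p), dimnames = list(p, p))
  V[1, 1] <- sd_beta0^2
  ids <- counties$county_ids
  structure(list(coefficients = beta, vcov = V, sigma2_u = 0,
                 u = setNames(rep(0, length(ids)), ids),
                 u_var = setNames(rep(0, length(ids)), ids),
                 spec = spec, window = spec$window,
                 ref_year = mean(spec$window),
                 formula = countyprev:::design_formula(spec), geo = NULL,
                 counties_with_data = ids, n_obs = 0L,
                 method = "synthetic", converged = TRUE,
                 messages = character(0)), class = "sae_fit")
}
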