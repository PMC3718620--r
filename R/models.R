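#' The four small-area model variants
#' @export
model_variants <- c("naive", "covariate", "geospatial", "full")

#' Specification of one model fit
#'
#' A model spec fixes the variant, outcome, sex, and five-year window of one
#' hierarchical logistic fit. Every variant contains individual-level race
#' and age-group dummies, a linear time trend, and a county random intercept.
#' The covariate and full variants add county-level covariates (the
#' physical-activity covariate list, plus the doctors/dentists rate for
#' obesity) and county racial-composition shares; the geospatial and full
#' variants add a neighbor-mean geospatial term computed from a base fit.
#'
#' @param variant one of [model_variants].
#' @param outcome one of [outcome_names].
#' @param sex `"male"` or `"female"`.
#' @param window integer vector of consecutive calendar years (usually 5).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(variant, outcome, sex, window) {
  variant <- match.arg(variant, model_variants)
  outcome <- match.arg(outcome, outcome_names)
  sex <- match.arg(sex, sexes)
  window <- sort(as.integer(window))
  if (length(window) < 1L || !all(diff(window) == 1L))
    stop("'window' must be consecutive calendar years")
  covs <- if (variant %in% c("covariate", "full")) {
    if (outcome == "obesity") county_covariates else pa_covariates
  } else character(0)
  structure(list(variant = variant, outcome = outcome, sex = sex,
                 window = window, covariates = covs,
                 uses_geo = variant %in% c("geospatial", "full"),
                 uses_composition = variant %in% c("covariate", "full")),
            class = "model_spec")
}

#' Moving five-year windows
#'
#' All consecutive spans of `width` years between `first_year` and
#' `last_year`, ascending — the moving-window scheme under which each model
#' is fit on each set of five adjacent years.
#'
#' @param first_year,last_year inclusive year range.
#' @param width window width in years (default 5).
#' @return List of integer vectors, one per window.
#' @examples
#' length(sliding_windows(2001, 2011))  # 7
#' @export
sliding_windows <- function(first_year, last_year, width = 5L) {
  first_year <- as.integer(first_year); last_year <- as.integer(last_year)
  width <- as.integer(width)
  if (width < 1L) stop("'width' must be >= 1")
  if (last_year - first_year + 1L < width)
    stop("year range shorter than the window width")
  lapply(first_year:(last_year - width + 1L), function(s) s:(s + width - 1L))
}

# county covariates enter the linear predictor rescaled to unit-ish ranges
# (pollution in tens, rates per 100k in thousands) so the optimizer sees
# comparably scaled columns; fitting and prediction share the same scaling
covariate_scale <- c(poverty = 1, unemployment = 1, pct_rural = 1,
                     pct_hs_diploma = 1, pm25 = 10, docs_per_100k = 1000)

# county-level columns (covariates by year, composition shares, geo term)
# attached to a per-row data frame; shared by design building and prediction
augment_county_columns <- function(d, counties, spec, geo_term = NULL) {
  if (length(spec$covariates)) {
    cv <- counties$covariates
    if (is.null(cv)) stop("county table has no covariates")
    miss <- setdiff(spec$covariates, names(cv))
    if (length(miss))
      stop("county covariate column(s) missing from county table: ",
           paste(miss, collapse = ", "))
    rows <- match(paste(d$county_id, d$year), paste(cv$county_id, cv$year))
    if (anyNA(rows))
      stop("county covariates missing for some county/year combinations")
    for (v in spec$covariates)
      d[[v]] <- cv[[v]][rows] / covariate_scale[[v]]
  }
  if (spec$uses_composition) {
    shares <- race_share_matrix(counties)
    ci <- match(d$county_id, rownames(shares))
    for (r in setdiff(race_groups, "white"))
      d[[paste0("comp_", r)]] <- shares[ci, r]
  }
  if (spec$uses_geo) {
    if (is.null(geo_term))
      stop("variant '", spec$variant, "' requires a geospatial term")
    if (!all(d$county_id %in% names(geo_term)))
      stop("geospatial term missing for some counties")
    d$geo <- as.numeric(geo_term[d$county_id])
  }
  d
}

design_formula <- function(spec, response = TRUE) {
  rhs <- c("race", "age_group", "year_c", spec$covariates,
           if (spec$uses_composition)
             paste0("comp_", setdiff(race_groups, "white")),
           if (spec$uses_geo) "geo")
  stats::as.formula(paste(if (response) "y" else "",
                          "~", paste(rhs, collapse = " + ")))
}

#' Build the fixed-effect design for one model fit
#'
#' Restricts the records to the model spec's sex and window, drops rows with a
#' missing outcome or missing age, race, or county, and assembles the model
#' frame: reference-coded race (reference white) and age group (reference
#' 20-34), a year index centered at the window midpoint, county covariate
#' and racial-composition columns where the variant uses them, and the
#' geospatial column for second-stage variants.
#'
#' @param records microdata with outcome columns (see [add_outcomes()]).
#' @param counties a populated [county_table()].
#' @param spec a [model_spec()].
#' @param geo_term named per-county numeric vector (geospatial variants).
#' @return A list of class `sae_design` with the model frame, fixed-effect
#'   formula, and bookkeeping for prediction.
#' @export
build_design <- function(records, counties, spec, geo_term = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  ycol <- outcome_column(spec$outcome)
  if (is.null(records[[ycol]]))
    stop("records carry no '", ycol, "' outcome column; run add_outcomes()")
  keep <- records$sex %in% spec$sex &
    records$year %in% spec$window &
    !is.na(records[[ycol]]) & !is.na(records$age_group) &
    !is.na(records$race) & !is.na(records$county_id)
  d <- records[keep, , drop = FALSE]
  if (nrow(d) == 0L)
    stop("no usable records for sex '", spec$sex, "' in window ",
         spec$window[1], "-", spec$window[length(spec$window)])
  bad_race <- setdiff(unique(d$race), race_groups)
  if (length(bad_race)) stop("unknown race level(s): ",
                             paste(bad_race, collapse = ", "))
  ref_year <- mean(spec$window)
  out <- data.frame(
    y = as.integer(d[[ycol]]),
    county_id = as.character(d$county_id),
    race = factor(d$race, levels = race_groups),
    age_group = factor(d$age_group, levels = age_groups),
    year_c = d$year - ref_year,
    year = d$year, stringsAsFactors = FALSE)
  out <- augment_county_columns(out, counties, spec, geo_term)
  structure(list(data = out, formula = design_formula(spec),
                 spec = spec, ref_year = ref_year,
                 geo = if (spec$uses_geo) geo_term else NULL,
                 county_ids = counties$county_ids),
            class = "sae_design")
}

#' Control settings for the mixed-model fit
#'
#' @param nAGQ adaptive Gauss-Hermite points passed to [lme4::glmer()]
#'   (1 = Laplace).
#' @param maxfun optimizer evaluation cap.
#' @param optimizer optimizer for both of lme4's stages; bobyqa is robust
#'   when the random-effect variance sits near its boundary at 0.
#' @return list of class `fit_control`.
#' @export
fit_control <- function(nAGQ = 1L, maxfun = 1e5, optimizer = "bobyqa") {
  structure(list(nAGQ = as.integer(nAGQ), maxfun = maxfun,
                 optimizer = optimizer), class = "fit_control")
}

#' Fit the hierarchical logistic model for one design
#'
#' Maximizes the Laplace-approximate marginal likelihood of a logistic
#' regression with a Gaussian county random intercept (via [lme4::glmer()])
#' and extracts everything downstream stages need: fixed effects with their
#' covariance, the random-effect variance, empirical-Bayes posterior county
#' means and conditional variances, and convergence diagnostics. Counties
#' without data in the window receive the prior mean 0 with variance equal
#' to the estimated random-effect variance. A design with a single county
#' collapses to ordinary logistic regression (`sigma2_u = 0`), since the
#' random intercept is then unidentifiable.
#'
#' @param design an [build_design()] bundle.
#' @param control a [fit_control()].
#' @return An object of class `sae_fit`.
#' @export
fit_mixed_logit <- function(design, control = fit_control()) {
  stopifnot(inherits(design, "sae_design"))
  d <- design$data
  # a constant geospatial term carries no between-county information (it is
  # confounded with the intercept); fit without it and report coefficient 0
  form <- design$formula
  drop_geo <- "geo" %in% names(d) && stats::var(d$geo) == 0
  if (drop_geo) form <- stats::update.formula(form, . ~ . - geo)
  X <- stats::model.matrix(form, d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear fixed-effect design; inestimable column(s): ",
         paste(aliased, collapse = ", "))
  }
  if (length(unique(d$y)) < 2L)
    stop("outcome is constant in this window; model not estimable")
  all_ids <- design$county_ids
  obs_ids <- unique(d$county_id)
  if (length(obs_ids) == 1L) {
    fit <- stats::glm(form, family = stats::binomial(), data = d)
    beta <- stats::coef(fit)
    V <- as.matrix(stats::vcov(fit))
    sigma2_u <- 0
    u <- stats::setNames(rep(0, length(all_ids)), all_ids)
    u_var <- stats::setNames(rep(0, length(all_ids)), all_ids)
    method <- "glm (single county; random intercept collapses)"
    converged <- fit$converged
    msgs <- character(0)
  } else {
    f <- stats::update.formula(form, . ~ . + (1 | county_id))
    fit <- lme4::glmer(f, data = d, family = stats::binomial(),
                       nAGQ = control$nAGQ,
                       control = lme4::glmerControl(
                         optimizer = control$optimizer,
                         optCtrl = list(maxfun = control$maxfun),
                         calc.derivs = FALSE,
                         check.scaleX = "ignore"))
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    sigma2_u <- as.numeric(lme4::VarCorr(fit)$county_id[1, 1])
    re <- lme4::ranef(fit, condVar = TRUE)$county_id
    pv <- as.numeric(attr(re, "postVar"))
    u <- stats::setNames(rep(0, length(all_ids)), all_ids)
    u_var <- stats::setNames(rep(sigma2_u, length(all_ids)), all_ids)
    u[rownames(re)] <- re[, 1]
    u_var[rownames(re)] <- pv
    method <- sprintf("lme4::glmer, %s",
                      if (control$nAGQ <= 1L) "Laplace approximation"
                      else sprintf("adaptive GHQ (nAGQ = %d)", control$nAGQ))
    msgs <- unlist(fit@optinfo$conv$lme4$messages)
    if (is.null(msgs)) msgs <- character(0)
    converged <- fit@optinfo$conv$opt == 0
  }
  if (drop_geo) {
    beta <- c(beta, geo = 0)
    V <- rbind(cbind(V, 0), 0)
    dimnames(V) <- list(names(beta), names(beta))
  }
  structure(list(coefficients = beta, vcov = V, sigma2_u = sigma2_u,
                 u = u, u_var = u_var, spec = design$spec,
                 window = design$spec$window, ref_year = design$ref_year,
                 formula = design$formula, geo = design$geo,
                 counties_with_data = obs_ids, n_obs = nrow(d),
                 method = method, converged = converged, messages = msgs),
            class = "sae_fit")
}

#' @export
print.sae_fit <- function(x, ...) {
  cat(sprintf("sae_fit: %s model, outcome %s, sex %s, window %d-%d\n",
              x$spec$variant, x$spec$outcome, x$spec$sex,
              x$window[1], x$window[length(x$window)]))
  cat(sprintf("  n = %d, counties with data = %d, sigma2_u = %.4f\n",
              x$n_obs, length(x$counties_with_data), x$sigma2_u))
  cat("  method:", x$method, "\n")
  invisible(x)
}

#' Neighbor mean of county effects
#'
#' The geospatial term: for one county, the arithmetic mean of the posterior
#' county-effect means of all adjacent counties (0 for a county with no
#' neighbors).
#'
#' @param effects numeric vector named by county id, covering every county
#'   (no-data counties at their documented default 0).
#' @param counties a [county_table()].
#' @param county_id a single county id.
#' @return The neighbor mean.
#' @export
neighbor_mean <- function(effects, counties, county_id) {
  if (!county_id %in% counties$county_ids)
    stop("unknown county id: ", county_id)
  nb <- counties$neighbors[[county_id]]
  if (!length(nb)) return(0)
  if (!all(nb %in% names(effects)))
    stop("effects missing for neighbor(s) of ", county_id)
  mean(effects[nb])
}

#' @rdname neighbor_mean
#' @return `neighbor_means()`: the full named vector over all counties.
#' @export
neighbor_means <- function(effects, counties) {
  vapply(counties$county_ids, function(id)
    neighbor_mean(effects, counties, id), numeric(1))
}

#' Fit one model variant, including the two-stage geospatial variants
#'
#' The naive and covariate variants are single mixed-logit fits. The
#' geospatial variant first fits the naive model, computes each county's
#' neighbor mean of the posterior county effects, and refits with that value
#' as a fixed covariate; the full variant does the same starting from the
#' covariate model. The geospatial term is computed exactly once (no
#' iteration to a fixed point).
#'
#' @inheritParams build_design
#' @param control a [fit_control()].
#' @return An `sae_fit`; for two-stage variants its `base_fit` element holds
#'   the first-stage fit.
#' @export
fit_variant <- function(records, counties, spec, control = fit_control()) {
  stopifnot(inherits(spec, "model_spec"))
  if (!spec$uses_geo) {
    return(fit_mixed_logit(build_design(records, counties, spec), control))
  }
  base_variant <- if (spec$variant == "geospatial") "naive" else "covariate"
  base_spec <- model_spec(base_variant, spec$outcome, spec$sex, spec$window)
  base_fit <- tryCatch(
    fit_mixed_logit(build_design(records, counties, base_spec), control),
    error = function(e) stop("base stage (", base_variant, "): ",
                             conditionMessage(e), call. = FALSE))
  geo <- neighbor_means(base_fit$u, counties)
  fit <- tryCatch(
    fit_mixed_logit(build_design(records, counties, spec, geo_term = geo),
                    control),
    error = function(e) stop("geo-augmented stage (", spec$variant, "): ",
                             conditionMessage(e), call. = FALSE))
  fit$base_fit <- base_fit
  fit
}

# all four variants with the base fits shared (used by validation loops)
fit_all_variants <- function(records, counties, outcome, sex, window,
                             control = fit_control()) {
  naive <- fit_mixed_logit(build_design(
    records, counties, model_spec("naive", outcome, sex, window)), control)
  covariate <- fit_mixed_logit(build_design(
    records, counties, model_spec("covariate", outcome, sex, window)),
    control)
  geo_spec <- model_spec("geospatial", outcome, sex, window)
  geospatial <- fit_mixed_logit(build_design(
    records, counties, geo_spec, geo_term = neighbor_means(naive$u,
                                                           counties)),
    control)
  geospatial$base_fit <- naive
  full_spec <- model_spec("full", outcome, sex, window)
  full <- fit_mixed_logit(build_design(
    records, counties, full_spec, geo_term = neighbor_means(covariate$u,
                                                            counties)),
    control)
  full$base_fit <- covariate
  list(naive = naive, covariate = covariate, geospatial = geospatial,
       full = full)
}

#' Predicted prevalence for county/year/age/race cells
#'
#' Inverse-logit of the fitted linear predictor, using the empirical-Bayes
#' posterior county effect (0 for counties without data in the window).
#'
#' @param fit an [fit_mixed_logit()] or [fit_variant()] result.
#' @param newdata `data.frame` with columns `county_id`, `year`,
#'   `age_group`, `race`.
#' @param counties the [county_table()] used for fitting.
#' @return Numeric vector of probabilities strictly in (0, 1).
#' @export
predict_cells <- function(fit, newdata, counties) {
  stopifnot(inherits(fit, "sae_fit"))
  bad <- setdiff(unique(newdata$county_id), counties$county_ids)
  if (length(bad)) stop("unknown county id(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(newdata$age_group), age_groups)
  if (length(bad)) stop("unknown age group(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(newdata$race), race_groups)
  if (length(bad)) stop("unknown race level(s): ", paste(bad, collapse = ", "))
  X <- cell_model_matrix(fit, newdata, counties)
  eta <- as.numeric(X %*% fit$coefficients) +
    as.numeric(fit$u[newdata$county_id])
  as.numeric(stats::plogis(eta))
}

# fixed-effect model matrix for prediction cells
cell_model_matrix <- function(fit, newdata, counties) {
  d <- data.frame(county_id = as.character(newdata$county_id),
                  year = newdata$year,
                  race = factor(newdata$race, levels = race_groups),
                  age_group = factor(newdata$age_group, levels = age_groups),
                  year_c = newdata$year - fit$ref_year,
                  stringsAsFactors = FALSE)
  d <- augment_county_columns(d, counties, fit$spec, fit$geo)
  tt <- stats::delete.response(stats::terms(fit$formula))
  stats::model.matrix(tt, d)
}

#' @rdname predict_cells
#' @param county_id,year,age_group,race a single cell.
#' @export
predict_cell <- function(fit, county_id, year, age_group, race, counties) {
  predict_cells(fit, data.frame(county_id = county_id, year = year,
                                age_group = age_group, race = race,
                                stringsAsFactors = FALSE), counties)
}

#' Combine overlapping moving-window predictions into one annual value
#'
#' Unweighted mean, over all windows containing the year, of each window's
#' prediction. Predictions may be vectors or matrices (e.g. draw matrices);
#' they are averaged elementwise, so convex bounds are preserved.
#'
#' @param window_predictions list of numeric vectors/matrices, one per
#'   window, all of the same shape.
#' @param windows list of integer year vectors aligned with
#'   `window_predictions`.
#' @param year the calendar year to combine for.
#' @return The elementwise mean over covering windows.
#' @export
combine_windows <- function(window_predictions, windows, year) {
  stopifnot(length(window_predictions) == length(windows))
  covering <- which(vapply(windows, function(w) year %in% w, logical(1)))
  if (!length(covering)) stop("year ", year, " is covered by no window")
  Reduce(`+`, window_predictions[covering]) / length(covering)
}
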