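#' Generative settings for the synthetic truth surface
#'
#' Parameters of the logit-linear surface the generator uses for each binary
#' outcome: a per-outcome intercept, additive age/race/sex effects, a linear
#' calendar-time slope, county-covariate coefficients, and a spatially mixed
#' county random effect with standard deviation `sigma_u` and mixing weight
#' `rho` (0 = independent county effects, 1 = pure neighbor average before
#' rescaling). Any shared parameter can be overridden per outcome through the
#' `outcomes` list. The defaults put national prevalence near 30% (obesity),
#' 75% (any activity) and 50% (sufficient activity) for a middle-aged white
#' population at average covariate levels.
#'
#' @param intercept baseline logit for the reference cell (white, 20-34,
#'   male, mid-period, covariates at zero).
#' @param age_effects,race_effects,sex_effect named logit offsets; the first
#'   level of each is the reference and must be 0.
#' @param time_slope logit change per calendar year.
#' @param covariate_coefs named coefficients over [county_covariates]. The
#'   defaults follow a variance budget: together the covariates contribute
#'   roughly 0.35 SD on the county logit scale, comparable to the residual
#'   county effect, so county-level covariates genuinely inform prediction.
#' @param covariate_centers reference covariate levels; effects act on
#'   deviations from these, so intercepts stay interpretable as prevalence
#'   at average county conditions.
#' @param sigma_u standard deviation of the county random effect (logit).
#' @param rho spatial mixing weight in [0, 1].
#' @param bmi_log_sd dispersion of log BMI around the 30 kg/m^2 threshold on
#'   each side, controlling how far obese/non-obese BMI sit from 30.
#' @param outcomes named list of per-outcome overrides (at least an
#'   `intercept` for each of [outcome_names]).
#' @return A list of class `truth_params`.
#' @export
truth_params <- function(intercept = -1.4,
                         age_effects = c("20-34" = 0, "35-44" = 0.30,
                                         "45-54" = 0.50, "55-64" = 0.55,
                                         "65-74" = 0.45, "75+" = 0.20),
                         race_effects = c(white = 0, black = 0.35,
                                          hispanic = 0.20,
                                          native_american = 0.30,
                                          other = -0.15),
                         sex_effect = c(male = 0, female = 0.10),
                         time_slope = 0.05,
                         covariate_coefs = c(poverty = 4, unemployment = 4,
                                             pct_rural = 0.35,
                                             pct_hs_diploma = -3,
                                             pm25 = 0.02,
                                             docs_per_100k = -1e-3),
                         covariate_centers = c(poverty = 0.15,
                                               unemployment = 0.07,
                                               pct_rural = 0.5,
                                               pct_hs_diploma = 0.8,
                                               pm25 = 10,
                                               docs_per_100k = 200),
                         sigma_u = 0.5, rho = 0.8, bmi_log_sd = 0.15,
                         outcomes = list(
                           obesity = list(intercept = -1.4),
                           any_pa = list(intercept = 1.2, time_slope = -0.005,
                                         age_effects = c("20-34" = 0,
                                           "35-44" = -0.1, "45-54" = -0.2,
                                           "55-64" = -0.35, "65-74" = -0.5,
                                           "75+" = -0.9)),
                           sufficient_pa = list(intercept = 0.0,
                                                time_slope = 0.03))) {
  stopifnot(identical(names(age_effects), age_groups),
            identical(names(race_effects), race_groups),
            identical(names(sex_effect), sexes),
            age_effects[[1]] == 0, race_effects[[1]] == 0,
            sex_effect[[1]] == 0,
            all(names(covariate_coefs) %in% county_covariates),
            all(names(covariate_coefs) %in% names(covariate_centers)))
  if (rho < 0 || rho > 1) stop("'rho' must lie in [0, 1]")
  if (sigma_u < 0) stop("'sigma_u' must be >= 0")
  structure(list(intercept = intercept, age_effects = age_effects,
                 race_effects = race_effects, sex_effect = sex_effect,
                 time_slope = time_slope, covariate_coefs = covariate_coefs,
                 covariate_centers = covariate_centers,
                 sigma_u = sigma_u, rho = rho, bmi_log_sd = bmi_log_sd,
                 outcomes = outcomes),
            class = "truth_params")
}

# parameter for one outcome, honoring per-outcome overrides
truth_param <- function(truth, outcome, name) {
  ov <- truth$params$outcomes[[outcome]]
  if (!is.null(ov[[name]])) ov[[name]] else truth$params[[name]]
}

#' Simulate the true prevalence surface
#'
#' Draws, for every outcome, a county random effect on the logit scale as a
#' convex spatial mixture: with mixing weight `rho`, each county's raw effect
#' is `rho` times the mean of its neighbors' raw i.i.d. draws plus `1 - rho`
#' times its own, then rescaled so the county effects have the requested
#' standard deviation. Together with the fixed effects in `params` this
#' defines the true prevalence for every county/year/sex/age/race cell.
#'
#' @param counties a populated [county_table()].
#' @param years integer vector of calendar years the surface covers.
#' @param params a [truth_params()] object.
#' @param seed integer seed.
#' @return An object of class `truth_surface`.
#' @export
simulate_truth <- function(counties, years, params = truth_params(),
                           seed = 1L) {
  stopifnot(inherits(counties, "county_table"),
            inherits(params, "truth_params"))
  if (is.null(counties$covariates))
    stop("county table has no covariates; call populate_county_data() first")
  years <- sort(as.integer(years))
  ids <- counties$county_ids
  draw_u <- function(sigma_u, rho, sub) {
    with_seed(sub, {
      z <- stats::rnorm(length(ids))
      names(z) <- ids
      zm <- vapply(ids, function(id) {
        nb <- counties$neighbors[[id]]
        nbm <- if (length(nb)) mean(z[nb]) else 0
        rho * nbm + (1 - rho) * z[[id]]
      }, numeric(1))
      s <- stats::sd(zm)
      if (sigma_u == 0 || !is.finite(s) || s == 0) zm[] <- 0
      else zm <- zm * sigma_u / s
      zm
    })
  }
  out <- list()
  for (oc in names(params$outcomes)) {
    su <- if (!is.null(params$outcomes[[oc]]$sigma_u))
      params$outcomes[[oc]]$sigma_u else params$sigma_u
    rh <- if (!is.null(params$outcomes[[oc]]$rho))
      params$outcomes[[oc]]$rho else params$rho
    out[[oc]] <- list(u = draw_u(su, rh, child_seed(seed, "u", oc)))
  }
  structure(list(params = params, county_ids = ids, years = years,
                 ref_year = mean(years), effects = out, seed = seed),
            class = "truth_surface")
}

#' True prevalence for given cells
#'
#' Evaluates the generative logit surface of one outcome at the requested
#' county/year/sex/age/race cells.
#'
#' @param truth a [simulate_truth()] surface.
#' @param counties the [county_table()] the surface was built on.
#' @param newdata `data.frame` with columns `county_id`, `year`, `sex`,
#'   `age_group`, `race`.
#' @param outcome one of [outcome_names].
#' @return Numeric vector of probabilities strictly inside (0, 1).
#' @export
true_prevalence <- function(truth, counties, newdata, outcome = "obesity") {
  outcome <- match.arg(outcome, outcome_names)
  stopifnot(inherits(truth, "truth_surface"))
  need <- c("county_id", "year", "sex", "age_group", "race")
  miss <- setdiff(need, names(newdata))
  if (length(miss)) stop("newdata missing column(s): ",
                         paste(miss, collapse = ", "))
  p <- truth$params
  g <- function(nm) truth_param(truth, outcome, nm)
  eta <- g("intercept") +
    g("sex_effect")[as.character(newdata$sex)] +
    g("age_effects")[as.character(newdata$age_group)] +
    g("race_effects")[as.character(newdata$race)] +
    g("time_slope") * (newdata$year - truth$ref_year) +
    truth$effects[[outcome]]$u[as.character(newdata$county_id)]
  coefs <- g("covariate_coefs")
  if (length(coefs)) {
    ctr <- g("covariate_centers")
    cv <- counties$covariates
    key <- paste(cv$county_id, cv$year)
    rows <- match(paste(newdata$county_id, newdata$year), key)
    if (anyNA(rows)) stop("covariates missing for some county/year cells")
    for (v in names(coefs))
      eta <- eta + coefs[[v]] * (cv[[v]][rows] - ctr[[v]])
  }
  as.numeric(stats::plogis(eta))
}

# E[BMI | obese] and E[BMI | not obese] under the two-sided log-folded-normal
# model BMI = 30 * exp(+/- s|Z|): E[exp(a|Z|)] = 2 exp(a^2/2) Phi(a)
bmi_conditional_means <- function(bmi_log_sd) {
  s <- bmi_log_sd
  c(obese = 30 * 2 * exp(s^2 / 2) * stats::pnorm(s),
    non_obese = 30 * 2 * exp(s^2 / 2) * stats::pnorm(-s))
}

#' Default respondent age and sex distribution
#'
#' Marginal sampling distribution of survey respondents over the six adult
#' age groups (near-uniform with thinner older tails) and the two sexes.
#' @return list with components `age` and `sex` (named probability vectors).
#' @export
default_age_sex_distribution <- function() {
  list(age = c("20-34" = 0.24, "35-44" = 0.19, "45-54" = 0.18,
               "55-64" = 0.16, "65-74" = 0.13, "75+" = 0.10),
       sex = c(male = 0.5, female = 0.5))
}

#' Simulate survey microdata from a truth surface
#'
#' Draws respondents county-by-county and year-by-year: demographics from the
#' county race composition and the age/sex marginals, binary outcomes as
#' Bernoulli draws from the true prevalence, true height from a sex-specific
#' log-normal and true BMI from a two-sided log-normal around 30 kg/m^2
#' conditional on the drawn obesity status. Self-report distortion is affine
#' in weight (`weight_scale`, `weight_shift`) and additive in height
#' (`height_shift`), each with optional Gaussian noise. Weekly activity
#' minutes are generated consistently with the drawn sufficiency outcome, and
#' the detailed minutes are blanked in even survey years before 2011,
#' mirroring the odd-year-only detailed questionnaire.
#'
#' @param truth a [simulate_truth()] surface.
#' @param counties the populated [county_table()].
#' @param n_per_county_year respondents per county per year; a scalar or a
#'   vector named by county id.
#' @param reporting_bias list with `weight_scale`, `weight_shift` (kg),
#'   `height_shift` (m), `weight_noise_sd`, `height_noise_sd`.
#' @param seed integer seed.
#' @param age_sex list as from [default_age_sex_distribution()].
#' @param odd_year_detail if `TRUE` (default), minutes are missing in even
#'   years before 2011.
#' @param keep_truth keep hidden truth columns (`true_bmi`, `true_obese`,
#'   `true_any`, `true_sufficient`) for testing and validation.
#' @return A `data.frame` of individual records (one row per respondent).
#' @export
simulate_survey <- function(truth, counties, n_per_county_year,
                            reporting_bias = list(weight_scale = 1,
                                                  weight_shift = 0,
                                                  height_shift = 0,
                                                  weight_noise_sd = 0,
                                                  height_noise_sd = 0),
                            seed = 1L,
                            age_sex = default_age_sex_distribution(),
                            odd_year_detail = TRUE, keep_truth = TRUE) {
  stopifnot(inherits(truth, "truth_surface"))
  rb <- utils::modifyList(list(weight_scale = 1, weight_shift = 0,
                               height_shift = 0, weight_noise_sd = 0,
                               height_noise_sd = 0), as.list(reporting_bias))
  ids <- counties$county_ids
  npc <- if (length(n_per_county_year) == 1L)
    stats::setNames(rep(as.integer(n_per_county_year), length(ids)), ids)
  else {
    if (!all(ids %in% names(n_per_county_year)))
      stop("'n_per_county_year' must name every county")
    stats::setNames(as.integer(n_per_county_year[ids]), ids)
  }
  if (any(npc < 0)) stop("'n_per_county_year' must be >= 0")
  counts <- expand.grid(county_id = ids, year = truth$years,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  counts$n <- as.integer(npc[counts$county_id])
  N <- sum(counts$n)
  if (N == 0L)
    return(empty_microdata(keep_truth))
  shares <- race_share_matrix(counties)
  with_seed(child_seed(seed, "survey"), {
    d <- data.frame(
      county_id = rep(counts$county_id, counts$n),
      year = rep(counts$year, counts$n), stringsAsFactors = FALSE)
    d$sex <- sample(sexes, N, replace = TRUE, prob = age_sex$sex[sexes])
    d$age_group <- sample(age_groups, N, replace = TRUE,
                          prob = age_sex$age[age_groups])
    ci <- match(d$county_id, ids)
    u <- stats::runif(N)
    cum <- t(apply(shares, 1, cumsum))
    d$race <- race_groups[max.col(cum[ci, , drop = FALSE] >= u,
                                  ties.method = "first")]
    p_ob <- true_prevalence(truth, counties, d, "obesity")
    p_any <- true_prevalence(truth, counties, d, "any_pa")
    p_suf <- true_prevalence(truth, counties, d, "sufficient_pa")
    d$true_obese <- stats::rbinom(N, 1L, p_ob) == 1L
    d$true_any <- stats::rbinom(N, 1L, p_any) == 1L
    d$true_sufficient <- stats::rbinom(N, 1L, p_suf) == 1L
    # anthropometrics
    s <- truth$params$bmi_log_sd
    z <- abs(stats::rnorm(N))
    d$true_bmi <- 30 * exp(ifelse(d$true_obese, s, -s) * z)
    mh <- ifelse(d$sex == "male", log(1.76), log(1.62))
    true_height <- exp(stats::rnorm(N, mh, 0.04))
    true_weight <- d$true_bmi * true_height^2
    d$reported_weight <- rb$weight_scale * true_weight + rb$weight_shift +
      (if (rb$weight_noise_sd > 0) stats::rnorm(N, 0, rb$weight_noise_sd)
       else 0)
    d$reported_height <- true_height + rb$height_shift +
      (if (rb$height_noise_sd > 0) stats::rnorm(N, 0, rb$height_noise_sd)
       else 0)
    # activity responses
    d$any_pa <- ifelse(d$true_any, "yes", "no")
    me <- ifelse(d$true_sufficient,
                 150 + stats::rexp(N, rate = 1 / 90),
                 stats::runif(N, 0, 150))
    f <- stats::runif(N, 0, 0.6)
    vig <- me * f / 2
    mod <- me - 2 * vig  # exact reconstruction: mod + 2*vig == me bit-for-bit
    d$moderate_min_week <- mod
    d$vigorous_min_week <- vig
    if (odd_year_detail) {
      blank <- d$year %% 2 == 0 & d$year < 2011
      d$moderate_min_week[blank] <- NA_real_
      d$vigorous_min_week[blank] <- NA_real_
    }
    if (!keep_truth)
      d <- d[, setdiff(names(d), c("true_bmi", "true_obese", "true_any",
                                   "true_sufficient"))]
    rownames(d) <- NULL
    d[, microdata_columns(keep_truth)]
  })
}

microdata_columns <- function(keep_truth = FALSE) {
  base <- c("year", "county_id", "sex", "age_group", "race",
            "reported_weight", "reported_height", "any_pa",
            "moderate_min_week", "vigorous_min_week")
  if (keep_truth) c(base, "true_bmi", "true_obese", "true_any",
                    "true_sufficient") else base
}

empty_microdata <- function(keep_truth = FALSE) {
  cols <- microdata_columns(keep_truth)
  d <- data.frame(year = integer(0), county_id = character(0),
                  sex = character(0), age_group = character(0),
                  race = character(0), reported_weight = numeric(0),
                  reported_height = numeric(0), any_pa = character(0),
                  moderate_min_week = numeric(0),
                  vigorous_min_week = numeric(0))
  if (keep_truth) {
    d$true_bmi <- numeric(0); d$true_obese <- logical(0)
    d$true_any <- logical(0); d$true_sufficient <- logical(0)
  }
  d[, cols]
}

#' Simulate examination-survey BMI cell means
#'
#' Produces measured (undistorted) mean BMI by two-year cycle, sex, and age
#' group — the synthetic counterpart of an examination survey used as the
#' reference for self-report calibration. With `exact = TRUE` the closed-form
#' population cell means are returned (no sampling noise); otherwise
#' `n_per_cell` examinees are drawn per cell (county by population share,
#' race by county composition, year uniform within the cycle) and their mean
#' BMI reported.
#'
#' @param truth a [simulate_truth()] surface.
#' @param counties the populated [county_table()].
#' @param cycles list of length-2 integer vectors `c(start, end)` with
#'   `end == start + 1`, e.g. `list(c(2001, 2002))`.
#' @param n_per_cell examinees per cycle x sex x age cell (ignored when
#'   `exact = TRUE`).
#' @param seed integer seed.
#' @param exact return noiseless population cell means.
#' @return `data.frame` with columns `cycle_start`, `cycle_end`, `sex`,
#'   `age_group`, `n`, `mean_bmi`.
#' @export
simulate_examination_cells <- function(truth, counties, cycles,
                                       n_per_cell = 500L, seed = 1L,
                                       exact = FALSE) {
  if (length(cycles) == 0) stop("'cycles' must be non-empty")
  for (cy in cycles)
    if (length(cy) != 2L || cy[2] != cy[1] + 1)
      stop("each cycle must be a two-year span c(start, start + 1)")
  shares <- race_share_matrix(counties)
  wc <- county_total_population(counties)
  wc <- wc / sum(wc)
  ids <- counties$county_ids
  m <- bmi_conditional_means(truth$params$bmi_log_sd)
  cells <- expand.grid(sex = sexes, age_group = age_groups,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  one_cycle <- function(cy, sub) {
    yrs <- cy[1]:cy[2]
    if (exact) {
      grid <- expand.grid(county_id = ids, race = race_groups, year = yrs,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      w <- wc[match(grid$county_id, ids)] *
        shares[cbind(match(grid$county_id, ids),
                     match(grid$race, race_groups))] / length(yrs)
      mb <- vapply(seq_len(nrow(cells)), function(i) {
        grid$sex <- cells$sex[i]; grid$age_group <- cells$age_group[i]
        p <- true_prevalence(truth, counties, grid, "obesity")
        sum(w * (p * m[["obese"]] + (1 - p) * m[["non_obese"]]))
      }, numeric(1))
      data.frame(cycle_start = cy[1], cycle_end = cy[2], cells,
                 n = NA_integer_, mean_bmi = mb)
    } else {
      with_seed(sub, {
        mb <- numeric(nrow(cells)); nn <- integer(nrow(cells))
        for (i in seq_len(nrow(cells))) {
          g <- data.frame(
            county_id = sample(ids, n_per_cell, replace = TRUE, prob = wc),
            year = sample(yrs, n_per_cell, replace = TRUE),
            sex = cells$sex[i], age_group = cells$age_group[i],
            stringsAsFactors = FALSE)
          ci <- match(g$county_id, ids)
          u <- stats::runif(n_per_cell)
          cum <- t(apply(shares, 1, cumsum))
          g$race <- race_groups[max.col(cum[ci, , drop = FALSE] >= u,
                                        ties.method = "first")]
          p <- true_prevalence(truth, counties, g, "obesity")
          ob <- stats::rbinom(n_per_cell, 1L, p) == 1L
          s <- truth$params$bmi_log_sd
          bmi <- 30 * exp(ifelse(ob, s, -s) * abs(stats::rnorm(n_per_cell)))
          mb[i] <- mean(bmi); nn[i] <- n_per_cell
        }
        data.frame(cycle_start = cy[1], cycle_end = cy[2], cells,
                   n = nn, mean_bmi = mb)
      })
    }
  }
  res <- do.call(rbind, lapply(seq_along(cycles), function(k)
    one_cycle(cycles[[k]], child_seed(seed, "exam", k))))
  rownames(res) <- NULL
  res
}

#' Moran's I spatial autocorrelation of county values
#'
#' Direct-summation Moran's I under binary rook adjacency weights, used to
#' check that the generator's spatial mixing produces positively correlated
#' county effects.
#'
#' @param x numeric vector named by county id (or in county-table order).
#' @param counties a [county_table()].
#' @return Moran's I statistic.
#' @export
morans_i <- function(x, counties) {
  ids <- counties$county_ids
  if (!is.null(names(x))) x <- x[ids]
  stopifnot(length(x) == length(ids))
  xc <- x - mean(x)
  num <- 0; W <- 0
  for (i in seq_along(ids)) {
    nb <- match(counties$neighbors[[ids[i]]], ids)
    num <- num + sum(xc[i] * xc[nb])
    W <- W + length(nb)
  }
  (length(x) / W) * num / sum(xc^2)
}
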