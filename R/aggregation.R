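#' Standard population for direct age standardization
#'
#' @param weights named non-negative weights over age groups, summing to 1
#'   (within 1e-9).
#' @return Object of class `standard_population`.
#' @export
standard_population <- function(weights) {
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("'weights' must be named by age group")
  if (any(weights < 0)) stop("standard-population weights must be >= 0")
  if (abs(sum(weights) - 1) > 1e-9)
    stop("standard-population weights must sum to 1")
  structure(list(weights = weights), class = "standard_population")
}

#' The 2000 US census adult age standard
#'
#' Age weights for adults 20 and older over the package's six age groups,
#' derived (approximately) from the 2000 US census population, shipped as a
#' plain-text asset. Supply your own [standard_population()] where exact
#' census weights are required.
#'
#' @return A [standard_population()].
#' @export
age_standard_2000 <- function() {
  path <- system.file("extdata", "age_standard_2000.csv",
                      package = "countyprev", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  w <- stats::setNames(d$weight, d$age_group)[age_groups]
  standard_population(w / sum(w))
}

#' Population-weighted all-race prevalence
#'
#' Collapses race-specific predictions for one county/year/sex/age cell to
#' an all-race value, weighting by the county's race-specific populations.
#'
#' @param predictions numeric vector (or matrix with rows) named by race.
#' @param populations non-negative person counts named by the same races.
#' @return The weighted average (convex combination).
#' @export
aggregate_race <- function(predictions, populations) {
  pn <- if (is.matrix(predictions)) rownames(predictions)
        else names(predictions)
  if (!setequal(pn, names(populations)))
    stop("race sets of predictions and populations differ")
  populations <- populations[pn]
  if (any(populations < 0)) stop("populations must be >= 0")
  tot <- sum(populations)
  if (tot <= 0) stop("total population must be > 0")
  w <- populations / tot
  if (is.matrix(predictions)) as.numeric(w %*% predictions)
  else sum(w * predictions)
}

#' Direct age standardization
#'
#' Weighted average of age-specific prevalences with fixed standard-
#' population weights.
#'
#' @param predictions numeric vector (or matrix with rows) named by age
#'   group, covering every group in the standard.
#' @param standard a [standard_population()].
#' @return The standardized prevalence.
#' @export
age_standardize <- function(predictions, standard) {
  stopifnot(inherits(standard, "standard_population"))
  w <- standard$weights
  pn <- if (is.matrix(predictions)) rownames(predictions)
        else names(predictions)
  miss <- setdiff(names(w), pn)
  if (length(miss))
    stop("predictions missing age group(s): ", paste(miss, collapse = ", "))
  if (is.matrix(predictions))
    as.numeric(w %*% predictions[names(w), , drop = FALSE])
  else sum(w * predictions[names(w)])
}

# draws of (beta, u) from the Gaussian approximation stored in a fit;
# a non-positive-definite covariance is repaired by eigenvalue flooring
draw_parameters <- function(fit, n_draws, seed, repair = TRUE) {
  stopifnot(inherits(fit, "sae_fit"), n_draws >= 2)
  V <- (fit$vcov + t(fit$vcov)) / 2
  ev <- eigen(V, symmetric = TRUE)
  if (min(ev$values) < 0) {
    if (!repair) stop("fixed-effect covariance is not positive definite")
    warning("covariance repaired by eigenvalue flooring")
    ev$values <- pmax(ev$values, 0)
    V <- ev$vectors %*% diag(ev$values, nrow = length(ev$values)) %*%
      t(ev$vectors)
  }
  with_seed(seed, {
    beta <- MASS::mvrnorm(n_draws, mu = fit$coefficients, Sigma = V)
    if (n_draws == 1L) beta <- matrix(beta, nrow = 1)
    colnames(beta) <- names(fit$coefficients)
    C <- length(fit$u)
    u <- matrix(stats::rnorm(n_draws * C), n_draws, C)
    u <- sweep(u, 2, sqrt(pmax(fit$u_var, 0)), `*`)
    u <- sweep(u, 2, fit$u, `+`)
    colnames(u) <- names(fit$u)
    list(beta = beta, u = u)
  })
}

# sparse aggregation operator mapping county x year x sex x age x race cells
# to county x year targets: race poststratification times age standardization
aggregation_matrix <- function(grid, counties, standard) {
  shares <- race_share_matrix(counties)
  key <- paste(grid$county_id, grid$year)
  targets <- unique(key)
  w_age <- standard$weights[as.character(grid$age_group)]
  w_race <- shares[cbind(match(grid$county_id, rownames(shares)),
                         match(grid$race, colnames(shares)))]
  A <- matrix(0, length(targets), nrow(grid),
              dimnames = list(targets, NULL))
  A[cbind(match(key, targets), seq_len(nrow(grid)))] <- w_age * w_race
  A
}

#' Simulated uncertainty for poststratified, age-standardized estimates
#'
#' Draws fixed-effect vectors and county effects from the fit's Gaussian
#' approximation, pushes every draw through cell prediction, race
#' poststratification and direct age standardization, and summarizes each
#' county/year with the draw mean and the 2.5th/97.5th percentile interval.
#' The same draw indices are shared across counties and years, so draw-wise
#' differences carry the right correlation.
#'
#' @param fit an `sae_fit`.
#' @param counties the populated [county_table()].
#' @param years years to predict (within the fit's window).
#' @param standard a [standard_population()].
#' @param n_draws number of simulation draws (>= 2).
#' @param seed integer seed.
#' @param level interval coverage (default 0.95).
#' @param repair repair a non-positive-definite covariance by eigenvalue
#'   flooring instead of erroring.
#' @return list with `estimates` (`data.frame`: county_id, year, sex,
#'   outcome, point, mean, lower, upper, n_draws) and `draws` (matrix,
#'   one row per estimate row).
#' @export
simulate_uncertainty <- function(fit, counties, years, standard,
                                 n_draws = 1000L, seed = 1L, level = 0.95,
                                 repair = TRUE) {
  stopifnot(inherits(fit, "sae_fit"))
  years <- as.integer(years)
  if (!all(years %in% fit$window))
    stop("requested year(s) outside the fit's window")
  grid <- expand.grid(race = race_groups, age_group = age_groups,
                      year = years, county_id = counties$county_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  X <- cell_model_matrix(fit, grid, counties)
  uc <- match(grid$county_id, names(fit$u))
  point_cells <- stats::plogis(as.numeric(X %*% fit$coefficients) +
                                 fit$u[uc])
  A <- aggregation_matrix(grid, counties, standard)
  draws <- draw_parameters(fit, n_draws, seed, repair)
  P <- stats::plogis(X %*% t(draws$beta) + t(draws$u[, uc, drop = FALSE]))
  agg_draws <- A %*% P
  point <- as.numeric(A %*% point_cells)
  alpha <- (1 - level) / 2
  qs <- t(apply(agg_draws, 1, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE))
  tk <- strsplit(rownames(A), " ")
  est <- data.frame(
    county_id = vapply(tk, `[`, character(1), 1),
    year = as.integer(vapply(tk, `[`, character(1), 2)),
    sex = fit$spec$sex, outcome = fit$spec$outcome,
    point = point, mean = as.numeric(rowMeans(agg_draws)),
    lower = qs[, 1], upper = qs[, 2], n_draws = as.integer(n_draws),
    stringsAsFactors = FALSE)
  rownames(est) <- NULL
  list(estimates = est, draws = unname(as.matrix(agg_draws)))
}

#' End-to-end prevalence estimation on moving windows
#'
#' Fits the chosen model variant per sex on every five-year window needed to
#' cover the requested output years, simulates draws of the poststratified
#' age-standardized county prevalence for each window, and averages across
#' overlapping windows (point estimates and draws alike, draw-wise) to give
#' one estimate with a 95% percentile interval per county, year, and sex.
#'
#' @param records microdata with outcome columns (see [add_outcomes()]).
#' @param counties populated [county_table()].
#' @param outcome one of [outcome_names].
#' @param sexes sexes to estimate (default both).
#' @param variant one of [model_variants] (default `"full"`).
#' @param years year range fitted (default: range observed in records).
#' @param years_out years to report (default: all fitted years).
#' @param window_width moving-window width (default 5).
#' @param n_draws simulation draws per window.
#' @param seed integer master seed.
#' @param standard a [standard_population()] (default the shipped 2000 US
#'   standard).
#' @param control a [fit_control()].
#' @return Object of class `prevalence_estimates`: list with `estimates`
#'   (`data.frame`) and `draws` (matrix aligned with its rows).
#' @export
estimate_prevalence <- function(records, counties, outcome,
                                sexes = c("male", "female"),
                                variant = "full", years = NULL,
                                years_out = NULL, window_width = 5L,
                                n_draws = 1000L, seed = 1L,
                                standard = age_standard_2000(),
                                control = fit_control()) {
  outcome <- match.arg(outcome, outcome_names)
  variant <- match.arg(variant, model_variants)
  if (is.null(years)) years <- range(records$year)
  wins <- sliding_windows(years[1], years[2], window_width)
  if (is.null(years_out)) years_out <- years[1]:years[2]
  years_out <- sort(as.integer(years_out))
  needed <- which(vapply(wins, function(w) any(years_out %in% w),
                         logical(1)))
  est_all <- NULL; draws_all <- NULL
  for (sx in sexes) {
    fits <- list(); res <- list()
    for (k in needed) {
      spec <- model_spec(variant, outcome, sx, wins[[k]])
      fit <- fit_variant(records, counties, spec, control)
      yrs <- intersect(wins[[k]], years_out)
      res[[as.character(k)]] <- simulate_uncertainty(
        fit, counties, yrs, standard, n_draws,
        seed = child_seed(seed, "draws", sx, wins[[k]][1]))
      fits[[as.character(k)]] <- fit
    }
    for (y in years_out) {
      cov_w <- needed[vapply(wins[needed], function(w) y %in% w,
                             logical(1))]
      pts <- lapply(as.character(cov_w), function(k) {
        r <- res[[k]]; i <- r$estimates$year == y
        list(point = r$estimates$point[i], mean_draws = r$draws[i, ,
                                                               drop = FALSE],
             county = r$estimates$county_id[i])
      })
      ids <- pts[[1]]$county
      point <- Reduce(`+`, lapply(pts, `[[`, "point")) / length(pts)
      dr <- Reduce(`+`, lapply(pts, `[[`, "mean_draws")) / length(pts)
      qs <- t(apply(dr, 1, stats::quantile, probs = c(0.025, 0.975),
                    names = FALSE))
      est_all <- rbind(est_all, data.frame(
        county_id = ids, year = y, sex = sx, outcome = outcome,
        point = point, mean = rowMeans(dr), lower = qs[, 1], upper = qs[, 2],
        n_draws = as.integer(n_draws), stringsAsFactors = FALSE))
      draws_all <- rbind(draws_all, dr)
    }
  }
  rownames(est_all) <- NULL
  structure(list(estimates = est_all, draws = draws_all, outcome = outcome,
                 variant = variant, n_draws = n_draws, seed = seed),
            class = "prevalence_estimates")
}

#' @export
print.prevalence_estimates <- function(x, ...) {
  cat(sprintf("prevalence_estimates: %s (%s variant), %d county-year-sex rows, %d draws\n",
              x$outcome, x$variant, nrow(x$estimates), x$n_draws))
  print(utils::head(x$estimates))
  invisible(x)
}
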