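#' Percentage-point change between two prevalence estimates
#'
#' Point change is simply `est_end - est_start` on the percent scale. When
#' index-aligned simulation draws for both years are supplied, the interval
#' is the percentile interval of the draw-wise differences, so correlated
#' uncertainty between years propagates.
#'
#' @param est_start,est_end prevalence on the percent scale.
#' @param draws_start,draws_end optional equal-length draw vectors on the
#'   percent scale, aligned by draw index.
#' @param level interval coverage (default 0.95).
#' @return list with `pp_change` and, when draws are given, `lower` and
#'   `upper`.
#' @examples
#' pp_change(25.7, 44.0)$pp_change  # 18.3
#' @export
pp_change <- function(est_start, est_end, draws_start = NULL,
                      draws_end = NULL, level = 0.95) {
  out <- list(pp_change = est_end - est_start)
  if (!is.null(draws_start) || !is.null(draws_end)) {
    if (is.null(draws_start) || is.null(draws_end) ||
        length(draws_start) != length(draws_end))
      stop("draws must be supplied for both years with equal length")
    d <- draws_end - draws_start
    alpha <- (1 - level) / 2
    q <- stats::quantile(d, probs = c(alpha, 1 - alpha), names = FALSE)
    out$lower <- q[1]; out$upper <- q[2]
  }
  out
}

#' County-level percentage-point changes from a pipeline estimate
#'
#' Computes, per county and sex, the change in prevalence (percentage
#' points) between two years of an [estimate_prevalence()] result, with
#' draw-wise percentile intervals and the baseline prevalence.
#'
#' @param est a `prevalence_estimates` object.
#' @param year_start,year_end years compared (defaults 2001 and 2009).
#' @param level interval coverage.
#' @return `data.frame`: county_id, sex, outcome, baseline, pp_change,
#'   lower, upper.
#' @export
compute_changes <- function(est, year_start = 2001L, year_end = 2009L,
                            level = 0.95) {
  stopifnot(inherits(est, "prevalence_estimates"))
  e <- est$estimates
  out <- NULL
  for (sx in unique(e$sex)) {
    i0 <- which(e$sex == sx & e$year == year_start)
    i1 <- which(e$sex == sx & e$year == year_end)
    if (!length(i0) || !length(i1))
      stop("estimates do not cover years ", year_start, " and ", year_end)
    i1 <- i1[match(e$county_id[i0], e$county_id[i1])]
    ch <- lapply(seq_along(i0), function(k)
      pp_change(100 * e$mean[i0[k]], 100 * e$mean[i1[k]],
                100 * est$draws[i0[k], ], 100 * est$draws[i1[k], ], level))
    out <- rbind(out, data.frame(
      county_id = e$county_id[i0], sex = sx, outcome = est$outcome,
      baseline = 100 * e$mean[i0],
      pp_change = vapply(ch, `[[`, numeric(1), "pp_change"),
      lower = vapply(ch, `[[`, numeric(1), "lower"),
      upper = vapply(ch, `[[`, numeric(1), "upper"),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Assemble the county change table for the ecological regression
#'
#' Merges obesity and physical-activity changes per county (and sex) with
#' the county covariate changes the regression controls for: percent rural
#' at the end year, changes in poverty, unemployment, and doctors per
#' 100,000, and baseline obesity.
#'
#' @param obesity_changes,pa_changes outputs of [compute_changes()].
#' @param counties populated [county_table()].
#' @param year_start,year_end years the changes span.
#' @return `data.frame` with one row per county x sex.
#' @export
build_change_table <- function(obesity_changes, pa_changes, counties,
                               year_start = 2001L, year_end = 2009L) {
  m <- merge(obesity_changes[, c("county_id", "sex", "pp_change",
                                 "baseline")],
             pa_changes[, c("county_id", "sex", "pp_change")],
             by = c("county_id", "sex"),
             suffixes = c("_obesity", "_pa"))
  cv <- counties$covariates
  c0 <- cv[cv$year == year_start, ]; c1 <- cv[cv$year == year_end, ]
  i0 <- match(m$county_id, c0$county_id)
  i1 <- match(m$county_id, c1$county_id)
  if (anyNA(i0) || anyNA(i1))
    stop("county covariates missing for years ", year_start, " or ",
         year_end)
  data.frame(
    county_id = m$county_id, sex = m$sex,
    change_obesity = m$pp_change_obesity,
    change_pa = m$pp_change_pa,
    pct_rural = 100 * c1$pct_rural[i1],
    change_poverty = 100 * (c1$poverty[i1] - c0$poverty[i0]),
    change_unemployment = 100 * (c1$unemployment[i1] -
                                   c0$unemployment[i0]),
    change_docs = c1$docs_per_100k[i1] - c0$docs_per_100k[i0],
    baseline_obesity = m$baseline_obesity,
    stringsAsFactors = FALSE)
}

#' Ecological regression of change in obesity on change in physical activity
#'
#' Unweighted ordinary least squares across counties of the change in
#' obesity prevalence (percentage points) on the change in sufficient
#' physical activity, controlling for percent rural, changes in poverty,
#' unemployment, and doctors per 100,000 population, and baseline obesity.
#'
#' @param changes `data.frame` as from [build_change_table()]; regressor
#'   columns other than the defaults may be supplied through `regressors`.
#' @param regressors character vector of regressor column names.
#' @return Object of class `eco_regression`: a coefficient table with
#'   estimates and conventional standard errors, plus the `lm` fit.
#' @export
ecological_regression <- function(changes,
                                  regressors = c("change_pa", "pct_rural",
                                                 "change_poverty",
                                                 "change_unemployment",
                                                 "change_docs",
                                                 "baseline_obesity")) {
  miss <- setdiff(c("change_obesity", regressors), names(changes))
  if (length(miss)) stop("change table missing column(s): ",
                         paste(miss, collapse = ", "))
  d <- changes[stats::complete.cases(changes[, c("change_obesity",
                                                 regressors)]), ,
               drop = FALSE]
  if (nrow(d) <= length(regressors) + 1L)
    stop("more regressors than counties with complete cases")
  X <- as.matrix(cbind(`(Intercept)` = 1, d[, regressors, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("collinear regressors: ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
               collapse = ", "))
  fit <- stats::lm(stats::reformulate(if (length(regressors)) regressors
                                      else "1", "change_obesity"),
                   data = d)
  sm <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, fit = fit, n = nrow(d)),
            class = "eco_regression")
}

#' @export
print.eco_regression <- function(x, ...) {
  cat("Ecological regression of change in obesity (n =", x$n, "counties)\n")
  print(x$table, digits = 4)
  invisible(x)
}
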