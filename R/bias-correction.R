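#' Body mass index from weight and height
#'
#' @param weight weight in kg (vectorized).
#' @param height height in m.
#' @return BMI in kg/m^2. Non-positive weight or height is an error; `NA`
#'   inputs propagate to `NA` outputs.
#' @examples
#' compute_bmi(90, 1.5)   # 40
#' @export
compute_bmi <- function(weight, height) {
  if (length(weight) != length(height) && length(weight) != 1L &&
      length(height) != 1L)
    stop("'weight' and 'height' lengths are incompatible")
  bad_w <- !is.na(weight) & weight <= 0
  bad_h <- !is.na(height) & height <= 0
  if (any(bad_w)) stop("'weight' must be > 0")
  if (any(bad_h)) stop("'height' must be > 0")
  weight / height^2
}

#' Mean reported BMI by sex and age group within a two-year cycle
#'
#' Pools the survey records falling in one two-year cycle and returns the
#' arithmetic mean BMI per sex x age-group cell. Records with missing weight
#' or height are dropped; cells with no records are absent from the result.
#'
#' @param records microdata `data.frame` (see [simulate_survey()]).
#' @param cycle length-2 integer vector `c(start, end)`, `end == start + 1`.
#' @param value `"reported"` uses reported weight/height; `"true"` uses the
#'   generator's hidden `true_bmi` column (noiseless measured reference for
#'   synthetic studies).
#' @return `data.frame` with columns `cycle_start`, `cycle_end`, `sex`,
#'   `age_group`, `n`, `mean_bmi`; zero rows if the cycle has no records.
#' @export
cell_means <- function(records, cycle, value = c("reported", "true")) {
  value <- match.arg(value)
  if (length(cycle) != 2L || cycle[2] != cycle[1] + 1)
    stop("'cycle' must be a two-year span c(start, start + 1)")
  d <- records[records$year >= cycle[1] & records$year <= cycle[2], ,
               drop = FALSE]
  bmi <- if (value == "reported")
    compute_bmi(d$reported_weight, d$reported_height)
  else {
    if (is.null(d$true_bmi)) stop("records carry no 'true_bmi' column")
    d$true_bmi
  }
  keep <- !is.na(bmi) & !is.na(d$sex) & !is.na(d$age_group)
  d <- d[keep, , drop = FALSE]; bmi <- bmi[keep]
  if (nrow(d) == 0L)
    return(data.frame(cycle_start = integer(0), cycle_end = integer(0),
                      sex = character(0), age_group = character(0),
                      n = integer(0), mean_bmi = numeric(0)))
  key <- interaction(d$sex, d$age_group, drop = TRUE)
  mb <- tapply(bmi, key, mean)
  nn <- tapply(bmi, key, length)
  parts <- do.call(rbind, strsplit(names(mb), ".", fixed = TRUE))
  out <- data.frame(cycle_start = cycle[1], cycle_end = cycle[2],
                    sex = parts[, 1], age_group = parts[, 2],
                    n = as.integer(nn), mean_bmi = as.numeric(mb))
  out <- out[order(out$sex, match(out$age_group, age_groups)), ]
  rownames(out) <- NULL
  out
}

#' Fit the per-sex linear self-report calibration
#'
#' Ordinary least squares of measured mean BMI on reported mean BMI over all
#' matched (cycle x age-group) cells, fitted separately for males and
#' females. Cells are matched on the exact two-year span, sex, and age group;
#' unmatched cells are dropped. By default the regression is unweighted; set
#' `weight_by_n = TRUE` to weight cells by the measured cell count.
#'
#' @param reported_cells cell means of reported BMI (from [cell_means()] or
#'   stacked over cycles), with columns `cycle_start`, `cycle_end`, `sex`,
#'   `age_group`, `mean_bmi` (and `n` if weighting).
#' @param measured_cells cell means of measured BMI with the same columns
#'   (e.g. from [simulate_examination_cells()]).
#' @param weight_by_n weight cells by measured `n`.
#' @return A `calibration_model`: per-sex `intercept` (kg/m^2) and `slope`,
#'   plus the matched cells used.
#' @export
fit_calibration <- function(reported_cells, measured_cells,
                            weight_by_n = FALSE) {
  key <- c("cycle_start", "cycle_end", "sex", "age_group")
  m <- merge(reported_cells[, c(key, "mean_bmi")],
             measured_cells[, c(key, "mean_bmi",
                                intersect("n", names(measured_cells)))],
             by = key, suffixes = c("_reported", "_measured"))
  coefs <- list()
  for (sx in sexes) {
    d <- m[m$sex == sx, , drop = FALSE]
    if (nrow(d) < 2L)
      stop("degenerate calibration fit for sex '", sx,
           "': fewer than 2 matched cells")
    x <- d$mean_bmi_reported; y <- d$mean_bmi_measured
    if (stats::var(x) == 0)
      stop("degenerate calibration fit for sex '", sx,
           "': zero variance in reported cell means")
    w <- if (weight_by_n) d$n else NULL
    fit <- stats::lm.wfit(cbind(1, x), y,
                          w = if (is.null(w)) rep(1, length(y)) else w)
    coefs[[sx]] <- list(intercept = unname(fit$coefficients[1]),
                        slope = unname(fit$coefficients[2]))
  }
  structure(list(coefficients = coefs, cells = m,
                 weighted = weight_by_n), class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("BMI self-report calibration (measured ~ reported, per sex)\n")
  for (sx in names(x$coefficients))
    cat(sprintf("  %-6s intercept % .4f  slope % .4f\n", sx,
                x$coefficients[[sx]]$intercept, x$coefficients[[sx]]$slope))
  cat("  fitted on", nrow(x$cells), "matched cells",
      if (x$weighted) "(n-weighted)\n" else "(unweighted)\n")
  invisible(x)
}

#' Corrected BMI for a given sex and reported BMI
#'
#' @param model a [fit_calibration()] model.
#' @param sex vector over [sexes].
#' @param reported_bmi numeric vector.
#' @return `intercept + slope * reported_bmi`, using the sex-specific fit.
#' @export
calibrate_bmi <- function(model, sex, reported_bmi) {
  stopifnot(inherits(model, "calibration_model"))
  bad <- !is.na(sex) & !(sex %in% names(model$coefficients))
  if (any(bad)) stop("no calibration fitted for sex '",
                     sex[bad][1], "'")
  a <- vapply(model$coefficients, `[[`, numeric(1), "intercept")[sex]
  b <- vapply(model$coefficients, `[[`, numeric(1), "slope")[sex]
  as.numeric(a + b * reported_bmi)
}

#' Apply the calibration to survey records
#'
#' Computes reported BMI from reported weight and height and maps it through
#' the sex-specific calibration line. Records with missing anthropometrics
#' get `NA` (flagged missing-outcome and excluded downstream), not an error.
#'
#' @inheritParams calibrate_bmi
#' @param records microdata `data.frame`.
#' @return Numeric vector of corrected BMI, one per record.
#' @export
apply_calibration <- function(model, records) {
  rb <- compute_bmi(records$reported_weight, records$reported_height)
  out <- rep(NA_real_, nrow(records))
  ok <- !is.na(rb) & !is.na(records$sex)
  out[ok] <- calibrate_bmi(model, records$sex[ok], rb[ok])
  out
}

#' Obesity classification
#'
#' @param bmi numeric BMI vector.
#' @return `TRUE` iff `bmi >= 30` (inclusive threshold); `NA` propagates.
#' @export
classify_obese <- function(bmi) {
  if (any(is.infinite(bmi) | is.nan(bmi))) stop("BMI must be finite")
  bmi >= 30
}
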