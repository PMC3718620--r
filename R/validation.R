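#' Gold-standard counties for down-sampling validation
#'
#' Counties with at least `min_n` records carrying a non-missing outcome
#' within the validation span; their pooled direct proportions serve as
#' validation truth.
#'
#' @param records microdata with outcome columns.
#' @param outcome one of [outcome_names].
#' @param min_n minimum record count (default 900).
#' @param span inclusive year range `c(first, last)` (default 2001-2005).
#' @return Character vector of county ids.
#' @export
select_gold_counties <- function(records, outcome, min_n = 900L,
                                 span = c(2001L, 2005L)) {
  ycol <- outcome_column(outcome)
  d <- records[records$year >= span[1] & records$year <= span[2] &
                 !is.na(records[[ycol]]), , drop = FALSE]
  cnt <- table(d$county_id)
  out <- names(cnt)[cnt >= min_n]
  if (!length(out))
    stop("no county reaches ", min_n, " usable records in ",
         span[1], "-", span[2], "; validation infeasible")
  sort(out)
}

#' Pooled direct prevalence in a gold-standard county
#'
#' @inheritParams select_gold_counties
#' @param county a county id.
#' @return Simple proportion of the outcome over all usable records of the
#'   county within the span.
#' @export
gold_standard <- function(records, county, outcome,
                          span = c(2001L, 2005L)) {
  ycol <- outcome_column(outcome)
  d <- records[records$county_id == county & records$year >= span[1] &
                 records$year <= span[2] & !is.na(records[[ycol]]), ,
               drop = FALSE]
  if (nrow(d) == 0L) stop("no usable records for county ", county)
  mean(d[[ycol]])
}

#' Deterministic down-sample of one county's records
#'
#' Simple random sample without replacement of `m` of the county's records
#' within the span; the subset is a deterministic function of
#' `(seed, replicate, county, m)` so replicate streams are separated and the
#' whole metric grid reproduces bit-identically.
#'
#' @inheritParams gold_standard
#' @param m sample size.
#' @param replicate replicate index (>= 1).
#' @param seed master seed.
#' @return The sampled rows of `records`.
#' @export
downsample <- function(records, county, m, replicate, seed,
                       span = c(2001L, 2005L)) {
  idx <- which(records$county_id == county & records$year >= span[1] &
                 records$year <= span[2])
  if (m > length(idx))
    stop("requested m = ", m, " exceeds the ", length(idx),
         " available records in county ", county)
  keep <- with_seed(child_seed(seed, "downsample", replicate, county, m),
                    sample(idx, m))
  records[sort(keep), , drop = FALSE]
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of `x` with `y` against the identity line:
#' `2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`, with
#' population (1/n) moments.
#'
#' @param x,y equal-length numeric vectors (n >= 2, not both constant).
#' @return CCC in \[-1, 1\].
#' @examples
#' lin_ccc(c(0, 1), c(0.5, 1.5))  # 2/3
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs")
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  den <- vx + vy + (mx - my)^2
  if (den == 0) stop("CCC undefined: both vectors constant and equal")
  2 * cxy / den
}

#' Mean relative error and root mean squared error
#'
#' `mean_relative_error()` is the signed mean of `(x - y) / y` (set
#' `absolute = TRUE` for the absolute variant); `rmse()` is
#' `sqrt(mean((x - y)^2))`.
#'
#' @param x estimate vector; `y` gold vector (strictly positive for the
#'   relative metric).
#' @param absolute use `|x - y| / y`.
#' @return The metric value.
#' @export
mean_relative_error <- function(x, y, absolute = FALSE) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  bad <- which(y == 0)
  if (length(bad))
    stop("relative error undefined: zero gold value at position(s) ",
         paste(bad, collapse = ", "))
  e <- (x - y) / y
  if (absolute) e <- abs(e)
  mean(e)
}

#' @rdname mean_relative_error
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  sqrt(mean((x - y)^2))
}

#' Down-sampling validation of the four model variants
#'
#' The model-selection experiment: gold-standard counties are repeatedly
#' sampled down to `m` respondents, all four variants are refit on the
#' reduced data (all other counties keep their full records), each variant's
#' pooled prevalence prediction for every gold county is scored against the
#' pooled direct gold standard with Lin's CCC, mean relative error, and
#' RMSE, and the variant with the best mean CCC is selected.
#'
#' A variant's pooled prediction for a county averages the fitted cell
#' probabilities over the county's full (pre-down-sampling) respondent
#' composition, so crude pooled prevalence is compared with crude pooled
#' prevalence.
#'
#' @param records microdata with outcome columns.
#' @param counties populated [county_table()].
#' @param outcome one of [outcome_names].
#' @param sexes sexes to pool over (fits stay sex-specific).
#' @param m_values down-sample sizes (default 10, 50, 100).
#' @param reps replicates per size (default 25).
#' @param seed master seed.
#' @param span validation window (default 2001-2005).
#' @param min_n gold-standard threshold (default 900).
#' @param control a [fit_control()].
#' @return Object of class `validation_report`: `metrics` (variant, m,
#'   replicate, ccc, mre, rmse, failed), `summary` (replicate means), and
#'   `selected_variant`.
#' @export
run_validation <- function(records, counties, outcome, sexes = "female",
                           m_values = c(10L, 50L, 100L), reps = 25L,
                           seed = 1L, span = c(2001L, 2005L),
                           min_n = 900L, control = fit_control()) {
  outcome <- match.arg(outcome, outcome_names)
  if (reps < 1L) stop("'reps' must be >= 1")
  ycol <- outcome_column(outcome)
  base <- records[records$year >= span[1] & records$year <= span[2] &
                    records$sex %in% sexes, , drop = FALSE]
  gold_ids <- select_gold_counties(base, outcome, min_n, span)
  gold <- vapply(gold_ids, function(cid)
    gold_standard(base, cid, outcome, span), numeric(1))
  # full-composition cells of each gold county, used to pool predictions
  usable <- base[!is.na(base[[ycol]]) & !is.na(base$age_group) &
                   !is.na(base$race) & base$county_id %in% gold_ids, ,
                 drop = FALSE]
  window <- span[1]:span[2]
  rows <- list()
  for (m in m_values) for (rep in seq_len(reps)) {
    reduced <- base[!(base$county_id %in% gold_ids), , drop = FALSE]
    for (cid in gold_ids)
      reduced <- rbind(reduced,
                       downsample(base, cid, m, rep,
                                  child_seed(seed, m), span))
    metrics <- tryCatch({
      pred <- matrix(NA_real_, length(gold_ids), length(model_variants),
                     dimnames = list(gold_ids, model_variants))
      acc <- matrix(0, length(gold_ids), length(model_variants),
                    dimnames = list(gold_ids, model_variants))
      wt <- stats::setNames(rep(0, length(gold_ids)), gold_ids)
      for (sx in sexes) {
        fits <- fit_all_variants(reduced, counties, outcome, sx, window,
                                 control)
        cells <- usable[usable$sex == sx, , drop = FALSE]
        if (nrow(cells) == 0L) next
        for (v in model_variants) {
          p <- predict_cells(fits[[v]], cells, counties)
          acc[, v] <- acc[, v] +
            vapply(gold_ids, function(cid)
              sum(p[cells$county_id == cid]), numeric(1))
        }
        wt <- wt + vapply(gold_ids, function(cid)
          sum(cells$county_id == cid), numeric(1))
      }
      for (v in model_variants) pred[, v] <- acc[, v] / wt
      do.call(rbind, lapply(model_variants, function(v)
        data.frame(variant = v, m = m, replicate = rep,
                   ccc = lin_ccc(pred[, v], gold),
                   mre = mean_relative_error(pred[, v], gold),
                   rmse = rmse(pred[, v], gold), failed = FALSE,
                   stringsAsFactors = FALSE)))
    }, error = function(e)
      data.frame(variant = model_variants, m = m, replicate = rep,
                 ccc = NA_real_, mre = NA_real_, rmse = NA_real_,
                 failed = TRUE, stringsAsFactors = FALSE))
    rows[[length(rows) + 1L]] <- metrics
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  summ <- stats::aggregate(metrics[, c("ccc", "mre", "rmse")],
                           by = list(variant = metrics$variant,
                                     m = metrics$m),
                           FUN = mean, na.rm = TRUE)
  report <- structure(list(metrics = metrics, summary = summ,
                           gold_counties = gold_ids,
                           settings = list(outcome = outcome, sexes = sexes,
                                           m_values = m_values, reps = reps,
                                           seed = seed, span = span,
                                           min_n = min_n)),
                      class = "validation_report")
  report$selected_variant <- select_model(report)
  report
}

#' Select the winning model variant from a validation report
#'
#' Highest mean CCC across sample sizes; ties broken by lower RMSE, then by
#' lower absolute mean relative error.
#'
#' @param report a [run_validation()] report.
#' @return One of [model_variants].
#' @export
select_model <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  m <- report$metrics[!report$metrics$failed, , drop = FALSE]
  missing_cells <- character(0)
  for (v in model_variants) for (mm in unique(report$metrics$m))
    if (!any(m$variant == v & m$m == mm))
      missing_cells <- c(missing_cells, paste0(v, " @ m=", mm))
  if (length(missing_cells))
    stop("validation report incomplete; no successful replicate for: ",
         paste(missing_cells, collapse = ", "))
  by_var <- stats::aggregate(m[, c("ccc", "mre", "rmse")],
                             by = list(variant = m$variant), FUN = mean)
  ord <- order(-by_var$ccc, by_var$rmse, abs(by_var$mre))
  as.character(by_var$variant[ord][1])
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report:", length(x$gold_counties), "gold counties,",
      x$settings$reps, "replicates, m =",
      paste(x$settings$m_values, collapse = "/"), "\n")
  print(x$summary, digits = 3)
  cat("selected variant:", x$selected_variant, "\n")
  invisible(x)
}
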