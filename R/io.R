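# CSV/JSON interfaces. Missing values are written as empty fields and read
# back as NA; sentinel numeric codes are rejected by the schema checks.
# Errors name the file, row, and column so malformed inputs are auditable.

schema_stop <- function(file, row, column, msg) {
  stop(sprintf("%s: row %s, column '%s': %s", file,
               paste(row, collapse = ","), column, msg), call. = FALSE)
}

check_levels <- function(d, file, column, levels, allow_na = TRUE) {
  x <- d[[column]]
  bad <- which(!(x %in% levels) & !(allow_na & is.na(x)))
  if (length(bad))
    schema_stop(file, utils::head(bad, 5), column,
                paste0("unknown level '", x[bad[1]], "' (expected ",
                       paste(levels, collapse = ", "), ")"))
}

check_nonneg <- function(d, file, column) {
  x <- d[[column]]
  bad <- which(!is.na(x) & x < 0)
  if (length(bad))
    schema_stop(file, utils::head(bad, 5), column, "must be non-negative")
}

check_positive <- function(d, file, column) {
  x <- d[[column]]
  bad <- which(!is.na(x) & x <= 0)
  if (length(bad))
    schema_stop(file, utils::head(bad, 5), column, "must be > 0")
}

#' Read and write survey microdata CSV
#'
#' One row per respondent with the documented columns (`year`, `county_id`,
#' `sex`, `age_group`, `race`, `reported_weight`, `reported_height`,
#' `any_pa`, `moderate_min_week`, `vigorous_min_week`, plus any outcome or
#' truth columns already attached). Missing values are empty fields;
#' categorical levels and sign constraints are validated on read with
#' row-addressed errors. Write-then-read is lossless.
#'
#' @param records microdata `data.frame`.
#' @param path CSV file path.
#' @return `read_microdata()` returns the validated `data.frame`.
#' @export
write_microdata <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_microdata
#' @export
read_microdata <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- microdata_columns(FALSE)
  miss <- setdiff(need, names(d))
  if (length(miss)) stop(path, ": missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(d)) {
    check_levels(d, path, "sex", sexes)
    check_levels(d, path, "age_group", age_groups)
    check_levels(d, path, "race", race_groups)
    check_levels(d, path, "any_pa", c("yes", "no", "TRUE", "FALSE"))
    check_positive(d, path, "reported_weight")
    check_positive(d, path, "reported_height")
    check_nonneg(d, path, "moderate_min_week")
    check_nonneg(d, path, "vigorous_min_week")
  }
  d
}

#' Read and write the county table as plain-text files
#'
#' Three CSVs: per-year covariates (wide: `county_id`, `year`, the columns
#' of [county_covariates]), an adjacency edge list (`county_id`,
#' `neighbor_id`; each undirected edge may appear once or twice), and
#' race-specific populations (`county_id`, `race`, `population`).
#'
#' @param counties a [county_table()].
#' @param covariates_path,adjacency_path,populations_path file paths.
#' @return `read_county_table()` returns a validated [county_table()].
#' @export
write_county_table <- function(counties, covariates_path, adjacency_path,
                               populations_path) {
  utils::write.csv(counties$covariates, covariates_path,
                   row.names = FALSE, na = "")
  edges <- do.call(rbind, lapply(counties$county_ids, function(id) {
    nb <- counties$neighbors[[id]]
    if (length(nb)) data.frame(county_id = id, neighbor_id = nb,
                               stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(county_id = character(0),
                        neighbor_id = character(0))
  utils::write.csv(edges, adjacency_path, row.names = FALSE)
  utils::write.csv(counties$race_populations, populations_path,
                   row.names = FALSE)
  invisible(counties)
}

#' @rdname write_county_table
#' @export
read_county_table <- function(covariates_path, adjacency_path,
                              populations_path) {
  cov <- utils::read.csv(covariates_path, stringsAsFactors = FALSE,
                         na.strings = "")
  edges <- utils::read.csv(adjacency_path, stringsAsFactors = FALSE)
  pops <- utils::read.csv(populations_path, stringsAsFactors = FALSE)
  check_levels(pops, populations_path, "race", race_groups,
               allow_na = FALSE)
  check_nonneg(pops, populations_path, "population")
  ids <- sort(unique(c(cov$county_id, edges$county_id, edges$neighbor_id,
                       pops$county_id)))
  nbrs <- stats::setNames(lapply(ids, function(id) {
    sort(unique(c(edges$neighbor_id[edges$county_id == id],
                  edges$county_id[edges$neighbor_id == id])))
  }), ids)
  county_table(ids, nbrs, covariates = cov, race_populations = pops)
}

#' Read and write examination-survey cell means
#'
#' Columns: `cycle_start`, `cycle_end`, `sex`, `age_group`, `n`,
#' `mean_bmi`.
#'
#' @param cells `data.frame` of cell means.
#' @param path CSV file path.
#' @export
write_examination_cells <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_examination_cells
#' @export
read_examination_cells <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("cycle_start", "cycle_end", "sex", "age_group", "mean_bmi")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop(path, ": missing column(s): ",
                         paste(miss, collapse = ", "))
  check_levels(d, path, "sex", sexes, allow_na = FALSE)
  check_levels(d, path, "age_group", age_groups, allow_na = FALSE)
  check_positive(d, path, "mean_bmi")
  d
}

#' Read and write a fitted calibration model as JSON
#'
#' @param model a [fit_calibration()] model.
#' @param path JSON file path.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(model$coefficients, path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  co <- jsonlite::read_json(path, simplifyVector = TRUE)
  miss <- setdiff(sexes, names(co))
  if (length(miss)) stop(path, ": calibration missing sex(es): ",
                         paste(miss, collapse = ", "))
  structure(list(coefficients = lapply(co[sexes], as.list),
                 cells = NULL, weighted = NA), class = "calibration_model")
}

#' Read and write prevalence estimates CSV
#'
#' Columns: `county_id`, `year`, `sex`, `outcome`, `point`, `mean`,
#' `lower`, `upper`, `n_draws`.
#'
#' @param estimates the `estimates` data.frame of a `prevalence_estimates`
#'   object (or the object itself).
#' @param path CSV file path.
#' @export
write_estimates <- function(estimates, path) {
  if (inherits(estimates, "prevalence_estimates"))
    estimates <- estimates$estimates
  utils::write.csv(estimates, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("county_id", "year", "sex", "outcome", "mean", "lower",
            "upper")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop(path, ": missing column(s): ",
                         paste(miss, collapse = ", "))
  check_levels(d, path, "sex", sexes, allow_na = FALSE)
  for (v in c("mean", "lower", "upper")) {
    bad <- which(is.na(d[[v]]) | d[[v]] < 0 | d[[v]] > 1)
    if (length(bad))
      schema_stop(path, utils::head(bad, 5), v,
                  "prevalence must be a number in [0, 1]")
  }
  d
}

#' Write a validation report as CSV plus summary JSON
#'
#' @param report a [run_validation()] report.
#' @param csv_path per-replicate metric grid CSV.
#' @param json_path summary JSON including the selected variant.
#' @export
write_validation_report <- function(report, csv_path, json_path) {
  stopifnot(inherits(report, "validation_report"))
  utils::write.csv(report$metrics, csv_path, row.names = FALSE, na = "")
  jsonlite::write_json(
    list(selected_variant = report$selected_variant,
         summary = report$summary, settings = report$settings),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
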