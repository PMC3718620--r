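#' Moderate-equivalent weekly activity minutes
#'
#' Weekly moderate minutes plus twice weekly vigorous minutes (one vigorous
#' minute counts as two moderate minutes).
#'
#' @param moderate,vigorous non-negative weekly minutes; `NA` propagates.
#' @param vigorous_multiplier minutes of moderate activity one vigorous
#'   minute is worth (default 2).
#' @return moderate + vigorous_multiplier * vigorous.
#' @examples
#' moderate_equivalent_minutes(0, 75)  # 150
#' @export
moderate_equivalent_minutes <- function(moderate, vigorous,
                                        vigorous_multiplier = 2) {
  if (any(!is.na(moderate) & moderate < 0) ||
      any(!is.na(vigorous) & vigorous < 0))
    stop("activity minutes must be non-negative")
  moderate + vigorous_multiplier * vigorous
}

#' Sufficient physical activity
#'
#' A respondent is sufficiently active when moderate-equivalent weekly
#' minutes reach the threshold (inclusive): 150 total minutes of moderate
#' activity, the equivalent in vigorous activity, or a combination. Missing
#' minutes propagate to a missing classification.
#'
#' @inheritParams moderate_equivalent_minutes
#' @param threshold weekly moderate-equivalent minutes defining sufficiency.
#' @return logical vector (`NA` where either minutes field is missing).
#' @export
classify_sufficient <- function(moderate, vigorous, threshold = 150,
                                vigorous_multiplier = 2) {
  me <- moderate_equivalent_minutes(moderate, vigorous, vigorous_multiplier)
  me >= threshold
}

#' Any leisure-time physical activity
#'
#' Pass-through of the yes/no screening response; missing stays missing so
#' the record is excluded from the any-activity model only.
#'
#' @param any_pa character vector with levels `"yes"`, `"no"`, or `NA`.
#' @return logical vector.
#' @export
classify_any <- function(any_pa) {
  known <- is.na(any_pa) | any_pa %in% c("yes", "no")
  if (!all(known))
    stop("unknown any_pa level(s): ",
         paste(unique(any_pa[!known]), collapse = ", "))
  ifelse(is.na(any_pa), NA, any_pa == "yes")
}

#' Weekly minutes from session frequency and duration
#'
#' Converts the frequency-times-duration form of the activity questions
#' (sessions per week and minutes per session) to weekly minutes.
#'
#' @param times_per_week,minutes_per_session non-negative; `NA` propagates.
#' @return weekly minutes.
#' @export
weekly_minutes <- function(times_per_week, minutes_per_session) {
  if (any(!is.na(times_per_week) & times_per_week < 0) ||
      any(!is.na(minutes_per_session) & minutes_per_session < 0))
    stop("frequency and duration must be non-negative")
  times_per_week * minutes_per_session
}

#' Attach the three binary outcomes to survey microdata
#'
#' Adds `obese` (corrected BMI at or above 30, via the self-report
#' calibration), converts `any_pa` to logical, and adds `sufficient_pa`
#' (moderate-equivalent minutes at or above the threshold). One definition is
#' applied to every survey year.
#'
#' @param records microdata `data.frame`.
#' @param calibration a [fit_calibration()] model, or `NULL` to classify on
#'   uncorrected reported BMI.
#' @param threshold,vigorous_multiplier see [classify_sufficient()].
#' @return `records` with logical columns `obese`, `any_pa`, `sufficient_pa`
#'   and a numeric `corrected_bmi` column.
#' @export
add_outcomes <- function(records, calibration = NULL, threshold = 150,
                         vigorous_multiplier = 2) {
  bmi <- if (is.null(calibration))
    compute_bmi(records$reported_weight, records$reported_height)
  else apply_calibration(calibration, records)
  records$corrected_bmi <- bmi
  records$obese <- classify_obese(bmi)
  records$any_pa <- classify_any(records$any_pa)
  records$sufficient_pa <- classify_sufficient(records$moderate_min_week,
                                               records$vigorous_min_week,
                                               threshold,
                                               vigorous_multiplier)
  records
}
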