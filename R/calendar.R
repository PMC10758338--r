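#' Study calendar helpers
#'
#' All dates in the package are integer day indices on a study calendar whose
#' origin (day 0) is 2008-07-01, the first day of cohort accrual.  Days before
#' the origin are negative.  Intervals are half-open `[start, end)` throughout.
#' Enrollment is month-granular: a calendar month is either covered or not,
#' and months are indexed from January 2008 (month 0), so the origin day falls
#' in month 6.
#'
#' @name study_calendar
#' @keywords internal
NULL

.STUDY_ORIGIN <- as.Date("2008-07-01")
.MONTH_BASE <- 2008L * 12L

#' Convert a study day index to a calendar date
#' @param day integer day index (day 0 = 2008-07-01)
#' @return a `Date` vector
#' @export
day_to_date <- function(day) .STUDY_ORIGIN + day

#' Convert a calendar date to a study day index
#' @param date a `Date` vector
#' @return integer day indices
#' @export
date_to_day <- function(date) as.integer(as.Date(date) - .STUDY_ORIGIN)

#' Calendar month index of a study day
#'
#' Months are counted from January 2008 (month 0); the study origin day is in
#' month 6 (July 2008).
#' @param day integer day index
#' @return integer month indices
#' @export
day_to_month <- function(day) {
  d <- day_to_date(day)
  y <- as.integer(format(d, "%Y"))
  m <- as.integer(format(d, "%m"))
  y * 12L + (m - 1L) - .MONTH_BASE
}

#' First study day of a calendar month index
#' @param month integer month index (0 = January 2008)
#' @return integer day index of the month's first day
#' @export
month_start_day <- function(month) {
  y <- (month + .MONTH_BASE) %/% 12L
  m <- (month + .MONTH_BASE) %% 12L + 1L
  date_to_day(as.Date(sprintf("%d-%02d-01", y, m)))
}

# Last index date admitting cohort entry (2013-06-30) and last follow-up day
# of the study period (2013-12-31), as day indices.
.ACCRUAL_END_DAY <- 1825L
.STUDY_END_DAY <- 2009L

#' Study period constants
#'
#' Day indices of the accrual close (2013-06-30) and the administrative end of
#' follow-up (2013-12-31).
#' @return a named list with elements `accrual_end` and `study_end`
#' @export
study_period <- function() {
  list(accrual_end = .ACCRUAL_END_DAY, study_end = .STUDY_END_DAY)
}

# Durations used by the cohort design: the 6-month pre-period is 183 days,
# follow-up caps at 3 years = 1095 days, the monotherapy qualifying window is
# 90 days and the diabetes claim-pair window is 365 days.
.PRE_PERIOD_DAYS <- 183L
.FOLLOWUP_DAYS <- 1095L
.MONO_WINDOW_DAYS <- 90L
.DX_PAIR_WINDOW_DAYS <- 365L
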