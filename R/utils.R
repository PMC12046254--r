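# Shared date conventions and small validators.
#
# Weeks are identified by their start date (calendar dates, 7 days apart);
# months by the first day of the calendar month.  The study windows follow
# the usual infodemiology setup: a five-year pre-pandemic baseline and a
# pandemic analysis window that opens the day the baseline closes.

#' Default study windows
#'
#' The baseline window (used to train the counterfactual model) runs from
#' 2015-03-01 to 2020-02-29; the pandemic window (where excess is measured)
#' from 2020-03-01 to 2022-10-15, i.e. 137 analysis weeks when weeks start
#' on Sundays.
#'
#' @return A list with `baseline_start`, `baseline_end`, `pandemic_start`,
#'   `pandemic_end` as `Date`s.
#' @export
#' @examples
#' study_windows()
study_windows <- function() {
  list(
    baseline_start = as.Date("2015-03-01"),
    baseline_end   = as.Date("2020-02-29"),
    pandemic_start = as.Date("2020-03-01"),
    pandemic_end   = as.Date("2022-10-15")
  )
}

#' Pandemic-year stratum of a calendar month
#'
#' Year 1 covers March 2020 through February 2021, year 2 March 2021 through
#' February 2022, and year 3 the eight months March through October 2022
#' (mobility data access ended there, so no annualisation is applied).
#'
#' @param month A `Date` vector (any day within the month).
#' @return Integer vector with values 1, 2, 3 or `NA` outside the study
#'   window.
#' @export
#' @examples
#' pandemic_year_of(as.Date(c("2020-06-01", "2021-03-01", "2022-10-01")))
pandemic_year_of <- function(month) {
  m <- lubridate::floor_date(as.Date(month), "month")
  idx <- 12L * lubridate::year(m) + lubridate::month(m) -
    (12L * 2020L + 3L) # months since March 2020
  yr <- idx %/% 12L + 1L
  yr[idx < 0L | m > as.Date("2022-10-01")] <- NA_integer_
  as.integer(yr)
}

# Sequence of week-start dates covering [from, to], stepping 7 days.
week_seq <- function(from, to) {
  seq(as.Date(from), as.Date(to), by = "7 days")
}

month_of <- function(date) lubridate::floor_date(as.Date(date), "month")

# internal: stop unless all columns are present
assert_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s) %s; found: %s",
      what, paste0("'", missing, "'", collapse = ", "),
      paste0("'", names(df), "'", collapse = ", ")
    ))
  }
  invisible(df)
}

# internal: strictly increasing date check
assert_increasing_dates <- function(dates, what = "series") {
  d <- diff(as.numeric(dates))
  if (any(d <= 0)) {
    i <- which(d <= 0)[1]
    abort(sprintf(
      "%s dates must be strictly increasing; violation at %s followed by %s",
      what, format(dates[i]), format(dates[i + 1])
    ))
  }
  invisible(dates)
}
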