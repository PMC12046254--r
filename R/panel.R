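# Country-by-month panel assembly.
#
# Daily exposure (deaths or cases) and mediator (residential mobility)
# streams are averaged over calendar months; weekly excess is assigned to
# the month containing its week-start date and averaged.  The three are
# inner-joined per (country, month), stratum labels attached, and rows with
# any missing component dropped (listwise deletion, no imputation).

monthly_mean_tbl <- function(country, dates, values, out_name) {
  if (length(values) == 0) {
    out <- tibble::tibble(country_code = character(),
                          month = as.Date(character()), val = numeric())
    names(out)[3] <- out_name
    return(out)
  }
  m <- month_of(dates)
  key <- paste(country, as.integer(m), sep = "\r")
  first <- !duplicated(key)
  agg <- rowsum(cbind(values, 1), key, reorder = FALSE)
  ord <- match(key[first], rownames(agg))
  out <- tibble::new_tibble(list(
    country_code = country[first],
    month = m[first],
    val = as.numeric(agg[ord, 1] / agg[ord, 2])
  ), nrow = sum(first))
  names(out)[3] <- out_name
  dplyr::arrange(out, .data$country_code, .data$month)
}

#' Monthly mean daily exposure (deaths or cases)
#'
#' Averages a daily count series over calendar months, per country.  Months
#' with no coverage are simply absent; partially covered months use the
#' available days.
#'
#' @param deaths Daily tibble with columns `country_code`, `date`, `value`.
#' @return A tibble `country_code`, `month` (first of month), `exposure`.
#' @export
monthly_exposure <- function(deaths) {
  assert_cols(deaths, c("country_code", "date", "value"), "daily exposure")
  monthly_mean_tbl(deaths$country_code, deaths$date, deaths$value,
                   "exposure")
}

#' Monthly mean residential mobility change
#'
#' @param mobility Daily tibble with columns `country_code`, `date`,
#'   `value` (percent change from baseline).
#' @return A tibble `country_code`, `month`, `mediator`.
#' @export
monthly_mediator <- function(mobility) {
  assert_cols(mobility, c("country_code", "date", "value"), "daily mobility")
  monthly_mean_tbl(mobility$country_code, mobility$date, mobility$value,
                   "mediator")
}

#' Monthly mean weekly excess search volume
#'
#' Each week is assigned to the calendar month containing its week-start
#' date (a week starting 27 February belongs to February even though it
#' spans March); the month's value is the mean over its assigned weeks.
#'
#' @param excess Weekly tibble with columns `country_code`, `week_start`,
#'   `excess`.
#' @return A tibble `country_code`, `month`, `outcome`.
#' @export
monthly_outcome <- function(excess) {
  assert_cols(excess, c("country_code", "week_start", "excess"),
              "weekly excess")
  monthly_mean_tbl(excess$country_code, excess$week_start, excess$excess,
                   "outcome")
}

#' Assemble the country-by-month mediation panel
#'
#' Inner-joins monthly exposure, mediator and outcome per (country, month),
#' attaches income group and pandemic-year strata, and drops incomplete
#' rows (their count is reported).  Countries contributing fewer than two
#' months are dropped with a warning.
#'
#' @param registry Country registry tibble (see [load_registry()]).
#' @param excess Weekly excess tibble (`country_code`, `week_start`,
#'   `excess`), e.g. rows of [estimate_excess()] output.
#' @param mobility Daily mobility tibble.
#' @param exposure Daily deaths/cases tibble.
#' @param term Search term label stored on the panel.
#' @param exposure_metric Label for the exposure stream.
#' @return A panel tibble with columns `country_code`, `month`, `exposure`,
#'   `mediator`, `outcome`, `income_group`, `pandemic_year`, `term`, and
#'   attribute `exposure_metric`.
#' @export
assemble_panel <- function(registry, excess, mobility, exposure,
                           term = "insomnia",
                           exposure_metric = "new_deaths") {
  parts <- list(
    exposure = monthly_exposure(exposure),
    mediator = monthly_mediator(mobility),
    outcome = monthly_outcome(excess)
  )
  empty <- names(parts)[vapply(parts, nrow, 0L) == 0]
  if (length(empty) > 0) {
    abort(sprintf("panel assembly failed: no monthly values from '%s'",
                  empty[1]))
  }
  panel <- purrr::reduce(parts, dplyr::inner_join,
                         by = c("country_code", "month"))
  if (nrow(panel) == 0) {
    sizes <- vapply(parts, nrow, 0L)
    abort(sprintf(
      "panel empty after joining; smallest input was '%s' (%d months)",
      names(which.min(sizes)), min(sizes)))
  }
  n_dropped <- max(vapply(parts, nrow, 0L)) - nrow(panel)
  if (n_dropped > 0) {
    inform(sprintf(
      "%d country-month(s) dropped for missing exposure/mediator/outcome",
      n_dropped))
  }
  missing_countries <- setdiff(
    unique(c(parts$exposure$country_code, parts$mediator$country_code,
             parts$outcome$country_code)),
    unique(panel$country_code))
  if (length(missing_countries) > 0) {
    warn(sprintf("excluded from panel (no complete months): %s",
                 paste(missing_countries, collapse = ", ")))
  }
  few <- names(which(table(panel$country_code) < 2))
  if (length(few) > 0) {
    warn(sprintf("dropping countries with fewer than 2 months: %s",
                 paste(few, collapse = ", ")))
    panel <- dplyr::filter(panel, !.data$country_code %in% few)
  }
  panel <- panel |>
    dplyr::left_join(
      dplyr::select(registry, "country_code", "income_group"),
      by = "country_code") |>
    dplyr::mutate(pandemic_year = pandemic_year_of(.data$month),
                  term = term) |>
    dplyr::arrange(.data$country_code, .data$month)
  if (anyDuplicated(panel[c("country_code", "month")])) {
    abort("duplicated (country, month) keys in panel")
  }
  attr(panel, "exposure_metric") <- exposure_metric
  panel
}

#' Restrict a panel to one stratum
#'
#' @param panel Panel tibble from [assemble_panel()].
#' @param income `"high"`, `"middle"` or `NULL` (both).
#' @param year Pandemic year 1, 2, 3 or `NULL` (all).
#' @return The filtered panel tibble.
#' @export
filter_stratum <- function(panel, income = NULL, year = NULL) {
  if (!is.null(income)) {
    panel <- dplyr::filter(panel, .data$income_group == !!income)
  }
  if (!is.null(year)) {
    panel <- dplyr::filter(panel, .data$pandemic_year %in% !!year)
  }
  panel
}
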