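# Readers and writers for the three public-data dialects:
#  * Trends-style weekly relative search volumes (0-100, "<1" censored),
#  * mobility-report-style daily residential percent change from baseline,
#  * long-format daily death / confirmed-case counts.
# All readers accept a file path or a connection and return plain tibbles.

#' Read a Trends-style weekly search-volume export
#'
#' Parses a Google-Trends-style CSV: any metadata/header lines are skipped
#' until the first row whose first field parses as a date, then `week,value`
#' rows follow.  Censored cells `"<1"` are mapped to 0.5 (midpoint
#' imputation, unbiased under a uniform prior on the censored interval and
#' preserving the 0-100 range).  Gaps in the weekly grid are flagged with a
#' warning but never filled.
#'
#' @param source Path or connection to the CSV.
#' @param country_code ISO-3166 alpha-2 code to attach to the series.
#' @param term Search term label, `"insomnia"` or `"suicide"`.
#' @return A tibble with columns `country_code`, `term`, `week_start`
#'   (`Date`) and `value` (relative search volume in \[0, 100\]).
#' @export
read_trends_csv <- function(source, country_code = NA_character_,
                            term = NA_character_) {
  lines <- readr::read_lines(source, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  first_field <- sub(",.*$", "", lines)
  is_data <- !is.na(suppressWarnings(as.Date(first_field,
                                             format = "%Y-%m-%d")))
  if (!any(is_data)) abort("no data rows found in Trends export")
  body <- lines[seq(which(is_data)[1], length(lines))]
  parts <- strsplit(body, ",", fixed = TRUE)
  if (any(lengths(parts) < 2)) {
    abort(sprintf("malformed row: '%s'", body[which(lengths(parts) < 2)[1]]))
  }
  week_start <- as.Date(vapply(parts, `[[`, "", 1L))
  raw <- trimws(vapply(parts, `[[`, "", 2L))
  value <- ifelse(raw == "<1", 0.5, suppressWarnings(as.numeric(raw)))
  if (anyNA(value)) {
    abort(sprintf("non-numeric search volume in row '%s'",
                  body[which(is.na(value))[1]]))
  }
  assert_increasing_dates(week_start, "Trends export")
  bad <- which(value < 0 | value > 100)
  if (length(bad) > 0) {
    abort(sprintf("search volume outside [0, 100] in row '%s'",
                  body[bad[1]]))
  }
  gaps <- which(diff(as.numeric(week_start)) != 7)
  if (length(gaps) > 0) {
    warn(sprintf("weekly grid has %d gap(s), first after %s; gaps not filled",
                 length(gaps), format(week_start[gaps[1]])))
  }
  tibble::tibble(country_code = country_code, term = term,
                 week_start = week_start, value = value)
}

#' Write a weekly search-volume series in the Trends dialect
#'
#' @param series Tibble with columns `week_start`, `value` (and optionally
#'   `term`, used in the header).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trends_csv <- function(series, path) {
  assert_cols(series, c("week_start", "value"), "weekly series")
  term <- if ("term" %in% names(series)) series$term[1] else "term"
  header <- c("Category: All categories", "",
              sprintf("Week,%s", term))
  rows <- sprintf("%s,%s", format(series$week_start, "%Y-%m-%d"),
                  formatC(series$value, format = "g", digits = 15))
  readr::write_lines(c(header, rows), path)
  invisible(path)
}

# shared long-format reader for country,date,value files
read_long_daily <- function(source, metric, country = NULL,
                            what = "daily series") {
  df <- readr::read_csv(source, show_col_types = FALSE, progress = FALSE)
  assert_cols(df, c("country", "date", "value"), what)
  df$country <- as.character(df$country)
  df$date <- as.Date(df$date)
  df$value <- as.numeric(df$value)
  if (!is.null(country)) df <- dplyr::filter(df, .data$country %in% !!country)
  dup <- duplicated(df[c("country", "date")])
  if (any(dup)) {
    d <- df[dup, ][1, ]
    abort(sprintf("duplicate (country, date) pair: (%s, %s)",
                  d$country, format(d$date)))
  }
  df <- dplyr::arrange(df, .data$country, .data$date)
  tibble::tibble(country_code = df$country, metric = metric,
                 date = df$date, value = df$value)
}

#' Read a mobility-report-style residential-mobility CSV
#'
#' Long-format `country,date,value` rows where `value` is the percent change
#' in time spent at residences relative to the provider's pre-pandemic
#' baseline (the 5-week median window 2020-01-03 to 2020-02-06); values may
#' be negative.
#'
#' @param source Path or connection.
#' @param country Optional character vector of country codes to keep.
#' @return A tibble with columns `country_code`, `metric`
#'   (`"residential_pct_change"`), `date`, `value`.
#' @export
read_mobility_csv <- function(source, country = NULL) {
  read_long_daily(source, "residential_pct_change", country,
                  what = "mobility CSV")
}

#' Read a daily death- or case-count CSV
#'
#' Long-format `country,date,value` rows as in public epidemic extracts.
#' Negative daily counts (retrospective data corrections) are accepted with
#' a warning; monthly averaging downstream absorbs them, whereas clipping
#' would bias monthly means.
#'
#' @param source Path or connection.
#' @param metric `"new_deaths"` (default) or `"new_cases"`.
#' @param country Optional character vector of country codes to keep.
#' @return A tibble with columns `country_code`, `metric`, `date`, `value`.
#' @export
read_deaths_csv <- function(source, metric = c("new_deaths", "new_cases"),
                            country = NULL) {
  metric <- match.arg(metric)
  out <- read_long_daily(source, metric, country, what = "deaths CSV")
  n_neg <- sum(out$value < 0)
  if (n_neg > 0) {
    warn(sprintf("%d negative %s value(s) retained (data corrections)",
                 n_neg, metric))
  }
  out
}

#' Write a daily series in the long `country,date,value` dialect
#'
#' Inverse of [read_mobility_csv()] / [read_deaths_csv()].
#'
#' @param daily Tibble with columns `country_code`, `date`, `value`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_daily_csv <- function(daily, path) {
  assert_cols(daily, c("country_code", "date", "value"), "daily series")
  readr::write_csv(
    tibble::tibble(country = daily$country_code, date = daily$date,
                   value = daily$value),
    path, progress = FALSE
  )
  invisible(path)
}
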