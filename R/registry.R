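#' Load the country registry
#'
#' The registry lists the countries under study with their World Bank income
#' stratum (`"high"` or `"middle"`) and the locally translated search
#' keywords for insomnia and suicide.  The packaged default covers the 45
#' countries of the study (31 high-income, 14 middle-income).  The registry
#' is shipped as data, not code, so users can swap in their own country set.
#'
#' @param source Path to a registry CSV with columns `country_code`, `name`,
#'   `income_group`, `keyword_insomnia`, `keyword_suicide`.  `NULL` (the
#'   default) loads the packaged registry.
#' @return A tibble with one row per country and the five columns above;
#'   `income_group` is a factor with levels `high`, `middle`.
#' @export
#' @examples
#' reg <- load_registry()
#' dplyr::count(reg, income_group)
load_registry <- function(source = NULL) {
  path <- source %||%
    system.file("extdata", "country_registry.csv", package = "trendmediate")
  reg <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  assert_cols(reg, c("country_code", "name", "income_group",
                     "keyword_insomnia", "keyword_suicide"), "registry")
  bad <- setdiff(unique(reg$income_group), c("high", "middle"))
  if (length(bad) > 0) {
    abort(sprintf(
      "unknown income_group label(s): %s (must be 'high' or 'middle')",
      paste0("'", bad, "'", collapse = ", ")
    ))
  }
  if (anyDuplicated(reg$country_code)) {
    abort("duplicated country_code in registry")
  }
  dplyr::mutate(
    reg,
    income_group = factor(.data$income_group, levels = c("high", "middle"))
  )
}
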