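# ggplot2 visualisations: counterfactual panels (observed vs expected with
# its 95% band, plus weekly excess) and exposure/mediator/outcome
# trajectory triptychs.

#' Plot observed vs counterfactual search volume with weekly excess
#'
#' Two stacked panels per series: the observed pandemic-period search
#' volume over the expected counterfactual (with its 95% band), and the
#' weekly excess below.
#'
#' @param excess Excess tibble from [estimate_excess()] /
#'   [compute_excess()] (one or more country-terms; facetted if several).
#' @return A ggplot object.
#' @export
plot_counterfactual <- function(excess) {
  assert_cols(excess, c("week_start", "observed", "expected", "excess"),
              "excess table")
  id <- paste(excess$country_code, excess$term, sep = " / ")
  top <- dplyr::mutate(excess, series_id = id, panel = "search volume")
  bottom <- dplyr::mutate(excess, series_id = id, panel = "weekly excess")
  p <- ggplot2::ggplot(top, ggplot2::aes(x = .data$week_start)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower95, ymax = .data$upper95),
      fill = "grey70", alpha = 0.6, na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected),
                       colour = "black", linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed),
                       colour = "#2166ac", linewidth = 0.4) +
    ggplot2::geom_line(data = bottom,
                       ggplot2::aes(y = .data$excess),
                       colour = "#b2182b", linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        linewidth = 0.2) +
    ggplot2::facet_grid(panel ~ series_id, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "relative search volume") +
    ggplot2::theme_minimal()
  p
}

#' Plot exposure, mediator and outcome trajectories for one country
#'
#' A three-panel figure: daily deaths, daily residential mobility change,
#' and weekly excess search volume, sharing the time axis.
#'
#' @param deaths,mobility Daily tibbles (`date`, `value`).
#' @param excess Weekly excess tibble (`week_start`, `excess`).
#' @param country Country code used in the title.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(deaths, mobility, excess, country = NULL) {
  country <- country %||% deaths$country_code[1]
  long <- dplyr::bind_rows(
    tibble::tibble(date = deaths$date, value = deaths$value,
                   panel = "daily deaths"),
    tibble::tibble(date = mobility$date, value = mobility$value,
                   panel = "residential mobility (% change)"),
    tibble::tibble(date = excess$week_start, value = excess$excess,
                   panel = "weekly excess search volume")
  )
  long$panel <- factor(long$panel, levels = unique(long$panel))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$date, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.35, colour = "#2166ac") +
    ggplot2::facet_grid(panel ~ ., scales = "free_y") +
    ggplot2::labs(title = country, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Forest-style plot of stratified mediation estimates
#'
#' @param results Results tibble from [run_mediation()].
#' @return A ggplot object (effects on their natural scale; the
#'   proportion-mediated rows are excluded since they live on a percent
#'   scale).
#' @export
plot_mediation <- function(results) {
  df <- dplyr::filter(results, .data$effect != "proportion_mediated")
  strat <- intersect(c("income_group", "pandemic_year"), names(df))
  df$stratum <- if (length(strat) > 0) {
    do.call(paste, c(df[strat], sep = " / "))
  } else {
    "all"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$stratum,
                                   colour = .data$effect)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lower95, xmax = .data$upper95),
      height = 0.2, position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        linewidth = 0.2) +
    ggplot2::labs(x = "effect (outcome points per exposure unit)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
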