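# End-to-end pipeline: ingest (or simulate) -> counterfactual excess ->
# country-by-month panel -> stratified mediation -> rendered tables, driven
# by a single YAML configuration and seed.

#' Read and validate a pipeline run configuration
#'
#' The configuration is a YAML (or already-parsed list) with keys:
#' \describe{
#'   \item{synthetic}{Optional list of [scenario_truth()] arguments; when
#'     present the pipeline simulates its inputs.}
#'   \item{paths}{Otherwise, a list with `trends_dir` (containing
#'     `trends_<code>_<term>.csv` files), `mobility`, `deaths`, and
#'     optionally `registry` CSV paths.}
#'   \item{terms}{Search terms to analyse (default both).}
#'   \item{exposure_metric}{`"new_deaths"` (default) or `"new_cases"`.}
#'   \item{baseline_start, baseline_end, pandemic_start, pandemic_end}{
#'     Study windows; the baseline must end the day before the pandemic
#'     window opens.}
#'   \item{seasonal_period}{Seasonal period for the counterfactual model
#'     (default 52).}
#'   \item{stratify}{Stratifying columns (default income group and
#'     pandemic year).}
#'   \item{seed}{Integer seed for every source of randomness.}
#'   \item{outdir}{Output directory.}
#' }
#'
#' @param config Path to a YAML file, or a list.
#' @return A validated configuration list with defaults filled in.
#' @export
read_run_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  defaults <- study_windows()
  cfg$terms <- cfg$terms %||% c("insomnia", "suicide")
  cfg$exposure_metric <- cfg$exposure_metric %||% "new_deaths"
  cfg$seasonal_period <- cfg$seasonal_period %||% 52
  cfg$stratify <- cfg$stratify %||% c("income_group", "pandemic_year")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$outdir <- cfg$outdir %||% "trendmediate_out"
  for (k in c("baseline_start", "baseline_end",
              "pandemic_start", "pandemic_end")) {
    cfg[[k]] <- as.Date(cfg[[k]] %||% defaults[[sub("_(start|end)$", "_\\1",
                                                    k)]])
  }
  if (cfg$baseline_end + 1 != cfg$pandemic_start) {
    abort(sprintf(
      "baseline must end the day before the pandemic window opens (got %s vs %s)",
      format(cfg$baseline_end), format(cfg$pandemic_start)))
  }
  if (!cfg$exposure_metric %in% c("new_deaths", "new_cases")) {
    abort("exposure_metric must be 'new_deaths' or 'new_cases'")
  }
  bad <- setdiff(cfg$terms, c("insomnia", "suicide"))
  if (length(bad) > 0) {
    abort(sprintf("unknown term(s): %s", paste(bad, collapse = ", ")))
  }
  if (is.null(cfg$synthetic) && is.null(cfg$paths)) {
    abort("config needs either a 'synthetic' scenario or input 'paths'")
  }
  cfg
}

config_windows <- function(cfg) {
  list(baseline_start = cfg$baseline_start, baseline_end = cfg$baseline_end,
       pandemic_start = cfg$pandemic_start, pandemic_end = cfg$pandemic_end)
}

stage <- function(name, detail, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed%s: %s", name,
                  if (nzchar(detail)) paste0(" (", detail, ")") else "",
                  conditionMessage(e)))
  })
  inform(sprintf("[%s] %s done in %.1fs", name, detail,
                 as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

load_pipeline_inputs <- function(cfg) {
  windows <- config_windows(cfg)
  if (!is.null(cfg$synthetic)) {
    args <- cfg$synthetic
    args$windows <- windows
    args$seed <- args$seed %||% cfg$seed
    truth <- do.call(scenario_truth, args)
    sim <- generate_pandemic_panel(truth, terms = cfg$terms)
    list(registry = sim$registry, search = sim$search,
         mobility = sim$mobility, deaths = sim$deaths, truth = truth)
  } else {
    p <- cfg$paths
    registry <- load_registry(p$registry)
    mobility <- read_mobility_csv(p$mobility)
    deaths <- read_deaths_csv(p$deaths, metric = cfg$exposure_metric)
    search <- purrr::map(cfg$terms, function(tm) {
      purrr::map(registry$country_code, function(cc) {
        f <- file.path(p$trends_dir, sprintf("trends_%s_%s.csv", cc, tm))
        if (!file.exists(f)) {
          warn(sprintf("missing Trends file for %s/%s; country skipped",
                       cc, tm))
          return(NULL)
        }
        read_trends_csv(f, country_code = cc, term = tm)
      })
    })
    list(registry = registry,
         search = dplyr::bind_rows(purrr::flatten(search)),
         mobility = mobility, deaths = deaths, truth = NULL)
  }
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes ingest (or simulation), per-series counterfactual excess
#' estimation, panel assembly and stratified mediation, writing all
#' artefacts to the output directory: `excess.csv`,
#' `panel_<term>.csv`, `results.csv`, `results.json`, a rendered
#' `results.txt` and a machine-readable `manifest.json` (package version,
#' configuration hash, row counts).  Given the same configuration and seed
#' the outputs are identical across runs.
#'
#' @param config Path to a YAML configuration or a list
#'   (see [read_run_config()]).
#' @param outdir Optional override of the configured output directory.
#' @return Invisibly, a list with `excess`, `panels`, `results`, `config`
#'   and the manifest.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- read_run_config(config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  windows <- config_windows(cfg)

  inputs <- stage("ingest", "", load_pipeline_inputs(cfg))

  keys <- dplyr::distinct(inputs$search, .data$country_code, .data$term)
  excess <- purrr::pmap(keys, function(country_code, term) {
    series <- dplyr::filter(inputs$search,
                            .data$country_code == !!country_code,
                            .data$term == !!term)
    stage("excess", paste(country_code, term, sep = "/"),
          estimate_excess(series, windows = windows,
                          m = cfg$seasonal_period))
  })
  excess <- dplyr::bind_rows(excess)
  readr::write_csv(excess, file.path(cfg$outdir, "excess.csv"),
                   progress = FALSE)

  panels <- list()
  results <- list()
  for (tm in cfg$terms) {
    ex_tm <- dplyr::filter(excess, .data$term == !!tm)
    panel <- stage("panel", tm, assemble_panel(
      inputs$registry, ex_tm, inputs$mobility, inputs$deaths,
      term = tm, exposure_metric = cfg$exposure_metric))
    readr::write_csv(panel, file.path(cfg$outdir,
                                      sprintf("panel_%s.csv", tm)),
                     progress = FALSE)
    panels[[tm]] <- panel
    results[[tm]] <- stage("mediate", tm,
                           run_mediation(panel, by = cfg$stratify))
  }
  results <- dplyr::bind_rows(results)
  readr::write_csv(results, file.path(cfg$outdir, "results.csv"),
                   progress = FALSE)
  jsonlite::write_json(results, file.path(cfg$outdir, "results.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(render_results(results),
             file.path(cfg$outdir, "results.txt"))

  manifest <- list(
    package = "trendmediate",
    version = as.character(utils::packageVersion("trendmediate")),
    config_hash = rlang::hash(cfg),
    seed = cfg$seed,
    n_series = nrow(keys),
    n_excess_weeks = nrow(excess),
    panel_rows = purrr::map_int(panels, nrow),
    result_rows = nrow(results)
  )
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(excess = excess, panels = panels, results = results,
                 config = cfg, manifest = manifest))
}

format_cell <- function(effect, value, digits_pm = 1) {
  ifelse(is.na(value), "NA",
         ifelse(effect == "proportion_mediated",
                sprintf(paste0("%.", digits_pm, "f"), value),
                sub("e([+-])0?(\\d+)", "e\\1\\2",
                    formatC(value, format = "e", digits = 1))))
}

#' Render stratified mediation results as an aligned text table
#'
#' Effect estimates and confidence limits are printed in scientific
#' notation with two significant digits; proportion-mediated rows in
#' percent with one decimal.  Empty strata appear as `NA` rows rather than
#' being omitted.
#'
#' @param results Results tibble from [run_mediation()].
#' @return A character vector of table lines (also usable with
#'   `writeLines()`).
#' @export
render_results <- function(results) {
  strat <- intersect(c("term", "income_group", "pandemic_year"),
                     names(results))
  df <- dplyr::mutate(
    results,
    Estimate = format_cell(.data$effect, .data$estimate),
    `95% CI` = ifelse(
      is.na(.data$lower95), "NA",
      paste(format_cell(.data$effect, .data$lower95), "to",
            format_cell(.data$effect, .data$upper95))),
    `P value` = ifelse(is.na(.data$p_value), "NA",
                       ifelse(.data$p_value < 0.001, "<.001",
                              sub("^0", "", sprintf("%.2f", .data$p_value))))
  )
  cols <- c(strat, "effect", "Estimate", "95% CI", "P value")
  m <- as.matrix(dplyr::mutate(df[cols],
                               dplyr::across(dplyr::everything(),
                                             as.character)))
  m[is.na(m)] <- "NA"
  m <- rbind(cols, m)
  widths <- apply(nchar(m), 2, max)
  apply(m, 1, function(r) {
    paste(mapply(formatC, r, width = widths, flag = "-"), collapse = "  ")
  })
}
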