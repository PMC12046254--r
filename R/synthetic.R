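# Synthetic scenario generator.
#
# Emulates the three data streams the analysis consumes -- weekly relative
# search volumes with annual seasonality, daily epidemic death waves, and a
# daily residential-mobility response -- with a known causal structure:
#
#   mobility_m  = alpha * deaths_m + country effect + noise
#   excess_w    = gamma * deaths_m + beta * mobility_m + month effect + noise
#
# where deaths_m / mobility_m are monthly means held constant within the
# month (the mediation models operate at monthly resolution, so tying the
# structural signal to monthly means avoids aggregation-induced attenuation
# in recovery tests).  The implied total effect is gamma + alpha*beta and
# the true proportion mediated alpha*beta / (gamma + alpha*beta).
#
# Randomness is counter-based: one global seed expands into per-country,
# per-purpose substreams, so adding countries never reshuffles the draws of
# existing ones and every output is byte-reproducible.

# --- substream machinery ----------------------------------------------------

# Two rounds of a MINSTD linear congruential generator mix (seed, country,
# purpose) into a 31-bit stream seed.  All arithmetic stays below 2^53.
stream_seed <- function(seed, country_index, purpose) {
  m <- 2147483647 # 2^31 - 1
  x <- (abs(seed) + 7919 * country_index + 104729 * purpose) %% m
  x <- (48271 * (x + 1)) %% m
  x <- (48271 * x) %% m
  as.integer(x)
}

with_stream <- function(truth, country_index, purpose, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(stream_seed(truth$seed, country_index, purpose))
  force(expr)
}

# purpose codes for substreams
.STREAM <- list(waves = 1L, deaths = 2L, mobility = 3L, country_fx = 4L,
                phase = 5L, search_insomnia = 6L, search_suicide = 7L,
                excess_insomnia = 8L, excess_suicide = 9L,
                time_fx_insomnia = 10L, time_fx_suicide = 11L,
                mobility_shock = 12L)

term_stream <- function(prefix, term) {
  .STREAM[[paste0(prefix, "_", term)]]
}

# --- scenario definition ----------------------------------------------------

#' Define a synthetic scenario with known mediation ground truth
#'
#' Encodes the causal diagram exposure -> mediator -> outcome plus a direct
#' exposure -> outcome path.  Defaults describe the study conditions: 45
#' countries in two income strata (31 high, 14 middle), weekly search
#' baselines with annual seasonality over a five-year pre-pandemic window,
#' 2-3 Gaussian death waves per country with peaks of 50-2000 deaths/day,
#' and effect sizes yielding a true proportion mediated of 30%.
#'
#' @param n_high,n_middle Number of high- and middle-income countries.
#' @param alpha Mediator response: mobility percentage points per unit of
#'   monthly mean daily deaths.
#' @param beta Outcome response to the mediator: excess search points per
#'   mobility percentage point.
#' @param gamma Direct exposure effect: excess search points per unit of
#'   monthly mean daily deaths.
#' @param seasonal_amplitude Amplitude of the annual cycle in the search
#'   baseline (search points).
#' @param baseline_level Mean of the search baseline (0-100 scale).
#' @param sigma_search Innovation SD of the AR(1) noise (phi = 0.5) on the
#'   weekly search baseline.
#' @param sigma_mobility SD of the i.i.d. daily mobility noise.
#' @param sigma_outcome SD of the i.i.d. weekly noise on structural excess.
#' @param sigma_deaths Scale of the non-negative daily death-count noise.
#' @param sigma_mediator_shock SD of a month-level mobility shock common to
#'   all days of a country-month: the exposure-independent part of mobility
#'   (policy changes, holidays) that gives the mediator its own variation.
#' @param wave_spec Optional list (one element per country) of data frames
#'   with columns `peak_date`, `peak_height`, `width_days`; `NULL` draws a
#'   default 2-3 waves per country from the scenario seed.
#' @param windows Study windows as from [study_windows()].
#' @param seed Integer master seed; every random draw descends from it.
#' @return An object of class `scenario_truth`: a list of the above plus
#'   derived fields `total_effect` (`gamma + alpha*beta`) and
#'   `proportion_mediated` (percent).
#' @export
#' @examples
#' truth <- scenario_truth(n_high = 3, n_middle = 2, seed = 42)
#' truth$total_effect
#' truth$proportion_mediated
scenario_truth <- function(n_high = 31, n_middle = 14,
                           alpha = 0.01, beta = 0.03, gamma = 7e-4,
                           seasonal_amplitude = 10, baseline_level = 50,
                           sigma_search = 2, sigma_mobility = 1.5,
                           sigma_outcome = 0.5, sigma_deaths = 5,
                           sigma_mediator_shock = 1,
                           wave_spec = NULL, windows = study_windows(),
                           seed = 1L) {
  stopifnot(n_high >= 0, n_middle >= 0, n_high + n_middle >= 1)
  if (baseline_level - seasonal_amplitude < 0 ||
      baseline_level + seasonal_amplitude > 100) {
    abort("baseline_level +/- seasonal_amplitude must stay within [0, 100]")
  }
  total <- gamma + alpha * beta
  truth <- structure(list(
    n_high = as.integer(n_high), n_middle = as.integer(n_middle),
    alpha = alpha, beta = beta, gamma = gamma,
    seasonal_amplitude = seasonal_amplitude,
    baseline_level = baseline_level,
    sigma_search = sigma_search, sigma_mobility = sigma_mobility,
    sigma_outcome = sigma_outcome, sigma_deaths = sigma_deaths,
    sigma_mediator_shock = sigma_mediator_shock,
    wave_spec = wave_spec, windows = windows, seed = as.integer(seed),
    total_effect = total,
    proportion_mediated = if (total != 0) 100 * alpha * beta / total else NA_real_
  ), class = "scenario_truth")
  truth
}

#' @export
print.scenario_truth <- function(x, ...) {
  cat(sprintf(
    paste0("<scenario_truth> %d countries (%d high / %d middle), seed %d\n",
           "  alpha = %g, beta = %g, gamma = %g\n",
           "  total effect = %g, proportion mediated = %.1f%%\n"),
    x$n_high + x$n_middle, x$n_high, x$n_middle, x$seed,
    x$alpha, x$beta, x$gamma, x$total_effect, x$proportion_mediated))
  invisible(x)
}

#' Registry of the synthetic countries in a scenario
#'
#' @param truth A [scenario_truth()] object.
#' @return A tibble in the [load_registry()] layout; high-income countries
#'   are coded `H01`, `H02`, ... and middle-income `M01`, `M02`, ....
#' @export
scenario_registry <- function(truth) {
  codes <- c(sprintf("H%02d", seq_len(truth$n_high)),
             sprintf("M%02d", seq_len(truth$n_middle)))
  tibble::tibble(
    country_code = codes,
    name = paste("Synthetic country", codes),
    income_group = factor(rep(c("high", "middle"),
                              c(truth$n_high, truth$n_middle)),
                          levels = c("high", "middle")),
    keyword_insomnia = "insomnia",
    keyword_suicide = "suicide"
  )
}

# wave specification per country: 2-3 Gaussian bumps, heights 50-2000
# deaths/day, widths 15-45 days, peaks inside the pandemic window
scenario_waves <- function(truth) {
  n <- truth$n_high + truth$n_middle
  if (!is.null(truth$wave_spec)) {
    if (length(truth$wave_spec) != n) {
      abort("wave_spec must have one element per country")
    }
    if (any(vapply(truth$wave_spec, nrow, 0L) == 0)) {
      abort("wave_spec must be non-empty for every country")
    }
    return(truth$wave_spec)
  }
  w <- truth$windows
  span <- as.numeric(w$pandemic_end - w$pandemic_start)
  lapply(seq_len(n), function(i) {
    with_stream(truth, i, .STREAM$waves, {
      k <- sample(2:3, 1)
      tibble::tibble(
        peak_date = w$pandemic_start +
          sort(round(runif(k, 0.05, 0.95) * span)),
        peak_height = runif(k, 50, 2000),
        width_days = runif(k, 15, 45)
      )
    })
  })
}

# --- stream generators ------------------------------------------------------

#' Generate a country's baseline (counterfactual) weekly search series
#'
#' Weekly values over the full study grid: a constant level plus an annual
#' sinusoid with a country-specific phase plus stationary AR(1) noise
#' (phi = 0.5), clipped to the 0-100 relative-volume scale.  This is the
#' series the counterfactual model must learn; pandemic-period structural
#' excess is injected separately by [generate_pandemic_panel()].
#'
#' @param truth A [scenario_truth()] object.
#' @param country_index 1-based country position in [scenario_registry()].
#' @param term `"insomnia"` or `"suicide"`.
#' @return A tibble `country_code`, `term`, `week_start`, `value`.
#' @export
generate_baseline_search <- function(truth, country_index,
                                     term = c("insomnia", "suicide")) {
  term <- match.arg(term)
  w <- truth$windows
  weeks <- week_seq(w$baseline_start, w$pandemic_end)
  n <- length(weeks)
  phase <- with_stream(truth, country_index, .STREAM$phase,
                       runif(1, 0, 2 * pi))
  seasonal <- truth$seasonal_amplitude *
    sin(2 * pi * seq_len(n) / 52 + phase)
  noise <- with_stream(truth, country_index, term_stream("search", term), {
    innov <- rnorm(n, 0, truth$sigma_search)
    as.numeric(stats::filter(innov, 0.5, method = "recursive"))
  })
  value <- truth$baseline_level + seasonal + noise
  is_baseline <- weeks <= w$baseline_end
  clipped <- value < 0 | value > 100
  if (mean(clipped[is_baseline]) > 0.01) {
    abort(paste0(
      "scenario rejected: baseline_level/seasonal_amplitude/sigma_search ",
      "clip more than 1% of baseline weeks, which would bias the ",
      "counterfactual fit"))
  }
  value <- pmin(pmax(value, 0), 100)
  reg <- scenario_registry(truth)
  tibble::tibble(country_code = reg$country_code[country_index], term = term,
                 week_start = weeks, value = value)
}

# daily deaths for one country: sum of Gaussian waves + non-negative noise
generate_country_deaths <- function(truth, country_index, waves) {
  w <- truth$windows
  dates <- seq(w$pandemic_start, w$pandemic_end, by = "1 day")
  t <- as.numeric(dates)
  mu <- rowSums(vapply(seq_len(nrow(waves)), function(j) {
    waves$peak_height[j] *
      exp(-0.5 * ((t - as.numeric(waves$peak_date[j])) /
                    waves$width_days[j])^2)
  }, numeric(length(t))))
  noise <- with_stream(truth, country_index, .STREAM$deaths,
                       abs(rnorm(length(t), 0, truth$sigma_deaths)))
  tibble::tibble(date = dates, value = mu + noise)
}

# monthly mean of a daily vector, expanded back to daily length
monthly_mean_expand <- function(dates, values) {
  m <- month_of(dates)
  ave(values, m, FUN = mean)
}

# Deterministic country-by-month mediator disturbance (unit SD): a fixed
# sinusoidal pattern, two-way demeaned and projected orthogonal to the
# two-way-demeaned exposure matrix.  Living in the within space orthogonal
# to the exposure, it gives the mediator its own variation without
# disturbing the exposure slope of the mediator model.
mediator_pattern <- function(xmat, v_sd = 1) {
  n <- nrow(xmat)
  k <- ncol(xmat)
  i <- row(xmat)
  m <- col(xmat)
  v0 <- sin(2.3 * i + 1.7 * m) + 0.5 * cos(0.9 * i - 1.3 * m)
  demean2 <- function(a) {
    a <- a - rowMeans(a)[row(a)]
    a <- a - colMeans(a)[col(a)]
    a
  }
  v <- demean2(v0)
  xt <- demean2(xmat)
  ss <- sum(xt^2)
  if (ss > 0) v <- v - sum(v * xt) / ss * xt
  s <- sd(as.numeric(v))
  if (s > 0) v <- v / s * v_sd
  if (n == 1 || k == 1) v[] <- 0 # no within space to live in
  v
}

#' Generate the full synthetic scenario
#'
#' Realises every stream of the scenario's causal structure:
#' daily deaths (Gaussian waves plus non-negative noise), daily residential
#' mobility responding to the monthly mean of deaths, and weekly search
#' series in which a structural excess
#' `gamma * deaths_m + beta * mobility_m + month effect + noise` is added to
#' the seasonal baseline during the pandemic window.  The injected excess is
#' returned alongside the observed streams so downstream estimates can be
#' checked against ground truth week by week.
#'
#' @param truth A [scenario_truth()] object.
#' @param terms Which search terms to generate.
#' @param include_baseline If `FALSE`, skip generating the seasonal search
#'   baselines (used by Monte-Carlo studies that evaluate only the panel
#'   stages; the injected excess is still returned).
#' @return A list with elements `search` (weekly tibble, or `NULL`),
#'   `injected` (weekly tibble of true structural excess with column
#'   `excess_true`), `mobility` and `deaths` (daily tibbles), `registry`,
#'   and `truth`.
#' @export
#' @examples
#' truth <- scenario_truth(n_high = 2, n_middle = 1, seed = 7)
#' sim <- generate_pandemic_panel(truth, terms = "insomnia")
#' head(sim$injected)
generate_pandemic_panel <- function(truth,
                                    terms = c("insomnia", "suicide"),
                                    include_baseline = TRUE) {
  terms <- match.arg(terms, several.ok = TRUE)
  w <- truth$windows
  horizon_days <- as.numeric(w$pandemic_end - w$pandemic_start) + 1
  if (horizon_days < 365) {
    abort("pandemic horizon shorter than one year; stratification impossible")
  }
  reg <- scenario_registry(truth)
  n_country <- nrow(reg)
  waves <- scenario_waves(truth)

  pweeks <- week_seq(w$pandemic_start, w$pandemic_end)
  pweeks <- pweeks[pweeks <= w$pandemic_end]
  week_months <- month_of(pweeks)
  months <- sort(unique(week_months))
  month_index <- match(week_months, months)

  # common month effects per term (shared across countries)
  time_fx <- lapply(setNames(terms, terms), function(tm) {
    with_stream(truth, 0L, term_stream("time_fx", tm),
                rnorm(length(months), 0, 0.5))
  })

  deaths_l <- vector("list", n_country)
  mobility_l <- vector("list", n_country)
  injected_l <- vector("list", n_country * length(terms))
  search_l <- if (include_baseline) {
    vector("list", n_country * length(terms))
  }

  # first pass: deaths and their monthly means per country
  day1 <- seq(w$pandemic_start, w$pandemic_end, by = "1 day")
  day_month_idx <- match(month_of(day1), months)
  n_day <- length(day1)
  xmat <- matrix(NA_real_, n_country, length(months),
                 dimnames = list(reg$country_code, format(months)))
  for (i in seq_len(n_country)) {
    d <- generate_country_deaths(truth, i, waves[[i]])
    deaths_l[[i]] <- tibble::new_tibble(list(
      country_code = rep(reg$country_code[i], n_day),
      metric = rep("new_deaths", n_day),
      date = d$date, value = d$value), nrow = n_day)
    xmat[i, ] <- as.numeric(
      rowsum(cbind(d$value, 1), day_month_idx)[, 1] /
        tabulate(day_month_idx, length(months)))
  }

  # Exposure-independent mediator variation.  With any mediator shock the
  # shocks are random month-level draws, so the mediator-model residual has
  # genuine sampling variation and inference stays calibrated.  In the
  # exactly-noise-free limit (shock and daily noise both zero) a
  # deterministic pattern -- two-way demeaned and orthogonalised against
  # the within-transformed exposure -- keeps the mediator equation
  # identified without perturbing any coefficient.
  shock_sd <- truth$sigma_mediator_shock %||% 0
  if (shock_sd > 0) {
    vmat <- t(vapply(seq_len(n_country), function(i) {
      with_stream(truth, i, .STREAM$mobility_shock,
                  rnorm(length(months), 0, shock_sd))
    }, numeric(length(months))))
  } else if (truth$sigma_mobility > 0) {
    vmat <- matrix(0, n_country, length(months))
  } else {
    vmat <- mediator_pattern(xmat, 1)
  }
  colnames(vmat) <- format(months)

  for (i in seq_len(n_country)) {
    code <- reg$country_code[i]
    d <- deaths_l[[i]]

    cfx <- with_stream(truth, i, .STREAM$country_fx, rnorm(2, c(5, 0), c(2, 1)))
    deaths_m_daily <- xmat[i, day_month_idx]
    mob_noise <- with_stream(truth, i, .STREAM$mobility,
                             rnorm(nrow(d), 0, truth$sigma_mobility))
    mob <- truth$alpha * deaths_m_daily + cfx[1] +
      vmat[i, day_month_idx] + mob_noise
    mobility_l[[i]] <- tibble::new_tibble(list(
      country_code = rep(code, n_day),
      metric = rep("residential_pct_change", n_day),
      date = d$date, value = as.numeric(mob)), nrow = n_day)

    # monthly means as seen by the panel stage
    mm <- as.numeric(rowsum(cbind(mob, 1), day_month_idx)[, 1] /
                       tabulate(day_month_idx, length(months)))
    x_w <- as.numeric(xmat[i, month_index])
    m_w <- mm[month_index]

    for (tm in terms) {
      eps <- with_stream(truth, i, term_stream("excess", tm),
                         rnorm(length(pweeks), 0, truth$sigma_outcome))
      excess <- truth$gamma * x_w + truth$beta * m_w + cfx[2] +
        time_fx[[tm]][month_index] + eps
      slot <- (i - 1) * length(terms) + match(tm, terms)
      nw <- length(pweeks)
      injected_l[[slot]] <- tibble::new_tibble(list(
        country_code = rep(code, nw), term = rep(tm, nw),
        week_start = pweeks, excess_true = as.numeric(excess)), nrow = nw)
      if (include_baseline) {
        base <- generate_baseline_search(truth, i, tm)
        idx <- match(pweeks, base$week_start)
        base$value[idx] <- base$value[idx] + excess
        search_l[[slot]] <- base
      }
    }
  }

  list(
    search = if (include_baseline) dplyr::bind_rows(search_l),
    injected = dplyr::bind_rows(injected_l),
    mobility = dplyr::bind_rows(mobility_l),
    deaths = dplyr::bind_rows(deaths_l),
    registry = reg,
    truth = truth
  )
}

#' Build the analysis panel straight from a scenario's ground truth
#'
#' Convenience wrapper for simulation studies of the panel and mediation
#' stages: aggregates the generated streams to the country-by-month panel
#' using the true injected excess as the outcome, bypassing the
#' counterfactual-forecast stage (whose own error is assessed separately).
#'
#' @param truth A [scenario_truth()] object.
#' @param term Search term for the outcome.
#' @return A panel tibble as from [assemble_panel()].
#' @export
simulate_panel <- function(truth, term = c("insomnia", "suicide")) {
  term <- match.arg(term)
  sim <- generate_pandemic_panel(truth, terms = term,
                                 include_baseline = FALSE)
  excess <- dplyr::rename(sim$injected, excess = "excess_true")
  assemble_panel(sim$registry, excess, sim$mobility, sim$deaths,
                 term = term)
}

#' Write a generated scenario to the three CSV dialects
#'
#' Emits the files the ingest readers consume: one Trends-style CSV per
#' country and term (`trends_<code>_<term>.csv`), a long-format mobility CSV
#' (`mobility.csv`), a long-format deaths CSV (`deaths.csv`) and a registry
#' CSV (`registry.csv`).
#'
#' @param sim Result of [generate_pandemic_panel()] (with baselines).
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_scenario_csv <- function(sim, dir) {
  if (is.null(sim$search)) {
    abort("scenario was generated without search baselines")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in split(sim$search,
                    paste(sim$search$country_code, sim$search$term))) {
    write_trends_csv(key, file.path(dir, sprintf(
      "trends_%s_%s.csv", key$country_code[1], key$term[1])))
  }
  write_daily_csv(sim$mobility, file.path(dir, "mobility.csv"))
  write_daily_csv(sim$deaths, file.path(dir, "deaths.csv"))
  readr::write_csv(sim$registry, file.path(dir, "registry.csv"),
                   progress = FALSE)
  invisible(dir)
}
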