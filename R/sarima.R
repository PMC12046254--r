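# Counterfactual engine: automatic seasonal ARIMA baseline selection,
# forecasting with normal-theory intervals, and weekly excess.
#
# Order selection follows the stepwise automatic procedure familiar from
# forecasting practice: the seasonal difference order D comes from a
# seasonal-strength heuristic, the ordinary difference order d from
# successive KPSS level-stationarity tests applied after seasonal
# differencing, and (p, q, P, Q) from an AICc-guided neighbourhood search
# started from four standard models.  AICc values are only compared between
# models sharing the same (d, D), which the search guarantees by fixing
# (d, D) up front.

# KPSS level-stationarity statistic with a Bartlett-window long-run
# variance (bandwidth 4*(n/100)^(1/4)).  5% critical value 0.463.
kpss_statistic <- function(x) {
  n <- length(x)
  e <- x - mean(x)
  s <- cumsum(e)
  l <- trunc(4 * (n / 100)^0.25)
  lrv <- sum(e^2) / n
  if (l > 0) {
    for (k in seq_len(l)) {
      lrv <- lrv + 2 * (1 - k / (l + 1)) *
        sum(e[1:(n - k)] * e[(k + 1):n]) / n
    }
  }
  sum(s^2) / (n^2 * lrv)
}

# number of successive ordinary differences needed for KPSS level
# stationarity at the 5% level (capped at max_d)
choose_d <- function(x, max_d = 2) {
  d <- 0
  while (d < max_d && length(x) > 10 && var(x) > 0 &&
         kpss_statistic(x) > 0.463) {
    x <- diff(x)
    d <- d + 1
  }
  d
}

# seasonal difference order via the seasonal-strength heuristic:
# strength = max(0, 1 - var(remainder)/var(seasonal + remainder)) from an
# STL decomposition; strength above 0.64 calls for one seasonal difference.
choose_D <- function(x, m) {
  if (m <= 1 || length(x) < 2 * m + 5) return(0L)
  dec <- stats::stl(ts(x, frequency = m), s.window = "periodic")$time.series
  rem <- dec[, "remainder"]
  strength <- max(0, 1 - var(rem) / var(dec[, "seasonal"] + rem))
  as.integer(strength > 0.64)
}

# corrected AIC for a fitted arima object
arima_aicc <- function(fit) {
  k <- length(fit$coef) + 1 # + sigma^2
  n <- fit$nobs
  if (n - k - 1 <= 0) return(Inf)
  fit$aic + 2 * k * (k + 1) / (n - k - 1)
}

# fit one candidate; NULL on failure.  Constant handling: a mean term when
# d + D = 0, a linear drift regressor when d + D = 1, none otherwise.
fit_sarima_candidate <- function(x, p, d, q, P, D, Q, m, constant) {
  n <- length(x)
  args <- list(x = x, order = c(p, d, q),
               optim.control = list(maxit = 500))
  if (m > 1) args$seasonal <- list(order = c(P, D, Q), period = m)
  if (d + D == 0) {
    args$include.mean <- constant
  } else if (d + D == 1 && constant) {
    args$xreg <- matrix(seq_len(n), dimnames = list(NULL, "drift"))
    args$include.mean <- FALSE
  } else {
    args$include.mean <- FALSE
  }
  fit <- tryCatch(suppressWarnings(do.call(stats::arima, args)),
                  error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  if (anyNA(fit$coef) || !is.finite(fit$loglik)) return(NULL)
  fit
}

new_sarima_spec <- function(p, d, q, P, D, Q, m, constant, aicc, fit, x) {
  structure(list(order = c(p = p, d = d, q = q),
                 seasonal = c(P = P, D = D, Q = Q), m = m,
                 include_constant = constant, aicc = aicc,
                 fit = fit, train = x),
            class = "sarima_spec")
}

#' @export
print.sarima_spec <- function(x, ...) {
  cat(sprintf("sARIMA(%d,%d,%d)(%d,%d,%d)[%d]%s, AICc = %.2f\n",
              x$order[1], x$order[2], x$order[3],
              x$seasonal[1], x$seasonal[2], x$seasonal[3], x$m,
              if (x$include_constant) " with constant" else "",
              x$aicc))
  invisible(x)
}

series_values <- function(series) {
  if (is.numeric(series)) return(as.numeric(series))
  assert_cols(series, "value", "weekly series")
  series$value
}

#' Select a seasonal ARIMA baseline model by stepwise AICc search
#'
#' Chooses the seasonal difference order by a seasonal-strength heuristic
#' (strength > 0.64), the ordinary difference order by successive KPSS
#' tests on the seasonally differenced series, and the remaining orders by
#' a stepwise neighbourhood search minimising AICc, started from the four
#' standard models (2,d,2)(1,D,1), (0,d,0)(0,D,0), (1,d,0)(1,D,0) and
#' (0,d,1)(0,D,1).  The search is bounded by `max_p`/`max_q` (5) and
#' `max_P`/`max_Q` (2); candidates that fail to converge are skipped and
#' recorded in the returned fit log.
#'
#' @param series A weekly tibble with a `value` column, or a numeric vector
#'   (the pre-pandemic baseline segment).
#' @param m Seasonal period in observations (52 for weekly data with annual
#'   seasonality).
#' @param max_p,max_q,max_P,max_Q Search bounds on the orders.
#' @param trace If `TRUE`, print each candidate and its AICc.
#' @return A `sarima_spec` object: orders, seasonal orders, period,
#'   constant flag, the winning AICc, and the fitted model (reused by
#'   [forecast_expected()] when forecasting the same segment).
#' @export
select_sarima <- function(series, m = 52, max_p = 5, max_q = 5,
                          max_P = 2, max_Q = 2, trace = FALSE) {
  x <- series_values(series)
  if (length(x) < 2 * m) {
    abort(sprintf("baseline segment has %d observations; need at least 2*m = %d",
                  length(x), 2 * m))
  }
  if (var(x) == 0) abort("degenerate series: zero variance")

  D <- if (m > 1) choose_D(x, m) else 0L
  xd <- if (D > 0) diff(x, lag = m) else x
  d <- choose_d(xd)
  const_ok <- (d + D) <= 1

  cache <- new.env(parent = emptyenv())
  log_lines <- character()
  eval_cand <- function(p, q, P, Q, constant) {
    if (p < 0 || q < 0 || P < 0 || Q < 0 ||
        p > max_p || q > max_q || P > max_P || Q > max_Q ||
        (constant && !const_ok)) {
      return(Inf)
    }
    if (m <= 1 && (P > 0 || Q > 0)) return(Inf)
    key <- paste(p, q, P, Q, constant, sep = "-")
    if (!is.null(cache[[key]])) return(cache[[key]]$aicc)
    fit <- fit_sarima_candidate(x, p, d, q, P, D, Q, m, constant)
    aicc <- if (is.null(fit)) Inf else arima_aicc(fit)
    cache[[key]] <- list(fit = fit, aicc = aicc)
    log_lines <<- c(log_lines, sprintf(
      "(%d,%d,%d)(%d,%d,%d)[%d]%s: %s", p, d, q, P, D, Q, m,
      if (constant) "+c" else "",
      if (is.finite(aicc)) sprintf("AICc=%.3f", aicc) else "failed"))
    if (trace) message(tail(log_lines, 1))
    aicc
  }

  sP <- function(k) if (m > 1) k else 0
  starts <- list(c(2, 2, sP(1), sP(1)), c(0, 0, 0, 0),
                 c(1, 0, sP(1), 0), c(0, 1, 0, sP(1)))
  best <- NULL
  best_aicc <- Inf
  for (s in starts) {
    a <- eval_cand(s[1], s[2], s[3], s[4], const_ok)
    if (a < best_aicc) {
      best_aicc <- a
      best <- c(s, const_ok)
    }
  }
  if (!is.finite(best_aicc)) {
    abort(paste0("all starting seasonal ARIMA fits failed to converge:\n",
                 paste(log_lines, collapse = "\n")))
  }

  repeat {
    p <- best[1]; q <- best[2]; P <- best[3]; Q <- best[4]
    constant <- as.logical(best[5])
    moves <- list(
      c(p - 1, q, P, Q, constant), c(p + 1, q, P, Q, constant),
      c(p, q - 1, P, Q, constant), c(p, q + 1, P, Q, constant),
      c(p - 1, q - 1, P, Q, constant), c(p + 1, q + 1, P, Q, constant),
      c(p, q, P - 1, Q, constant), c(p, q, P + 1, Q, constant),
      c(p, q, P, Q - 1, constant), c(p, q, P, Q + 1, constant),
      c(p, q, P - 1, Q - 1, constant), c(p, q, P + 1, Q + 1, constant),
      c(p, q, P, Q, !constant)
    )
    improved <- FALSE
    for (mv in moves) {
      a <- eval_cand(mv[1], mv[2], mv[3], mv[4], as.logical(mv[5]))
      if (a < best_aicc - 1e-8) {
        best_aicc <- a
        best <- mv
        improved <- TRUE
      }
    }
    if (!improved) break
  }

  key <- paste(best[1], best[2], best[3], best[4], as.logical(best[5]),
               sep = "-")
  win <- cache[[key]]
  spec <- new_sarima_spec(best[1], d, best[2], best[3], D, best[4], m,
                          as.logical(best[5]), best_aicc, win$fit, x)
  attr(spec, "fit_log") <- log_lines
  spec
}

#' Forecast the counterfactual expected series
#'
#' Produces point forecasts and normal-theory 95% intervals from a seasonal
#' ARIMA specification fitted to the baseline segment.  If `spec` carries a
#' model fitted to exactly this segment (as returned by [select_sarima()]
#' on the same data) that fit is reused; otherwise the specified orders are
#' refit to `series`.
#'
#' @param series Baseline weekly tibble (columns `week_start`, `value`) or
#'   numeric vector.
#' @param spec A `sarima_spec`, or a list with elements `order`,
#'   `seasonal`, `m`, `include_constant`.
#' @param horizon Number of weeks to forecast.
#' @return A tibble with `week_start` (continuing the baseline grid when
#'   dates are available, otherwise the step index), `expected`, `lower95`,
#'   `upper95`.
#' @export
forecast_expected <- function(series, spec, horizon) {
  stopifnot(horizon >= 1)
  x <- series_values(series)
  fit <- spec$fit
  if (is.null(fit) || !identical(as.numeric(spec$train), as.numeric(x))) {
    fit <- fit_sarima_candidate(
      x, spec$order[1], spec$order[2], spec$order[3],
      spec$seasonal[1], spec$seasonal[2], spec$seasonal[3],
      spec$m %||% 1, isTRUE(spec$include_constant))
    if (is.null(fit)) {
      abort("seasonal ARIMA refit failed on the supplied baseline segment")
    }
  }
  newxreg <- if (!is.null(fit$xreg) || "drift" %in% names(fit$coef)) {
    matrix(length(x) + seq_len(horizon), dimnames = list(NULL, "drift"))
  }
  pr <- predict(fit, n.ahead = horizon, newxreg = newxreg)
  expected <- as.numeric(pr$pred)
  se <- as.numeric(pr$se)
  week_start <- if (!is.numeric(series) && "week_start" %in% names(series)) {
    max(series$week_start) + 7 * seq_len(horizon)
  } else {
    length(x) + seq_len(horizon)
  }
  tibble::tibble(week_start = week_start, expected = expected,
                 lower95 = expected - 1.96 * se,
                 upper95 = expected + 1.96 * se)
}

#' Weekly excess: observed minus expected
#'
#' @param observed Pandemic-segment weekly tibble (`week_start`, `value`,
#'   optionally `country_code`, `term`).
#' @param forecast Counterfactual tibble from [forecast_expected()] on the
#'   same weekly grid.
#' @return A tibble `country_code`, `term`, `week_start`, `observed`,
#'   `expected`, `lower95`, `upper95`, `excess`; excess is never clipped.
#' @export
compute_excess <- function(observed, forecast) {
  assert_cols(observed, c("week_start", "value"), "observed series")
  assert_cols(forecast, c("week_start", "expected"), "forecast")
  if (nrow(observed) != nrow(forecast) ||
      !all(observed$week_start == forecast$week_start)) {
    off <- observed$week_start[
      !(observed$week_start %in% forecast$week_start)]
    if (length(off) == 0) {
      off <- forecast$week_start[
        !(forecast$week_start %in% observed$week_start)]
    }
    abort(sprintf("observed and forecast dates differ; first mismatch: %s",
                  format(off[1])))
  }
  obs_val <- observed$value
  exp_val <- forecast$expected
  tibble::tibble(
    country_code = (observed[["country_code"]] %||% NA_character_)[1],
    term = (observed[["term"]] %||% NA_character_)[1],
    week_start = observed$week_start,
    observed = obs_val,
    expected = exp_val,
    lower95 = forecast[["lower95"]] %||% NA_real_,
    upper95 = forecast[["upper95"]] %||% NA_real_,
    excess = obs_val - exp_val
  )
}

#' Full counterfactual-excess pipeline for one weekly series
#'
#' Splits the series at the baseline/pandemic boundary, selects (or takes)
#' a seasonal ARIMA specification on the baseline segment, forecasts the
#' pandemic horizon and returns the weekly excess table.
#'
#' @param series Weekly tibble for one country and term.
#' @param windows Study windows as from [study_windows()].
#' @param m Seasonal period (52 for weekly data).
#' @param spec Optional pre-chosen `sarima_spec`; `NULL` runs
#'   [select_sarima()].
#' @param ... Passed to [select_sarima()].
#' @return The excess tibble from [compute_excess()], with the chosen spec
#'   attached as attribute `"spec"`.
#' @export
estimate_excess <- function(series, windows = study_windows(), m = 52,
                            spec = NULL, ...) {
  assert_cols(series, c("week_start", "value"), "weekly series")
  base <- dplyr::filter(series, .data$week_start <= windows$baseline_end)
  pand <- dplyr::filter(series,
                        .data$week_start >= windows$pandemic_start &
                          .data$week_start <= windows$pandemic_end)
  if (nrow(pand) == 0) abort("no pandemic-period observations in series")
  if (is.null(spec)) spec <- select_sarima(base, m = m, ...)
  fc <- forecast_expected(base, spec, horizon = nrow(pand))
  fc$week_start <- pand$week_start # same weekly grid by construction
  out <- compute_excess(pand, fc)
  attr(out, "spec") <- spec
  out
}
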