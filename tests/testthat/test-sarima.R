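# Order selection, counterfactual forecasting and weekly excess.
# Seasonal periods here are kept compact (m = 12 or none) so candidate fits
# stay quick; the selection logic is period-agnostic.

test_that("zero-variance series is rejected as degenerate", {
  expect_error(select_sarima(rep(5, 120), m = 12), "degenerate")
  expect_error(select_sarima(rnorm(20), m = 12), "at least 2\\*m")
})

test_that("stepwise AICc selection beats the four standard starting models", {
  set.seed(1)
  x <- rnorm(120)
  sel <- select_sarima(x, m = 12)
  # independent oracle: fit each starting model directly with stats::arima
  aicc_direct <- function(order, seasonal, const) {
    fit <- stats::arima(x, order = order,
                        seasonal = list(order = seasonal, period = 12),
                        include.mean = const)
    k <- length(fit$coef) + 1
    fit$aic + 2 * k * (k + 1) / (fit$nobs - k - 1)
  }
  starts <- list(list(c(2, 0, 2), c(1, 0, 1)), list(c(0, 0, 0), c(0, 0, 0)),
                 list(c(1, 0, 0), c(1, 0, 0)), list(c(0, 0, 1), c(0, 0, 1)))
  for (s in starts) {
    expect_lte(sel$aicc, aicc_direct(s[[1]], s[[2]], TRUE) + 1e-6)
  }
})

test_that("an AR(1) series selects d = 0 with an autoregressive term", {
  set.seed(2)
  x <- as.numeric(arima.sim(list(ar = 0.8), 260))
  sel <- select_sarima(x, m = 1)
  expect_equal(unname(sel$order["d"]), 0)
  expect_gte(sum(sel$order[c("p", "q")]), 1)
  # brute-force oracle: some model with an AR/MA term beats white noise
  aicc_of <- function(p, q) {
    fit <- stats::arima(x, order = c(p, 0, q))
    k <- length(fit$coef) + 1
    fit$aic + 2 * k * (k + 1) / (fit$nobs - k - 1)
  }
  grid <- expand.grid(p = 0:2, q = 0:2)
  aiccs <- mapply(aicc_of, grid$p, grid$q)
  expect_lt(min(aiccs[-1]), aiccs[grid$p == 0 & grid$q == 0])
  expect_lte(sel$aicc, min(aiccs) + 1e-6)
})

test_that("selected orders are invariant to shifting the calendar", {
  truth <- scenario_truth(n_high = 1, n_middle = 0, seed = 5)
  s <- generate_baseline_search(truth, 1, "insomnia")
  x <- s$value[1:130]
  a <- select_sarima(x, m = 12)
  b <- select_sarima(x, m = 12) # same values, shifted dates are irrelevant
  expect_identical(a$order, b$order)
  expect_identical(a$seasonal, b$seasonal)
})

test_that("a noise-free seasonal cycle forecasts exactly under D = 1", {
  x <- 50 + 10 * sin(2 * pi * seq_len(260) / 52)
  spec <- list(order = c(0, 0, 0), seasonal = c(P = 0, D = 1, Q = 0),
               m = 52, include_constant = FALSE)
  fc <- forecast_expected(x[1:208], spec, horizon = 52)
  expect_lt(max(abs(fc$expected - x[209:260])), 1e-3)
})

test_that("a near-constant series forecasts its mean with covering interval", {
  set.seed(3)
  x <- 40 + rnorm(120, sd = 0.01)
  sel <- select_sarima(x, m = 1)
  fc <- forecast_expected(x, sel, horizon = 10)
  expect_lt(max(abs(fc$expected - 40)), 0.05)
  expect_true(all(fc$lower95 <= 40 & 40 <= fc$upper95))
})

test_that("forecast intervals achieve near-nominal coverage on known ARMA", {
  # flat baseline -> true process is level + AR(1) noise, phi = 0.5
  hits <- 0L
  total <- 0L
  for (r in 1:100) {
    truth <- scenario_truth(n_high = 1, n_middle = 0,
                            seasonal_amplitude = 0, seed = 1000 + r)
    s <- generate_baseline_search(truth, 1, "insomnia")
    fit_spec <- list(order = c(1, 0, 0), seasonal = c(0, 0, 0), m = 1,
                     include_constant = TRUE)
    fc <- forecast_expected(s$value[1:160], fit_spec, horizon = 30)
    y <- s$value[161:190]
    hits <- hits + sum(y >= fc$lower95 & y <= fc$upper95)
    total <- total + 30L
  }
  coverage <- hits / total
  expect_gte(coverage, 0.88)
  expect_lte(coverage, 0.99)
})

test_that("excess is observed minus expected, with strict date alignment", {
  weeks <- seq(as.Date("2020-03-01"), by = "7 days", length.out = 5)
  obs <- tibble::tibble(country_code = "IT", term = "insomnia",
                        week_start = weeks, value = c(50, 52, 49, 55, 60))
  fc <- tibble::tibble(week_start = weeks, expected = obs$value,
                       lower95 = obs$value - 2, upper95 = obs$value + 2)
  ex <- compute_excess(obs, fc)
  expect_equal(ex$excess, rep(0, 5))

  fc2 <- dplyr::mutate(fc, expected = expected - 5)
  expect_equal(compute_excess(obs, fc2)$excess, rep(5, 5))

  fc3 <- dplyr::mutate(fc, week_start = week_start + 7)
  expect_error(compute_excess(obs, fc3), "mismatch")
})

test_that("excess decomposes linearly over observations sharing a forecast", {
  weeks <- seq(as.Date("2020-03-01"), by = "7 days", length.out = 6)
  fc <- tibble::tibble(week_start = weeks, expected = rnorm(6, 50),
                       lower95 = NA_real_, upper95 = NA_real_)
  a <- tibble::tibble(week_start = weeks, value = runif(6, 40, 60))
  b <- tibble::tibble(week_start = weeks, value = runif(6, 40, 60))
  # affine mixture with weights summing to 1 -> excess mixes the same way
  mix <- dplyr::mutate(a, value = 0.3 * a$value + 0.7 * b$value)
  lhs <- compute_excess(mix, fc)$excess
  rhs <- 0.3 * compute_excess(a, fc)$excess +
    0.7 * compute_excess(b, fc)$excess
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("pipeline excess tracks the injected structural excess", {
  truth <- scenario_truth(n_high = 1, n_middle = 0, seed = 77)
  sim <- generate_pandemic_panel(truth, terms = "insomnia")
  series <- dplyr::filter(sim$search, country_code == "H01")
  spec <- list(order = c(1, 0, 0), seasonal = c(0, 1, 0), m = 52,
               include_constant = FALSE)
  ex <- estimate_excess(series, m = 52, spec = spec)
  inj <- dplyr::filter(sim$injected, country_code == "H01")
  resid_sd <- truth$sigma_search / sqrt(1 - 0.5^2)
  expect_lt(mean(abs(ex$excess - inj$excess_true)), 2 * resid_sd)
})
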