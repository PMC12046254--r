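test_that("scenario truth derives total effect and proportion mediated", {
  truth <- scenario_truth(alpha = 2, beta = 3, gamma = 4, seed = 1)
  expect_identical(truth$total_effect, 4 + 2 * 3)
  expect_identical(truth$proportion_mediated, 100 * 6 / 10)
  expect_error(scenario_truth(baseline_level = 95, seasonal_amplitude = 10),
               "within \\[0, 100\\]")
})

test_that("degenerate baseline is constant and generation is reproducible", {
  truth <- scenario_truth(n_high = 2, n_middle = 0, sigma_search = 0,
                          seasonal_amplitude = 0, seed = 4)
  s <- generate_baseline_search(truth, 1, "insomnia")
  expect_true(all(s$value == truth$baseline_level))

  truth2 <- scenario_truth(n_high = 2, n_middle = 1, seed = 21)
  a <- generate_baseline_search(truth2, 2, "suicide")
  b <- generate_baseline_search(truth2, 2, "suicide")
  expect_identical(a, b)
  sim1 <- generate_pandemic_panel(truth2, terms = "insomnia")
  sim2 <- generate_pandemic_panel(truth2, terms = "insomnia")
  expect_identical(sim1$search, sim2$search)
  expect_identical(sim1$deaths, sim2$deaths)
})

test_that("adding countries never reshuffles earlier countries' draws", {
  t3 <- scenario_truth(n_high = 3, n_middle = 0, seed = 8)
  t5 <- scenario_truth(n_high = 5, n_middle = 0, seed = 8)
  expect_identical(generate_baseline_search(t3, 2, "insomnia")$value,
                   generate_baseline_search(t5, 2, "insomnia")$value)
  d3 <- generate_pandemic_panel(t3, terms = "insomnia",
                                include_baseline = FALSE)$deaths
  d5 <- generate_pandemic_panel(t5, terms = "insomnia",
                                include_baseline = FALSE)$deaths
  expect_identical(dplyr::filter(d3, country_code == "H02")$value,
                   dplyr::filter(d5, country_code == "H02")$value)
})

test_that("pre-pandemic baseline shows annual seasonality", {
  truth <- scenario_truth(n_high = 1, n_middle = 0, seed = 12)
  s <- generate_baseline_search(truth, 1, "insomnia")
  base <- s$value[s$week_start <= study_windows()$baseline_end]
  ac <- acf(base, lag.max = 52, plot = FALSE)$acf
  expect_gt(ac[53], ac[27]) # lag 52 beats lag 26
})

test_that("injected structural excess equals pandemic minus baseline series", {
  truth <- scenario_truth(n_high = 2, n_middle = 1, seed = 30)
  sim <- generate_pandemic_panel(truth, terms = "insomnia")
  for (i in 1:3) {
    code <- sim$registry$country_code[i]
    obs <- dplyr::filter(sim$search, country_code == code)
    base <- generate_baseline_search(truth, i, "insomnia")
    inj <- dplyr::filter(sim$injected, country_code == code)
    idx <- match(inj$week_start, obs$week_start)
    expect_equal(obs$value[idx] - base$value[idx], inj$excess_true,
                 tolerance = 1e-12)
  }
})

test_that("scenarios that clip the baseline or truncate the horizon fail", {
  truth <- scenario_truth(n_high = 1, n_middle = 0, baseline_level = 88,
                          seasonal_amplitude = 11, sigma_search = 3,
                          seed = 2)
  expect_error(generate_baseline_search(truth, 1, "insomnia"),
               "clip")
  w <- study_windows()
  w$pandemic_end <- w$pandemic_start + 200
  short <- scenario_truth(n_high = 2, n_middle = 0, windows = w, seed = 2)
  expect_error(generate_pandemic_panel(short), "horizon")
})

test_that("wave specification must be non-empty per country", {
  truth <- scenario_truth(n_high = 2, n_middle = 0, seed = 2,
                          wave_spec = list(tibble::tibble(
                            peak_date = as.Date("2020-06-01"),
                            peak_height = 100, width_days = 20)))
  expect_error(generate_pandemic_panel(truth), "one element per country")
})
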