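test_that("proportion mediated reproduces published-style ratio cells", {
  # effect pairs (mediation, total) and the PM each implies, to 1 decimal
  cells <- list(
    list(6.7e-5, 2.1e-4, 31.9),   # insomnia, high income, year 1
    list(3.4e-5, 1.2e-4, 28.3),   # insomnia, high income, year 2
    list(2.1e-4, 2.2e-4, 95.5),   # insomnia, middle income, year 1
    list(-5.1e-5, -3.5e-4, 14.6), # suicide, middle income, year 1
    list(2.5e-5, 2.2e-4, 11.4),   # suicide, high income, year 2
    list(3.0e-5, -2.6e-4, -11.5)  # suicide, middle income, year 2
  )
  for (cell in cells) {
    pm <- proportion_mediated(cell[[1]], cell[[2]])$pm
    expect_equal(round(pm, 1), cell[[3]])
  }
})

test_that("degenerate proportion-mediated cases behave", {
  expect_equal(proportion_mediated(0, 2e-4)$pm, 0)
  expect_error(proportion_mediated(1e-5, 0), "numerically zero")
  # CI may spill far outside [0, 100]%
  res <- proportion_mediated(6.7e-5, 2.1e-4, var_m = (2.2e-5)^2,
                             var_t = (8.8e-5)^2)
  expect_lt(res$lower95, res$pm)
  expect_gt(res$upper95, 100 * 6.7 / 21)
})

test_that("a noise-free panel recovers the decomposition exactly", {
  truth <- noisefree_truth(alpha = 2, beta = 3, gamma = 4)
  fit <- mediate_panel(simulate_panel(truth))
  g <- glance(fit)
  expect_equal(g$total, 10, tolerance = 1e-8)
  expect_equal(g$mediation, 6, tolerance = 1e-8)
  expect_equal(g$alternative, 4, tolerance = 1e-8)
  expect_equal(g$proportion_mediated, 60, tolerance = 1e-8)
})

test_that("a scenario without a mediated path estimates near-zero mediation", {
  truth <- scenario_truth(n_high = 6, n_middle = 0, alpha = 0,
                          sigma_mobility = 1e-8, sigma_outcome = 1e-8,
                          sigma_mediator_shock = 1e-4, seed = 17)
  g <- glance(mediate_panel(simulate_panel(truth)))
  expect_lt(abs(g$mediation), 1e-6)
  expect_equal(g$total, truth$gamma, tolerance = 1e-6)
})

test_that("additivity and ratio identities hold on every stratum", {
  truth <- scenario_truth(n_high = 6, n_middle = 5, seed = 23)
  panel <- simulate_panel(truth)
  for (inc in c("high", "middle")) {
    for (yr in 1:3) {
      fit <- mediate_panel(filter_stratum(panel, income = inc, year = yr))
      e <- setNames(fit$effects$estimate, fit$effects$effect)
      # product-of-coefficients equals the difference method
      expect_equal(e[["mediation"]], e[["total"]] - e[["alternative"]],
                   tolerance = 1e-8)
      expect_equal(e[["proportion_mediated"]] * e[["total"]],
                   100 * e[["mediation"]], tolerance = 1e-8)
    }
  }
})

test_that("rescaling the exposure rescales effects and leaves PM invariant", {
  truth <- scenario_truth(n_high = 5, n_middle = 0, seed = 29)
  panel <- simulate_panel(truth)
  g1 <- glance(mediate_panel(panel))
  panel10 <- dplyr::mutate(panel, exposure = exposure * 10)
  g10 <- glance(mediate_panel(panel10))
  expect_equal(g10$total, g1$total / 10, tolerance = 1e-10)
  expect_equal(g10$mediation, g1$mediation / 10, tolerance = 1e-10)
  expect_equal(g10$alternative, g1$alternative / 10, tolerance = 1e-10)
  expect_equal(g10$proportion_mediated, g1$proportion_mediated,
               tolerance = 1e-10)
})

test_that("decompose validates its three models", {
  panel <- make_small_panel()
  m1 <- fit_twoway_fe(panel, "outcome", "exposure")
  m2 <- fit_twoway_fe(panel, "outcome", c("exposure", "mediator"))
  m3 <- fit_twoway_fe(panel, "mediator", "exposure")
  expect_s3_class(decompose(m1, m2, m3), "mediation_fit")
  expect_error(decompose(m1, m1, m3), "mediator")
})

test_that("stratified runs keep unfittable strata as NA rows", {
  truth <- scenario_truth(n_high = 4, n_middle = 0, seed = 37)
  panel <- simulate_panel(truth)
  # cripple year 3: a single month cannot support month fixed effects
  panel <- dplyr::filter(panel, pandemic_year < 3 |
                           month == as.Date("2022-03-01"))
  expect_warning(res <- run_mediation(panel, by = "pandemic_year"),
                 "skipped")
  expect_equal(nrow(res), 3 * 4)
  y3 <- dplyr::filter(res, pandemic_year == 3)
  expect_true(all(is.na(y3$estimate)))
  y1 <- dplyr::filter(res, pandemic_year == 1)
  expect_false(any(is.na(y1$estimate)))
})
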