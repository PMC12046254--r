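test_that("monthly aggregation is the arithmetic mean over available days", {
  days <- seq(as.Date("2020-04-01"), as.Date("2020-04-30"), by = "1 day")
  d <- tibble::tibble(country_code = "IT", date = days, value = 10)
  expect_equal(monthly_exposure(d)$exposure, 10)

  d2 <- tibble::tibble(country_code = "IT", date = days,
                       value = rep(c(0, 20), each = 15))
  expect_equal(monthly_exposure(d2)$exposure, 10)

  # mirrors the printed annual mobility means: a constant series averages
  # to itself in every month
  year <- seq(as.Date("2020-03-01"), as.Date("2021-02-28"), by = "1 day")
  mob <- tibble::tibble(country_code = "AU", date = year, value = 8.52)
  mm <- monthly_mediator(mob)
  expect_equal(nrow(mm), 12)
  expect_equal(mm$mediator, rep(8.52, 12), tolerance = 1e-12)

  empty <- tibble::tibble(country_code = character(), date = as.Date(character()),
                          value = numeric())
  expect_equal(nrow(monthly_mediator(empty)), 0)
})

test_that("monthly means agree with a brute-force grouping oracle", {
  set.seed(14)
  days <- seq(as.Date("2020-03-01"), as.Date("2021-06-30"), by = "1 day")
  d <- tibble::tibble(country_code = sample(c("A", "B"), length(days) * 2,
                                            replace = TRUE),
                      date = rep(days, 2), value = rnorm(length(days) * 2))
  d <- d[!duplicated(d[c("country_code", "date")]), ]
  got <- monthly_exposure(d)
  oracle <- aggregate(value ~ country_code + format(date, "%Y-%m"), d, mean)
  oracle <- oracle[order(oracle$country_code, oracle[[2]]), ]
  expect_equal(got$exposure, oracle$value, tolerance = 1e-12)
})

test_that("weeks belong to the month containing their start date", {
  ex <- tibble::tibble(
    country_code = "IT",
    week_start = as.Date(c("2021-02-21", "2021-02-28", "2021-03-07")),
    excess = c(1, 3, 5))
  mo <- monthly_outcome(ex)
  # the week starting 28 Feb spans March but counts toward February
  expect_equal(mo$outcome[mo$month == as.Date("2021-02-01")], 2)
  expect_equal(mo$outcome[mo$month == as.Date("2021-03-01")], 5)
})

test_that("monthly aggregation is scale-equivariant", {
  set.seed(15)
  days <- seq(as.Date("2020-03-01"), by = "1 day", length.out = 100)
  d <- tibble::tibble(country_code = "A", date = days, value = rnorm(100))
  d10 <- dplyr::mutate(d, value = value * 10)
  expect_equal(monthly_exposure(d10)$exposure,
               10 * monthly_exposure(d)$exposure, tolerance = 1e-12)
})

test_that("pandemic years partition the study window as 12 + 12 + 8 months", {
  months <- seq(as.Date("2020-03-01"), as.Date("2022-10-01"), by = "month")
  yr <- pandemic_year_of(months)
  expect_equal(as.integer(table(yr)), c(12L, 12L, 8L))
  expect_true(is.na(pandemic_year_of(as.Date("2020-02-01"))))
  expect_true(is.na(pandemic_year_of(as.Date("2022-11-01"))))
  # contiguous blocks
  expect_equal(yr, sort(yr))
})

test_that("panel assembly joins, stratifies and reports exclusions", {
  truth <- scenario_truth(n_high = 2, n_middle = 2, seed = 31)
  sim <- generate_pandemic_panel(truth, terms = "insomnia",
                                 include_baseline = FALSE)
  excess <- dplyr::rename(sim$injected, excess = excess_true)
  panel <- assemble_panel(sim$registry, excess, sim$mobility, sim$deaths)
  # 4 countries x 32 pandemic months (2020-03 .. 2022-10), complete coverage
  expect_equal(nrow(panel), 4 * 32)
  expect_false(anyDuplicated(panel[c("country_code", "month")]) > 0)
  expect_setequal(unique(panel$pandemic_year), 1:3)

  # strata partition the panel
  strata <- lapply(1:3, function(y) filter_stratum(panel, year = y))
  expect_equal(sum(vapply(strata, nrow, 0L)), nrow(panel))

  # a country with no mobility at all is excluded with a warning
  mob2 <- dplyr::filter(sim$mobility, country_code != "M01")
  expect_warning(
    p2 <- assemble_panel(sim$registry, excess, mob2, sim$deaths),
    "M01")
  expect_false("M01" %in% p2$country_code)

  # losing every stream empties the join informatively
  expect_error(
    assemble_panel(sim$registry, excess[0, ], sim$mobility, sim$deaths),
    "outcome")
})
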