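# Shared fixtures, built in code.

# small noise-free scenario used by exact-recovery tests
noisefree_truth <- function(alpha = 2, beta = 3, gamma = 4, n_high = 4,
                            n_middle = 0, seed = 3) {
  scenario_truth(
    n_high = n_high, n_middle = n_middle,
    alpha = alpha, beta = beta, gamma = gamma,
    sigma_search = 0, sigma_mobility = 0, sigma_outcome = 0,
    sigma_deaths = 0, sigma_mediator_shock = 0,
    seasonal_amplitude = 0, seed = seed
  )
}

# deterministic 4-country x 6-month panel with known structure
make_small_panel <- function(seed = 9, sd = 0.3) {
  set.seed(seed)
  months <- seq(as.Date("2020-03-01"), by = "month", length.out = 6)
  panel <- tibble::tibble(
    country_code = rep(sprintf("C%d", 1:4), each = 6),
    month = rep(months, 4),
    exposure = rnorm(24, 10, 3),
    mediator = rnorm(24, 5, 2)
  )
  panel$outcome <- 1.5 * panel$exposure - 0.7 * panel$mediator +
    rep(rnorm(4), each = 6) + rep(rnorm(6), 4) + rnorm(24, sd = sd)
  panel
}

# Trends-style export text for a given weekly series
trends_text <- function(weeks, values) {
  c("Category: All categories", "", "Week,insomnia: (Testland)",
    sprintf("%s,%s", format(weeks, "%Y-%m-%d"), values))
}
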