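# Three-model causal mediation decomposition with delta-method inference.
#
# Model 1: outcome  ~ exposure              -> total effect (theta_T)
# Model 2: outcome  ~ exposure + mediator   -> alternative effect (theta_A),
#                                              mediator slope beta
# Model 3: mediator ~ exposure              -> alpha
#
# theta_M = alpha * beta (product of coefficients).  In this linear,
# no-interaction specification with a common fixed-effect structure the
# product estimator coincides with the difference estimator
# theta_T - theta_A, so theta_T = theta_M + theta_A holds as an exact
# estimator identity.  se(theta_M) is the Sobel-type delta-method SE; the
# proportion mediated PM = 100 * theta_M / theta_T gets a delta-method SE
# with cov(theta_M, theta_T) approximated by var(theta_M).

#' Proportion mediated with delta-method inference
#'
#' Computes `PM = 100 * theta_m / theta_t` and propagates the effect
#' variances through the ratio by a first-order delta method:
#' `var(PM) = g' Sigma g` with gradient `g = (100/theta_t,
#' -100*theta_m/theta_t^2)`.  The covariance between the mediation and
#' total effects defaults to `var(theta_m)` (from the decomposition
#' identity `theta_t = theta_m + theta_a` with the two components treated
#' as uncorrelated).  Confidence limits are unconstrained and may fall
#' outside \[0, 100\]%.
#'
#' @param theta_m Mediation (indirect) effect estimate.
#' @param theta_t Total effect estimate (must be nonzero).
#' @param var_m,var_t Variances of the two estimates (default 0, giving
#'   the point identity only).
#' @param cov_mt Covariance between them; defaults to `var_m`.
#' @return A one-row tibble with `pm` (percent), `se`, `lower95`,
#'   `upper95`, `p_value` (two-sided normal test of PM = 0).
#' @export
#' @examples
#' proportion_mediated(6.7e-5, 2.1e-4)$pm # 31.9
proportion_mediated <- function(theta_m, theta_t, var_m = 0, var_t = 0,
                                cov_mt = var_m) {
  if (abs(theta_t) < 1e-12) {
    abort("total effect numerically zero; proportion mediated undefined")
  }
  pm <- 100 * theta_m / theta_t
  g <- c(100 / theta_t, -100 * theta_m / theta_t^2)
  v <- g[1]^2 * var_m + g[2]^2 * var_t + 2 * g[1] * g[2] * cov_mt
  se <- sqrt(max(v, 0))
  z <- if (se > 0) pm / se else NA_real_
  tibble::tibble(
    pm = pm, se = se,
    lower95 = pm - 1.96 * se, upper95 = pm + 1.96 * se,
    p_value = if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z))
  )
}

#' Decompose a total effect into mediation and alternative components
#'
#' Combines the three fixed-effects fits into the mediation decomposition:
#' the total effect is the exposure slope of `model1`, the alternative
#' (direct) effect the exposure slope of `model2`, and the mediation
#' effect the product of the exposure slope of `model3` and the mediator
#' slope of `model2`, with Sobel delta-method standard error
#' `sqrt(beta^2 var(alpha) + alpha^2 var(beta))`.
#'
#' @param model1 `fe_fit` of outcome on exposure.
#' @param model2 `fe_fit` of outcome on exposure and mediator.
#' @param model3 `fe_fit` of mediator on exposure.
#' @param exposure,mediator Names of the exposure and mediator regressors.
#' @return An object of class `mediation_fit`; see [tidy.mediation_fit()].
#' @export
decompose <- function(model1, model2, model3,
                      exposure = "exposure", mediator = "mediator") {
  if (!mediator %in% model2$regressors) {
    abort(sprintf("model2 must include the mediator '%s'", mediator))
  }
  if (!exposure %in% model1$regressors ||
      !exposure %in% model2$regressors ||
      !exposure %in% model3$regressors) {
    abort(sprintf("all three models must include the exposure '%s'",
                  exposure))
  }
  theta_t <- model1$coefficients[[exposure]]
  var_t <- model1$vcov[exposure, exposure]
  theta_a <- model2$coefficients[[exposure]]
  var_a <- model2$vcov[exposure, exposure]
  alpha <- model3$coefficients[[exposure]]
  var_alpha <- model3$vcov[exposure, exposure]
  beta <- model2$coefficients[[mediator]]
  var_beta <- model2$vcov[mediator, mediator]
  theta_m <- alpha * beta
  var_m <- beta^2 * var_alpha + alpha^2 * var_beta

  eff <- tibble::tibble(
    effect = c("total", "mediation", "alternative"),
    estimate = c(theta_t, theta_m, theta_a),
    se = sqrt(c(var_t, var_m, var_a))
  ) |>
    dplyr::mutate(
      lower95 = .data$estimate - 1.96 * .data$se,
      upper95 = .data$estimate + 1.96 * .data$se,
      p_value = 2 * pnorm(-abs(.data$estimate / .data$se))
    )
  pm <- proportion_mediated(theta_m, theta_t, var_m, var_t)
  eff <- dplyr::bind_rows(eff, tibble::tibble(
    effect = "proportion_mediated", estimate = pm$pm, se = pm$se,
    lower95 = pm$lower95, upper95 = pm$upper95, p_value = pm$p_value))

  structure(list(
    effects = eff,
    alpha = c(estimate = alpha, var = var_alpha),
    beta = c(estimate = beta, var = var_beta),
    models = list(model1 = model1, model2 = model2, model3 = model3),
    n_obs = model1$n_obs
  ), class = "mediation_fit")
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf("Mediation decomposition (n = %d)\n", x$n_obs))
  print(x$effects)
  invisible(x)
}

#' Tidy a mediation decomposition
#'
#' @param x A `mediation_fit`.
#' @param ... Unused.
#' @return The effects tibble: one row per effect (`total`, `mediation`,
#'   `alternative`, `proportion_mediated`) with `estimate`, `se`,
#'   `lower95`, `upper95`, `p_value`.  The proportion mediated row is in
#'   percent; the others are in outcome units per exposure unit.
#' @export
tidy.mediation_fit <- function(x, ...) x$effects

#' One-line summary of a mediation decomposition
#'
#' @param x A `mediation_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the four point estimates and `n_obs`.
#' @export
glance.mediation_fit <- function(x, ...) {
  e <- setNames(x$effects$estimate, x$effects$effect)
  tibble::tibble(total = e[["total"]], mediation = e[["mediation"]],
                 alternative = e[["alternative"]],
                 proportion_mediated = e[["proportion_mediated"]],
                 n_obs = x$n_obs)
}

#' Run the three-model mediation analysis on one panel stratum
#'
#' Fits the three two-way fixed-effects models on the same panel and
#' returns their decomposition.
#'
#' @param panel Panel tibble (one stratum) with columns `exposure`,
#'   `mediator`, `outcome`, `country_code`, `month`.
#' @param cluster Use country-clustered covariances in the three fits.
#' @return A `mediation_fit`.
#' @export
mediate_panel <- function(panel, cluster = FALSE) {
  m1 <- fit_twoway_fe(panel, "outcome", "exposure", cluster = cluster)
  m2 <- fit_twoway_fe(panel, "outcome", c("exposure", "mediator"),
                      cluster = cluster)
  m3 <- fit_twoway_fe(panel, "mediator", "exposure", cluster = cluster)
  decompose(m1, m2, m3)
}

#' Stratified mediation analysis over a full panel
#'
#' Splits the panel by income group and pandemic year (by default) and
#' runs [mediate_panel()] within each stratum, mirroring the layout of the
#' study's results tables: four effect rows per stratum.
#'
#' @param panel Panel tibble from [assemble_panel()].
#' @param by Stratifying columns; use `character(0)` for a single
#'   unstratified analysis.
#' @param cluster Use country-clustered covariances.
#' @return A tibble with the stratum labels, `effect`, `estimate`, `se`,
#'   `lower95`, `upper95`, `p_value` and `n_obs`.  Strata whose models
#'   cannot be fit (too few countries or months) are returned as `NA`
#'   rows rather than dropped.
#' @export
run_mediation <- function(panel,
                          by = c("income_group", "pandemic_year"),
                          cluster = FALSE) {
  groups <- if (length(by) == 0) {
    list(panel)
  } else {
    split(panel, panel[by], drop = TRUE, sep = "\r")
  }
  out <- purrr::imap(groups, function(g, key) {
    labels <- if (length(by) > 0) {
      setNames(as.list(strsplit(key, "\r", fixed = TRUE)[[1]]), by)
    } else {
      list()
    }
    fit <- tryCatch(mediate_panel(g, cluster = cluster),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warn(sprintf("stratum %s skipped: %s",
                   paste(unlist(labels), collapse = "/"),
                   conditionMessage(fit)))
      eff <- tibble::tibble(
        effect = c("total", "mediation", "alternative",
                   "proportion_mediated"),
        estimate = NA_real_, se = NA_real_, lower95 = NA_real_,
        upper95 = NA_real_, p_value = NA_real_, n_obs = NA_integer_)
    } else {
      eff <- dplyr::mutate(tidy(fit), n_obs = fit$n_obs)
    }
    if (length(labels) == 0) eff else {
      dplyr::bind_cols(tibble::as_tibble(labels), eff)
    }
  })
  out <- dplyr::bind_rows(out)
  if ("pandemic_year" %in% names(out)) {
    out$pandemic_year <- as.integer(out$pandemic_year)
  }
  if ("term" %in% names(panel)) {
    out <- dplyr::mutate(out, term = panel$term[1], .before = 1)
  }
  out
}

#' Country-bootstrap standard errors for the mediation decomposition
#'
#' Nonparametric bootstrap resampling countries with replacement,
#' re-running the three-model decomposition on each resample.  Serves as a
#' distribution-free check on the delta-method standard errors.
#'
#' @param panel Panel tibble (one stratum).
#' @param n_boot Number of resamples.
#' @param seed Seed for the resampling.
#' @return A tibble with one row per effect: `effect`, `se_boot`, and the
#'   number of successful resamples `n_ok`.
#' @export
bootstrap_mediation <- function(panel, n_boot = 500, seed = 1) {
  countries <- unique(panel$country_code)
  by_country <- split(panel, panel$country_code)
  set.seed(seed)
  draws <- purrr::map(seq_len(n_boot), function(b) {
    picked <- sample(countries, length(countries), replace = TRUE)
    boot <- purrr::imap(picked, function(cc, i) {
      g <- by_country[[cc]]
      g$country_code <- sprintf("boot%03d", i) # duplicates kept distinct
      g
    })
    boot <- dplyr::bind_rows(boot)
    fit <- tryCatch(mediate_panel(boot), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    setNames(fit$effects$estimate, fit$effects$effect)
  })
  draws <- purrr::compact(draws)
  mat <- do.call(rbind, draws)
  tibble::tibble(
    effect = colnames(mat),
    se_boot = apply(mat, 2, sd),
    n_ok = nrow(mat)
  )
}
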