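# Two-way fixed-effects (within) estimator.
#
# Country and time intercepts are absorbed by iterated demeaning
# (alternating projections, exact in one pass on balanced panels), then the
# slopes come from OLS on the transformed data.  The covariance is the
# classical OLS covariance with residual degrees of freedom corrected for
# the absorbed effects; a cluster-robust (by country) variant is available.

demean_twoway <- function(v, g1, g2, tol = 1e-12, max_iter = 200) {
  for (i in seq_len(max_iter)) {
    v1 <- v - ave(v, g1)
    v2 <- v1 - ave(v1, g2)
    if (max(abs(v2 - v)) < tol * (1 + max(abs(v)))) {
      return(v2)
    }
    v <- v2
  }
  v
}

#' Fit a two-way fixed-effects panel regression
#'
#' Estimates `outcome ~ regressors` with country and month intercepts
#' absorbed by the within transformation (iterated demeaning over the two
#' grouping factors until convergence).  The coefficient covariance is the
#' classical OLS covariance on the transformed data with residual degrees
#' of freedom `n - k - (G - 1) - (T - 1) - 1` (G countries, T months, k
#' slopes); set `cluster = TRUE` for a CR1 cluster-robust (by country)
#' covariance instead.
#'
#' @param panel Panel tibble with columns `country_code`, `month`, the
#'   outcome and the regressors.
#' @param outcome Name of the outcome column.
#' @param regressors Character vector of regressor column names.
#' @param cluster If `TRUE`, use a country-clustered robust covariance.
#' @return An object of class `fe_fit` with elements `coefficients`,
#'   `vcov`, `n_obs`, `df_residual`, `r_squared_within`, `n_country`,
#'   `n_month`, `outcome`, `regressors`.
#' @export
#' @examples
#' panel <- tibble::tibble(
#'   country_code = rep(c("A", "B"), each = 6),
#'   month = rep(seq(as.Date("2020-03-01"), by = "month", length.out = 6), 2),
#'   x = rnorm(12))
#' panel$y <- 2 * panel$x + rep(c(0, 5), each = 6) + rnorm(12, sd = 0.1)
#' fit <- fit_twoway_fe(panel, "y", "x")
#' tidy(fit)
fit_twoway_fe <- function(panel, outcome, regressors, cluster = FALSE) {
  assert_cols(panel, c("country_code", "month", outcome, regressors),
              "panel")
  keep <- complete.cases(panel[c("country_code", "month", outcome,
                                 regressors)])
  panel <- panel[keep, ]
  g1 <- factor(panel$country_code)
  g2 <- factor(format(panel$month))
  n <- nrow(panel)
  G <- nlevels(g1)
  T_ <- nlevels(g2)
  if (G < 2 || T_ < 2) {
    abort("two-way fixed effects need at least 2 countries and 2 months")
  }
  y <- demean_twoway(panel[[outcome]], g1, g2)
  X <- vapply(regressors,
              function(r) demean_twoway(panel[[r]], g1, g2),
              numeric(n))
  X <- matrix(X, nrow = n, dimnames = list(NULL, regressors))
  scale_ref <- vapply(regressors, function(r) var(panel[[r]]), 0)
  within_var <- apply(X, 2, var)
  degenerate <- within_var <= 1e-12 * pmax(scale_ref, 1e-300)
  if (any(degenerate)) {
    abort(sprintf("regressor(s) collinear with the fixed effects: %s",
                  paste(regressors[degenerate], collapse = ", ")))
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    abort("singular design after the within transformation")
  }
  beta <- qr.coef(qrx, y)
  resid <- as.numeric(y - X %*% beta)
  k <- length(regressors)
  df <- n - k - (G - 1) - (T_ - 1) - 1
  if (df <= 0) abort("no residual degrees of freedom after absorbing effects")
  # (X'X)^-1 via the R factor, un-pivoted
  Vp <- chol2inv(qr.R(qrx))
  pos <- match(seq_len(k), qrx$pivot)
  XtX_inv <- Vp[pos, pos, drop = FALSE]
  if (cluster) {
    scores <- rowsum(X * as.numeric(resid), g1)
    meat <- crossprod(as.matrix(scores))
    cr1 <- (G / (G - 1)) * ((n - 1) / df)
    V <- cr1 * XtX_inv %*% meat %*% XtX_inv
  } else {
    sigma2 <- sum(resid^2) / df
    V <- sigma2 * XtX_inv
  }
  V <- (V + t(V)) / 2
  dimnames(V) <- list(regressors, regressors)
  structure(list(
    coefficients = setNames(as.numeric(beta), regressors),
    vcov = V,
    n_obs = n,
    df_residual = df,
    r_squared_within = 1 - sum(resid^2) / sum(y^2),
    n_country = G,
    n_month = T_,
    outcome = outcome,
    regressors = regressors,
    cluster = cluster
  ), class = "fe_fit")
}

#' @export
print.fe_fit <- function(x, ...) {
  cat(sprintf("Two-way FE fit: %s ~ %s  (n = %d, %d countries, %d months)\n",
              x$outcome, paste(x$regressors, collapse = " + "),
              x$n_obs, x$n_country, x$n_month))
  print(tidy(x))
  invisible(x)
}

#' @export
coef.fe_fit <- function(object, ...) object$coefficients

#' @export
vcov.fe_fit <- function(object, ...) object$vcov

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a two-way fixed-effects fit
#'
#' @param x An `fe_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value` (normal theory).
#' @export
tidy.fe_fit <- function(x, ...) {
  est <- x$coefficients
  se <- sqrt(diag(x$vcov))
  z <- est / se
  tibble::tibble(term = names(est), estimate = as.numeric(est),
                 std.error = as.numeric(se), statistic = as.numeric(z),
                 p.value = 2 * pnorm(-abs(z)))
}

#' One-line summary of a two-way fixed-effects fit
#'
#' @param x An `fe_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `r.squared_within`, `n_obs`,
#'   `df.residual`, `n_country`, `n_month`.
#' @export
glance.fe_fit <- function(x, ...) {
  tibble::tibble(r.squared_within = x$r_squared_within, n_obs = x$n_obs,
                 df.residual = x$df_residual, n_country = x$n_country,
                 n_month = x$n_month)
}
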