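---
title: "Methods: counterfactual excess search volumes and fixed-effects mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: counterfactual excess search volumes and fixed-effects mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trendmediate)
```

## Overview

`trendmediate` estimates how much of an epidemic's effect on
population-level mental-health search behaviour is carried by stay-at-home
behaviour. The analysis has three stages, each with its own model and
assumptions:

1. a **counterfactual stage** that turns weekly relative search volumes
   into weekly *excess* volumes via a seasonal ARIMA baseline;
2. a **panel stage** that aligns excess outcomes, mobility mediators and
   death-count exposures on a country × month grid with income-group and
   pandemic-year strata;
3. a **mediation stage** that decomposes the total effect of deaths on
   excess searches into a mobility-mediated and an alternative component,
   with delta-method inference.

This vignette records the models, the tunable parameters, the synthetic
ground-truth generator used for validation, and the numerical and design
choices made where more than one defensible option existed. It states no
empirical result that the package's tests and acceptance script do not
themselves compute.

## Stage 1: counterfactual excess

### Model

For each country and search term, the weekly relative search volume
$y_t \in [0, 100]$ over the pre-pandemic baseline window (by default
2015-03-01 to 2020-02-29, five full annual cycles) is modelled as a
seasonal ARIMA$(p,d,q)(P,D,Q)_m$ process with $m = 52$ weeks. The fitted
model forecasts the pandemic window (2020-03-01 to 2022-10-15, 137 weeks)
in one shot, and the weekly excess is

$$e_t = y_t^{\text{obs}} - \hat{y}_t^{\text{expected}},$$

never clipped, so excess is linear in the observed series. One-shot
full-horizon forecasting (rather than rolling re-estimation) matches the
idea of a single counterfactual: the expected trajectory had the epidemic
not happened. The alternative — rolling one-step forecasts — answers a
different question (short-horizon anomaly detection) and is intentionally
not implemented.

### Order selection

`select_sarima()` follows the familiar stepwise automatic procedure:

* **Seasonal differences $D$** come from a seasonal-strength heuristic: an
  STL decomposition with a periodic seasonal window gives
  $F_s = \max(0,\, 1 - \mathrm{var}(R)/\mathrm{var}(S + R))$; $D = 1$ when
  $F_s > 0.64$, else 0. This is deterministic, dependency-free, and
  behaves like the usual seasonal unit-root tests on strongly seasonal
  series. It is a swappable choice: a formal OCSB/HEGY test could replace
  it without touching the rest of the search.
* **Ordinary differences $d$** come from successive KPSS
  level-stationarity tests (Bartlett long-run variance, bandwidth
  $4(n/100)^{1/4}$, 5% critical value 0.463) applied after seasonal
  differencing, capped at $d = 2$.
* **$(p, q, P, Q)$** are chosen by AICc from a neighbourhood search
  started at the four standard models $(2,d,2)(1,D,1)$, $(0,d,0)(0,D,0)$,
  $(1,d,0)(1,D,0)$ and $(0,d,1)(0,D,1)$, moving to the best
  single-step neighbour (including toggling the constant) until no
  improvement, bounded by $p, q \le 5$ and $P, Q \le 2$. Because $d$ and
  $D$ are fixed before the search, all AICc comparisons are between models
  of the same differencing order, as likelihood comparison requires.

A constant is allowed only when $d + D \le 1$: a mean term when
$d + D = 0$ and a linear drift regressor when $d + D = 1$. Candidate fits
use `stats::arima` (Gaussian ML, up to 500 optimiser iterations);
candidates that fail to converge are skipped and recorded in a fit log
attached to the returned specification. A zero-variance baseline is
rejected as degenerate.

Forecast intervals are normal-theory: point forecast ± 1.96 forecast
standard errors. Series clipped at the 0/100 scale limits are not
re-truncated after differencing, so excess can exceed the nominal bounds —
the price of keeping excess exactly linear.

### Problem sizes

Seasonal fits at period 52 with nonzero seasonal AR/MA orders are
expensive (the state dimension grows with $m$), which matters only for the
automatic search, not for forecasting with a fixed specification. The test
suite therefore exercises the *selection logic* at compact periods
($m = 12$ on 120 observations, and $m = 1$ for non-seasonal series) —
every property checked (AICc dominance over the starting models, correct
differencing decisions, calendar-shift invariance) is period-agnostic —
and uses fixed specifications for period-52 forecasts. Full period-52
selection remains available and is simply slower per series.

## Stage 2: the country × month panel

Daily exposures (deaths or cases) and mediators (residential mobility
percent change) are averaged over calendar months using whatever days are
available; months with no coverage are absent rather than imputed. Weekly
excess is assigned to the calendar month containing its **week-start
date** — a week starting 27 February counts toward February even though it
spans March. This is the simplest deterministic assignment; a
proportional-split rule would change month means by well under one week's
weight and is not implemented.

The panel is the inner join of the three monthly tables per (country,
month); rows missing any component are dropped (listwise deletion — no
imputation, keeping every estimator standard), and countries contributing
fewer than two months are removed with a warning. Exposures stay in raw
absolute counts (deaths per day), not per-capita rates, so effect
estimates are "per daily death" and numerically small (≈10⁻⁴ per death for
realistic wave heights); this is deliberate, matching the convention of
using absolute national counts for cross-country comparability.

Strata: income group (high / middle, from the packaged registry of 45
countries: 31 high, 14 middle) × pandemic year (1: 2020-03..2021-02, 2:
2021-03..2022-02, 3: 2022-03..2022-10). Year 3 is an eight-month stratum
because open mobility data ended in October 2022; no annualisation is
applied. Monthly (not weekly) outcome aggregation is used throughout so
that outcome, mediator and exposure share one grid; the weekly-outcome
alternative would mix grids and is noted but not implemented.

## Stage 3: mediation with two-way fixed effects

Within each stratum three regressions are fit, each absorbing country and
calendar-month intercepts by the within transformation (iterated demeaning
over the two factors until convergence — exact in one pass on balanced
panels):

$$
\begin{aligned}
\text{(1)}\quad \text{excess}_{it} &= \theta_T\, X_{it} + \mu_i + \tau_t + \varepsilon_{it}\\
\text{(2)}\quad \text{excess}_{it} &= \theta_A\, X_{it} + \beta\, M_{it} + \mu_i + \tau_t + \varepsilon_{it}\\
\text{(3)}\quad M_{it} &= \alpha\, X_{it} + \mu_i + \tau_t + \nu_{it}
\end{aligned}
$$

with $X$ the monthly mean daily deaths and $M$ the monthly mean mobility
change. Fixed rather than random effects: "adjust for variations specific
to each country and time frame" is exactly fixed-effect absorption, and FE
requires no distributional assumption on the country effects. Slopes come
from QR-based least squares on the demeaned data; the covariance is the
classical OLS covariance with residual degrees of freedom
$n - k - (G-1) - (T-1) - 1$ (verified to equal `lm` with explicit dummy
variables), with an optional CR1 country-clustered covariance
(`cluster = TRUE`) for users who prefer it — clustering is off by default
because the default inference target is the classical delta-method chain.

**Decomposition.** $\theta_M = \hat\alpha\hat\beta$ (product of
coefficients) with Sobel delta-method standard error
$\sqrt{\hat\beta^2\,\mathrm{var}(\hat\alpha) + \hat\alpha^2\,\mathrm{var}(\hat\beta)}$.
In this linear specification without an exposure–mediator interaction the
product estimator coincides with the difference estimator
$\hat\theta_T - \hat\theta_A$ when all three models share the same
fixed-effect structure, so $\theta_T = \theta_M + \theta_A$ holds as an
exact arithmetic identity on every output (and is asserted in the tests to
10⁻⁸). An interaction term would break this identity, which is why it is a
non-goal.

**Proportion mediated.** $\mathrm{PM} = 100\,\theta_M/\theta_T$, with
delta-method variance using gradient
$(100/\theta_T,\ -100\,\theta_M/\theta_T^2)$ and
$\mathrm{cov}(\theta_M, \theta_T)$ approximated by
$\mathrm{var}(\theta_M)$ — from $\theta_T = \theta_M + \theta_A$ with the
two components treated as uncorrelated. No closed form exists for this
covariance across the three fits; the approximation reproduces the
qualitative behaviour of real analyses (PM intervals spilling far outside
[0, 100]%), and the country bootstrap (`bootstrap_mediation()`) is
provided as the distribution-free check — delta and bootstrap standard
errors for the mediation effect agree within a few percent on the default
synthetic scenario. PM is undefined (an error) when $|\theta_T|$ falls
below 10⁻¹²; its p-value is a Wald test of PM = 0, which under the
approximation is equivalent to the mediation-effect test. Normal-theory
two-sided p-values are used throughout and no multiple-testing correction
is applied (none is standard for a single pre-specified decomposition per
stratum).

## The synthetic-data generator

`scenario_truth()` + `generate_pandemic_panel()` realise the causal
diagram with known parameters, so the pipeline can be validated against
ground truth. Defaults describe the study conditions and were fixed once:

| parameter | default | units / meaning |
|---|---|---|
| `n_high`, `n_middle` | 31, 14 | countries per income stratum |
| `alpha` | 0.01 | mobility %-points per daily death |
| `beta` | 0.03 | excess search points per mobility %-point |
| `gamma` | 7×10⁻⁴ | direct effect, excess points per daily death |
| `seasonal_amplitude` | 10 | annual cycle of the search baseline |
| `baseline_level` | 50 | mean search volume (0–100 scale) |
| `sigma_search` | 2 | AR(1) innovation SD of the baseline (φ = 0.5) |
| `sigma_mobility` | 1.5 | i.i.d. daily mobility noise SD |
| `sigma_mediator_shock` | 1 | month-level mobility shock SD |
| `sigma_outcome` | 0.5 | i.i.d. weekly excess noise SD |
| `sigma_deaths` | 5 | scale of non-negative daily death noise |

These give a true total effect of 10⁻³ and a true proportion mediated of
exactly 30%. Death waves are 2–3 Gaussian bumps per country with peaks of
50–2000 deaths/day and widths of 15–45 days, so monthly mean exposures
span roughly 0–1500 and effects are of order 0.1–1 search point — the
regime in which per-death effect estimates are ≈10⁻⁴–10⁻³. No published
noise magnitudes exist for these streams; the noise SDs were chosen once
to make recovery tests informative (estimates visibly noisy but stable),
not to match any dataset.

Two structural choices deserve explanation:

* **The mediator responds to monthly-mean exposure held constant within
  the month**, not to daily deaths, because the mediation models operate
  at monthly resolution; tying the structural signal to the monthly mean
  avoids aggregation-induced attenuation that would otherwise contaminate
  recovery tests with a bias that is an artefact of the generator, not of
  the estimator.
* **The mediator needs variation of its own.** If mobility were exactly
  `alpha × deaths + country effect (+ month effect)`, the within-transformed
  mediator would be exactly collinear with the exposure and model 2 would
  be singular — exact zero-noise recovery of $(\theta_M, \theta_A)$ would
  be mathematically impossible. Real mobility has large
  exposure-independent components (policy calendars, holidays), and the
  generator mirrors that with a month-level mobility shock
  (`sigma_mediator_shock`, default 1 %-point, drawn per country-month).
  Because the shocks are genuine random draws, the mediator-model residual
  has real sampling variation and delta-method inference stays calibrated.
  In the *exactly* noise-free limit (shock and noise both zero) the
  generator instead adds a deterministic country-by-month pattern that is
  two-way demeaned and projected orthogonal to the within-transformed
  exposure: it keeps model 2 identified while leaving every coefficient
  exact, which is what makes machine-precision recovery tests possible.
  An earlier design that used the fixed orthogonal pattern at all noise
  levels was rejected: a fixed pattern inflates the mediator-model
  residual variance without contributing sampling variation, making the
  Sobel test degenerate under the null.

Randomness is counter-based: the master seed expands through a
double-round MINSTD mix into per-country, per-purpose substreams, so
outputs are byte-reproducible and adding a country never reshuffles the
draws of existing ones. Structural excess is injected *additively* onto
the baseline series without re-clipping, so the conservation identity
(pandemic series − baseline series = injected excess, week by week) holds
exactly and is tested.

What the generator does **not** emulate: Google-Trends-style integer
quantisation and query-share renormalisation, epidemic-dynamics (SIR)
realism in the death curves, weekday structure in mobility, and
cross-country correlation of noise. Passing recovery tests therefore shows
that the estimators are correct *under the assumed model*, not that the
assumptions hold for any particular real dataset.

## Validation design and problem sizes

The acceptance layer checks, at these sizes (chosen to keep the full
validation run in the minutes range on one CPU):

* **Ratio identities** of published-style effect tables: feeding printed
  (mediation, total) pairs into `proportion_mediated()` reproduces the
  printed PM percentages after 1-decimal rounding.
* **Exact recovery** on a zero-noise panel (α = 2, β = 3, γ = 4 →
  θ_M = 6, θ_A = 4, θ_T = 10, PM = 60%) to 10⁻⁸.
* **Monte-Carlo recovery**: default 45-country scenario, pandemic window
  truncated to 24 months, 200 replicate seeds — mean PM within 5
  percentage points of 30%, mean total effect within 10% of 10⁻³.
* **Calibration**: 95% CI for θ_T covers the truth in 90–98% of 500
  replicates; under α = 0 the mediation-effect test rejects at nominal 5%
  between 2% and 9% of 1000 replicates (the Sobel test is conservative at
  small effect sizes — expected and documented behaviour).
* **Oracles**: the within estimator equals dummy-variable least squares to
  10⁻⁸; the product estimator equals the difference estimator on every
  stratum; the delta-method SE of θ_M is within 25% of a 500-resample
  country bootstrap.
* **Counterfactual engine**: zero excess when observed equals expected; a
  noise-free annual cycle forecast under D = 1 errs below 10⁻³ per week;
  95% forecast-interval coverage on 100 replicates of a known ARMA
  baseline lies in [88%, 99%].

## Known limitations

* The ingest layer takes a single consistent weekly series per country and
  term as given; it does not implement the stitching/rescaling needed to
  build a 7-year weekly series from overlapping shorter exports.
* No exogenous regressors, Box–Cox transforms or model averaging in the
  counterfactual stage; no lag structure in the panel (same-month
  association only); no sensitivity analysis for unmeasured confounding or
  time-varying-confounder mediation (g-methods).
* The PM covariance approximation is first-order; for small or
  sign-ambiguous total effects the PM interval should be read
  qualitatively and the bootstrap preferred.
* Plotting helpers draw generic counterfactual/trajectory/forest layouts,
  not publication facsimiles.
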