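---
title: "Country-level temperature-related mortality damage functions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Country-level temperature-related mortality damage functions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(climmort)
```

## The problem

Epidemiological studies estimate, for a limited set of countries with daily
mortality registries, how much climate change will raise heat-related
mortality and lower cold-related mortality over the twenty-first century.
Carbon-pricing and integrated-assessment work, however, needs a *damage
function* — a mapping from warming to mortality change — for **every**
country. climmort implements the extrapolation strategy that bridges the
two: model the published country-level mortality projections as a function
of each country's warming, baseline climatology and income, validate the
specification out of sample, and then evaluate the fitted function for all
countries under scenario warming fields.

## The model

For country $c$, scenario $s$ and period $t$, with warming
$T_{s,c,t}$ (°C relative to the 2001–2020 mean), the heat response in
percent is

$$Y^{hot}_{s,c,t} = \beta_1 T_{s,c,t} + \beta_2 T_{s,c,t}^2 +
\beta_3\, T_{s,c,t} H_c + \beta_4\, T_{s,c,t} H_c \log(\mathrm{GDPpc}_c)
+ \varepsilon_{s,c,t},$$

where $H_c$ is the population-weighted mean temperature of the hottest
month. The cold response replaces $H_c$ with the coldest-month temperature
$C_c$ and stops at the double interaction:

$$Y^{cold}_{s,c,t} = \beta_1 T_{s,c,t} + \beta_2 T_{s,c,t}^2 +
\beta_3\, T_{s,c,t} C_c + \varepsilon_{s,c,t}.$$

Neither model has an intercept: zero warming must imply zero damage, which
is what makes the fitted surface interpretable as a damage function. Four
nested specifications (warming only; + quadratic; + climate interaction;
+ income interaction) are compared; the richest heat model and the
three-term cold model are the preferred specifications, selected by
leave-one-out cross-validation (below). The net effect is defined as
$Y^{net} = Y^{hot} + Y^{cold}$ and the package enforces this identity to
machine precision everywhere.

Key signs with the published coefficients: $\beta_3 > 0$ for heat (already
hot places are hurt more per degree) and $\beta_4 < 0$ (income attenuates
heat damages — the income-based adaptation channel, e.g. air-conditioning
uptake). The marginal effect of baseline heat, $\beta_3 + \beta_4 \log
\mathrm{GDPpc}$, stays positive up to $\log \mathrm{GDPpc} \approx 12.8$,
far above any observed income, so heat damages increase with baseline heat
throughout the plausible range. One caveat we flag rather than resolve:
the published narrative describes the quadratic heat coefficient as
positive while the printed preferred-model estimate is $-0.0629$ (not
significant); `published_betas()` carries the printed table values, which
are treated as authoritative. Likewise the cold model's climate
interaction is the three-term model's printed $-0.0113$, not the
four-term model's $-0.0127$.

## Estimation and inference

* **Estimator.** Ordinary least squares through the origin
  (`fit_cluster_ols()`, QR-based). Tests verify the solution against
  explicit normal equations on every instance.
* **Clustered covariance.** All eight of a country's observations derive
  from the same underlying exposure–response curve, so residuals are
  correlated within country. The covariance is the cluster sandwich with
  the CR1 small-sample factor $\tfrac{G}{G-1}\tfrac{n-1}{n-k}$ (the
  convention of the major commercial econometrics packages; configurable
  via `ssc`, and cross-checked in the tests against
  `sandwich::vcovCL(type = "HC1", cadjust = TRUE)`). Coefficient t
  statistics use $G-1$ degrees of freedom.
* **Fit statistics.** Because there is no intercept, $R^2$ is computed
  against the *uncentered* total sum of squares (the standard no-constant
  convention), with the centered variant reported alongside;
  $\mathrm{RMSE} = \sqrt{SSR/(n-k)}$; the $F$ statistic is the classical
  (non-robust) no-intercept $F$ on $(k,\,n-k)$ degrees of freedom. The
  published validation tables do not state their conventions, so all
  variants are exposed.
* **Cross-validation.** The selection criterion is leave-one-out RMSE.
  Since "one unit" is ambiguous in a clustered panel, the default fold is
  an entire country — matching both the clustering structure and the end
  use (extrapolation to countries never seen in estimation) — with
  per-observation folds available (`unit = "observation"`). The CV
  pseudo-$R^2$ uses the centered total sum of squares, again with the
  uncentered variant reported. Ties in CV RMSE break by CV MAE, then by
  fewer terms.

## Projection and uncertainty

`project_mortality()` evaluates the fitted damage functions at each
country's covariates and warming. With adaptation on, the income entering
the heat model is the projected per-capita GDP at the period midpoint
(2055 for mid-century, 2090 for end-of-century; configurable), linearly
interpolated between income-path nodes; "current" income is the base-year
value. Countries lacking covariates, warming, or income paths become rows
of an explicit missing-country report — never silent zeros.

Intervals are delta-method: predictions are linear in the coefficients, so
$x'\hat\beta \pm q\sqrt{x'Vx}$ is exact given $V$. The default quantile is
normal ($q = 1.96$ at 95%), with Student $t$ on $G-1$ degrees of freedom
available; only coefficient uncertainty is propagated — warming fields are
treated as fixed inputs. Because heat and cold are estimated in separate
regressions, their cross-covariance is unidentified; the net-effect
variance is the sum of the two, a documented independence assumption.

`global_rate_change()` aggregates with weights proportional to expected
baseline deaths (`mortality_rate * population`) — the natural weights when
the target is the global mortality *rate* — with population weights as a
sensitivity. The global interval uses the weighted-sum design vector
$x_{glob} = \sum_c w_c x_c$ against each covariance: averaging per-country
variances would wrongly shrink uncertainty that is perfectly correlated
across countries through the shared coefficients.
`warming_response_curve()` pattern-scales a grid of global-mean warming
(default 0–5 °C in 0.1 °C steps) through per-country ratios $r_c$ (the
no-intercept slope of country on global warming across scenario×period
fields) and aggregates at each grid point; the curve passes exactly
through the origin. A configurable preindustrial offset (default 1 °C)
converts the 2001–2020-relative axis to a preindustrial-relative one.

## Climatology covariates

`country_climatology()` collapses a gridded monthly climatology to
population-weighted country monthly means; `extreme_months()` then takes
the hottest and coldest of the twelve weighted means. The order of
operations is deliberate — weight first, then extremize — because the
covariate is a single country scalar ("the population-weighted average
temperature in the hottest month"); a constructed counterexample in the
tests shows the two orders genuinely differ. Ties break to the earliest
calendar month; months are 1-based with January = 1; cells belong wholly
to the country of their mask; multi-year series are assumed pre-averaged
to a 12-month climatology (mean over years per calendar month) before
entry. Zero-population cells never influence the weighted means, and a
country with zero total population is an error rather than a NaN.

## The synthetic world

The generator (`sim_config()` and friends) exists so every downstream
stage is testable without external data. Its defaults *are* the study
conditions:

* 23 countries — the size of the original estimation panel — observed
  under 4 RCPs × 2 periods (184 rows per outcome).
* True coefficients = the published preferred-model estimates, so
  synthetic magnitudes resemble the published ones.
* Noise = country random effect + i.i.d. observation noise, both normal,
  with total SDs matched to the published in-sample residual scales:
  $\sqrt{1.80^2 + 1.35^2} = 2.25$% for heat and
  $\sqrt{0.36^2 + 0.27^2} = 0.45$% for cold. The source data's residual
  law is not published; normal components were chosen for tractable
  coverage analysis, and the country effect induces exactly the
  within-country correlation the clustered estimator must absorb.
* Climatology uniform on [18, 34] °C (hottest month) and [−15, 15] °C
  (coldest month) — disjoint intervals, so `hottest > coldest` holds
  surely while both laws remain uniform; income log-uniform on
  [1 000, 60 000] PPP dollars (log-GDP ≈ 6.9–11, spanning poor to rich);
  population log-uniform on [10^6^, 2×10^8^]; crude mortality uniform on
  [0.005, 0.012] deaths per person-year (bracketing the world rate).
* Global-mean warming vs. 2001–2020 of 0.7/0.9/1.0/1.4 °C (mid) and
  0.8/1.2/1.8/3.3 °C (end) across RCP 2.6/4.5/6.0/8.5 — consistent, after
  adding back the ~1 °C realised by 2001–2020, with the roughly 2.2 °C
  (RCP 4.5) and 4.3 °C (RCP 8.5) above preindustrial quoted for
  end-of-century. Country warming is the global value times a log-normal
  ratio with mean 1 and dispersion 0.15 (pattern scaling).
* Income growth, when not supplied, is uniform on [0, 3]% per year,
  compounding from 2015.

Every generator call consumes a single seeded RNG stream
(`withr::with_seed`), so identical configs give bit-identical outputs and
no global RNG state leaks. What the toy world deliberately does *not*
emulate: spatial autocorrelation of real climate fields, multiple
socioeconomic pathways per country, and non-normal or heteroskedastic
projection errors — so passing tests demonstrate correctness of the
machinery under the stated error model, not robustness to every feature
of real data.

## What the tests establish

With the defaults above, 500 noise replicates on a fixed world give
coefficient estimates unbiased to Monte-Carlo precision and 95%
cluster-robust CI coverage between 90% and 98% for every coefficient of
both preferred models — slight undercoverage relative to nominal is the
expected finite-cluster (G = 23) degradation of CR1 inference and is the
reason the t reference uses $G-1$ degrees of freedom. Generating heat data
from the four-term truth and re-running the full selection machinery
recovers that specification by LOOCV RMSE in well over 80% of 200
replicates. These replicate counts keep the default test run around half a
minute on one core.

## Numerical choices and edge cases

* Rank-deficient designs abort with the offending columns named (the
  four-term heat model needs at least three distinct countries; with two,
  the interaction columns are exactly collinear).
* A single cluster, fewer rows than columns, or fewer than three CV folds
  are errors, as are negative warming in response tables, nonpositive
  incomes, and mortality rates outside [0, 1).
* Quadratic forms are floored at zero before square roots; covariances are
  symmetrized; a materially negative quadratic form (non-PSD covariance)
  is an error.
* At `dT = 0` the design row is identically zero, so point estimates *and*
  interval bounds are exactly 0 — asserted, not approximate.
* With the published cold coefficients the cold response crosses zero near
  `dT ≈ 5.5` °C for the coldest climates (around −30 °C): the fitted
  cold benefit is not globally monotone, and sign-based checks are
  restricted to warming up to 5 °C.

## Known limitations

The damage functions inherit the 23-country panel's coverage: hot, poor
countries are underrepresented in estimation yet dominate projected
damages, so extrapolation uncertainty there is larger than the intervals
express. Only income-based adaptation is modelled — no heat-alert systems,
behavioural change, or technology trends. Warming-field uncertainty is not
propagated, and the hot/cold independence assumption makes net intervals
conservative or anticonservative depending on the unobserved
cross-covariance sign.
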