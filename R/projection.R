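# internal: per-row delta-method variances x' V x for a design matrix
quad_form_rows <- function(X, V) {
  rowSums((X %*% V) * X)
}

#' Delta-method interval for a linear damage-function prediction
#'
#' Predictions are linear in the coefficients, so the interval
#' `x'beta +/- q * sqrt(x' V x)` is exact given the coefficient
#' covariance.  `q` is the standard-normal quantile by default, or Student
#' t on `G - 1` degrees of freedom (G = number of clusters) when
#' `quantile = "t"`.
#'
#' @param fit A `damage_fit`.
#' @param x Design vector aligned with `fit$beta`.
#' @param level Confidence level in (0, 1).
#' @param quantile `"z"` (default) or `"t"`.
#' @return Named numeric `c(fit =, low =, high =)`.
#' @export
#' @examples
#' # zero design vector (no warming) gives a degenerate [0, 0] interval
projection_interval <- function(fit, x, level = 0.95,
                                quantile = c("z", "t")) {
  quantile <- match.arg(quantile)
  stopifnot(inherits(fit, "damage_fit"))
  x <- as.numeric(x)
  if (length(x) != length(fit$beta)) {
    abort_climmort("design vector length %d does not match %d coefficients",
                   length(x), length(fit$beta))
  }
  v <- drop(t(x) %*% fit$vcov %*% x)
  if (v < -1e-8 * max(1, sum(x^2))) {
    abort_climmort("coefficient covariance is not positive semidefinite")
  }
  v <- max(v, 0)
  q <- ci_quantile(level, quantile, df = fit$df)
  point <- sum(x * fit$beta)
  c(fit = point, low = point - q * sqrt(v), high = point + q * sqrt(v))
}

# internal: log income to use for the heat design under a given adaptation
# setting; `income_at_period` is a vector aligned with `df` rows (or NULL)
adapted_covariates <- function(covariates, df, adaptation, income_at_period) {
  if (!adaptation) return(covariates)
  if (is.null(income_at_period)) {
    abort_climmort("adaptation = TRUE requires projected incomes")
  }
  if (any(income_at_period <= 0, na.rm = TRUE)) {
    abort_climmort("projected incomes must be strictly positive")
  }
  income_at_period
}

#' Project one country's mortality-rate change
#'
#' Evaluates the fitted heat and cold damage functions at a single
#' country's covariates and warming `dT`.  With `adaptation = TRUE` the
#' income entering the heat model's triple interaction is
#' `income_at_period` (the projected per-capita GDP at the period
#' midpoint) instead of the record's current income; specifications
#' without an income term are unaffected.
#'
#' @param fit_hot,fit_cold `damage_fit` objects for the heat and cold
#'   outcomes.
#' @param record One-row data frame of the country's covariates.
#' @param dT Country warming (degrees C vs. 2001-2020), `>= 0`.
#' @param adaptation Use projected income in the heat model?
#' @param income_at_period Projected per-capita GDP (PPP dollars) at the
#'   period midpoint; required when `adaptation = TRUE`.
#' @param level,quantile Interval options, see [projection_interval()].
#' @return One-row tibble: `country`, `adaptation`, `dT`, `y_hot`,
#'   `y_cold`, `y_net` (= `y_hot + y_cold` exactly), `se_net`, `ci_low`,
#'   `ci_high` (net-effect interval; the heat and cold coefficient vectors
#'   come from separate regressions and are treated as independent, so
#'   `Var(net) = Var(hot) + Var(cold)`).
#' @export
project_country <- function(fit_hot, fit_cold, record, dT,
                            adaptation = FALSE, income_at_period = NULL,
                            level = 0.95, quantile = c("z", "t")) {
  quantile <- match.arg(quantile)
  stopifnot(inherits(fit_hot, "damage_fit"), inherits(fit_cold, "damage_fit"))
  if (!is.finite(dT) || dT < 0) abort_climmort("'dT' must be finite and >= 0")
  record <- tibble::as_tibble(record)[1, ]
  rec_hot <- record
  if (adaptation) {
    inc <- adapted_covariates(record, NULL, TRUE, income_at_period)
    rec_hot$gdp_pc_ppp <- inc
    rec_hot$log_gdp_pc <- log(inc)
  }
  obs <- tibble::tibble(country = record$country, dT = dT)
  x_hot <- as.numeric(build_design(obs, rec_hot, fit_hot$spec))
  x_cold <- as.numeric(build_design(obs, rec_hot, fit_cold$spec))
  y_hot <- sum(x_hot * fit_hot$beta)
  y_cold <- sum(x_cold * fit_cold$beta)
  v <- max(drop(t(x_hot) %*% fit_hot$vcov %*% x_hot), 0) +
       max(drop(t(x_cold) %*% fit_cold$vcov %*% x_cold), 0)
  q <- ci_quantile(level, quantile,
                   df = min(fit_hot$df, fit_cold$df))
  y_net <- y_hot + y_cold
  tibble::tibble(
    country = record$country, adaptation = adaptation, dT = dT,
    y_hot = y_hot, y_cold = y_cold, y_net = y_net,
    se_net = sqrt(v), ci_low = y_net - q * sqrt(v),
    ci_high = y_net + q * sqrt(v)
  )
}

# internal: projected per-capita income at `year`, linearly interpolated
# between income-path nodes, one value per requested country
income_at_year <- function(income_paths, countries, year) {
  assert_columns(income_paths, c("country", "year", "gdp_pc_ppp"),
                 "income_paths")
  vapply(countries, function(cc) {
    p <- income_paths[income_paths$country == cc, ]
    if (nrow(p) == 0) return(NA_real_)
    if (nrow(p) == 1) return(p$gdp_pc_ppp)
    approx(p$year, p$gdp_pc_ppp, xout = year, rule = 2)$y
  }, numeric(1))
}

#' Project mortality-rate changes for every country under a warming field
#'
#' Applies the fitted heat and cold damage functions to each
#' country x scenario x period row of `warming`.  Countries present in the
#' warming field but lacking covariates (or with missing `dT`, or — under
#' adaptation — missing income paths) are not silently dropped or zeroed:
#' they are collected in a missing-country report attached as attribute
#' `"missing"`.
#'
#' @inheritParams project_country
#' @param covariates Country records (must include `hottest_month_temp`,
#'   `coldest_month_temp` and income fields as required by the fitted
#'   specs).
#' @param warming Warming field: `country`, `scenario`, `period`, `dT`
#'   (rows with `country == "GLOBAL"` are set aside and ignored here).
#' @param income_paths Income paths (`country`, `year`, `gdp_pc_ppp`)
#'   used when `adaptation = TRUE`.
#' @param period_years Named vector mapping period labels to the midpoint
#'   calendar year at which projected income is evaluated.
#' @return Tibble of class `mortality_projection`: one row per projectable
#'   country x scenario x period with `y_hot`, `y_cold`,
#'   `y_net = y_hot + y_cold`, `se_net`, `ci_low`, `ci_high`, and the
#'   design vectors used (`x_hot`, `x_cold`, list columns — needed for
#'   exact global aggregation of coefficient uncertainty).  Attributes:
#'   `"missing"` (report tibble), `"fits"` (the two fits).
#' @export
project_mortality <- function(fit_hot, fit_cold, covariates, warming,
                              adaptation = FALSE, income_paths = NULL,
                              period_years = c(mid = 2055, end = 2090),
                              level = 0.95, quantile = c("z", "t")) {
  quantile <- match.arg(quantile)
  stopifnot(inherits(fit_hot, "damage_fit"), inherits(fit_cold, "damage_fit"))
  assert_columns(warming, c("country", "scenario", "period", "dT"), "warming")
  assert_columns(covariates, "country", "covariates")
  w <- dplyr::filter(warming, .data$country != GLOBAL_ID)
  if (length(intersect(w$country, covariates$country)) == 0) {
    abort_climmort("no overlap between warming-field and covariate countries")
  }

  miss <- tibble::tibble(country = character(), scenario = character(),
                         period = character(), reason = character())
  no_cov <- !(w$country %in% covariates$country)
  if (any(no_cov)) {
    miss <- dplyr::bind_rows(miss, dplyr::mutate(
      w[no_cov, c("country", "scenario", "period")],
      reason = "no covariate record"))
    w <- w[!no_cov, ]
  }
  bad_dt <- !is.finite(w$dT)
  if (any(bad_dt)) {
    miss <- dplyr::bind_rows(miss, dplyr::mutate(
      w[bad_dt, c("country", "scenario", "period")],
      reason = "missing warming"))
    w <- w[!bad_dt, ]
  }

  cov_hot <- covariates
  if (adaptation) {
    if (is.null(income_paths)) {
      abort_climmort("adaptation = TRUE requires 'income_paths'")
    }
    # one heat design per period: income at that period's midpoint year
    per_period <- lapply(PERIOD_LEVELS, function(p) {
      inc <- income_at_year(income_paths, covariates$country,
                            period_years[[p]])
      cv <- covariates
      cv$gdp_pc_ppp <- inc
      cv$log_gdp_pc <- log(inc)
      cv
    })
    names(per_period) <- PERIOD_LEVELS
    no_inc <- covariates$country[is.na(per_period[[1]]$gdp_pc_ppp)]
    drop_rows <- w$country %in% no_inc
    if (any(drop_rows)) {
      miss <- dplyr::bind_rows(miss, dplyr::mutate(
        w[drop_rows, c("country", "scenario", "period")],
        reason = "no income path"))
      w <- w[!drop_rows, ]
    }
  }
  if (nrow(w) == 0) abort_climmort("no projectable rows remain")

  Xh <- matrix(NA_real_, nrow(w), length(fit_hot$beta))
  for (p in unique(w$period)) {
    sel <- w$period == p
    cv <- if (adaptation) per_period[[p]] else cov_hot
    Xh[sel, ] <- as.matrix(build_design(w[sel, ], cv, fit_hot$spec))
  }
  Xc <- as.matrix(build_design(w, covariates, fit_cold$spec))

  y_hot <- drop(Xh %*% fit_hot$beta)
  y_cold <- drop(Xc %*% fit_cold$beta)
  v_net <- pmax(quad_form_rows(Xh, fit_hot$vcov), 0) +
           pmax(quad_form_rows(Xc, fit_cold$vcov), 0)
  q <- ci_quantile(level, quantile, df = min(fit_hot$df, fit_cold$df))

  out <- tibble::tibble(
    country = w$country, scenario = w$scenario, period = w$period,
    adaptation = adaptation, dT = w$dT,
    y_hot = y_hot, y_cold = y_cold, y_net = y_hot + y_cold,
    se_net = sqrt(v_net),
    ci_low = y_hot + y_cold - q * sqrt(v_net),
    ci_high = y_hot + y_cold + q * sqrt(v_net),
    x_hot = asplit(Xh, 1), x_cold = asplit(Xc, 1)
  )
  out <- tibble::new_tibble(out, class = "mortality_projection")
  attr(out, "missing") <- miss
  attr(out, "fits") <- list(hot = fit_hot, cold = fit_cold)
  attr(out, "level") <- level
  attr(out, "quantile") <- quantile
  out
}

#' Missing-country report of a projection
#'
#' @param projections A `mortality_projection`.
#' @return Tibble `country`, `scenario`, `period`, `reason` for every
#'   warming-field row that could not be projected.
#' @export
missing_report <- function(projections) {
  attr(projections, "missing") %||%
    tibble::tibble(country = character(), scenario = character(),
                   period = character(), reason = character())
}
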