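# internal: normalized aggregation weights for a set of countries
aggregation_weights <- function(countries, covariates, weight_scheme) {
  assert_columns(covariates, c("country", "population"), "covariates")
  idx <- match(countries, covariates$country)
  if (anyNA(idx)) {
    abort_climmort("no covariate record for country: %s",
                   paste(countries[is.na(idx)], collapse = ", "))
  }
  w <- switch(weight_scheme,
    baseline_deaths = {
      assert_columns(covariates, "mortality_rate", "covariates")
      covariates$mortality_rate[idx] * covariates$population[idx]
    },
    population = covariates$population[idx],
    abort_climmort("unknown weight scheme '%s'", weight_scheme)
  )
  if (sum(w) <= 0) abort_climmort("aggregation weights sum to zero")
  w / sum(w)
}

#' Aggregate country projections to a global mortality-rate change
#'
#' Computes the weighted global mean of the country percent changes, per
#' scenario x period x adaptation group.  Default weights are expected
#' baseline deaths (`mortality_rate * population`), the natural weights
#' when the target is the global mortality *rate*; population weights are
#' available for sensitivity.  The confidence interval is built from the
#' weighted-sum design vector `x_glob = sum(w_c * x_c)` evaluated against
#' each outcome's coefficient covariance — countries share the same
#' coefficient vector, so their uncertainties are perfectly correlated and
#' must not be averaged away; heat and cold variances are then added
#' (separate fits, treated as independent).
#'
#' @param projections A `mortality_projection` from [project_mortality()].
#' @param covariates Country records supplying the weights.
#' @param weight_scheme `"baseline_deaths"` (default) or `"population"`.
#' @param level,quantile Interval options (default: the ones stored on the
#'   projection object).
#' @return Tibble of class `global_summary`, one row per
#'   scenario x period x adaptation: `y_hot_global`, `y_cold_global`,
#'   `y_net_global` (= hot + cold), `se_net`, `ci_low`, `ci_high`,
#'   `weight_scheme`, `n_countries`.
#' @export
global_rate_change <- function(projections, covariates,
                               weight_scheme = c("baseline_deaths",
                                                 "population"),
                               level = NULL, quantile = NULL) {
  weight_scheme <- match.arg(weight_scheme)
  fits <- attr(projections, "fits")
  if (is.null(fits)) {
    abort_climmort(
      "projections must carry their fits (use project_mortality())")
  }
  if (nrow(projections) == 0) abort_climmort("no non-missing projections")
  level <- level %||% attr(projections, "level") %||% 0.95
  quantile <- quantile %||% attr(projections, "quantile") %||% "z"
  q <- ci_quantile(level, quantile,
                   df = min(fits$hot$df, fits$cold$df))

  groups <- dplyr::group_split(
    dplyr::group_by(tibble::as_tibble(projections),
                    .data$scenario, .data$period, .data$adaptation))
  purrr::map_dfr(groups, function(g) {
    w <- aggregation_weights(g$country, covariates, weight_scheme)
    xg_hot <- Reduce(`+`, purrr::map2(g$x_hot, w, ~ .x * .y))
    xg_cold <- Reduce(`+`, purrr::map2(g$x_cold, w, ~ .x * .y))
    v <- max(drop(t(xg_hot) %*% fits$hot$vcov %*% xg_hot), 0) +
         max(drop(t(xg_cold) %*% fits$cold$vcov %*% xg_cold), 0)
    y_hot <- sum(w * g$y_hot)
    y_cold <- sum(w * g$y_cold)
    tibble::tibble(
      scenario = g$scenario[1], period = g$period[1],
      adaptation = g$adaptation[1],
      y_hot_global = y_hot, y_cold_global = y_cold,
      y_net_global = y_hot + y_cold,
      se_net = sqrt(v),
      ci_low = y_hot + y_cold - q * sqrt(v),
      ci_high = y_hot + y_cold + q * sqrt(v),
      weight_scheme = weight_scheme, n_countries = nrow(g)
    )
  }) |>
    tibble::new_tibble(class = "global_summary")
}

#' Convert a mortality-rate change to excess deaths
#'
#' `excess = (rate_change_pct / 100) * projected_deaths`.  Vectorized: pass
#' country-level rate changes and country-level projected deaths and sum
#' the result for a country-by-country accounting, or pass the global rate
#' change and total projected deaths.
#'
#' @param rate_change_pct Percent change(s) in the mortality rate.
#' @param projected_deaths Baseline projected deaths (count, `>= 0`) in the
#'   same year/period.
#' @return Excess deaths (same length as the longer input).
#' @export
#' @examples
#' excess_deaths(1, 1e6)   # 10,000
excess_deaths <- function(rate_change_pct, projected_deaths) {
  if (any(!is.finite(projected_deaths)) || any(projected_deaths < 0)) {
    abort_climmort("'projected_deaths' must be finite and nonnegative")
  }
  (rate_change_pct / 100) * projected_deaths
}

#' Country warming ratios from a set of warming fields
#'
#' Pattern scaling: each country's warming is approximated as a constant
#' multiple `r_c` of the global-mean warming.  `r_c` is the no-intercept
#' least-squares slope of country `dT` on global `dT` across the available
#' scenario x period fields; a country observed in fewer than two fields
#' gets the single-point ratio with a warning.
#'
#' @param warming Warming field(s): `country`, `scenario`, `period`, `dT`,
#'   including `country == "GLOBAL"` rows giving the global-mean warming
#'   per scenario x period (at least two with `dT > 0`).
#' @return Tibble `country`, `ratio`, `n_points`.
#' @export
pattern_ratios <- function(warming) {
  assert_columns(warming, c("country", "scenario", "period", "dT"), "warming")
  glob <- dplyr::filter(warming, .data$country == GLOBAL_ID,
                        is.finite(.data$dT), .data$dT > 0)
  if (nrow(glob) < 2) {
    abort_climmort("need >= 2 warming fields with positive global dT")
  }
  ctry <- warming |>
    dplyr::filter(.data$country != GLOBAL_ID, is.finite(.data$dT)) |>
    dplyr::inner_join(glob[c("scenario", "period", "dT")],
                      by = c("scenario", "period"),
                      suffix = c("", "_global"))
  out <- ctry |>
    dplyr::group_by(.data$country) |>
    dplyr::summarise(
      ratio = sum(.data$dT * .data$dT_global) / sum(.data$dT_global^2),
      n_points = dplyr::n(), .groups = "drop"
    )
  single <- out$country[out$n_points < 2]
  if (length(single) > 0) {
    warning(sprintf("ratio from a single field for: %s",
                    paste(single, collapse = ", ")), call. = FALSE)
  }
  out
}

#' Global mortality response as a function of global-mean warming
#'
#' Traces the aggregated heat, cold and net mortality-rate changes along a
#' grid of global-mean warming levels: at each grid point every country
#' warms by `r_c` times the global value (pattern scaling), the damage
#' functions are evaluated, and the country values are aggregated as in
#' [global_rate_change()].  The curve passes exactly through the origin.
#'
#' @inheritParams project_mortality
#' @param ratios Country warming ratios from [pattern_ratios()] (or the
#'   `"ratios"` attribute of [sim_warming()]).
#' @param global_dT Grid of global-mean warming values (degrees C vs.
#'   2001-2020, all `>= 0`).
#' @param income_year Calendar year whose projected income is used when
#'   `adaptation = TRUE` (default: the end-of-century midpoint).
#' @param weight_scheme Aggregation weights, see [global_rate_change()].
#' @param preindustrial_offset Degrees C separating the 2001-2020 baseline
#'   from preindustrial; reported as the extra column
#'   `global_dT_preindustrial = global_dT + offset`.
#' @return Tibble of class `mortality_curve`: `global_dT`,
#'   `global_dT_preindustrial`, `y_hot`, `y_cold`, `y_net`, `ci_low`,
#'   `ci_high` (net-effect interval).
#' @export
warming_response_curve <- function(fit_hot, fit_cold, covariates, ratios,
                                   global_dT = seq(0, 5, by = 0.1),
                                   adaptation = FALSE, income_paths = NULL,
                                   income_year = 2090,
                                   weight_scheme = c("baseline_deaths",
                                                     "population"),
                                   level = 0.95, quantile = c("z", "t"),
                                   preindustrial_offset = 1.0) {
  weight_scheme <- match.arg(weight_scheme)
  quantile <- match.arg(quantile)
  if (any(!is.finite(global_dT)) || any(global_dT < 0)) {
    abort_climmort("'global_dT' grid values must be finite and >= 0")
  }
  assert_columns(ratios, c("country", "ratio"), "ratios")
  if (any(ratios$ratio <= 0)) {
    abort_climmort("warming ratios must be strictly positive")
  }
  cc <- dplyr::inner_join(covariates, ratios, by = "country")
  if (nrow(cc) == 0) {
    abort_climmort("no overlap between covariate and ratio countries")
  }
  if (adaptation) {
    if (is.null(income_paths)) {
      abort_climmort("adaptation = TRUE requires 'income_paths'")
    }
    inc <- income_at_year(income_paths, cc$country, income_year)
    keep <- !is.na(inc)
    cc <- cc[keep, ]
    cc$gdp_pc_ppp <- inc[keep]
    cc$log_gdp_pc <- log(inc[keep])
  }
  w <- aggregation_weights(cc$country, covariates, weight_scheme)
  q <- ci_quantile(level, quantile, df = min(fit_hot$df, fit_cold$df))

  rows <- purrr::map_dfr(global_dT, function(g) {
    obs <- tibble::tibble(country = cc$country, dT = cc$ratio * g)
    Xh <- as.matrix(build_design(obs, cc, fit_hot$spec))
    Xc <- as.matrix(build_design(obs, cc, fit_cold$spec))
    xg_hot <- drop(w %*% Xh)
    xg_cold <- drop(w %*% Xc)
    y_hot <- sum(xg_hot * fit_hot$beta)
    y_cold <- sum(xg_cold * fit_cold$beta)
    v <- max(drop(t(xg_hot) %*% fit_hot$vcov %*% xg_hot), 0) +
         max(drop(t(xg_cold) %*% fit_cold$vcov %*% xg_cold), 0)
    tibble::tibble(
      global_dT = g,
      global_dT_preindustrial = g + preindustrial_offset,
      y_hot = y_hot, y_cold = y_cold, y_net = y_hot + y_cold,
      ci_low = y_hot + y_cold - q * sqrt(v),
      ci_high = y_hot + y_cold + q * sqrt(v)
    )
  })
  tibble::new_tibble(rows, class = "mortality_curve")
}
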