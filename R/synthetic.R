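#' Configuration for the synthetic-world generator
#'
#' Bundles every knob of the synthetic-data module.  The defaults define a
#' toy study: 23 countries (the size of the published estimation panel),
#' true damage-function coefficients equal to the published preferred
#' specifications (heat model 4, cold model 3, see [published_betas()]),
#' and clustered noise whose total standard deviation matches the published
#' in-sample residual scales (about 2.25% for heat, 0.45% for cold), split
#' into a country-level random effect and i.i.d. observation noise.
#'
#' @param n_countries Number of countries (>= 2).
#' @param seed Integer seed; every generator draws from a stream derived
#'   from it, so identical configs give bit-identical outputs.
#' @param beta_hot True heat coefficients, length 4, ordered as
#'   `damage_spec("heat", 4)$terms` (units % per degree C and products).
#' @param beta_cold True cold coefficients, length 3, ordered as
#'   `damage_spec("cold", 3)$terms`.
#' @param sigma_country Between-country noise SDs (%), named `hot`/`cold`:
#'   a draw shared by all of a country's rows, inducing the within-country
#'   residual correlation the clustered estimator must absorb.
#' @param sigma_obs Within-country (observation) noise SDs (%), `hot`/`cold`.
#' @param hottest_range,coldest_range Uniform sampling intervals (degrees C)
#'   for the hottest- and coldest-month mean temperatures.
#' @param income_range Log-uniform bounds for per-capita GDP (PPP dollars).
#' @param population_range Log-uniform bounds for population (persons).
#' @param mortality_range Uniform bounds for the baseline crude mortality
#'   rate (deaths per person-year).
#' @param pattern_spread Dispersion of the country warming ratios around 1
#'   (log-normal sdlog); 0 means every country warms exactly at the global
#'   rate.
#' @param global_dT Global-mean warming (degrees C vs. 2001-2020) per
#'   scenario x period; defaults to [default_global_warming()].
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_countries = 5, seed = 1)
#' sim_world(cfg)
sim_config <- function(n_countries = 23L,
                       seed = 42L,
                       beta_hot = published_betas("heat", 4),
                       beta_cold = published_betas("cold", 3),
                       sigma_country = c(hot = 1.80, cold = 0.36),
                       sigma_obs = c(hot = 1.35, cold = 0.27),
                       hottest_range = c(18, 34),
                       coldest_range = c(-15, 15),
                       income_range = c(1000, 60000),
                       population_range = c(1e6, 2e8),
                       mortality_range = c(0.005, 0.012),
                       pattern_spread = 0.15,
                       global_dT = default_global_warming()) {
  if (!is.numeric(n_countries) || n_countries < 2) {
    abort_climmort("'n_countries' must be an integer >= 2")
  }
  if (length(beta_hot) != 4 || length(beta_cold) != 3) {
    abort_climmort("'beta_hot' must have length 4 and 'beta_cold' length 3")
  }
  for (nm in c("sigma_country", "sigma_obs")) {
    s <- get(nm)
    if (length(s) != 2 || any(!is.finite(s)) || any(s < 0)) {
      abort_climmort("'%s' must be two nonnegative numbers (hot, cold)", nm)
    }
  }
  for (nm in c("hottest_range", "coldest_range", "income_range",
               "population_range", "mortality_range")) {
    r <- get(nm)
    if (length(r) != 2 || !all(is.finite(r)) || r[1] >= r[2]) {
      abort_climmort("'%s' must be an interval with lower < upper", nm)
    }
  }
  if (income_range[1] <= 0 || population_range[1] < 0) {
    abort_climmort("income must be positive and population nonnegative")
  }
  assert_number(pattern_spread, "pattern_spread", lower = 0)
  assert_columns(global_dT, c("scenario", "period", "dT"), "global_dT")
  if (any(global_dT$dT <= 0)) {
    abort_climmort("global warming 'dT' must be strictly positive")
  }
  structure(
    list(n_countries = as.integer(n_countries), seed = as.integer(seed),
         beta_hot = setNames(as.numeric(beta_hot),
                             damage_spec("heat", 4)$terms),
         beta_cold = setNames(as.numeric(beta_cold),
                              damage_spec("cold", 3)$terms),
         sigma_country = setNames(as.numeric(sigma_country), c("hot", "cold")),
         sigma_obs = setNames(as.numeric(sigma_obs), c("hot", "cold")),
         hottest_range = hottest_range, coldest_range = coldest_range,
         income_range = income_range, population_range = population_range,
         mortality_range = mortality_range,
         pattern_spread = pattern_spread,
         global_dT = tibble::as_tibble(global_dT)),
    class = "sim_config"
  )
}

#' Default global-mean warming table
#'
#' Global-mean temperature increase (degrees C, relative to the 2001-2020
#' average) for the four RCP scenarios at mid-century and end-of-century,
#' strictly increasing across RCP 2.6 -> 8.5 within each period.  End-of-
#' century values correspond to roughly 2.2 C (RCP 4.5) and 4.3 C (RCP 8.5)
#' above preindustrial when the ~1 C already realised by 2001-2020 is added
#' back.
#'
#' @return Tibble with columns `scenario`, `period`, `dT`.
#' @export
default_global_warming <- function() {
  tidyr::expand_grid(scenario = RCP_LEVELS, period = PERIOD_LEVELS) |>
    dplyr::mutate(dT = c(0.7, 0.8, 0.9, 1.2, 1.0, 1.8, 1.4, 3.3))
}

#' Generate a synthetic world of country records
#'
#' Samples `n_countries` country records: hottest- and coldest-month mean
#' temperatures uniform on their configured intervals, per-capita income
#' log-uniform, population log-uniform and baseline mortality rate uniform.
#' If the climate intervals overlap, the coldest-month draw is rejected
#' until it falls below the hottest-month draw, so
#' `hottest_month_temp > coldest_month_temp` always holds.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed override (default `config$seed`).
#' @return Tibble of country records: `country`, `hottest_month_temp`,
#'   `coldest_month_temp`, `gdp_pc_ppp`, `log_gdp_pc`, `population`,
#'   `mortality_rate`.
#' @export
sim_world <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_countries
  withr::with_seed(seed, {
    hot <- runif(n, config$hottest_range[1], config$hottest_range[2])
    cold <- runif(n, config$coldest_range[1], config$coldest_range[2])
    for (i in which(cold >= hot)) {
      while (cold[i] >= hot[i]) {
        cold[i] <- runif(1, config$coldest_range[1], config$coldest_range[2])
      }
    }
    gdp <- exp(runif(n, log(config$income_range[1]),
                     log(config$income_range[2])))
    pop <- exp(runif(n, log(config$population_range[1]),
                     log(config$population_range[2])))
    mort <- runif(n, config$mortality_range[1], config$mortality_range[2])
  })
  tibble::tibble(
    country = sprintf("C%03d", seq_len(n)),
    hottest_month_temp = hot,
    coldest_month_temp = cold,
    gdp_pc_ppp = gdp,
    log_gdp_pc = log(gdp),
    population = pop,
    mortality_rate = mort
  )
}

#' Generate a pattern-scaled country warming field
#'
#' Each country warms at a fixed multiple `r_c` of the global-mean warming
#' (pattern scaling).  The ratios are drawn once per country from a
#' log-normal with mean 1 and dispersion `pattern_spread`
#' (`sdlog = pattern_spread`, `meanlog = -pattern_spread^2 / 2`), so the
#' average country warming matches the global value and every ratio is
#' strictly positive; `pattern_spread = 0` collapses every ratio to 1.
#'
#' @inheritParams sim_world
#' @param global_dT Global-mean warming table (`scenario`, `period`, `dT`,
#'   all `dT > 0`); defaults to the one in `config`.
#' @param pattern_spread Ratio dispersion; defaults to the config value.
#' @return Tibble `country`, `scenario`, `period`, `dT`, including rows with
#'   `country == "GLOBAL"` carrying the global-mean warming.  The drawn
#'   ratios are attached as attribute `"ratios"`.
#' @export
sim_warming <- function(world, config, global_dT = config$global_dT,
                        pattern_spread = config$pattern_spread,
                        seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  assert_columns(world, "country", "world")
  assert_columns(global_dT, c("scenario", "period", "dT"), "global_dT")
  if (any(!is.finite(global_dT$dT)) || any(global_dT$dT <= 0)) {
    abort_climmort("global warming 'dT' must be strictly positive")
  }
  inc <- global_dT |>
    dplyr::mutate(scenario = factor(.data$scenario, RCP_LEVELS)) |>
    dplyr::arrange(.data$period, .data$scenario) |>
    dplyr::group_by(.data$period) |>
    dplyr::summarise(ok = all(diff(.data$dT) > 0), .groups = "drop")
  if (!all(inc$ok)) {
    abort_climmort("global 'dT' must increase strictly across RCPs within a period")
  }
  n <- nrow(world)
  assert_number(pattern_spread, "pattern_spread", lower = 0)
  withr::with_seed(seed, {
    r <- if (pattern_spread == 0) rep(1, n) else
      exp(rnorm(n, mean = -pattern_spread^2 / 2, sd = pattern_spread))
  })
  ratios <- tibble::tibble(country = world$country, ratio = r)
  field <- tidyr::expand_grid(country = world$country,
                              global_dT[c("scenario", "period", "dT")]) |>
    dplyr::rename(global = "dT") |>
    dplyr::left_join(ratios, by = "country") |>
    dplyr::mutate(dT = .data$ratio * .data$global) |>
    dplyr::select("country", "scenario", "period", "dT")
  out <- dplyr::bind_rows(
    field,
    dplyr::mutate(global_dT[c("scenario", "period", "dT")],
                  country = GLOBAL_ID) |>
      dplyr::select("country", "scenario", "period", "dT")
  )
  attr(out, "ratios") <- ratios
  out
}

#' Generate a mortality-response table from known coefficients
#'
#' Forward-simulates the heat and cold damage functions: for each
#' country x scenario x period row, the noiseless response is the design
#' row (heat model 4 / cold model 3 at the country's covariates and the
#' row's `dT`) times the configured true coefficients; noise is a
#' country-level random effect (`sigma_country`, shared by all the
#' country's rows per outcome) plus i.i.d. observation noise
#' (`sigma_obs`).  Rows with `dT = 0` therefore have exactly zero response
#' when both SDs are zero.
#'
#' @inheritParams sim_warming
#' @param warming A warming field from [sim_warming()] (rows with
#'   `country == "GLOBAL"` are ignored).
#' @return Tibble `country`, `scenario`, `period`, `dT`, `y_hot`, `y_cold`
#'   (percent changes in the mortality rate).
#' @export
sim_response_table <- function(world, warming, config,
                               seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  obs <- dplyr::filter(warming, .data$country != GLOBAL_ID)
  Xh <- as.matrix(build_design(obs, world, damage_spec("heat", 4)))
  Xc <- as.matrix(build_design(obs, world, damage_spec("cold", 3)))
  mu_hot <- drop(Xh %*% config$beta_hot)
  mu_cold <- drop(Xc %*% config$beta_cold)
  countries <- unique(obs$country)
  idx <- match(obs$country, countries)
  withr::with_seed(seed, {
    u_hot <- rnorm(length(countries), 0, config$sigma_country["hot"])
    u_cold <- rnorm(length(countries), 0, config$sigma_country["cold"])
    e_hot <- rnorm(nrow(obs), 0, config$sigma_obs["hot"])
    e_cold <- rnorm(nrow(obs), 0, config$sigma_obs["cold"])
  })
  tibble::tibble(
    country = obs$country, scenario = obs$scenario, period = obs$period,
    dT = obs$dT,
    y_hot = mu_hot + u_hot[idx] + e_hot,
    y_cold = mu_cold + u_cold[idx] + e_cold
  )
}

#' Generate a gridded toy world consistent with country climatology
#'
#' Expands each country into `cells_per_country` populated grid cells whose
#' population-weighted monthly means reproduce the country's 12-month
#' climatology exactly.  The country profile is a cosine annual cycle
#' peaking in July at `hottest_month_temp` and bottoming in January at
#' `coldest_month_temp`; cells carry a constant offset from the profile,
#' centred so the population-weighted offsets sum to zero.
#'
#' @inheritParams sim_warming
#' @param cells_per_country Populated cells per country (>= 1).
#' @param zero_pop_cells Additional zero-population cells per country
#'   (their temperatures must not influence any weighted statistic).
#' @param cell_offset_sd SD (degrees C) of the per-cell temperature offsets.
#' @return Long tibble, one row per cell: `lat_idx`, `lon_idx`, `country`,
#'   `pop`, `t01`..`t12`.
#' @export
sim_grids <- function(world, cells_per_country = 4L, seed = 99L,
                      zero_pop_cells = 0L, cell_offset_sd = 2) {
  assert_columns(world, c("country", "hottest_month_temp",
                          "coldest_month_temp", "population"), "world")
  if (cells_per_country < 1) {
    abort_climmort("'cells_per_country' must be >= 1")
  }
  m <- 1:12
  rows <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(world)), function(i) {
      H <- world$hottest_month_temp[i]
      C <- world$coldest_month_temp[i]
      profile <- (H + C) / 2 + (H - C) / 2 * cos(2 * pi * (m - 7) / 12)
      nc <- cells_per_country
      pop <- runif(nc, 0.2, 5) * world$population[i] / nc
      delta <- rnorm(nc, 0, cell_offset_sd)
      delta <- delta - sum(pop * delta) / sum(pop)   # exact weighted centring
      temps <- outer(delta, profile, `+`)
      colnames(temps) <- MONTH_COLS
      cells <- tibble::tibble(lat_idx = i, lon_idx = seq_len(nc),
                              country = world$country[i], pop = pop)
      cells <- dplyr::bind_cols(cells, tibble::as_tibble(temps))
      if (zero_pop_cells > 0) {
        zt <- matrix(rep(profile + 5, zero_pop_cells),
                     nrow = zero_pop_cells, byrow = TRUE)
        colnames(zt) <- MONTH_COLS
        zero <- tibble::tibble(lat_idx = i,
                               lon_idx = nc + seq_len(zero_pop_cells),
                               country = world$country[i], pop = 0)
        cells <- dplyr::bind_rows(cells,
                                  dplyr::bind_cols(zero, tibble::as_tibble(zt)))
      }
      cells
    })
  })
  rows
}

#' Generate compound-growth income paths
#'
#' Projects per-capita income as `gdp_base * (1 + g)^(year - base_year)`
#' with one constant growth rate per country — a single-path stand-in for a
#' socioeconomic scenario family (labelled SSP3, the pathway used for
#' income-based adaptation).
#'
#' @inheritParams sim_warming
#' @param growth Per-country annual growth rate: a single number recycled to
#'   all countries, a vector named by country, or `NULL` to draw rates
#'   uniformly on `[0, 0.03]`.  Rates must exceed -1.
#' @param years Years to evaluate (must bracket the projection period
#'   midpoints used downstream).
#' @param base_year Year at which incomes equal the world records' values.
#' @param scenario Label stored in the `scenario` column.
#' @return Tibble `country`, `scenario`, `year`, `gdp_pc_ppp`; the growth
#'   rates are attached as attribute `"growth"`.
#' @export
sim_income_paths <- function(world, growth = NULL,
                             years = seq(2015, 2100, by = 5),
                             base_year = 2015, scenario = "SSP3",
                             seed = 7L) {
  assert_columns(world, c("country", "gdp_pc_ppp"), "world")
  n <- nrow(world)
  if (is.null(growth)) {
    growth <- withr::with_seed(seed, runif(n, 0, 0.03))
  } else if (length(growth) == 1) {
    growth <- rep(growth, n)
  } else if (!is.null(names(growth))) {
    growth <- growth[world$country]
  }
  if (length(growth) != n || anyNA(growth) || any(!is.finite(growth))) {
    abort_climmort("'growth' must supply one finite rate per country")
  }
  if (any(growth <= -1)) {
    abort_climmort("growth rates must be greater than -1")
  }
  tidyr::expand_grid(i = seq_len(n), year = years) |>
    dplyr::mutate(
      country = world$country[.data$i],
      scenario = .env$scenario,
      gdp_pc_ppp = world$gdp_pc_ppp[.data$i] *
        (1 + growth[.data$i])^(.data$year - base_year)
    ) |>
    dplyr::select("country", "scenario", "year", "gdp_pc_ppp") |>
    structure(growth = setNames(growth, world$country))
}
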