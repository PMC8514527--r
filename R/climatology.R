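#' Population-weighted country monthly climatology
#'
#' Collapses a gridded monthly temperature climatology to one 12-value
#' record per country, weighting each cell by its population: month `m` of
#' country `c` is `sum(pop * t_m) / sum(pop)` over the country's cells with
#' positive population.  Zero-population cells never influence the result;
#' a country whose total population is zero is an error (not a silent NaN).
#'
#' @param grid Long-format grid: one row per cell with columns `country`,
#'   `pop` and the twelve monthly means `t01`..`t12` (degrees C; `t01` is
#'   January).  Columns `lat_idx`/`lon_idx` may be present and are ignored.
#' @return Tibble, one row per country: `country`, `population` (the weight
#'   mass) and `t01`..`t12` (population-weighted monthly means).
#' @seealso [extreme_months()] to extract the hottest/coldest-month
#'   covariates; [sim_grids()] for a synthetic grid.
#' @export
#' @examples
#' g <- tibble::tibble(country = "AAA", pop = c(1, 3))
#' g[sprintf("t%02d", 1:12)] <- 0
#' g$t01 <- c(10, 20)
#' country_climatology(g)$t01  # (1*10 + 3*20)/4 = 17.5
country_climatology <- function(grid) {
  assert_columns(grid, c("country", "pop", MONTH_COLS), "grid")
  if (any(!is.finite(grid$pop)) || any(grid$pop < 0)) {
    abort_climmort("cell populations must be finite and nonnegative")
  }
  if (anyNA(grid[MONTH_COLS])) {
    abort_climmort("grid temperatures contain missing values")
  }
  mass <- grid |>
    dplyr::group_by(.data$country) |>
    dplyr::summarise(population = sum(.data$pop), .groups = "drop")
  empty <- mass$country[mass$population <= 0]
  if (length(empty) > 0) {
    abort_climmort("zero total population for country: %s",
                   paste(empty, collapse = ", "))
  }
  grid |>
    dplyr::filter(.data$pop > 0) |>
    dplyr::group_by(.data$country) |>
    dplyr::summarise(
      population = sum(.data$pop),
      dplyr::across(dplyr::all_of(MONTH_COLS),
                    ~ sum(.x * .data$pop) / sum(.data$pop)),
      .groups = "drop"
    )
}

#' Hottest- and coldest-month covariates from a monthly climatology
#'
#' Scans each country's 12 population-weighted monthly means and returns
#' the extreme values and their calendar months.  The order of operations
#' is deliberate: the grid is population-weighted first and the extreme
#' month is taken over the weighted climatology (the covariate is a single
#' country scalar, "the population-weighted average temperature in the
#' hottest month"), not the weighted mean of each cell's own extreme.
#' Ties go to the earliest calendar month.
#'
#' @param climatology Output of [country_climatology()] (or any tibble with
#'   `country` and `t01`..`t12`).
#' @return The input plus `hottest_month_temp`, `coldest_month_temp`
#'   (degrees C) and `hottest_month`, `coldest_month` (1-12, January = 1).
#' @export
extreme_months <- function(climatology) {
  assert_columns(climatology, c("country", MONTH_COLS), "climatology")
  tm <- as.matrix(climatology[MONTH_COLS])
  if (anyNA(tm)) abort_climmort("climatology contains missing values")
  hot_idx <- apply(tm, 1, which.max)   # which.max/min: earliest month on ties
  cold_idx <- apply(tm, 1, which.min)
  climatology |>
    dplyr::mutate(
      hottest_month_temp = tm[cbind(seq_len(nrow(tm)), hot_idx)],
      coldest_month_temp = tm[cbind(seq_len(nrow(tm)), cold_idx)],
      hottest_month = as.integer(hot_idx),
      coldest_month = as.integer(cold_idx)
    )
}
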