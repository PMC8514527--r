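#' Define a damage-function specification
#'
#' A damage function expresses the percent change in the heat- or
#' cold-related mortality rate as a polynomial in country warming `dT`
#' interacted with the country's extreme-month climatology and (for the
#' richest specification) log per-capita income.  Four nested models are
#' supported; none contains an intercept, so zero warming always implies a
#' zero mortality change:
#'
#' * Model 1: `dT`
#' * Model 2: `dT + dT^2`
#' * Model 3: `dT + dT^2 + dT * M`
#' * Model 4: `dT + dT^2 + dT * M + dT * M * log(GDPpc)`
#'
#' where `M` is the population-weighted mean temperature of the hottest
#' month (heat outcome) or coldest month (cold outcome).
#'
#' @param outcome `"heat"` or `"cold"`; selects the response column
#'   (`y_hot` / `y_cold`) and the extreme-month covariate.
#' @param model Integer 1–4, the nested specification.
#' @return An object of class `damage_spec`: a list with `outcome`,
#'   `model` and the ordered `terms` (design column names).
#' @seealso [build_design()], [fit_damage_model()]
#' @export
#' @examples
#' damage_spec("heat", 4)
#' damage_spec("cold", 3)
damage_spec <- function(outcome = c("heat", "cold"), model = 4L) {
  outcome <- match.arg(outcome)
  if (!is.numeric(model) || length(model) != 1 || !(model %in% 1:4)) {
    abort_climmort("'model' must be an integer in 1..4")
  }
  model <- as.integer(model)
  season <- if (outcome == "heat") "hottest" else "coldest"
  all_terms <- c("dT", "dT2",
                 paste0("dT_x_", season),
                 paste0("dT_x_", season, "_x_loggdp"))
  structure(
    list(outcome = outcome, model = model, terms = all_terms[seq_len(model)]),
    class = "damage_spec"
  )
}

#' @export
print.damage_spec <- function(x, ...) {
  cat(sprintf("<damage_spec> outcome = %s, model = %d\n  terms: %s\n",
              x$outcome, x$model, paste(x$terms, collapse = " + ")))
  invisible(x)
}

# response column a spec predicts
response_column <- function(spec) {
  if (spec$outcome == "heat") "y_hot" else "y_cold"
}

# extreme-month covariate column a spec needs (NULL for models 1-2)
season_column <- function(spec) {
  if (spec$model < 3) return(NULL)
  if (spec$outcome == "heat") "hottest_month_temp" else "coldest_month_temp"
}

#' Build the regression design for a damage-function specification
#'
#' Joins per-observation warming with per-country covariates and returns the
#' design columns of `spec`, in `spec$terms` order, aligned row-for-row with
#' `observations`.  `log_gdp_pc` is taken from the covariates if present,
#' otherwise computed as `log(gdp_pc_ppp)` (natural log).
#'
#' @param observations Data frame with columns `country` and `dT`
#'   (country warming in degrees Celsius relative to the 2001–2020 baseline).
#' @param covariates Data frame of country records with `country` and the
#'   fields the specification needs (`hottest_month_temp` /
#'   `coldest_month_temp` for models 3–4, income for model 4).
#' @param spec A [damage_spec()].
#' @return A tibble with the columns named in `spec$terms`, one row per
#'   observation row, with attribute `"terms"`.
#' @export
#' @examples
#' obs <- tibble::tibble(country = "AAA", dT = 2)
#' cov <- tibble::tibble(country = "AAA", hottest_month_temp = 30,
#'                       log_gdp_pc = 9)
#' build_design(obs, cov, damage_spec("heat", 4))  # 2, 4, 60, 540
build_design <- function(observations, covariates, spec) {
  stopifnot(inherits(spec, "damage_spec"))
  assert_columns(observations, c("country", "dT"), "observations")
  assert_columns(covariates, "country", "covariates")

  missing_ctry <- setdiff(unique(observations$country), covariates$country)
  if (length(missing_ctry) > 0) {
    abort_climmort("no covariate record for country: %s",
                   paste(missing_ctry, collapse = ", "))
  }

  need <- season_column(spec)
  if (spec$model >= 4) {
    if (!"log_gdp_pc" %in% names(covariates)) {
      if (!"gdp_pc_ppp" %in% names(covariates)) {
        abort_climmort(
          "model %d needs covariate field 'log_gdp_pc' or 'gdp_pc_ppp'",
          spec$model)
      }
      covariates <- dplyr::mutate(covariates,
                                  log_gdp_pc = log(.data$gdp_pc_ppp))
    }
    need <- c(need, "log_gdp_pc")
  }
  for (field in need) {
    if (!field %in% names(covariates)) {
      abort_climmort("model %d needs covariate field '%s'", spec$model, field)
    }
    bad <- covariates$country[!is.finite(covariates[[field]])]
    bad <- intersect(bad, observations$country)
    if (length(bad) > 0) {
      abort_climmort("covariate field '%s' is missing for country: %s",
                     field, paste(bad, collapse = ", "))
    }
  }

  keep <- unique(c("country", need))
  df <- dplyr::left_join(
    dplyr::select(observations, dplyr::all_of(c("country", "dT"))),
    dplyr::select(covariates, dplyr::all_of(keep)),
    by = "country"
  )

  out <- tibble::tibble(dT = df$dT)
  if (spec$model >= 2) out$dT2 <- df$dT^2
  if (spec$model >= 3) {
    season <- season_column(spec)
    out[[paste0("dT_x_", sub("_month_temp", "", season))]] <-
      df$dT * df[[season]]
  }
  if (spec$model >= 4) {
    season <- season_column(spec)
    out[[spec$terms[4]]] <- df$dT * df[[season]] * df$log_gdp_pc
  }
  names(out) <- spec$terms
  attr(out, "terms") <- spec$terms
  out
}

#' Published damage-function coefficient estimates
#'
#' Point estimates (and cluster-robust standard errors) of the four nested
#' heat and cold specifications as published for the 23-country
#' mortality-projection panel (184 observations per outcome).  These are
#' useful as ground-truth coefficients for synthetic worlds, for worked
#' evaluations of the damage functions, and for directional analyses
#' (e.g. the negative income interaction that drives adaptation).
#'
#' @param outcome `"heat"` or `"cold"`.
#' @param model Integer 1–4.  Defaults to the preferred specification for
#'   each outcome: model 4 for heat, model 3 for cold.
#' @param se If `TRUE` return the standard errors instead of the estimates.
#' @return Named numeric vector aligned with
#'   `damage_spec(outcome, model)$terms`.
#' @export
#' @examples
#' published_betas("heat")        # preferred heat model (4)
#' published_betas("cold")        # preferred cold model (3)
published_betas <- function(outcome = c("heat", "cold"), model = NULL,
                            se = FALSE) {
  outcome <- match.arg(outcome)
  model <- model %||% if (outcome == "heat") 4L else 3L
  tabs <- list(
    heat = list(
      est = list(
        `1` = c(1.940),
        `2` = c(2.463, -0.200),
        `3` = c(-1.943, -0.145, 0.196),
        `4` = c(-0.532, -0.0629, 0.525, -0.0409)
      ),
      se = list(
        `1` = c(0.400),
        `2` = c(0.508, 0.0989),
        `3` = c(1.673, 0.0771, 0.0839),
        `4` = c(1.224, 0.0935, 0.208, 0.0222)
      )
    ),
    cold = list(
      est = list(
        `1` = c(-0.977),
        `2` = c(-1.569, 0.226),
        `3` = c(-1.441, 0.199, -0.0113),
        `4` = c(-1.441, 0.199, -0.0127, 0.000146)
      ),
      se = list(
        `1` = c(0.0902),
        `2` = c(0.131, 0.0356),
        `3` = c(0.137, 0.0366, 0.00680),
        `4` = c(0.137, 0.0366, 0.0610, 0.00626)
      )
    )
  )
  spec <- damage_spec(outcome, model)
  vals <- tabs[[outcome]][[if (se) "se" else "est"]][[as.character(model)]]
  setNames(vals, spec$terms)
}
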