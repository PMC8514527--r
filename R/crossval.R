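#' Leave-one-out cross-validation of a damage-function specification
#'
#' Refits the specification with one unit held out at a time and predicts
#' the held-out rows.  Because the end use is extrapolation to countries
#' outside the estimation sample, the default unit is an entire country
#' (leave-one-country-out), consistent with country-level clustering;
#' per-observation folds are available.
#'
#' @inheritParams fit_damage_model
#' @param unit `"country"` (default): each fold holds out all of one
#'   country's rows; `"observation"`: classic row-wise LOOCV.
#' @return One-row tibble: `unit`, `n_folds`, `cv_rmse`, `cv_mae`,
#'   `cv_pseudo_r2` (1 - SSE_cv over the *centered* total sum of squares)
#'   and `cv_pseudo_r2_uncentered` (same with `sum(y^2)` in the
#'   denominator; reported because the no-intercept fit statistics use the
#'   uncentered convention).
#' @export
crossvalidate <- function(observations, covariates, spec,
                          unit = c("country", "observation")) {
  unit <- match.arg(unit)
  ycol <- response_column(spec)
  assert_columns(observations, c("country", "dT", ycol), "observations")
  X <- as.matrix(build_design(observations, covariates, spec))
  y <- observations[[ycol]]
  fold_id <- if (unit == "country") observations$country
             else seq_len(nrow(X))
  folds <- unique(fold_id)
  if (length(folds) < 3) {
    abort_climmort("cross-validation needs at least 3 folds, got %d",
                   length(folds))
  }

  pred <- rep(NA_real_, length(y))
  for (f in folds) {
    hold <- fold_id == f
    Xtr <- X[!hold, , drop = FALSE]
    qx <- qr(Xtr)
    if (qx$rank < ncol(X)) {
      abort_climmort("rank-deficient refit when holding out fold '%s'", f)
    }
    b <- qr.coef(qx, y[!hold])
    pred[hold] <- X[hold, , drop = FALSE] %*% b
  }
  err <- y - pred
  tibble::tibble(
    unit = unit,
    n_folds = length(folds),
    cv_rmse = sqrt(mean(err^2)),
    cv_mae = mean(abs(err)),
    cv_pseudo_r2 = 1 - sum(err^2) / sum((y - mean(y))^2),
    cv_pseudo_r2_uncentered = 1 - sum(err^2) / sum(y^2)
  )
}

#' Fit and rank the candidate damage-function specifications
#'
#' Runs every requested nested specification through the full fit
#' ([fit_damage_model()]) and leave-one-out cross-validation
#' ([crossvalidate()]) and returns a validation table ranked by
#' out-of-sample RMSE — the analogue of a published model-validation table
#' with in-sample (`adj_r2`, `F`, `rmse`) and LOOCV (`cv_rmse`, `cv_mae`,
#' `cv_pseudo_r2`) rows.  Ties in `cv_rmse` are broken by `cv_mae`, then by
#' fewer terms (parsimony).
#'
#' @inheritParams crossvalidate
#' @param outcome `"heat"` or `"cold"`.
#' @param models Integer vector of specifications to compare (subset of 1:4).
#' @param ssc Small-sample correction passed to [fit_cluster_ols()].
#' @return A tibble of class `damage_validation`, one row per model, with
#'   `rank` (1 = preferred).  The fitted `damage_fit` objects are attached
#'   as attribute `"fits"` (a named list), so the preferred fit is
#'   `attr(v, "fits")[[as.character(v$model[v$rank == 1])]]`.
#' @export
#' @examples
#' cfg <- sim_config(n_countries = 10, seed = 5)
#' world <- sim_world(cfg)
#' resp <- sim_response_table(world, sim_warming(world, cfg), cfg)
#' select_damage_model(resp, world, "heat")
select_damage_model <- function(observations, covariates,
                                outcome = c("heat", "cold"),
                                models = 1:4,
                                unit = c("country", "observation"),
                                ssc = "CR1") {
  outcome <- match.arg(outcome)
  unit <- match.arg(unit)
  if (length(models) < 2) {
    abort_climmort("model selection needs at least 2 candidate models")
  }
  specs <- lapply(models, function(m) damage_spec(outcome, m))
  fits <- lapply(specs, function(sp)
    fit_damage_model(observations, covariates, sp, ssc = ssc))
  rows <- purrr::map2_dfr(specs, fits, function(sp, ft) {
    dplyr::bind_cols(
      tibble::tibble(outcome = outcome, model = sp$model,
                     n_terms = length(sp$terms)),
      glance(ft)[c("n_obs", "adj_r2", "F", "rmse")],
      crossvalidate(observations, covariates, sp, unit = unit)[
        c("cv_rmse", "cv_mae", "cv_pseudo_r2")]
    )
  })
  ord <- order(rows$cv_rmse, rows$cv_mae, rows$n_terms)
  rows$rank <- integer(nrow(rows))
  rows$rank[ord] <- seq_len(nrow(rows))
  names(fits) <- as.character(rows$model)
  out <- tibble::new_tibble(rows, class = "damage_validation")
  attr(out, "fits") <- fits
  attr(out, "unit") <- unit
  out
}

#' Extract the preferred fitted model from a validation table
#'
#' @param validation A `damage_validation` from [select_damage_model()].
#' @return The `damage_fit` ranked first by LOOCV RMSE.
#' @export
preferred_fit <- function(validation) {
  stopifnot(inherits(validation, "damage_validation"))
  fits <- attr(validation, "fits")
  fits[[as.character(validation$model[validation$rank == 1])]]
}
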