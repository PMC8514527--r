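#' No-intercept least squares with cluster-robust (CR1) covariance
#'
#' Core estimator behind [fit_damage_model()]: ordinary least squares
#' through the origin with a sandwich covariance that allows arbitrary
#' residual correlation within clusters (countries).  The covariance is
#'
#' \deqn{V = c \, (X'X)^{-1} \Big[\sum_g X_g' e_g e_g' X_g\Big] (X'X)^{-1}}
#'
#' with small-sample factor `c = G/(G-1) * (n-1)/(n-k)` (the CR1 convention
#' of common econometrics software) by default; `ssc` accepts any numeric
#' factor, or `"none"` for `c = 1`.
#'
#' @param X Numeric design matrix (no intercept column; `n >= k` rows).
#' @param y Numeric response vector of length `nrow(X)`.
#' @param cluster Cluster identifier per row (at least two distinct values).
#' @param ssc Small-sample correction: `"CR1"` (default), `"none"`, or a
#'   positive number used as the factor directly.
#' @return An object of class `damage_fit`; see [fit_damage_model()].
#' @export
fit_cluster_ols <- function(X, y, cluster, ssc = "CR1") {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n || length(cluster) != n) {
    abort_climmort("X, y and cluster must have matching lengths")
  }
  if (anyNA(X) || anyNA(y)) abort_climmort("design or response contains NA")
  if (n < k) abort_climmort("fewer observations (%d) than columns (%d)", n, k)
  G <- length(unique(cluster))
  if (G < 2) abort_climmort("only one cluster; at least 2 are required")

  qx <- qr(X)
  if (qx$rank < k) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):k]]
    abort_climmort("design is rank-deficient; collinear column(s): %s",
                   paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(X %*% beta)
  e <- y - fitted

  cfac <- if (identical(ssc, "CR1")) {
    (G / (G - 1)) * ((n - 1) / max(n - k, 1))
  } else if (identical(ssc, "none")) {
    1
  } else if (is.numeric(ssc) && length(ssc) == 1 && ssc > 0) {
    ssc
  } else {
    abort_climmort("'ssc' must be \"CR1\", \"none\" or a positive number")
  }
  bread <- solve(crossprod(X))         # (X'X)^{-1}; k <= 4 so direct solve
  scores <- rowsum(X * e, group = cluster)   # G x k matrix of X_g' e_g
  meat <- crossprod(as.matrix(scores))
  vcov <- cfac * bread %*% meat %*% bread
  vcov <- (vcov + t(vcov)) / 2
  dimnames(vcov) <- list(colnames(X), colnames(X))

  ssr <- sum(e^2)
  r2u <- 1 - ssr / sum(y^2)
  r2c <- 1 - ssr / sum((y - mean(y))^2)
  structure(
    list(
      beta = setNames(as.numeric(beta), colnames(X)),
      vcov = vcov,
      residuals = e,
      fitted = fitted,
      n_obs = n,
      n_clusters = G,
      k = k,
      ssc_factor = cfac,
      df = G - 1,
      r2_uncentered = r2u,
      r2_centered = r2c,
      adj_r2 = 1 - (1 - r2u) * n / (n - k),
      f_statistic = (r2u / k) / ((1 - r2u) / (n - k)),
      rmse = sqrt(ssr / (n - k)),
      X = X, y = y, cluster = cluster,
      spec = NULL
    ),
    class = "damage_fit"
  )
}

#' Fit a damage-function specification to a mortality-response table
#'
#' Estimates the no-intercept regression defined by `spec` on the stacked
#' country x scenario x period response table, with standard errors
#' clustered at the country level (observations for the same country share
#' projection error from the same underlying exposure-response curve, so
#' their residuals are correlated).
#'
#' @param observations Response table with columns `country`, `dT` and the
#'   outcome column (`y_hot` or `y_cold` as selected by `spec`).
#' @param covariates Country records (see [build_design()]).
#' @param spec A [damage_spec()].
#' @inheritParams fit_cluster_ols
#' @return A `damage_fit` object: coefficient vector `beta`, cluster-robust
#'   `vcov`, residuals, and in-sample fit statistics (`adj_r2` and the `F`
#'   statistic on the no-intercept/uncentered convention, `rmse` with the
#'   `n - k` denominator).  Use [tidy()] for the coefficient table,
#'   [glance()] for the fit statistics and [predict()] for new designs.
#' @export
#' @examples
#' cfg <- sim_config(n_countries = 8, seed = 3)
#' world <- sim_world(cfg)
#' warm <- sim_warming(world, cfg)
#' resp <- sim_response_table(world, warm, cfg)
#' fit <- fit_damage_model(resp, world, damage_spec("heat", 4))
#' tidy(fit)
fit_damage_model <- function(observations, covariates, spec, ssc = "CR1") {
  ycol <- response_column(spec)
  assert_columns(observations, c("country", "dT", ycol), "observations")
  X <- as.matrix(build_design(observations, covariates, spec))
  fit <- fit_cluster_ols(X, observations[[ycol]], observations$country, ssc)
  fit$spec <- spec
  fit
}

#' In-sample fit statistics of a damage model
#'
#' @param fit A `damage_fit`.
#' @return One-row tibble with `adj_r2`, `F`, `rmse`, plus the uncentered
#'   and centered R-squared the adjusted value derives from.  The
#'   no-intercept convention is used: R-squared is computed against the
#'   uncentered total sum of squares `sum(y^2)` (the centered variant is
#'   reported alongside), and `rmse = sqrt(SSR / (n - k))`.
#' @export
fit_statistics <- function(fit) {
  stopifnot(inherits(fit, "damage_fit"))
  if (fit$n_obs <= fit$k) {
    abort_climmort("fit statistics need n > k (n = %d, k = %d)",
                   fit$n_obs, fit$k)
  }
  tibble::tibble(
    adj_r2 = fit$adj_r2,
    F = fit$f_statistic,
    rmse = fit$rmse,
    r2_uncentered = fit$r2_uncentered,
    r2_centered = fit$r2_centered
  )
}

#' @export
print.damage_fit <- function(x, ...) {
  hdr <- if (is.null(x$spec)) "<damage_fit>"
         else sprintf("<damage_fit> outcome = %s, model = %d",
                      x$spec$outcome, x$spec$model)
  cat(hdr, "\n", sep = "")
  cat(sprintf("  n = %d observations in %d clusters\n", x$n_obs, x$n_clusters))
  print(tidy(x), ...)
  invisible(x)
}

#' @describeIn fit_damage_model Coefficient table with cluster-robust
#'   standard errors, t statistics on `G - 1` degrees of freedom, p-values,
#'   significance stars and confidence bounds.
#' @param x,object A `damage_fit`.
#' @param conf.level Confidence level for `conf.low`/`conf.high`.
#' @param ... Unused.
#' @method tidy damage_fit
#' @export
tidy.damage_fit <- function(x, conf.level = 0.95, ...) {
  se <- sqrt(pmax(diag(x$vcov), 0))
  tstat <- ifelse(se > 0, x$beta / se, NA_real_)
  p <- 2 * pt(-abs(tstat), df = x$df)
  q <- qt((1 + conf.level) / 2, df = x$df)
  tibble::tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = se,
    statistic = tstat,
    p.value = p,
    stars = ifelse(is.na(p), "", p_stars(p)),
    conf.low = unname(x$beta) - q * se,
    conf.high = unname(x$beta) + q * se
  )
}

#' @describeIn fit_damage_model One-row model summary (sample sizes, fit
#'   statistics, small-sample factor).
#' @method glance damage_fit
#' @export
glance.damage_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_obs = x$n_obs, n_clusters = x$n_clusters,
                   n_terms = x$k),
    fit_statistics(x),
    tibble::tibble(ssc_factor = x$ssc_factor, df = x$df)
  )
}

#' @describeIn fit_damage_model Predict percent mortality-rate changes for
#'   new design rows (`newdata` must carry the design columns of the fitted
#'   specification, e.g. from [build_design()]).
#' @param newdata Data frame or matrix of design columns.
#' @export
predict.damage_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, names(object$beta), drop = FALSE]
  drop(X %*% object$beta)
}
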