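# independent oracles and small fixture builders shared across tests

# normal-equations solution of the no-intercept least-squares problem
oracle_ols <- function(X, y) {
  unname(drop(solve(crossprod(X), crossprod(X, y))))
}

# cluster-robust sandwich with the CR1 factor, written out longhand
oracle_cr1 <- function(X, y, cluster) {
  b <- oracle_ols(X, y)
  e <- y - drop(X %*% b)
  n <- nrow(X); k <- ncol(X); G <- length(unique(cluster))
  bread <- solve(crossprod(X))
  meat <- matrix(0, k, k)
  for (g in unique(cluster)) {
    s <- drop(crossprod(X[cluster == g, , drop = FALSE], e[cluster == g]))
    meat <- meat + tcrossprod(s)
  }
  (G / (G - 1)) * ((n - 1) / (n - k)) * bread %*% meat %*% bread
}

# brute-force leave-one-unit-out cross-validation: literal refit loop
oracle_loocv <- function(X, y, fold_id) {
  pred <- rep(NA_real_, length(y))
  for (f in unique(fold_id)) {
    hold <- fold_id == f
    b <- oracle_ols(X[!hold, , drop = FALSE], y[!hold])
    pred[hold] <- X[hold, , drop = FALSE] %*% b
  }
  list(
    cv_rmse = sqrt(mean((y - pred)^2)),
    cv_mae = mean(abs(y - pred)),
    cv_pseudo_r2 = 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  )
}

# a damage_fit carrying externally supplied coefficients (e.g. the
# published tables) so damage functions can be evaluated without refitting
make_fit <- function(beta, spec, vcov = NULL, df = 22L) {
  k <- length(beta)
  vcov <- vcov %||% matrix(0, k, k)
  structure(
    list(beta = setNames(as.numeric(beta), spec$terms),
         vcov = vcov, df = df, spec = spec,
         n_obs = 184L, n_clusters = df + 1L, k = k),
    class = "damage_fit"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

published_heat_fit <- function(vcov = NULL) {
  make_fit(published_betas("heat", 4), damage_spec("heat", 4), vcov)
}
published_cold_fit <- function(vcov = NULL) {
  make_fit(published_betas("cold", 3), damage_spec("cold", 3), vcov)
}

tiny_world <- function(n = 5, seed = 1) {
  sim_world(sim_config(n_countries = n, seed = seed))
}

# small synthetic dataset bundle: world + warming + responses
tiny_data <- function(n = 5, seed = 1, ...) {
  cfg <- sim_config(n_countries = n, seed = seed, ...)
  world <- sim_world(cfg)
  warming <- sim_warming(world, cfg)
  list(config = cfg, world = world, warming = warming,
       responses = sim_response_table(world, warming, cfg))
}
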