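test_that("delta-method intervals follow the closed form", {
  spec <- damage_spec("heat", 2)
  # zero covariance: degenerate interval at the point estimate
  f0 <- make_fit(c(1, 2), spec)
  expect_equal(unname(projection_interval(f0, c(1, 1))),
               c(3, 3, 3))

  # identity covariance, x = (1,1), level 0.95: half-width 1.96 * sqrt(2)
  fi <- make_fit(c(0, 0), spec, vcov = diag(2))
  ci <- projection_interval(fi, c(1, 1), level = 0.95)
  expect_equal(unname(ci["high"] - ci["low"]) / 2,
               qnorm(0.975) * sqrt(2), tolerance = 1e-12)
  expect_equal(round(unname(ci["high"]), 3), 2.772)

  # width strictly increasing in the level
  w <- vapply(c(0.5, 0.8, 0.9, 0.95, 0.99), function(l) {
    ci <- projection_interval(fi, c(1, 1), level = l)
    unname(ci["high"] - ci["low"])
  }, numeric(1))
  expect_true(all(diff(w) > 0))

  expect_error(projection_interval(fi, c(1, 1, 1)), "length")
  fneg <- make_fit(c(0, 0), spec, vcov = diag(c(-1, -1)))
  expect_error(projection_interval(fneg, c(1, 1)), "semidefinite")
})

test_that("single-country projection reproduces the published worked values", {
  fh <- published_heat_fit()
  fc <- published_cold_fit()
  rec <- tibble::tibble(country = "AAA", hottest_month_temp = 30,
                        coldest_month_temp = -5,
                        gdp_pc_ppp = exp(9), log_gdp_pc = 9)
  pr <- project_country(fh, fc, rec, dT = 2)
  # hand products of the printed coefficients
  y_hot_hand <- -0.532 * 2 - 0.0629 * 4 + 0.525 * 60 - 0.0409 * 540
  y_cold_hand <- -1.441 * 2 + 0.199 * 4 - 0.0113 * 2 * (-5)
  expect_equal(pr$y_hot, y_hot_hand)
  expect_equal(pr$y_cold, y_cold_hand)
  expect_equal(pr$y_net, pr$y_hot + pr$y_cold)
  expect_equal(round(pr$y_hot, 3), 8.098)
  expect_equal(round(pr$y_cold, 3), -1.973)
})

test_that("zero warming projects exactly zero with a degenerate interval", {
  fh <- published_heat_fit(vcov = diag(4))
  fc <- published_cold_fit(vcov = diag(3))
  rec <- tibble::tibble(country = "AAA", hottest_month_temp = 28,
                        coldest_month_temp = 3, gdp_pc_ppp = 2e4,
                        log_gdp_pc = log(2e4))
  pr <- project_country(fh, fc, rec, dT = 0)
  expect_identical(pr$y_hot, 0)
  expect_identical(pr$y_cold, 0)
  expect_identical(pr$y_net, 0)
  expect_identical(pr$ci_low, 0)
  expect_identical(pr$ci_high, 0)
})

test_that("adaptation changes nothing when income is unchanged", {
  fh <- published_heat_fit()
  fc <- published_cold_fit()
  rec <- tibble::tibble(country = "AAA", hottest_month_temp = 31,
                        coldest_month_temp = 10, gdp_pc_ppp = 5000,
                        log_gdp_pc = log(5000))
  base <- project_country(fh, fc, rec, dT = 3)
  same <- project_country(fh, fc, rec, dT = 3, adaptation = TRUE,
                          income_at_period = 5000)
  expect_equal(dplyr::select(base, -"adaptation"),
               dplyr::select(same, -"adaptation"))
})

test_that("income growth strictly reduces heat damages (beta4 < 0)", {
  fh <- published_heat_fit()
  fc <- published_cold_fit()
  rec <- tibble::tibble(country = "AAA", hottest_month_temp = 30,
                        coldest_month_temp = 5, gdp_pc_ppp = 3000,
                        log_gdp_pc = log(3000))
  for (dT in c(0.5, 2, 4)) {
    lo <- project_country(fh, fc, rec, dT, adaptation = TRUE,
                          income_at_period = 3000)
    hi <- project_country(fh, fc, rec, dT, adaptation = TRUE,
                          income_at_period = 30000)
    expect_lt(hi$y_hot, lo$y_hot)
    expect_equal(hi$y_cold, lo$y_cold)  # cold model has no income term
  }
})

test_that("heat damages increase with baseline heat below the income cutoff", {
  # d y_hot / d hottest = dT * (beta3 + beta4 * logGDP) > 0 for
  # logGDP < beta3 / (-beta4) ~ 12.84; asserted up to logGDP = 12
  b <- published_betas("heat", 4)
  for (lg in seq(7, 12, by = 0.5)) {
    slope <- b[["dT_x_hottest"]] + b[["dT_x_hottest_x_loggdp"]] * lg
    expect_gt(slope, 0)
  }
})

test_that("cold damages are negative over a plausible climate grid", {
  b <- published_betas("cold", 3)
  grid <- tidyr::expand_grid(dT = seq(0.1, 5, by = 0.1),
                             coldest = seq(-30, 25, by = 1))
  y <- b[["dT"]] * grid$dT + b[["dT2"]] * grid$dT^2 +
    b[["dT_x_coldest"]] * grid$dT * grid$coldest
  expect_true(all(y < 0))
})

test_that("world projection equals row-by-row evaluation and is additive", {
  d <- tiny_data(n = 6, seed = 51,
                 sigma_country = c(hot = 0, cold = 0),
                 sigma_obs = c(hot = 0, cold = 0))
  fh <- fit_damage_model(d$responses, d$world, damage_spec("heat", 4))
  fc <- fit_damage_model(d$responses, d$world, damage_spec("cold", 3))
  pr <- project_mortality(fh, fc, d$world, d$warming)
  expect_equal(nrow(pr), 6 * 8)
  # noiseless fits reproduce the forward model row by row
  key <- paste(pr$country, pr$scenario, pr$period)
  resp_key <- paste(d$responses$country, d$responses$scenario,
                    d$responses$period)
  m <- match(key, resp_key)
  expect_equal(pr$y_hot, d$responses$y_hot[m], tolerance = 1e-8)
  expect_equal(pr$y_cold, d$responses$y_cold[m], tolerance = 1e-8)
  expect_identical(pr$y_net, pr$y_hot + pr$y_cold)
  expect_true(all(pr$ci_low <= pr$y_net & pr$y_net <= pr$ci_high))
})

test_that("countries without covariates become explicit missing rows", {
  d <- tiny_data(n = 5, seed = 52)
  fh <- fit_damage_model(d$responses, d$world, damage_spec("heat", 4))
  fc <- fit_damage_model(d$responses, d$world, damage_spec("cold", 3))
  full <- project_mortality(fh, fc, d$world, d$warming)
  drop_one <- project_mortality(fh, fc, d$world[-3, ], d$warming)
  gone <- d$world$country[3]
  expect_false(gone %in% drop_one$country)
  rep <- missing_report(drop_one)
  expect_equal(unique(rep$country), gone)
  expect_equal(nrow(rep), 8)
  expect_equal(unique(rep$reason), "no covariate record")
  # all other rows unchanged
  keep <- full[full$country != gone, ]
  expect_equal(keep$y_net, drop_one$y_net)

  # missing dT is reported, not zeroed
  warm_na <- d$warming
  warm_na$dT[1] <- NA
  pr_na <- project_mortality(fh, fc, d$world, warm_na)
  expect_true("missing warming" %in% missing_report(pr_na)$reason)
})

test_that("adaptation projections draw income from the period midpoints", {
  d <- tiny_data(n = 4, seed = 53)
  fh <- fit_damage_model(d$responses, d$world, damage_spec("heat", 4))
  fc <- fit_damage_model(d$responses, d$world, damage_spec("cold", 3))
  # flat incomes: adaptation output identical to the no-adaptation run
  flat <- sim_income_paths(d$world, growth = 0)
  base <- project_mortality(fh, fc, d$world, d$warming)
  adap <- project_mortality(fh, fc, d$world, d$warming, adaptation = TRUE,
                            income_paths = flat)
  expect_equal(base$y_hot, adap$y_hot, tolerance = 1e-12)
  # growing incomes with beta4 < 0 reduce heat damages everywhere warmed
  grow <- sim_income_paths(d$world, growth = 0.03)
  fh_pub <- published_heat_fit()
  adap2 <- project_mortality(fh_pub, fc, d$world, d$warming,
                             adaptation = TRUE, income_paths = grow)
  base2 <- project_mortality(fh_pub, fc, d$world, d$warming)
  expect_true(all(adap2$y_hot < base2$y_hot))
  expect_error(project_mortality(fh, fc, d$world, d$warming,
                                 adaptation = TRUE), "income")
})
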