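# a projection object built by the package for a small world
make_projection <- function(n = 5, seed = 61, ...) {
  d <- tiny_data(n = n, seed = seed, ...)
  fh <- fit_damage_model(d$responses, d$world, damage_spec("heat", 4))
  fc <- fit_damage_model(d$responses, d$world, damage_spec("cold", 3))
  list(data = d, fh = fh, fc = fc,
       proj = project_mortality(fh, fc, d$world, d$warming))
}

test_that("global aggregation is a weighted mean with exact closed forms", {
  mp <- make_projection()
  d <- mp$data
  g <- global_rate_change(mp$proj, d$world)
  expect_equal(nrow(g), 8)  # 4 scenarios x 2 periods
  expect_equal(g$y_net_global, g$y_hot_global + g$y_cold_global)

  # hand-computed death-weighted mean for one scenario x period cell
  one <- mp$proj[mp$proj$scenario == "RCP8.5" & mp$proj$period == "end", ]
  w <- d$world$mortality_rate * d$world$population
  w <- w[match(one$country, d$world$country)]
  w <- w / sum(w)
  cell <- g[g$scenario == "RCP8.5" & g$period == "end", ]
  expect_equal(cell$y_net_global, sum(w * one$y_net))

  # population weighting as sensitivity
  gp <- global_rate_change(mp$proj, d$world, weight_scheme = "population")
  wp <- d$world$population[match(one$country, d$world$country)]
  wp <- wp / sum(wp)
  expect_equal(gp$y_net_global[gp$scenario == "RCP8.5" & gp$period == "end"],
               sum(wp * one$y_net))
})

test_that("shared values aggregate to themselves under any weights", {
  mp <- make_projection(n = 4, seed = 62)
  proj <- mp$proj
  proj$y_hot <- 2; proj$y_cold <- -0.5; proj$y_net <- 1.5
  for (scheme in c("baseline_deaths", "population")) {
    g <- global_rate_change(proj, mp$data$world, weight_scheme = scheme)
    expect_equal(g$y_net_global, rep(1.5, nrow(g)))
  }
})

test_that("two-country hand example: values 2 and 4 at death weights 1:3", {
  mp <- make_projection(n = 4, seed = 63)
  world <- mp$data$world
  pair <- world$country[1:2]
  world$population[1:2] <- c(1e6, 3e6)
  world$mortality_rate[1:2] <- 0.01       # deaths 1:3
  proj <- mp$proj[mp$proj$country %in% pair, ]
  attributes(proj)[c("fits", "level", "quantile")] <-
    attributes(mp$proj)[c("fits", "level", "quantile")]
  class(proj) <- class(mp$proj)
  proj$y_hot <- ifelse(proj$country == pair[1], 2, 4)
  proj$y_cold <- 0
  g <- global_rate_change(proj, world)
  expect_equal(g$y_net_global, rep(3.5, nrow(g)))
})

test_that("aggregation is invariant to order and to splitting a country", {
  mp <- make_projection(n = 5, seed = 64)
  d <- mp$data
  g <- global_rate_change(mp$proj, d$world)
  perm <- mp$proj[sample(nrow(mp$proj)), ]
  attributes(perm)[c("fits", "level", "quantile")] <-
    attributes(mp$proj)[c("fits", "level", "quantile")]
  class(perm) <- class(mp$proj)
  g2 <- global_rate_change(perm, d$world)
  expect_equal(dplyr::arrange(as.data.frame(g), scenario, period),
               dplyr::arrange(as.data.frame(g2), scenario, period))

  # split one country into two halves sharing its value and weight
  split_world <- dplyr::bind_rows(d$world, d$world[1, ])
  split_world$country[nrow(split_world)] <- "C999"
  split_world$population[c(1, nrow(split_world))] <- d$world$population[1] / 2
  split_proj <- dplyr::bind_rows(
    mp$proj,
    dplyr::mutate(mp$proj[mp$proj$country == d$world$country[1], ],
                  country = "C999"))
  attributes(split_proj)[c("fits", "level", "quantile")] <-
    attributes(mp$proj)[c("fits", "level", "quantile")]
  class(split_proj) <- class(mp$proj)
  g3 <- global_rate_change(split_proj, split_world)
  expect_equal(g$y_net_global, g3$y_net_global, tolerance = 1e-12)
  expect_equal(g$ci_low, g3$ci_low, tolerance = 1e-12)
})

test_that("excess deaths are a straight percentage of projected deaths", {
  expect_equal(excess_deaths(0, 5e7), 0)
  expect_equal(excess_deaths(1, 1e6), 1e4)
  expect_equal(excess_deaths(c(1, 2), c(1e6, 1e6)), c(1e4, 2e4))
  expect_error(excess_deaths(1, -5), "nonnegative")
})

test_that("pattern ratios recover proportional warming exactly", {
  warm <- tibble::tibble(
    country = c("AAA", "AAA", "GLOBAL", "GLOBAL"),
    scenario = c("RCP4.5", "RCP8.5", "RCP4.5", "RCP8.5"),
    period = "end",
    dT = c(1.0, 2.0, 0.5, 1.0))
  r <- pattern_ratios(warm)
  expect_equal(r$ratio, 2)

  # identity when country warming equals global warming
  warm2 <- warm
  warm2$dT <- c(0.5, 1.0, 0.5, 1.0)
  expect_equal(pattern_ratios(warm2)$ratio, 1)

  # single data point: ratio computed with a warning
  warm3 <- warm[c(1, 3, 4), ]
  expect_warning(r3 <- pattern_ratios(warm3), "single")
  expect_equal(r3$ratio, 2)

  expect_error(pattern_ratios(warm[1:2, ]), "2 warming fields")
})

test_that("ratio reconstruction explains noisy proportional fields", {
  cfg <- sim_config(n_countries = 30, seed = 65, pattern_spread = 0.2)
  world <- sim_world(cfg)
  warm <- sim_warming(world, cfg)
  # jitter the field and re-estimate the ratios from the data alone
  withr::with_seed(99, {
    noisy <- warm
    ctry <- noisy$country != "GLOBAL"
    noisy$dT[ctry] <- noisy$dT[ctry] * exp(rnorm(sum(ctry), 0, 0.05))
  })
  r <- pattern_ratios(noisy)
  glob <- warm[warm$country == "GLOBAL", c("scenario", "period", "dT")]
  obs <- dplyr::left_join(noisy[ctry, ], glob,
                          by = c("scenario", "period"),
                          suffix = c("", "_g")) |>
    dplyr::left_join(r, by = "country")
  recon <- obs$ratio * obs$dT_g
  r2 <- 1 - sum((obs$dT - recon)^2) / sum((obs$dT - mean(obs$dT))^2)
  expect_gte(r2, 0.9)
})

test_that("warming-response curve passes through the origin and is coherent", {
  mp <- make_projection(n = 6, seed = 66)
  d <- mp$data
  ratios <- attr(d$warming, "ratios")
  curve <- warming_response_curve(mp$fh, mp$fc, d$world, ratios,
                                  global_dT = seq(0, 5, by = 0.5))
  expect_equal(curve$y_hot[1], 0)
  expect_equal(curve$y_cold[1], 0)
  expect_equal(curve$y_net[1], 0)
  expect_equal(curve$ci_low[1], 0)
  expect_identical(curve$y_net, curve$y_hot + curve$y_cold)
  expect_true(all(abs(curve$y_net) <=
                  abs(curve$y_hot) + abs(curve$y_cold) + 1e-12))
  expect_equal(curve$global_dT_preindustrial, curve$global_dT + 1)
})

test_that("one-country curve with unit ratio equals its damage function", {
  mp <- make_projection(n = 4, seed = 67)
  d <- mp$data
  one <- d$world[1, ]
  ratios <- tibble::tibble(country = one$country, ratio = 1)
  grid <- seq(0, 4, by = 1)
  curve <- warming_response_curve(mp$fh, mp$fc, d$world, ratios,
                                  global_dT = grid)
  direct <- vapply(grid, function(g) {
    project_country(mp$fh, mp$fc, one, dT = g)$y_net
  }, numeric(1))
  expect_equal(curve$y_net, direct, tolerance = 1e-10)
})

test_that("curve components keep their signs with the published betas", {
  # heat nonnegative, cold nonpositive over (0, 5] on a plausible world
  cfg <- sim_config(n_countries = 15, seed = 68,
                    hottest_range = c(20, 35), coldest_range = c(-25, 15),
                    income_range = c(exp(7), exp(11)))
  world <- sim_world(cfg)
  ratios <- tibble::tibble(country = world$country, ratio = 1)
  curve <- warming_response_curve(published_heat_fit(), published_cold_fit(),
                                  world, ratios,
                                  global_dT = seq(0, 5, by = 0.25))
  expect_true(all(curve$y_hot >= 0))
  expect_true(all(curve$y_cold <= 0))
})

test_that("adaptation curve lies below the no-adaptation curve", {
  mp <- make_projection(n = 6, seed = 69)
  d <- mp$data
  ratios <- attr(d$warming, "ratios")
  grow <- sim_income_paths(d$world, growth = 0.03)
  base <- warming_response_curve(published_heat_fit(), mp$fc, d$world,
                                 ratios, global_dT = seq(0.5, 5, by = 0.5))
  adap <- warming_response_curve(published_heat_fit(), mp$fc, d$world,
                                 ratios, global_dT = seq(0.5, 5, by = 0.5),
                                 adaptation = TRUE, income_paths = grow)
  expect_true(all(adap$y_net <= base$y_net))
})
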