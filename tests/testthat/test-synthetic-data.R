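noiseless_overrides <- list(
  tmean = list(annual_sd = 0, monthly_sd = 0, trend = 0),
  ppt = list(annual_sd = 0, monthly_sd = 0),
  vpdmin = list(annual_sd = 0, monthly_sd = 0, trend = 0),
  vpdmax = list(annual_sd = 0, monthly_sd = 0, trend = 0),
  water_depth = list(anomaly_sd = 0))

test_that("zero noise and zero trend give exactly periodic series", {
  cfg <- small_config(seed = 1, n = 2L,
                      climate_overrides = noiseless_overrides)
  env <- gen_environment(cfg)
  for (v in c("tmean", "ppt", "water_depth")) {
    m <- env[[v]]$values
    for (y in 2:nrow(m)) expect_equal(unname(m[y, ]), unname(m[1, ]))
  }
  # seasonality is in the right place: wet, hot, deep in the right months
  expect_gt(env$ppt$values[1, 8], env$ppt$values[1, 1])
  expect_equal(unname(which.max(env$tmean$values[1, ])), 7)
  wd <- attr(env, "ground_truth")$water_depth_full$values
  expect_true(which.max(wd[1, ]) %in% 9:10)   # wet-season peak depth
  expect_true(which.min(wd[1, ]) %in% 3:5)    # spring minimum
})

test_that("the planted warming trend is recovered by OLS within 10%", {
  # a single 44-year window is too noisy for a 10% slope claim (the OLS
  # standard error is ~20% of the trend), so the check averages the
  # estimate over independent replicates: unbiased recovery of 0.025
  slopes <- vapply(1:25, function(k) {
    cfg <- small_config(seed = 500 + k, n = 2L)
    env <- gen_environment(cfg)
    ann <- rowMeans(env$tmean$values)
    yrs <- env$tmean$years
    post <- yrs >= 1979
    ols_oracle(yrs[post], ann[post])
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.025) / 0.025, 0.10)
})

test_that("water depth is only weakly coupled to precipitation", {
  # share of monthly depth-anomaly variance explained by smoothed
  # precipitation stays near the configured 5%
  r2 <- vapply(1:5, function(k) {
    cfg <- small_config(seed = 400 + k, n = 2L)
    env <- gen_environment(cfg)
    wd <- attr(env, "ground_truth")$water_depth_full
    # month-major anomalies about each month's climatology
    danom <- as.numeric(t(wd$values) - colMeans(wd$values))
    p <- as.numeric(t(env$ppt$values))
    sm <- stats::filter(p, rep(1 / 12, 12), sides = 1)
    ok <- !is.na(sm)
    summary(lm(danom[ok] ~ sm[ok]))$r.squared
  }, numeric(1))
  expect_gt(mean(r2), 0.01)
  expect_lt(mean(r2), 0.15)
})

test_that("generation is deterministic under the seed", {
  a <- simulate_study(sim_config(seed = 9))
  b <- simulate_study(sim_config(seed = 9))
  expect_identical(a$environment, b$environment)
  expect_identical(a$trees, b$trees)
  expect_identical(a$isotopes, b$isotopes)
  c <- simulate_study(sim_config(seed = 10))
  expect_false(identical(a$trees[[1]]$widths, c$trees[[1]]$widths))
})

test_that("silent generator gives the pure ontogenetic curve", {
  cfg <- small_config(seed = 2, n = 3L, noise_sigma = 0,
                      sensitivity = list(list(variable = "water_depth",
                                              months = 6:9, beta = 0)))
  env <- gen_environment(cfg)
  trees <- gen_ring_series(cfg, env)
  rs <- trees[[1]]
  a <- seq_along(rs$widths)
  onto <- (4.4 - 1.9) * exp(-a / 30) + 1.9  # TADI ontogeny parameters
  expect_equal(rs$widths, onto, tolerance = 1e-12)
})

test_that("no trees means an empty list", {
  cfg <- small_config(seed = 3, n = 0L)
  env <- gen_environment(cfg)
  expect_length(gen_ring_series(cfg, env), 0L)
})

test_that("tree census and age structure match the configuration", {
  sim <- simulate_study(sim_config(seed = 4))
  sp <- vapply(sim$trees, `[[`, "", "species_code")
  expect_equal(sum(sp == "TAAS"), 22L)
  expect_equal(sum(sp == "TADI"), 26L)
  expect_equal(sum(sp == "PIEL"), 26L)
  gt <- attr(sim$trees, "ground_truth")
  ages <- gt$trees$age
  expect_true(all(ages[gt$trees$species == "TAAS"] %in% 52:289))
  expect_true(all(ages[gt$trees$species == "TADI"] %in% 46:219))
  expect_true(all(ages[gt$trees$species == "PIEL"] %in% 46:162))
  # ground truth is attached for downstream assertions
  expect_true(!is.null(gt$signal) && !is.null(gt$betas))
})

test_that("isotope sampling reproduces the configured census", {
  sim <- simulate_study(sim_config(seed = 5))
  counts <- table(sim$isotopes$species_code)
  expect_equal(counts[["TAAS"]], 167L)
  expect_equal(counts[["TADI"]], 133L)
  expect_equal(counts[["PIEL"]], 116L)
  # decadal-then-bidecadal sampling years only
  grid <- c(seq(2020, 1880, -10), seq(1860, 1800, -20))
  expect_true(all(sim$isotopes$year %in% grid))
  # at most 16 trees per species
  per_tree <- table(sim$isotopes$species_code,
                    sim$isotopes$tree_id) > 0
  expect_true(all(rowSums(per_tree) <= 16L))
})

test_that("a constant prescribed iWUE survives the chain exactly", {
  cfg <- sim_config(seed = 6,
                    iwue = list(baseline = 80, age_slope = 0,
                                year_trend = 0, trend_start = 1930L,
                                temp_effect = 0, noise_sd = 0,
                                n_isotope_trees = 16L,
                                census = c(TAAS = 167L, TADI = 133L,
                                           PIEL = 116L)))
  sim <- simulate_study(cfg)
  rec <- iwue_pipeline(sim$isotopes)
  expect_lt(max(abs(rec$iwue - 80)), 1e-9)
})

test_that("a grid smaller than the census is refused", {
  cfg <- sim_config(seed = 7, n_trees = c(TADI = 16L),
                    iwue = list(baseline = 85, age_slope = -0.1,
                                year_trend = 0.3, trend_start = 1930L,
                                temp_effect = 2, noise_sd = 3,
                                n_isotope_trees = 4L,
                                census = c(TADI = 133L)))
  env <- gen_environment(cfg)
  trees <- gen_ring_series(cfg, env)
  expect_error(gen_isotope_series(cfg, trees), "smaller than")
})

test_that("unknown climate overrides are rejected", {
  expect_error(sim_config(climate_overrides = list(humidity = list())),
               "unknown climate")
})
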