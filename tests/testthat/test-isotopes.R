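test_that("delta notation is linear in the ratio", {
  expect_equal(delta13C_from_ratios(0.0112, 0.0112), 0)
  expect_equal(delta13C_from_ratios(0.99 * 0.0112, 0.0112), -10)
  expect_equal(delta13C_from_ratios(1.01 * 0.0112, 0.0112), 10)
  expect_error(delta13C_from_ratios(-1, 0.0112), "positive")
})

test_that("discrimination matches hand arithmetic and is monotone", {
  expect_equal(discrimination(-8, -8), 0)
  expect_equal(discrimination(-8, -27), 19 / 0.973)  # 19.527...
  ds <- seq(-30, -20, 0.5)
  expect_true(all(diff(discrimination(-8, ds)) < 0))
  expect_error(discrimination(-8, -1000), "-1000")
})

test_that("Ci inversion hits its boundary identities", {
  expect_equal(ci_from_discrimination(4.4, 370), 0)
  expect_equal(ci_from_discrimination(27, 370), 370)
  # continues the discrimination example
  expect_equal(ci_from_discrimination(19 / 0.973, 370),
               370 * (19 / 0.973 - 4.4) / 22.6)
  expect_equal(round(ci_from_discrimination(19 / 0.973, 370), 2), 247.66)
  expect_error(ci_from_discrimination(10, 370, a = 5, b = 5), "exceed")
})

test_that("iWUE is the CO2 draw-down over 1.6", {
  expect_equal(iwue(370, 370), 0)
  expect_equal(iwue(370, 0), 370 / 1.6)
  expect_equal(round(iwue(370, 247.66), 2), 76.46)
})

test_that("the packaged atmospheric history satisfies its invariants", {
  atm <- atmospheric_history()
  expect_true(all(c("year", "ca", "d13ca") %in% names(atm)))
  expect_equal(atm$year, 1700:2022)
  expect_true(all(atm$ca > 250))
  mod <- atm[atm$year >= 1850, ]
  expect_true(all(diff(mod$ca) > 0))       # rising CO2
  expect_true(all(diff(mod$d13ca) < 0))    # Suess-effect decline
})

test_that("wood-to-iWUE round trip is exact over the physical domain", {
  atm <- atmospheric_history()
  grid <- expand.grid(d13c = seq(-32, -20, 0.5),
                      year = seq(1750, 2020, 10))
  samples <- data.frame(tree_id = "G", year = grid$year,
                        cambial_age = 50, d13c = grid$d13c)
  samples$tree_id <- paste0("G", seq_len(nrow(samples)))  # unique keys
  rec <- iwue_pipeline(samples, atm)
  back <- delta13C_from_iwue(rec$iwue, rec$ca,
                             atm$d13ca[match(rec$year, atm$year)])
  expect_lt(max(abs(back - samples$d13c)), 1e-9)
  expect_equal(nrow(rec), nrow(samples))
})

test_that("zero wood correction means leaf-equivalent tissue", {
  atm <- atmospheric_history()
  s <- data.frame(tree_id = "L", year = 2000, cambial_age = 40,
                  d13c = -26)
  r0 <- iwue_pipeline(s, atm, wood_correction_d = 0)
  expect_equal(r0$d13c_leaf, -26)
  r2 <- iwue_pipeline(s, atm, wood_correction_d = 2)
  expect_equal(r2$d13c_leaf, -28)
  # wood is enriched relative to leaf, so correcting lowers delta,
  # raises discrimination, raises Ci, lowers iWUE
  expect_gt(r2$big_delta, r0$big_delta)
  expect_lt(r2$iwue, r0$iwue)
})

test_that("missing atmospheric years fail naming the year", {
  s <- data.frame(tree_id = "M", year = 1492, cambial_age = 10,
                  d13c = -25)
  expect_error(iwue_pipeline(s, atmospheric_history()), "1492")
})

test_that("nonphysical Ci is flagged but not discarded", {
  atm <- atmospheric_history()
  s <- data.frame(tree_id = c("A", "B"), year = 2000, cambial_age = 30,
                  d13c = c(-26, -3))  # -3 implies discrimination < a
  rec <- iwue_pipeline(s, atm)
  expect_equal(nrow(rec), 2L)
  expect_true(rec$physical[1])
  expect_false(rec$physical[2])
  expect_lt(rec$ci[2], 0)
})

test_that("iWUE rises with Ca when discrimination is held fixed", {
  cas <- seq(280, 420, 10)
  for (delta in c(15, 18, 21)) {
    ci <- ci_from_discrimination(delta, cas)
    expect_true(all(diff(iwue(cas, ci)) > 0))
  }
})

test_that("under constant leaf delta the packaged history implies rising iWUE", {
  atm <- atmospheric_history()
  sub <- atm[atm$year %in% 1930:2020, ]
  big_delta <- discrimination(sub$d13ca, -27)
  w <- iwue(sub$ca, ci_from_discrimination(big_delta, sub$ca))
  expect_gt(w[sub$year == 2020], w[sub$year == 1930])
  expect_gt(ols_oracle(sub$year, w), 0)
})

test_that("age detrending removes an exactly linear age effect", {
  rec <- structure(
    data.frame(tree_id = "T", species_code = "TADI",
               year = 1900 + seq(0, 98, 2), cambial_age = seq(10, 108, 2),
               d13c_wood = -26, d13c_leaf = -28, big_delta = 20,
               ca = 300, ci = 200,
               iwue = 100 - 0.25 * seq(10, 108, 2), physical = TRUE),
    class = c("iwue_records", "data.frame"))
  out <- age_detrend_iwue(rec)
  expect_equal(max(abs(out$iwue_age_residual)), 0, tolerance = 1e-9)
  expect_equal(attr(out, "age_slopes")[["TADI"]], -0.25)
})

test_that("age and year effects separate in an orthogonal design", {
  # factorial ages x years decouples the two predictors
  g <- expand.grid(cambial_age = seq(10, 100, 10),
                   year = seq(1935, 2015, 10))
  set.seed(8)
  iw <- 90 - 0.1 * g$cambial_age + 0.3 * (g$year - 1935) + rnorm(nrow(g), 0, 1)
  rec <- structure(
    data.frame(tree_id = paste0("T", seq_len(nrow(g))),
               species_code = "PIEL", year = g$year,
               cambial_age = g$cambial_age, d13c_wood = -26,
               d13c_leaf = -28, big_delta = 20, ca = 350, ci = 230,
               iwue = iw, physical = TRUE),
    class = c("iwue_records", "data.frame"))
  out <- age_detrend_iwue(rec)
  fit <- lm(iwue ~ cambial_age, data = rec)
  ci_age <- confint(fit)["cambial_age", ]
  expect_gt(-0.1, ci_age[1]); expect_lt(-0.1, ci_age[2])
  yr_slope <- ols_oracle(out$year, out$iwue_age_residual)
  expect_equal(yr_slope, 0.3, tolerance = 0.05)
  # residuals sum to zero per species (OLS property)
  expect_equal(sum(out$iwue_age_residual), 0, tolerance = 1e-8)
})

test_that("degenerate age structures are refused", {
  rec <- structure(
    data.frame(tree_id = paste0("T", 1:12), species_code = "X",
               year = 2000:2011, cambial_age = rep(30, 12),
               d13c_wood = -26, d13c_leaf = -28, big_delta = 20,
               ca = 350, ci = 230, iwue = rnorm(12, 90), physical = TRUE),
    class = c("iwue_records", "data.frame"))
  expect_error(age_detrend_iwue(rec), "span")
  expect_error(age_detrend_iwue(rec[1:5, ]), ">= 10")
})

test_that("covariate regressions behave at the extremes", {
  cfg <- sim_config(seed = 15)
  sim <- simulate_study(cfg)
  rec <- age_detrend_iwue(iwue_pipeline(sim$isotopes))
  # the residual regressed on itself is a perfect fit; restrict to one
  # species and unique years so the year join is unambiguous
  one <- rec[rec$species_code == "PIEL", ]
  one <- one[!duplicated(one$year), ]
  tab <- suppressWarnings(iwue_covariate_regressions(
    structure(one, class = c("iwue_records", "data.frame")),
    data.frame(year = one$year, self = one$iwue_age_residual)))
  expect_equal(tab$r_squared[tab$species == "PIEL"], 1, tolerance = 1e-9)
  # too few joined records: every species x covariate cell is skipped
  w <- capture_warnings(
    empty <- iwue_covariate_regressions(
      rec, data.frame(year = 1:5, cov = rnorm(5))))
  expect_true(all(grepl("skipped", w)))
  expect_equal(nrow(empty), 0L)
})
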