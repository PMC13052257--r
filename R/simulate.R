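#' Configuration for the synthetic wetland-dendro study generator
#'
#' Bundles every parameter of the synthetic-data module.  The defaults
#' emulate the sampling design and environment of a subtropical swamp-forest
#' study: three species (22 pond cypress TAAS, 26 bald cypress TADI, 26
#' slash pine PIEL), tree ages spanning 46-289 years at the final year,
#' a negative-exponential ontogenetic width curve per species, monthly
#' climate for 1895-2022 with wet-season (Apr-Oct) rainfall and
#' temperature peaks, a water-depth gauge record restricted to 1990-2021
#' whose variance is only ~5% explained by precipitation, a multiplicative
#' (log-linear) water-depth sensitivity of growth in June-September,
#' lognormal width noise, and decadally subsampled delta-13-C series whose
#' prescribed iWUE rises after 1930 with CO2 and temperature.
#'
#' @param seed Integer master seed; all generator randomness derives from
#'   it and outputs are byte-identical under a fixed value.
#' @param n_trees Named integer vector of trees per species.
#' @param sensitivity List of growth drivers; each element is a list with
#'   `variable` (environment variable name), `months` (month numbers of
#'   the current growth year), and `beta` (log-growth per SD of the
#'   seasonal aggregate).
#' @param noise_sigma Lognormal SD of per-tree-year width noise.
#' @param cohort_beta Log-growth change per 100 years of birth year
#'   (default 0: no cohort effect; `log(2)` makes trees born a century
#'   later grow twice as fast at equal age).
#' @param spatial_effect Optional list(`covariate`, `beta`): log-growth per
#'   SD of the named distance covariate (default `NULL`, no effect).
#' @param env_years,water_years Calendar spans of the climate series and of
#'   the (shorter) water-gauge record.
#' @param temp_trend Warming trend in degC/yr applied from
#'   `trend_start_year` on (default 0.025 from 1979).
#' @param trend_start_year Year the climate trends switch on.
#' @param iwue List of isotope-trajectory parameters: `baseline`
#'   (micromol/mol at age 0 before the trend), `age_slope` (per year of
#'   cambial age), `year_trend` (per year after `trend_start`),
#'   `trend_start`, `temp_effect` (per degC of annual temperature
#'   anomaly), `noise_sd`, `n_isotope_trees` (per species), `census`
#'   (named target sample counts per species).
#' @param climate_overrides Optional named list patching individual fields
#'   of the built-in per-variable climate settings (each variable is a list
#'   with `mean`, `amplitude`, `peak_month`, `trend`, `annual_sd`,
#'   `annual_phi`, `monthly_sd`; `water_depth` has `anomaly_sd`, `ppt_r2`,
#'   `annual_phi`), e.g.
#'   `list(tmean = list(annual_sd = 0, monthly_sd = 0))` for a
#'   deterministic temperature series.
#' @return An object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_trees = c(TAAS = 22L, TADI = 26L, PIEL = 26L),
                       sensitivity = list(
                         list(variable = "water_depth", months = 6:9,
                              beta = 0.35)),
                       noise_sigma = 0.3,
                       cohort_beta = 0,
                       spatial_effect = NULL,
                       env_years = c(1895L, 2022L),
                       water_years = c(1990L, 2021L),
                       temp_trend = 0.025,
                       trend_start_year = 1979L,
                       iwue = list(baseline = 85, age_slope = -0.1,
                                   year_trend = 0.3, trend_start = 1930L,
                                   temp_effect = 2.0, noise_sd = 3,
                                   n_isotope_trees = 16L,
                                   census = c(TAAS = 167L, TADI = 133L,
                                              PIEL = 116L)),
                       climate_overrides = NULL) {
  species <- list(
    TAAS = list(code = "TAAS", age_range = c(52L, 289L),
                ontogeny = c(w0 = 1.8, decay = 40, asymptote = 0.55),
                # fixed ages (at the final year) of the 16 isotope trees;
                # chosen to cover the species' reported age span and to
                # give a decadal sampling grid at least as large as the
                # isotope census
                isotope_ages = c(289, 270, 250, 235, 220, 205, 195, 185,
                                 175, 160, 140, 120, 100, 85, 70, 52)),
    TADI = list(code = "TADI", age_range = c(46L, 219L),
                ontogeny = c(w0 = 4.4, decay = 30, asymptote = 1.9),
                isotope_ages = c(219, 175, 140, 115, 95, 84, 76, 70, 65,
                                 60, 56, 53, 50, 48, 47, 46)),
    PIEL = list(code = "PIEL", age_range = c(46L, 162L),
                ontogeny = c(w0 = 5.5, decay = 25, asymptote = 2.0),
                isotope_ages = c(162, 120, 100, 88, 76, 70, 66, 62, 58,
                                 55, 52, 50, 48, 46, 46, 46)))
  climate <- list(
    tmean = list(mean = 22.5, amplitude = 4.5, peak_month = 7.5,
                 trend = temp_trend, annual_sd = 0.4, annual_phi = 0.3,
                 monthly_sd = 0.6),
    ppt = list(mean = 150, amplitude = 110, peak_month = 7.5,
               trend = 0, annual_sd = 15, annual_phi = 0.3,
               monthly_sd = 30),
    vpdmin = list(mean = 4, amplitude = 2, peak_month = 5,
                  trend = 0.005, annual_sd = 0.3, annual_phi = 0.3,
                  monthly_sd = 0.4),
    vpdmax = list(mean = 16, amplitude = 5, peak_month = 5,
                  trend = 0.015, annual_sd = 0.8, annual_phi = 0.3,
                  monthly_sd = 1.2),
    water_depth = list(mean = 210, amplitude = 60, peak_month = 9.5,
                       anomaly_sd = 25, ppt_r2 = 0.05, annual_phi = 0.4))
  if (!is.null(climate_overrides)) {
    bad <- setdiff(names(climate_overrides), names(climate))
    if (length(bad))
      stop("unknown climate variable(s): ", paste(bad, collapse = ", "))
    for (v in names(climate_overrides))
      climate[[v]] <- utils::modifyList(climate[[v]], climate_overrides[[v]])
  }
  cfg <- list(seed = as.integer(seed), n_trees = n_trees,
              species = species, climate = climate,
              sensitivity = sensitivity, noise_sigma = noise_sigma,
              cohort_beta = cohort_beta, spatial_effect = spatial_effect,
              env_years = as.integer(env_years),
              water_years = as.integer(water_years),
              trend_start_year = as.integer(trend_start_year),
              iwue = iwue)
  stopifnot(cfg$seed < 2^31, all(n_trees >= 0), noise_sigma >= 0,
            diff(cfg$env_years) > 0)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: seed %d, %s trees, env %d-%d, water %d-%d\n",
              x$seed,
              paste(sprintf("%s=%d", names(x$n_trees), x$n_trees),
                    collapse = "/"),
              x$env_years[1], x$env_years[2],
              x$water_years[1], x$water_years[2]))
  invisible(x)
}

# seasonal shape helper: value at month m for peak p and amplitude A
.seasonal <- function(mean, amplitude, peak_month) {
  mean + amplitude * cos(2 * pi * ((1:12) - peak_month) / 12)
}

# AR(1) series of length n with marginal sd `sd` and coefficient phi
.ar1 <- function(n, sd, phi) {
  if (sd == 0) return(numeric(n))
  e <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(e, phi, method = "recursive",
                           init = stats::rnorm(1, 0, sd)))
}

#' Generate the synthetic monthly environment set
#'
#' Produces monthly series (sinusoidal seasonality + optional linear trend
#' + AR(1) interannual anomaly + monthly noise) for precipitation,
#' mean/min/max temperature, min/max VPD, and water depth.  Water depth is
#' the 12-month trailing mean of precipitation (standardized) plus an
#' independent AR(1) anomaly, mixed so that precipitation explains
#' `climate$water_depth$ppt_r2` (~5%) of the depth anomaly variance; the
#' *observed* gauge record is truncated to `water_years`, while the
#' full-span truth (which drives tree growth) is kept in the
#' `"ground_truth"` attribute together with the standardized seasonal
#' driver aggregates used by [gen_ring_series()].
#'
#' @param config A [sim_config()].
#' @return Named list of [monthly_env()] objects (`ppt`, `tmean`, `tmin`,
#'   `tmax`, `vpdmin`, `vpdmax`, `water_depth`), with attribute
#'   `"ground_truth"`.
#' @export
gen_environment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  yrs <- seq.int(config$env_years[1], config$env_years[2])
  ny <- length(yrs)
  trend_yrs <- pmax(0, yrs - config$trend_start_year)

  gen_var <- function(p) {
    anom <- .ar1(ny, p$annual_sd, p$annual_phi)
    m <- outer(rep(1, ny), .seasonal(p$mean, p$amplitude, p$peak_month)) +
      p$trend * trend_yrs + anom +
      matrix(stats::rnorm(ny * 12L, 0, p$monthly_sd), ny, 12L)
    m
  }
  cl <- config$climate
  tmean_m <- gen_var(cl$tmean)
  tmin_m <- tmean_m - 5 + matrix(stats::rnorm(ny * 12L, 0, 0.3), ny, 12L)
  tmax_m <- tmean_m + 5 + matrix(stats::rnorm(ny * 12L, 0, 0.3), ny, 12L)
  ppt_m <- pmax(gen_var(cl$ppt), 0)
  vpdmin_m <- pmax(gen_var(cl$vpdmin), 0)
  vpdmax_m <- pmax(gen_var(cl$vpdmax), 0)

  # water depth: weakly coupled to precipitation
  wd <- cl$water_depth
  ppt_flat <- as.numeric(t(ppt_m))               # month-major
  smooth12 <- stats::filter(ppt_flat, rep(1 / 12, 12L), sides = 1)
  smooth12[is.na(smooth12)] <- mean(ppt_flat)
  z_ppt <- as.numeric(scale(smooth12))
  sd_sig <- wd$anomaly_sd * sqrt(wd$ppt_r2)
  sd_noi <- wd$anomaly_sd * sqrt(1 - wd$ppt_r2)
  noise <- .ar1(ny * 12L, sd_noi, wd$annual_phi)
  depth_anom <- sd_sig * z_ppt + noise
  depth_m <- outer(rep(1, ny), .seasonal(wd$mean, wd$amplitude,
                                         wd$peak_month)) +
    matrix(depth_anom, ny, 12L, byrow = TRUE)

  full_depth <- monthly_env("water_depth", yrs, depth_m)
  wy <- yrs >= config$water_years[1] & yrs <= config$water_years[2]
  obs_depth <- monthly_env("water_depth", yrs[wy],
                           depth_m[wy, , drop = FALSE])

  envs <- list(
    ppt = monthly_env("ppt", yrs, ppt_m),
    tmean = monthly_env("tmean", yrs, tmean_m),
    tmin = monthly_env("tmin", yrs, tmin_m),
    tmax = monthly_env("tmax", yrs, tmax_m),
    vpdmin = monthly_env("vpdmin", yrs, vpdmin_m),
    vpdmax = monthly_env("vpdmax", yrs, vpdmax_m),
    water_depth = obs_depth)

  # standardized seasonal driver aggregates (from the full-span truth)
  truth_envs <- c(envs[setdiff(names(envs), "water_depth")],
                  list(water_depth = full_depth))
  drivers <- data.frame(year = yrs)
  for (k in seq_along(config$sensitivity)) {
    s <- config$sensitivity[[k]]
    ev <- truth_envs[[s$variable]]
    agg <- if (s$variable == "ppt")
      rowSums(ev$values[, s$months, drop = FALSE])
    else rowMeans(ev$values[, s$months, drop = FALSE])
    drivers[[paste0("z", k)]] <- as.numeric(scale(agg))
  }
  attr(envs, "ground_truth") <- list(
    water_depth_full = full_depth,
    drivers = drivers,
    annual_tmean_anomaly = rowMeans(tmean_m) -
      mean(.seasonal(cl$tmean$mean, cl$tmean$amplitude,
                     cl$tmean$peak_month)))
  envs
}

#' Generate synthetic ring-width series
#'
#' Width of the ring at cambial age `a` in calendar year `y` is
#' `ontogeny(a) * exp(sum_k beta_k z_k(y)) * exp(cohort + spatial) *
#' lognormal noise`, with `ontogeny(a) = (w0 - asymptote) * exp(-a/decay)
#' + asymptote` and `z_k` the standardized seasonal drivers from
#' [gen_environment()].  Years outside the environment span carry no
#' common signal (`z = 0`): only the instrumented period is informative,
#' as for real gauges.  The lognormal noise is mean-corrected
#' (`exp(rnorm(0, sigma) - sigma^2/2)`) so the expected width equals the
#' deterministic part.
#'
#' The first `iwue$n_isotope_trees` trees of each species get the fixed
#' isotope-tree ages from the config (so the decadal sampling grid is
#' reproducible); remaining trees draw their age uniformly from the
#' species' age range.  Distance covariates (m) are attached per tree:
#' `dist_to_road` for all, `dist_to_dome` for the cypresses,
#' `dist_to_edge` for the pine.
#'
#' @param config A [sim_config()].
#' @param environment Result of [gen_environment()] (its ground-truth
#'   attribute supplies the drivers).
#' @return List of [ring_series()]; attribute `"ground_truth"` holds the
#'   drivers, betas, per-tree birth years and distances.
#' @export
gen_ring_series <- function(config, environment) {
  stopifnot(inherits(config, "sim_config"))
  gt <- attr(environment, "ground_truth")
  if (is.null(gt)) stop("'environment' lacks ground truth: use gen_environment()")
  set.seed(config$seed + 1L)
  final_year <- config$env_years[2]
  betas <- vapply(config$sensitivity, `[[`, numeric(1), "beta")
  zmat <- as.matrix(gt$drivers[, -1, drop = FALSE])
  signal <- as.numeric(zmat %*% betas)          # log-scale common signal
  # mean-correct so exp(signal) has expectation ~1: otherwise the years
  # inside the instrumented span (signal present) would be systematically
  # wider than the uninstrumented years (signal 0), faking a growth trend
  if (length(signal) > 1L && stats::var(signal) > 0)
    signal <- signal - 0.5 * stats::var(signal)
  names(signal) <- gt$drivers$year

  out <- list(); meta <- list()
  for (sp in names(config$n_trees)) {
    n <- config$n_trees[[sp]]
    if (n == 0L) next
    spc <- config$species[[sp]]
    n_iso <- min(config$iwue$n_isotope_trees, n, length(spc$isotope_ages))
    ages_final <- c(spc$isotope_ages[seq_len(n_iso)],
                    if (n > n_iso)
                      round(stats::runif(n - n_iso, spc$age_range[1],
                                         spc$age_range[2])))
    for (i in seq_len(n)) {
      age_f <- ages_final[i]
      first_year <- final_year - age_f + 1L
      yrs <- seq.int(first_year, final_year)
      a <- seq_along(yrs)
      o <- spc$ontogeny
      onto <- (o[["w0"]] - o[["asymptote"]]) * exp(-a / o[["decay"]]) +
        o[["asymptote"]]
      z <- signal[as.character(yrs)]
      z[is.na(z)] <- 0
      # cohort effect relative to the species' earliest possible birth year
      earliest <- final_year - spc$age_range[2] + 1L
      lg <- log(onto) + z +
        config$cohort_beta * (first_year - earliest) / 100
      covs <- c(dist_to_road = stats::runif(1, 700, 5000))
      if (sp %in% c("TAAS", "TADI"))
        covs["dist_to_dome"] <- stats::runif(1, 0, 60)
      if (sp == "PIEL")
        covs["dist_to_edge"] <- stats::runif(1, 5, 200)
      if (!is.null(config$spatial_effect)) {
        se <- config$spatial_effect   # list(covariate, beta per meter)
        if (se$covariate %in% names(covs))
          lg <- lg + se$beta * covs[[se$covariate]]
      }
      w <- exp(lg) * exp(stats::rnorm(length(yrs), 0, config$noise_sigma) -
                           config$noise_sigma^2 / 2)
      id <- sprintf("%s%02d", sp, i)
      out[[id]] <- ring_series(id, w, first_year, species_code = sp,
                               distance_covariates = covs)
      meta[[id]] <- data.frame(
        tree = id, species = sp, first_year = first_year, age = age_f,
        dist_to_road = covs[["dist_to_road"]],
        dist_to_dome = if ("dist_to_dome" %in% names(covs))
          covs[["dist_to_dome"]] else NA_real_,
        dist_to_edge = if ("dist_to_edge" %in% names(covs))
          covs[["dist_to_edge"]] else NA_real_)
    }
  }
  attr(out, "ground_truth") <- list(
    drivers = gt$drivers, betas = betas, signal = signal,
    cohort_beta = config$cohort_beta,
    annual_tmean_anomaly = data.frame(
      year = gt$drivers$year, anomaly = gt$annual_tmean_anomaly),
    trees = do.call(rbind, c(meta, list(make.row.names = FALSE))))
  out
}

#' Generate a synthetic decadally subsampled isotope table
#'
#' Emulates the isotope sampling design: per species, the first
#' `n_isotope_trees` trees are subsampled at decadal years (2020, 2010,
#' ..., 1880) and bidecadal years before that (1860, 1840, 1820, 1800),
#' restricted to years the tree was alive and the atmospheric history
#' covers.  The prescribed iWUE trajectory
#' `baseline + age_slope * age + year_trend * max(0, year - trend_start)
#' + temp_effect * temp_anomaly(year) + noise` is inverted *exactly*
#' through the discrimination chain (plus wood correction) to wood
#' delta-13-C, so [iwue_pipeline()] recovers the prescription up to the
#' added noise.  When the sampling grid exceeds the configured census the
#' grid is subsampled (seeded, uniform) down to the census, emulating
#' incomplete recovery of datable wood; a grid smaller than the census is
#' an error.
#'
#' @param config A [sim_config()].
#' @param trees Result of [gen_ring_series()].
#' @param atm Atmospheric history data.frame (default
#'   [atmospheric_history()]).
#' @return data.frame with `tree_id`, `species_code`, `year`,
#'   `cambial_age`, `d13c`; attribute `"ground_truth"` holds the noise-free
#'   and realized iWUE per row and the trajectory parameters.
#' @export
gen_isotope_series <- function(config, trees, atm = atmospheric_history()) {
  stopifnot(inherits(config, "sim_config"))
  gt_env <- attr(trees, "ground_truth")
  set.seed(config$seed + 2L)
  iw <- config$iwue
  grid_years <- c(seq(2020L, 1880L, -10L), seq(1860L, 1800L, -20L))
  grid_years <- grid_years[grid_years %in% atm$year]
  # annual temperature anomaly lookup (0 outside the climate span)
  sp_of <- vapply(trees, `[[`, "", "species_code")

  rows <- list()
  for (sp in unique(sp_of)) {
    tr <- trees[sp_of == sp][seq_len(min(iw$n_isotope_trees,
                                         sum(sp_of == sp)))]
    g <- do.call(rbind, lapply(tr, function(rs) {
      yrs <- ring_years(rs)
      y <- grid_years[grid_years %in% yrs]
      if (length(y) == 0L) return(NULL)
      data.frame(tree_id = rs$series_id, species_code = sp, year = y,
                 cambial_age = y - rs$first_year + 1L + rs$pith_offset)
    }))
    census <- iw$census[[sp]]
    if (!is.null(census) && !is.na(census)) {
      if (nrow(g) < census)
        stop("species ", sp, ": sampling grid (", nrow(g),
             ") smaller than configured census (", census, ")")
      if (nrow(g) > census)
        g <- g[sort(sample.int(nrow(g), census)), ]
    }
    rows[[sp]] <- g
  }
  d <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  # annual temperature anomaly (0 before the instrumented climate span)
  temp_anom <- rep(0, nrow(d))
  if (!is.null(gt_env) && !is.null(gt_env$annual_tmean_anomaly)) {
    ta <- gt_env$annual_tmean_anomaly
    j0 <- match(d$year, ta$year)
    temp_anom[!is.na(j0)] <- ta$anomaly[j0[!is.na(j0)]]
  }
  iwue_det <- iw$baseline + iw$age_slope * d$cambial_age +
    iw$year_trend * pmax(0, d$year - iw$trend_start) +
    iw$temp_effect * temp_anom
  iwue_real <- iwue_det + stats::rnorm(nrow(d), 0, iw$noise_sd)
  j <- match(d$year, atm$year)
  d$d13c <- delta13C_from_iwue(iwue_real, atm$ca[j], atm$d13ca[j])
  attr(d, "ground_truth") <- list(iwue_true = iwue_det,
                                  iwue_realized = iwue_real,
                                  params = iw)
  d
}

#' Generate a complete synthetic study
#'
#' Runs [gen_environment()], [gen_ring_series()] and [gen_isotope_series()]
#' under one config and bundles the results with the annual covariate table
#' needed by the iWUE regressions.  Fully deterministic under
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @param atm Atmospheric history (default [atmospheric_history()]).
#' @return An object of class `"swamp_simulation"`: list with
#'   `environment` (list of [monthly_env()]), `trees` (list of
#'   [ring_series()]), `isotopes` (sample data.frame), `annual_covariates`,
#'   and `config`.
#' @export
simulate_study <- function(config = sim_config(), atm = atmospheric_history()) {
  env <- gen_environment(config)
  trees <- gen_ring_series(config, env)
  iso <- gen_isotope_series(config, trees, atm)
  structure(
    list(environment = env, trees = trees, isotopes = iso,
         annual_covariates = annual_covariate_table(env, atm),
         config = config),
    class = "swamp_simulation")
}

#' @export
print.swamp_simulation <- function(x, ...) {
  sp <- table(vapply(x$trees, `[[`, "", "species_code"))
  cat(sprintf(
    "swamp_simulation (seed %d): %d trees (%s), %d isotope samples, %d environment variable(s)\n",
    x$config$seed, length(x$trees),
    paste(sprintf("%s=%d", names(sp), sp), collapse = "/"),
    nrow(x$isotopes), length(x$environment)))
  invisible(x)
}
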