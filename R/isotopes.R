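#' Delta notation from isotope ratios
#'
#' `delta13C = (R_sample / R_standard - 1) * 1000` per mil, with `R` the
#' 13C/12C ratio and the standard conventionally VPDB.
#'
#' @param R_sample,R_standard Positive isotope ratios.
#' @return delta-13-C in per mil.
#' @export
delta13C_from_ratios <- function(R_sample, R_standard) {
  if (any(R_sample <= 0) || any(R_standard <= 0))
    stop("isotope ratios must be positive")
  (R_sample / R_standard - 1) * 1000
}

#' Photosynthetic carbon isotope discrimination
#'
#' `Delta13C = (delta13Ca - delta13C_sample) / (1 + delta13C_sample / 1000)`
#' — the plant's discrimination against 13C relative to the atmospheric CO2
#' it fixed.
#'
#' @param delta13Ca delta-13-C of atmospheric CO2 in the year of wood
#'   formation, per mil.
#' @param delta13C_sample delta-13-C of the (leaf-equivalent) plant tissue,
#'   per mil; must exceed -1000.
#' @return Discrimination Delta-13-C in per mil.
#' @export
discrimination <- function(delta13Ca, delta13C_sample) {
  if (any(delta13C_sample <= -1000))
    stop("delta13C_sample must be > -1000 per mil")
  (delta13Ca - delta13C_sample) / (1 + delta13C_sample / 1000)
}

#' Intercellular CO2 from discrimination (simple Farquhar model)
#'
#' Inverts `Delta13C ~ a + (b - a) * Ci / Ca`, where `a` (~4.4 per mil) is
#' the fractionation from slower 13CO2 diffusion through stomata and `b`
#' (~27 per mil) the fractionation of carboxylation by Rubisco.
#'
#' @param big_delta Discrimination Delta-13-C, per mil.
#' @param ca Atmospheric CO2, ppm (> 0).
#' @param a,b Fractionation constants, per mil (defaults 4.4 and 27;
#'   `b > a` required).
#' @return Ci in ppm.  Values outside `[0, ca]` are physically impossible
#'   for this model; they are returned unchanged (so the sample census is
#'   preserved) but flagged downstream by [iwue_pipeline()].
#' @export
ci_from_discrimination <- function(big_delta, ca, a = 4.4, b = 27) {
  if (b <= a) stop("'b' must exceed 'a'")
  if (any(ca <= 0)) stop("'ca' must be positive")
  ca * (big_delta - a) / (b - a)
}

#' Intrinsic water-use efficiency
#'
#' `iWUE = A / g_s = (Ca - Ci) / 1.6` in micromol CO2 per mol H2O
#' conductance: assimilation per unit stomatal conductance, with 1.6 the
#' ratio of diffusivities of water vapour and CO2 in air.
#'
#' @param ca,ci Atmospheric and intercellular CO2, ppm.
#' @return iWUE in micromol per mol.
#' @export
iwue <- function(ca, ci) (ca - ci) / 1.6

#' Packaged annual atmospheric CO2 and delta-13-C history
#'
#' Loads the annual atmospheric history shipped with the package:
#' `Ca` (ppm) and `delta13Ca` (per mil VPDB) for 1700-2022.  The file is a
#' synthetic reconstruction — a monotone spline through hand-set anchor
#' points at the magnitudes of the published ice-core and flask
#' compilations — adequate for method development and simulation, not a
#' measurement record (hence `_synthetic` in its filename).  `Ca` rises
#' monotonically over 1850-2022 and `delta13Ca` declines (the Suess
#' effect).
#'
#' @param path Optional path to an alternative CSV with columns `year`,
#'   `ca`, `d13ca`.
#' @return data.frame with columns `year`, `ca`, `d13ca`.
#' @export
atmospheric_history <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "atmosphere_annual_synthetic.csv",
                        package = "swampdendro", mustWork = TRUE)
  d <- utils::read.csv(path)
  stopifnot(all(c("year", "ca", "d13ca") %in% names(d)))
  d
}

#' Wood delta-13-C to iWUE pipeline
#'
#' Applies the full chain to a per-ring sample table: subtract the
#' post-photosynthetic wood enrichment `d` (wood is enriched relative to
#' leaf, so `delta_leaf = delta_wood - d`), compute discrimination against
#' that year's atmospheric `delta13Ca`, invert the simple Farquhar model
#' for `Ci` under that year's `Ca`, and form `iWUE = (Ca - Ci) / 1.6`.
#' One record is emitted per input sample; physically impossible `Ci`
#' (< 0 or > `Ca`) is flagged in the `physical` column, not discarded, so
#' the sample census stays auditable.
#'
#' @param samples data.frame with columns `tree_id`, `year`, `cambial_age`,
#'   `d13c` (wood, per mil) and optionally `species_code`; see
#'   [read_isotope_table()].
#' @param atm Atmospheric history data.frame (`year`, `ca`, `d13ca`),
#'   default [atmospheric_history()]; every sample year must be present.
#' @param wood_correction_d Post-photosynthetic wood-to-leaf correction in
#'   per mil (default 2.0); 0 means the samples are leaf-equivalent tissue.
#' @param a,b Fractionation constants, see [ci_from_discrimination()].
#' @return An object of classes `"iwue_records"` and `"data.frame"`: one
#'   row per sample with `tree_id`, `species_code`, `year`, `cambial_age`,
#'   `d13c_wood`, `d13c_leaf`, `big_delta`, `ca`, `ci`, `iwue`, `physical`.
#' @export
iwue_pipeline <- function(samples, atm = atmospheric_history(),
                          wood_correction_d = 2.0, a = 4.4, b = 27) {
  need <- c("tree_id", "year", "cambial_age", "d13c")
  if (!all(need %in% names(samples)))
    stop("samples need columns ", paste(need, collapse = ", "))
  i <- match(samples$year, atm$year)
  if (anyNA(i))
    stop("year(s) missing from atmospheric history: ",
         paste(sort(unique(samples$year[is.na(i)])), collapse = ", "))
  d13c_leaf <- samples$d13c - wood_correction_d
  big_delta <- discrimination(atm$d13ca[i], d13c_leaf)
  ci <- ci_from_discrimination(big_delta, atm$ca[i], a, b)
  out <- data.frame(
    tree_id = samples$tree_id,
    species_code = if ("species_code" %in% names(samples))
      samples$species_code else NA_character_,
    year = samples$year,
    cambial_age = samples$cambial_age,
    d13c_wood = samples$d13c,
    d13c_leaf = d13c_leaf,
    big_delta = big_delta,
    ca = atm$ca[i],
    ci = ci,
    iwue = iwue(atm$ca[i], ci),
    physical = ci >= 0 & ci <= atm$ca[i])
  structure(out, class = c("iwue_records", "data.frame"),
            wood_correction_d = wood_correction_d, a = a, b = b)
}

#' Invert a prescribed iWUE to wood delta-13-C
#'
#' The exact algebraic inverse of [iwue_pipeline()]: given a target iWUE
#' and a year's `(Ca, delta13Ca)`, recovers the wood delta-13-C that the
#' pipeline would map back to that iWUE.  Used by the synthetic-data
#' generator and by round-trip tests.
#'
#' @param iwue_target iWUE in micromol per mol.
#' @param ca,d13ca The year's atmospheric CO2 (ppm) and delta-13-C (per mil).
#' @param wood_correction_d,a,b As in [iwue_pipeline()].
#' @return Wood delta-13-C, per mil.  Errors if the implied discrimination
#'   leaves the invertible domain (`delta_leaf <= -1000`).
#' @export
delta13C_from_iwue <- function(iwue_target, ca, d13ca,
                               wood_correction_d = 2.0, a = 4.4, b = 27) {
  ci <- ca - 1.6 * iwue_target
  big_delta <- a + (b - a) * ci / ca
  d13c_leaf <- (d13ca - big_delta) / (1 + big_delta / 1000)
  if (any(d13c_leaf <= -1000))
    stop("prescribed iWUE outside the invertible domain")
  d13c_leaf + wood_correction_d
}

#' Remove the tree-age effect from iWUE records
#'
#' Fits, per species, an OLS regression of iWUE on cambial age and stores
#' the residuals: the age-corrected iWUE used for trend and covariate
#' analyses.  Requires >= 10 records spanning >= 20 years of cambial age
#' per species.
#'
#' @param records An [iwue_pipeline()] result.
#' @return The same records with an `iwue_age_residual` column; per-species
#'   age slopes (micromol mol^-1 per year of age) in the `"age_slopes"`
#'   attribute.
#' @export
age_detrend_iwue <- function(records) {
  stopifnot(inherits(records, "iwue_records"))
  sp <- records$species_code
  if (all(is.na(sp))) sp <- rep("all", nrow(records))
  records$iwue_age_residual <- NA_real_
  slopes <- c()
  for (s in unique(sp)) {
    k <- which(sp == s)
    if (length(k) < 10L)
      stop("species '", s, "': need >= 10 records to fit the age model")
    if (diff(range(records$cambial_age[k])) < 20)
      stop("species '", s, "': cambial-age span < 20 yr, age effect ",
           "not identifiable")
    fit <- stats::lm(iwue ~ cambial_age, data = records[k, ])
    records$iwue_age_residual[k] <- stats::residuals(fit)
    slopes[s] <- stats::coef(fit)[["cambial_age"]]
  }
  attr(records, "age_slopes") <- slopes
  records
}

#' Regress age-corrected iWUE on annual covariates
#'
#' For each species and each covariate column, OLS of the iWUE age
#' residual on the covariate joined by calendar year.  Species-covariate
#' combinations with fewer than 10 joined records are skipped with a
#' warning.
#'
#' @param records An [age_detrend_iwue()] result (must carry
#'   `iwue_age_residual`).
#' @param annual_covariates data.frame with a `year` column plus one
#'   numeric column per covariate (e.g. mean annual temperature, total
#'   annual precipitation, min/max water depth, min/max VPD, `ca`,
#'   chronology RWI).
#' @return data.frame with one row per species x covariate: `species`,
#'   `covariate`, `slope`, `r_squared`, `p_value`, `n`.
#' @export
iwue_covariate_regressions <- function(records, annual_covariates) {
  if (!"iwue_age_residual" %in% names(records))
    stop("run age_detrend_iwue() first")
  stopifnot("year" %in% names(annual_covariates))
  covs <- setdiff(names(annual_covariates), "year")
  sp <- records$species_code
  if (all(is.na(sp))) sp <- rep("all", nrow(records))

  rows <- list()
  for (s in unique(sp)) {
    k <- which(sp == s)
    j <- match(records$year[k], annual_covariates$year)
    for (cv in covs) {
      x <- annual_covariates[[cv]][j]
      y <- records$iwue_age_residual[k]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 10L) {
        warning("species '", s, "' x '", cv, "' skipped: only ",
                sum(ok), " joined record(s)")
        next
      }
      fit <- stats::lm(y[ok] ~ x[ok])
      su <- summary(fit)
      rows[[length(rows) + 1L]] <- data.frame(
        species = s, covariate = cv,
        slope = stats::coef(fit)[[2L]],
        r_squared = su$r.squared,
        p_value = su$coefficients[2L, "Pr(>|t|)"],
        n = sum(ok))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(0), covariate = character(0),
               slope = numeric(0), r_squared = numeric(0),
               p_value = numeric(0), n = integer(0))
  rownames(out) <- NULL
  out
}
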