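#' Convert ring widths to basal area increments
#'
#' The basal area increment of year `t` is the annulus area
#' `BAI_t = pi * r_t^2 - pi * r_{t-1}^2`, where `r_t` is the cumulative
#' radius at the end of the increment.  The arithmetic is exact — no
#' smoothing — so `sum(BAI) = pi * (sum(widths))^2` whenever the starting
#' radius is zero.  When a series misses rings to the pith
#' (`pith_offset > 0`) the starting radius is seeded as
#' `pith_offset * mean(first five widths)` unless `r0` is given.
#'
#' @param rs A [ring_series()].
#' @param r0 Starting radius in mm before the first measured ring; default
#'   `NULL` means 0, or the pith-offset estimate above when
#'   `rs$pith_offset > 0`.
#' @return An object of class `"bai_series"`: list with `series_id`,
#'   `species_code`, `first_year`, `pith_offset`, `years`, `bai` (mm^2/yr),
#'   `cumulative_radius` (mm, end of each year), `distance_covariates`.
#' @export
widths_to_bai <- function(rs, r0 = NULL) {
  stopifnot(inherits(rs, "ring_series"))
  if (is.null(r0)) {
    r0 <- if (rs$pith_offset > 0L)
      rs$pith_offset * mean(utils::head(rs$widths, 5L)) else 0
  }
  stopifnot(is.numeric(r0), length(r0) == 1L, r0 >= 0)
  r <- r0 + cumsum(rs$widths)
  bai <- pi * (r^2 - c(r0, r[-length(r)])^2)
  structure(
    list(series_id = rs$series_id, species_code = rs$species_code,
         first_year = rs$first_year, pith_offset = rs$pith_offset,
         years = ring_years(rs), bai = bai, cumulative_radius = r,
         distance_covariates = rs$distance_covariates),
    class = "bai_series")
}

#' @export
print.bai_series <- function(x, ...) {
  cat(sprintf("bai_series '%s': %d yr, mean BAI %.1f mm^2/yr, final radius %.1f mm\n",
              x$series_id, length(x$years), mean(x$bai),
              x$cumulative_radius[length(x$cumulative_radius)]))
  invisible(x)
}

# cambial ages for a bai_series (same convention as ring_series)
.bai_ages <- function(b) seq_along(b$years) + b$pith_offset

#' Age-class-isolation trend analysis of basal area increment
#'
#' Separates ontogeny from calendar-time change by comparing the growth of
#' same-aged trees across calendar years: trees are grouped into 5-year
#' cambial-age classes centered at 10-year increments (ages 7.5-12.5,
#' 17.5-22.5, ...), the mean BAI of each class is computed per calendar
#' year, and the class means are regressed on calendar year by OLS.
#' Windows are half-open `[center - half_width, center + half_width)` so
#' every (tree, year) falls in at most one class.
#'
#' @param bai_list List of [widths_to_bai()] results.
#' @param class_centers Cambial-age class centers (default `seq(10, 120, 10)`).
#' @param half_width Half width of each class in years (default 2.5).
#' @param weighted Weight calendar years by the number of contributing
#'   trees in the regression (default `FALSE`, plain OLS).
#' @return An object of classes `"age_class_table"` and `"data.frame"`:
#'   one row per class with `class_center`, `slope` (mm^2/yr per calendar
#'   year), `r_squared`, `p_value`, `n_years`, `n_tree_years`.  Classes
#'   with fewer than 3 distinct calendar years (or 3 tree-years) are
#'   excluded with a warning.  The per-class, per-year mean-BAI table is
#'   attached as attribute `"class_means"`.
#' @export
age_class_isolation <- function(bai_list, class_centers = seq(10, 120, 10),
                                half_width = 2.5, weighted = FALSE) {
  stopifnot(all(vapply(bai_list, inherits, TRUE, "bai_series")))
  long <- do.call(rbind, lapply(bai_list, function(b) {
    data.frame(tree = b$series_id, year = b$years, age = .bai_ages(b),
               bai = b$bai)
  }))

  rows <- list(); means <- list()
  for (ctr in class_centers) {
    d <- long[long$age >= ctr - half_width & long$age < ctr + half_width, ]
    if (nrow(d) == 0L) next
    m <- stats::aggregate(bai ~ year, data = d, FUN = mean)
    m$n_trees <- stats::aggregate(bai ~ year, data = d, FUN = length)$bai
    m$class_center <- ctr
    means[[as.character(ctr)]] <- m
    if (length(unique(d$year)) < 3L || nrow(d) < 3L) {
      warning("age class ", ctr, " excluded: fewer than 3 calendar years")
      next
    }
    if (length(unique(d$tree)) < 2L) {
      # with one tree, cambial age and calendar year are perfectly
      # confounded inside the window: no trend is identifiable
      warning("age class ", ctr, " excluded: only one tree contributes")
      next
    }
    fit <- if (weighted) stats::lm(bai ~ year, data = m, weights = m$n_trees)
           else stats::lm(bai ~ year, data = m)
    s <- summary(fit)
    rows[[as.character(ctr)]] <- data.frame(
      class_center = ctr,
      slope = stats::coef(fit)[["year"]],
      r_squared = s$r.squared,
      p_value = s$coefficients["year", "Pr(>|t|)"],
      n_years = nrow(m),
      n_tree_years = nrow(d))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class_center = numeric(0), slope = numeric(0),
               r_squared = numeric(0), p_value = numeric(0),
               n_years = integer(0), n_tree_years = integer(0))
  rownames(out) <- NULL
  structure(out, class = c("age_class_table", "data.frame"),
            class_means = if (length(means)) do.call(rbind, means) else NULL,
            half_width = half_width, weighted = weighted)
}

#' @export
print.age_class_table <- function(x, ...) {
  cat(sprintf("age-class isolation: %d class(es)\n", nrow(x)))
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Spatial covariate regression on age-detrended BAI
#'
#' Tests whether growth varies across the landscape.  Ontogeny is removed
#' by fitting the age-dependent smoother (initial stiffness 20 years, as
#' for ring widths) to the *pooled* age-aligned BAI of each species — the
#' species-average growth curve — and expressing every tree-year as a
#' relative residual from that shared curve (`bai / curve - 1`, a BAI
#' index).  The mean index per tree (its average proportional growth
#' deviation at equal age) is then regressed by OLS on a named distance
#' covariate.  Detrending against a shared curve, rather than per tree,
#' preserves the between-tree level differences that a spatial gradient
#' would create; the relative scale keeps large old trees from dominating
#' the fit.
#'
#' @param bai_list List of [widths_to_bai()] results carrying
#'   `distance_covariates`.
#' @param covariate_name Name of the distance covariate (meters).
#' @param initial_stiffness Stiffness for the shared age-curve fit
#'   (default 20).
#' @return An object of class `"spatial_regression"`: list with `slope`,
#'   `r_squared`, `p_value`, `n`, `covariate_name`, and the per-tree table
#'   `trees` (`tree`, `species`, `covariate`, `mean_residual`).  Trees
#'   missing the covariate are dropped with a warning; >= 5 must remain,
#'   and the covariate must vary.
#' @export
spatial_regression <- function(bai_list, covariate_name,
                               initial_stiffness = 20) {
  stopifnot(all(vapply(bai_list, inherits, TRUE, "bai_series")))
  sp_of <- vapply(bai_list, function(b)
    if (is.na(b$species_code)) "all" else b$species_code, "")
  # species-average BAI-at-age curve from the pooled tree-years
  curve_of <- list()
  for (sp in unique(sp_of)) {
    grp <- bai_list[sp_of == sp]
    ages <- unlist(lapply(grp, .bai_ages))
    bais <- unlist(lapply(grp, `[[`, "bai"))
    mean_by_age <- tapply(bais, ages, mean)
    a <- as.numeric(names(mean_by_age))
    fit <- age_dependent_spline(as.numeric(mean_by_age), a,
                                initial_stiffness)
    curve_of[[sp]] <- stats::approxfun(a, fit, rule = 2)
  }
  rows <- lapply(seq_along(bai_list), function(i) {
    b <- bai_list[[i]]
    if (!covariate_name %in% names(b$distance_covariates)) return(NULL)
    cv <- b$distance_covariates[[covariate_name]]
    if (is.na(cv)) return(NULL)
    expected <- curve_of[[sp_of[i]]](.bai_ages(b))
    # relative deviation from the species age curve: comparable across
    # tree sizes, so one large old tree cannot dominate the regression
    data.frame(tree = b$series_id, species = sp_of[i], covariate = cv,
               mean_residual = mean(b$bai / expected - 1))
  })
  dropped <- sum(vapply(rows, is.null, TRUE))
  if (dropped > 0L)
    warning(dropped, " tree(s) dropped: missing covariate '",
            covariate_name, "'")
  d <- do.call(rbind, rows)
  if (is.null(d) || nrow(d) < 5L)
    stop("need the covariate for at least 5 trees")
  if (stats::sd(d$covariate) == 0)
    stop("covariate '", covariate_name, "' has zero variance")
  fit <- stats::lm(mean_residual ~ covariate, data = d)
  s <- summary(fit)
  structure(
    list(covariate_name = covariate_name,
         slope = stats::coef(fit)[["covariate"]],
         r_squared = s$r.squared,
         p_value = s$coefficients["covariate", "Pr(>|t|)"],
         n = nrow(d), trees = d),
    class = "spatial_regression")
}

#' @export
print.spatial_regression <- function(x, ...) {
  cat(sprintf(
    "spatial regression on '%s' (n = %d trees)\n  slope %.4g (BAI index per m), R^2 = %.3f, p = %.3g\n",
    x$covariate_name, x$n, x$slope, x$r_squared, x$p_value))
  invisible(x)
}
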