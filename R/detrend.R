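#' Age-dependent growth-curve smoother
#'
#' Fits the ontogenetic growth curve used for ring-width standardization:
#' a smoother whose stiffness starts at `initial_stiffness` years and grows
#' with cambial age, so the juvenile growth surge is tracked closely while
#' mature growth is fitted ever more rigidly.  The stiffness at age `t` is
#' the 50% frequency-response wavelength `max(initial_stiffness, t)`;
#' internally this is realised as a tricube-weighted local quadratic
#' regression whose kernel half-width is half that wavelength (the standard
#' wavelength-to-kernel-scale conversion for smoothers of this class).
#' Local polynomials reproduce constant and linear series exactly.
#'
#' @param widths Numeric vector of ring widths (mm/year) or other response.
#' @param ages Strictly increasing numeric vector of cambial ages, same
#'   length as `widths`.
#' @param initial_stiffness Initial 50% frequency-response wavelength in
#'   years (default 20).
#' @param floor_epsilon Curve floor in response units (default 0.001 mm);
#'   fitted values below it are raised to it before the curve is used as a
#'   divisor.  Floored years are recorded in the `"floored"` attribute.
#' @return Numeric vector of fitted curve values, same length as `widths`,
#'   all `>= floor_epsilon`.
#' @examples
#' t <- 1:120
#' w <- 3 * exp(-t / 40) + 0.3
#' f <- age_dependent_spline(w, t)
#' max(abs(w / f - 1))  # small: pure ontogeny is recovered
#' @export
age_dependent_spline <- function(widths, ages, initial_stiffness = 20,
                                 floor_epsilon = 0.001) {
  n <- length(widths)
  if (n < 10L)
    stop("series shorter than 10 years: fit a series mean instead of an ",
         "age-dependent curve")
  stopifnot(length(ages) == n, is.numeric(widths), is.numeric(ages))
  if (anyNA(widths) || any(!is.finite(widths)))
    stop("non-finite widths")
  if (is.unsorted(ages, strictly = TRUE))
    stop("'ages' must be strictly increasing")
  stopifnot(initial_stiffness > 0)

  fit <- numeric(n)
  for (i in seq_len(n)) {
    h <- max(initial_stiffness, ages[i]) / 2
    d <- (ages - ages[i]) / h
    wt <- (1 - abs(d)^3)^3
    wt[abs(d) >= 1] <- 0
    use <- wt > 0
    x <- ages[use] - ages[i]
    if (sum(use) >= 4L && length(unique(x)) >= 3L) {
      X <- cbind(1, x, x^2)
      fit[i] <- lm.wfit(X, widths[use], wt[use])$coefficients[1L]
    } else {
      fit[i] <- sum(wt[use] * widths[use]) / sum(wt[use])
    }
  }
  if (anyNA(fit)) stop("smoother produced non-finite fitted values")
  floored <- which(fit < floor_epsilon)
  fit[floored] <- floor_epsilon
  attr(fit, "floored") <- floored
  fit
}

#' Autoregressive prewhitening of a ring-width index series
#'
#' Removes the persistence in an RWI series by fitting an AR(p) model with
#' the order chosen by AIC over 0..`p_max` (Yule-Walker estimation) and
#' keeping the innovations.  Residuals are re-centered to mean 1 so they
#' remain interpretable as a growth index; the first `order` years, which
#' have no innovation, are `NA`.
#'
#' @param rwi Numeric vector, length >= 20, finite, non-constant.
#' @param p_max Maximum AR order considered (default 10).
#' @return List with `residual_rwi` (same length as `rwi`, leading `NA`s),
#'   `ar_order` (selected order) and `ar_coefficients`.
#' @export
ar_prewhiten <- function(rwi, p_max = 10) {
  if (length(rwi) < 20L) stop("need >= 20 values to prewhiten")
  if (anyNA(rwi) || any(!is.finite(rwi))) stop("non-finite values in 'rwi'")
  if (stats::var(rwi) == 0) stop("constant series: zero variance")
  f <- stats::ar(rwi, aic = TRUE, order.max = p_max, method = "yule-walker")
  res <- if (f$order == 0L) rwi - mean(rwi) else as.numeric(f$resid)
  res <- res - mean(res, na.rm = TRUE) + 1
  list(residual_rwi = res, ar_order = f$order,
       ar_coefficients = as.numeric(f$ar))
}

#' Detrend one ring-width series
#'
#' Standardizes a series by the ratio method: an age-dependent growth curve
#' is fitted with [age_dependent_spline()], the ring width index (RWI) is
#' the ratio of measured width to fitted curve, and the prewhitened
#' (residual) index is obtained with [ar_prewhiten()].  Absent rings
#' (width 0) get RWI 0, not `NA`.
#'
#' @param rs A [ring_series()].
#' @param initial_stiffness,floor_epsilon Passed to [age_dependent_spline()].
#' @param p_max Passed to [ar_prewhiten()].
#' @return An object of class `"detrended_series"`: a list with
#'   `series_id`, `species_code`, `years`, `widths`, `fitted_curve`, `rwi`,
#'   `residual_rwi`, `ar_order`.
#' @export
detrend_series <- function(rs, initial_stiffness = 20, floor_epsilon = 0.001,
                           p_max = 10) {
  stopifnot(inherits(rs, "ring_series"))
  ages <- cambial_ages(rs)
  curve <- age_dependent_spline(rs$widths, ages, initial_stiffness,
                                floor_epsilon)
  rwi <- as.vector(rs$widths / curve)
  pw <- if (length(rwi) >= 20L && stats::var(rwi) > 0) {
    ar_prewhiten(rwi, p_max)
  } else {
    list(residual_rwi = rwi - mean(rwi) + 1, ar_order = 0L,
         ar_coefficients = numeric(0))
  }
  structure(
    list(series_id = rs$series_id, species_code = rs$species_code,
         years = ring_years(rs), widths = rs$widths,
         fitted_curve = as.numeric(curve), rwi = rwi,
         residual_rwi = pw$residual_rwi, ar_order = pw$ar_order,
         ar_coefficients = pw$ar_coefficients),
    class = "detrended_series")
}

#' @export
print.detrended_series <- function(x, ...) {
  cat(sprintf(
    "detrended_series '%s': %d yr, AR order %d, mean RWI %.3f\n",
    x$series_id, length(x$years), x$ar_order, mean(x$rwi)))
  invisible(x)
}
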