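#' Tukey biweight robust mean
#'
#' Iteratively reweighted biweight location estimate with tuning constant
#' `c` (default 9) on the MAD scale, iterated to an absolute change below
#' `tol`.  For a single value it returns that value; when the MAD is zero
#' (a majority of identical values) it returns the median, which is the
#' limit of the estimator as the scale collapses.
#'
#' @param x Numeric vector with at least one finite value.
#' @param c Tuning constant in MAD units (default 9).
#' @param tol Convergence tolerance on the location (default 1e-8).
#' @param max_iter Iteration cap (default 100).
#' @return The biweight location estimate (numeric scalar).
#' @examples
#' biweight_mean(c(1, 2, 3))       # 2, symmetric sample
#' biweight_mean(c(1, 1, 1, 50))   # ~1, the outlier is discounted
#' @export
biweight_mean <- function(x, c = 9, tol = 1e-8, max_iter = 100L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no finite values")
  if (length(x) == 1L) return(x)
  m <- stats::median(x)
  s <- stats::median(abs(x - m))
  if (s == 0) return(m)
  for (it in seq_len(max_iter)) {
    u <- (x - m) / (c * s)
    w <- (1 - u^2)^2
    w[abs(u) >= 1] <- 0
    m_new <- sum(w * x) / sum(w)
    if (abs(m_new - m) < tol) return(m_new)
    m <- m_new
  }
  m
}

#' Build a species-level ring-width chronology
#'
#' Averages detrended series year by year with the Tukey biweight mean and
#' records the sample depth.  The default `"residual"` flavor averages the
#' prewhitened indices; `"standard"` averages the raw RWI.
#'
#' @param detrended_list List of [detrend_series()] results (>= 2 series
#'   with at least one common year).
#' @param flavor `"residual"` (prewhitened, default) or `"standard"`.
#' @param biweight_c Biweight tuning constant, see [biweight_mean()].
#' @return An object of class `"chronology"`: a data.frame with columns
#'   `year`, `rwi`, `depth`, plus attributes `species_code` and `flavor`.
#'   Years with depth < 2 carry only one tree's signal and are flagged in
#'   the `"shallow_years"` attribute.
#' @export
build_chronology <- function(detrended_list,
                             flavor = c("residual", "standard"),
                             biweight_c = 9) {
  flavor <- match.arg(flavor)
  if (length(detrended_list) < 2L)
    stop("need at least 2 series to build a chronology")
  stopifnot(all(vapply(detrended_list, inherits, TRUE, "detrended_series")))

  field <- if (flavor == "residual") "residual_rwi" else "rwi"
  yrs <- sort(unique(unlist(lapply(detrended_list, `[[`, "years"))))
  vals <- matrix(NA_real_, length(yrs), length(detrended_list))
  for (j in seq_along(detrended_list)) {
    d <- detrended_list[[j]]
    vals[match(d$years, yrs), j] <- d[[field]]
  }
  depth <- rowSums(!is.na(vals))
  if (!any(depth >= 2L))
    stop("series share no common years")
  keep <- depth >= 1L
  yrs <- yrs[keep]; vals <- vals[keep, , drop = FALSE]; depth <- depth[keep]

  rwi <- vapply(seq_along(yrs), function(i) {
    biweight_mean(vals[i, ][!is.na(vals[i, ])], c = biweight_c)
  }, numeric(1))

  sp <- unique(stats::na.omit(vapply(detrended_list, `[[`, "",
                                     "species_code")))
  out <- data.frame(year = yrs, rwi = rwi, depth = as.integer(depth))
  structure(out,
            class = c("chronology", "data.frame"),
            species_code = if (length(sp) == 1L) sp else NA_character_,
            flavor = flavor,
            shallow_years = yrs[depth < 2L])
}

#' @export
print.chronology <- function(x, ...) {
  cat(sprintf("%s chronology%s: %d yr (%d-%d), max depth %d\n",
              attr(x, "flavor"),
              if (is.na(attr(x, "species_code"))) ""
              else paste0(" [", attr(x, "species_code"), "]"),
              nrow(x), min(x$year), max(x$year), max(x$depth)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' @export
summary.chronology <- function(object, ...) {
  cat(sprintf(
    "chronology (%s flavor): %d years %d-%d\n  mean RWI %.3f, sd %.3f\n  depth: min %d, median %d, max %d; %d year(s) with depth < 2\n",
    attr(object, "flavor"), nrow(object), min(object$year), max(object$year),
    mean(object$rwi), stats::sd(object$rwi),
    min(object$depth), stats::median(object$depth), max(object$depth),
    length(attr(object, "shallow_years"))))
  invisible(object)
}

#' Plot a chronology with its sample depth
#' @param x A `chronology`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.chronology <- function(x, ...) {
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(x$year, x$rwi, type = "l", xlab = "Year",
                 ylab = "Ring width index", ...)
  graphics::abline(h = 1, lty = 3)
  graphics::par(new = TRUE)
  graphics::plot(x$year, x$depth, type = "s", col = "grey60", axes = FALSE,
                 xlab = "", ylab = "", ylim = c(0, max(x$depth) * 3))
  graphics::axis(4, col = "grey60", col.axis = "grey60")
  graphics::mtext("Sample depth", 4, line = 2.5, col = "grey60")
  invisible(x)
}
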