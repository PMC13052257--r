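#' Mean sensitivity of a ring series
#'
#' Mean sensitivity (MS) is the average relative year-to-year change,
#' `MS = mean over t of |2 (x_t - x_{t-1}) / (x_t + x_{t-1})|`, bounded by
#' 0 (no change) and 2 (alternation with zeros).  Year pairs whose sum is
#' zero (two consecutive absent rings) are undefined and skipped with a
#' warning; the average is then over the remaining pairs.
#'
#' @param x Numeric series of length >= 2, not all zero.  Conventionally a
#'   detrended index, though raw widths are accepted.
#' @return MS in \[0, 2\].
#' @seealso [classify_sensitivity()]
#' @export
mean_sensitivity <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values")
  if (all(x == 0)) stop("all-zero series")
  a <- x[-1]; b <- x[-length(x)]
  s <- a + b
  bad <- s == 0
  if (any(bad)) {
    warning(sum(bad), " consecutive pair(s) summing to 0 skipped")
    a <- a[!bad]; b <- b[!bad]; s <- s[!bad]
  }
  mean(abs(2 * (a - b) / s))
}

#' Classify a mean-sensitivity value
#'
#' MS below 0.2 marks low interannual variability, 0.2-0.6 the ideal range
#' for climate reconstruction, and above 0.6 excessive sensitivity that
#' hampers reliable crossdating.
#'
#' @param ms Mean sensitivity value(s).
#' @return Character vector: `"low"`, `"ideal"` or `"excessive"`.
#' @export
classify_sensitivity <- function(ms) {
  ifelse(ms < 0.2, "low", ifelse(ms <= 0.6, "ideal", "excessive"))
}

#' Series intercorrelation (rbar)
#'
#' For each series, the Pearson correlation with the master chronology built
#' from all *other* series (leave-one-out biweight mean) over their common
#' years; `rbar` is the arithmetic mean of those correlations.  Using the
#' leave-one-out master avoids the self-correlation inflation of comparing
#' a series against a mean that contains it.
#'
#' @param detrended_list List of [detrend_series()] results (>= 2).
#' @param use_residual Correlate prewhitened indices (`TRUE`) or plain RWI
#'   (default `FALSE`, matching crossdating practice).
#' @param min_overlap Minimum common years required per series (default 10);
#'   series with less overlap are skipped with a warning.
#' @return `rbar`, with per-series correlations in the `"per_series"`
#'   attribute.
#' @export
series_intercorrelation <- function(detrended_list, use_residual = FALSE,
                                    min_overlap = 10L) {
  if (length(detrended_list) < 2L) stop("need at least 2 series")
  field <- if (use_residual) "residual_rwi" else "rwi"
  yrs <- sort(unique(unlist(lapply(detrended_list, `[[`, "years"))))
  vals <- matrix(NA_real_, length(yrs), length(detrended_list))
  for (j in seq_along(detrended_list))
    vals[match(detrended_list[[j]]$years, yrs), j] <-
      detrended_list[[j]][[field]]

  r <- rep(NA_real_, ncol(vals))
  names(r) <- vapply(detrended_list, `[[`, "", "series_id")
  for (j in seq_len(ncol(vals))) {
    others <- vals[, -j, drop = FALSE]
    master <- vapply(seq_along(yrs), function(i) {
      v <- others[i, ][!is.na(others[i, ])]
      if (length(v) == 0L) NA_real_ else biweight_mean(v)
    }, numeric(1))
    ok <- !is.na(vals[, j]) & !is.na(master)
    if (sum(ok) < min_overlap) {
      warning("series '", names(r)[j], "' skipped: only ", sum(ok),
              " year(s) of overlap with the leave-one-out master")
      next
    }
    if (stats::sd(vals[ok, j]) == 0 || stats::sd(master[ok]) == 0) {
      warning("series '", names(r)[j], "' skipped: zero variance overlap")
      next
    }
    r[j] <- stats::cor(vals[ok, j], master[ok])
  }
  if (all(is.na(r))) stop("no series had sufficient overlap")
  structure(mean(r, na.rm = TRUE), per_series = r)
}

#' Expressed population signal (EPS)
#'
#' `EPS = n * rbar / (n * rbar + (1 - rbar))`: the fraction of the
#' hypothetical population signal captured by a chronology of `n` series
#' with mean interseries correlation `rbar`.
#'
#' @param rbar Mean interseries correlation, in (-1, 1\].
#' @param n_series Number of series (>= 1).
#' @return EPS in \[0, 1\] (clipped, with a warning, when `rbar <= 0`).
#' @examples
#' eps(0.3, 20)  # 6 / 6.7
#' @export
eps <- function(rbar, n_series) {
  stopifnot(all(n_series >= 1), all(rbar > -1), all(rbar <= 1))
  e <- n_series * rbar / (n_series * rbar + (1 - rbar))
  if (any(rbar <= 0)) {
    warning("rbar <= 0: EPS clipped to [0, 1]")
    e <- pmin(1, pmax(0, e))
  }
  e
}

#' Quality summary of a set of detrended series
#'
#' Computes the crossdating/chronology quality statistics as one bundle:
#' per-series mean sensitivity (and its average), the series
#' intercorrelation `rbar`, and the expressed population signal.
#'
#' @inheritParams series_intercorrelation
#' @return An object of class `"chronology_quality"`: list with
#'   `mean_sensitivity` (average across series), `ms_per_series`, `rbar`,
#'   `rbar_per_series`, `eps`, `n_series`, `sensitivity_class`.
#' @export
chronology_quality <- function(detrended_list, use_residual = FALSE,
                               min_overlap = 10L) {
  ms <- vapply(detrended_list, function(d) {
    mean_sensitivity(if (use_residual) d$residual_rwi[
      !is.na(d$residual_rwi)] else d$rwi)
  }, numeric(1))
  names(ms) <- vapply(detrended_list, `[[`, "", "series_id")
  rbar <- series_intercorrelation(detrended_list, use_residual, min_overlap)
  n <- length(detrended_list)
  structure(
    list(mean_sensitivity = mean(ms), ms_per_series = ms,
         rbar = as.numeric(rbar), rbar_per_series = attr(rbar, "per_series"),
         eps = eps(as.numeric(rbar), n), n_series = n,
         sensitivity_class = classify_sensitivity(mean(ms))),
    class = "chronology_quality")
}

#' @export
print.chronology_quality <- function(x, ...) {
  cat(sprintf(
    "chronology quality (n = %d series)\n  mean sensitivity: %.3f (%s)\n  series intercorrelation rbar: %.3f\n  expressed population signal: %.3f\n",
    x$n_series, x$mean_sensitivity, x$sensitivity_class, x$rbar, x$eps))
  invisible(x)
}
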