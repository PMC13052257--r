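#' Construct a dated ring-width series
#'
#' A `ring_series` holds one tree's (or core's) calendar-dated annual ring
#' widths plus the metadata the downstream analyses need: the species code,
#' an estimate of the number of rings missed between the innermost measured
#' ring and the pith, and optional landscape distance covariates.
#'
#' Widths are in mm/year.  A width of exactly 0 encodes a locally absent
#' ring: the year is dated but no wood was laid down on the measured radius.
#' Keeping absent rings as zeros (rather than `NA`) keeps the cumulative
#' radius, and hence basal area increment, well defined.
#'
#' The cambial age of the ring formed in calendar year `y` is
#' `y - first_year + 1 + pith_offset`.
#'
#' @param series_id Character scalar identifying the series (<= 8 characters
#'   for round-tripping through the Tucson format).
#' @param widths Numeric vector of ring widths, mm/year, one per consecutive
#'   calendar year.  All values must be finite and >= 0.
#' @param first_year Calendar year (CE, integer) of the innermost ring.
#' @param species_code Optional species code, e.g. `"TAAS"`, `"TADI"`,
#'   `"PIEL"`.
#' @param pith_offset Estimated number of rings missed to the pith
#'   (integer >= 0; default 0).
#' @param distance_covariates Optional named numeric vector of distances in
#'   meters (e.g. `c(dist_to_road = 1200, dist_to_dome = 35)`).
#' @return An object of class `"ring_series"`.
#' @examples
#' rs <- ring_series("TST01", c(1.2, 0.8, 1.5), 1990, species_code = "TADI")
#' ring_years(rs)
#' cambial_ages(rs)
#' @export
ring_series <- function(series_id, widths, first_year, species_code = NA_character_,
                        pith_offset = 0L, distance_covariates = NULL) {
  stopifnot(is.character(series_id), length(series_id) == 1L, nzchar(series_id))
  if (!is.numeric(widths) || length(widths) == 0L)
    stop("'widths' must be a nonempty numeric vector")
  if (anyNA(widths) || any(!is.finite(widths)))
    stop("'widths' must be finite (use 0 for locally absent rings)")
  if (any(widths < 0))
    stop("ring widths must be >= 0 (0 encodes an absent ring)")
  first_year <- as.integer(first_year)
  stopifnot(length(first_year) == 1L, !is.na(first_year))
  pith_offset <- as.integer(pith_offset)
  if (is.na(pith_offset) || pith_offset < 0L)
    stop("'pith_offset' must be a non-negative integer")
  if (!is.null(distance_covariates)) {
    if (!is.numeric(distance_covariates) || is.null(names(distance_covariates)))
      stop("'distance_covariates' must be a named numeric vector (meters)")
  }
  structure(
    list(series_id = series_id,
         species_code = species_code,
         first_year = first_year,
         widths = as.numeric(widths),
         pith_offset = pith_offset,
         distance_covariates = distance_covariates),
    class = "ring_series")
}

#' Calendar years covered by a ring series
#' @param x A `ring_series`.
#' @return Integer vector of calendar years, one per ring.
#' @export
ring_years <- function(x) {
  stopifnot(inherits(x, "ring_series"))
  seq.int(x$first_year, length.out = length(x$widths))
}

#' Cambial ages of the rings in a series
#'
#' Age 1 + `pith_offset` is assigned to the innermost measured ring.
#' @param x A `ring_series`.
#' @return Integer vector of cambial ages (years since pith), one per ring.
#' @export
cambial_ages <- function(x) {
  stopifnot(inherits(x, "ring_series"))
  seq_along(x$widths) + x$pith_offset
}

#' @export
print.ring_series <- function(x, ...) {
  yrs <- ring_years(x)
  cat(sprintf("ring_series '%s' (%s): %d rings, %d-%d, mean width %.3f mm/yr",
              x$series_id,
              if (is.na(x$species_code)) "?" else x$species_code,
              length(x$widths), yrs[1L], yrs[length(yrs)],
              mean(x$widths)))
  if (x$pith_offset > 0L) cat(sprintf(", pith offset %d yr", x$pith_offset))
  if (sum(x$widths == 0) > 0L)
    cat(sprintf(", %d absent ring(s)", sum(x$widths == 0)))
  cat("\n")
  invisible(x)
}

#' @export
length.ring_series <- function(x) length(x$widths)
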