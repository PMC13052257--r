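#' Known monthly environment variables and their units
#' @keywords internal
.env_units <- c(ppt = "mm", tmin = "degC", tmean = "degC", tmax = "degC",
                vpdmin = "hPa", vpdmax = "hPa", water_depth = "cm")

#' Construct a monthly environment object
#'
#' A `monthly_env` is a year-by-12 matrix of one monthly variable (PRISM-like
#' climate or EDEN-gauge-like water depth).  Missing months are `NA`; a year
#' is present iff at least one of its months is non-missing.
#'
#' @param variable One of `ppt`, `tmin`, `tmean`, `tmax`, `vpdmin`, `vpdmax`,
#'   `water_depth`.
#' @param years Integer vector of calendar years (strictly increasing).
#' @param values Numeric matrix `length(years)` x 12, `NA` allowed.
#' @return An object of class `"monthly_env"`.
#' @export
monthly_env <- function(variable, years, values) {
  variable <- match.arg(variable, names(.env_units))
  years <- as.integer(years)
  stopifnot(is.matrix(values), ncol(values) == 12L,
            nrow(values) == length(years))
  if (is.unsorted(years, strictly = TRUE))
    stop("'years' must be strictly increasing")
  # drop all-missing years so presence means >= 1 non-missing month
  present <- rowSums(!is.na(values)) > 0L
  years <- years[present]
  values <- values[present, , drop = FALSE]
  dimnames(values) <- list(years, month.abb)
  structure(list(variable = variable, units = .env_units[[variable]],
                 years = years, values = values),
            class = "monthly_env")
}

#' @export
print.monthly_env <- function(x, ...) {
  cat(sprintf("monthly_env '%s' [%s]: %d year(s) %d-%d, %d missing cell(s)\n",
              x$variable, x$units, length(x$years),
              min(x$years), max(x$years), sum(is.na(x$values))))
  invisible(x)
}

#' Read a long-form monthly table (year, month, value)
#'
#' @param path CSV file with columns `year`, `month`, `value`.
#' @param variable_name Which variable the file holds (sets the units); see
#'   [monthly_env()].
#' @return A [monthly_env()] object.
#' @export
read_monthly_table <- function(path, variable_name) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "month", "value")
  if (!all(need %in% names(d)))
    stop("expected columns year, month, value in ", path)
  if (!is.numeric(d$year) || !is.numeric(d$month))
    stop("non-numeric year or month in ", path)
  if (any(d$month < 1 | d$month > 12 | d$month != round(d$month)))
    stop("month outside 1-12 in ", path)
  if (!is.numeric(d$value))
    stop("non-numeric value column in ", path)
  key <- paste(d$year, d$month)
  if (anyDuplicated(key))
    stop("duplicate (year, month) rows in ", path, ": ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  yrs <- sort(unique(as.integer(d$year)))
  m <- matrix(NA_real_, length(yrs), 12L)
  m[cbind(match(d$year, yrs), as.integer(d$month))] <- d$value
  monthly_env(variable_name, yrs, m)
}

#' Write a monthly environment object as a long-form CSV
#' @param env A [monthly_env()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_monthly_table <- function(env, path) {
  stopifnot(inherits(env, "monthly_env"))
  idx <- which(!is.na(env$values), arr.ind = TRUE)
  d <- data.frame(year = env$years[idx[, 1L]], month = idx[, 2L],
                  value = env$values[idx])
  d <- d[order(d$year, d$month), ]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-ring carbon isotope sample table
#'
#' @param path CSV with columns `tree_id`, `year`, `cambial_age`, `d13c`
#'   (per-mil VPDB, bulk wood) and optionally `species_code`.
#' @return A data.frame with one row per tree x year.  Values outside the
#'   plausible wood range \[-35, -15\] per mil trigger a warning, not an error.
#' @export
read_isotope_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tree_id", "year", "cambial_age", "d13c")
  if (!all(need %in% names(d)))
    stop("expected columns tree_id, year, cambial_age, d13c in ", path)
  if (anyDuplicated(paste(d$tree_id, d$year)))
    stop("more than one sample per tree x year in ", path)
  if (any(d$d13c < -35 | d$d13c > -15, na.rm = TRUE))
    warning("d13c values outside the plausible wood range [-35, -15] per mil")
  d
}

#' Read per-tree spatial distance covariates
#'
#' @param path CSV with a `tree_id` column and one numeric column per named
#'   distance (meters), e.g. `dist_to_road`, `dist_to_dome`, `dist_to_edge`.
#' @return A data.frame keyed by `tree_id`.
#' @export
read_covariate_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"tree_id" %in% names(d)) stop("expected a tree_id column in ", path)
  if (anyDuplicated(d$tree_id)) stop("duplicate tree_id rows in ", path)
  d
}
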