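#' Read a Tucson (decadal) ring-width file
#'
#' Parses the classic decadal "Tucson" layout used by the ITRDB: each line
#' carries a series id, the calendar year of its first value, and up to ten
#' annual values; the final value of each series is an end marker that also
#' declares the measurement precision.  Both circulating dialects are
#' auto-detected per series: a `999` terminator means values are hundredths
#' of a millimeter, a `-9999` terminator thousandths.  The marker is only
#' recognised as the *last* value of a series, so a data value of 999
#' (9.99 mm) mid-series is kept as data.
#'
#' @param path Path to the `.rwl` file.
#' @return A list of [ring_series] objects, widths decoded to mm.
#' @seealso [write_rwl()]
#' @export
read_rwl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(list())

  ids <- character(length(lines))
  decades <- integer(length(lines))
  vals <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
    if (length(tok) < 3L)
      stop("malformed decade line ", lineno[i], ": expected id, year and values")
    yr <- suppressWarnings(as.integer(tok[2L]))
    v <- suppressWarnings(as.numeric(tok[-(1:2)]))
    if (is.na(yr) || anyNA(v))
      stop("malformed decade line ", lineno[i], ": non-numeric year or value")
    ids[i] <- tok[1L]
    decades[i] <- yr
    vals[[i]] <- v
  }

  # group consecutive lines per series; a re-appearing id is a duplicate
  runs <- rle(ids)
  if (anyDuplicated(runs$values))
    stop("overlapping duplicate series id(s): ",
         paste(unique(runs$values[duplicated(runs$values)]), collapse = ", "))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L

  out <- vector("list", length(runs$values))
  for (s in seq_along(runs$values)) {
    rows <- starts[s]:ends[s]
    first_year <- decades[rows[1L]]
    # contiguity: each later line must start where the previous left off
    expect <- first_year
    for (r in rows) {
      if (decades[r] != expect)
        stop("non-contiguous years for series '", ids[r], "' at line ",
             lineno[r], ": expected year ", expect, ", got ", decades[r])
      expect <- expect + length(vals[[r]])
    }
    raw <- unlist(vals[rows], use.names = FALSE)
    n <- length(raw)
    if (n < 2L)
      stop("series '", ids[rows[1L]], "' has no data before its end marker")
    term <- raw[n]
    scale <- if (term == 999) 0.01
             else if (term == -9999) 0.001
             else stop("series '", ids[rows[1L]],
                       "' does not end in a 999 or -9999 marker (got ", term, ")")
    widths <- raw[-n] * scale
    if (any(widths < 0))
      stop("negative ring width in series '", ids[rows[1L]], "'")
    out[[s]] <- ring_series(ids[rows[1L]], widths, first_year)
  }
  out
}

#' Write ring-width series in Tucson (decadal) format
#'
#' The inverse of [read_rwl()]: output is bit-stable for a fixed input and
#' round-trips through [read_rwl()] at the dialect's precision.
#'
#' @param series_list List of [ring_series] objects.
#' @param path Output path.
#' @param dialect Measurement precision: `"0.01"` writes hundredths of mm
#'   with a `999` terminator, `"0.001"` thousandths with `-9999`.
#' @return `path`, invisibly.
#' @export
write_rwl <- function(series_list, path, dialect = c("0.01", "0.001")) {
  dialect <- match.arg(dialect)
  scale <- if (dialect == "0.01") 100 else 1000
  term <- if (dialect == "0.01") "999" else "-9999"
  con <- file(path, "w")
  on.exit(close(con))
  for (rs in series_list) {
    stopifnot(inherits(rs, "ring_series"))
    if (any(rs$widths < 0)) stop("negative ring width in '", rs$series_id, "'")
    if (grepl("[[:space:]]", rs$series_id))
      stop("series id '", rs$series_id, "' contains whitespace")
    iv <- as.integer(round(rs$widths * scale))
    if (any(nchar(as.character(iv)) > 5L))
      stop("width overflow for 6-character field in '", rs$series_id,
           "' at ", dialect, " mm precision")
    yrs <- ring_years(rs)
    vals <- c(as.character(iv), term)
    # year label of the terminator slot is the year after the last ring
    vyrs <- c(yrs, yrs[length(yrs)] + 1L)
    id <- formatC(substr(rs$series_id, 1L, 8L), width = -8L)
    i <- 1L
    while (i <= length(vals)) {
      decade_end <- (vyrs[i] %/% 10L) * 10L + 9L
      j <- max(which(vyrs <= decade_end))
      writeLines(paste0(id, formatC(vyrs[i], width = 5L),
                        paste0(formatC(vals[i:j], width = 6L), collapse = "")),
                 con)
      i <- j + 1L
    }
  }
  invisible(path)
}
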