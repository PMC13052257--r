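#' Monthly and seasonal predictor matrix for climate-growth analysis
#'
#' Expands one monthly environment variable into the 28 candidate windows a
#' correlation-function analysis screens: the 12 months of the previous
#' year, the 12 months of the current (growth) year, and four seasonal
#' aggregates — winter (Jan-Mar) and summer (Jun-Sep) of each year.
#' Seasonal values are sums for precipitation and means for temperature,
#' VPD and water depth.
#'
#' @param env A [monthly_env()] object; must cover `min(target_years) - 1`
#'   through `max(target_years)` at least partially.
#' @param target_years Integer vector of growth years the predictors are
#'   aligned to.
#' @param max_missing Maximum tolerated fraction of missing entries per
#'   window column (default 0.2); windows above it are dropped with a
#'   warning.
#' @return Numeric matrix, rows = `target_years`, one column per retained
#'   window, named `"<variable>.prev.jan"`, `"<variable>.curr.summer"`, etc.
#' @export
monthly_predictors <- function(env, target_years, max_missing = 0.2) {
  stopifnot(inherits(env, "monthly_env"))
  target_years <- as.integer(target_years)
  get_year <- function(y) {
    i <- match(y, env$years)
    if (is.na(i)) rep(NA_real_, 12L) else env$values[i, ]
  }
  curr <- t(vapply(target_years, get_year, numeric(12)))
  prev <- t(vapply(target_years - 1L, get_year, numeric(12)))

  seas <- function(m, months) {
    block <- m[, months, drop = FALSE]
    miss <- rowSums(is.na(block)) > 0L
    agg <- if (env$variable == "ppt") rowSums(block) else rowMeans(block)
    agg[miss] <- NA_real_  # a season with any missing month is missing
    agg
  }
  mo <- tolower(month.abb)
  out <- cbind(prev, curr,
               seas(prev, 1:3), seas(prev, 6:9),
               seas(curr, 1:3), seas(curr, 6:9))
  colnames(out) <- paste0(env$variable, ".",
                          c(paste0("prev.", mo), paste0("curr.", mo),
                            "prev.winter", "prev.summer",
                            "curr.winter", "curr.summer"))
  rownames(out) <- target_years

  frac_na <- colMeans(is.na(out))
  drop <- frac_na > max_missing
  if (any(drop)) {
    warning("dropped ", sum(drop), " window(s) with > ",
            round(100 * max_missing), "% missing months: ",
            paste(colnames(out)[drop], collapse = ", "))
    out <- out[, !drop, drop = FALSE]
  }
  out
}

# Stationary-bootstrap (Politis-Romano) index matrix: geometric block
# lengths with mean L, circular wrap, one row per bootstrap resample.
# Consumes the current RNG stream.
.stationary_boot_indices <- function(n, n_boot, mean_block) {
  p <- 1 / mean_block
  idx <- matrix(0L, n_boot, n)
  idx[, 1L] <- sample.int(n, n_boot, replace = TRUE)
  for (t in 2:n) {
    restart <- stats::runif(n_boot) < p
    nxt <- idx[, t - 1L] %% n + 1L
    new <- sample.int(n, n_boot, replace = TRUE)
    idx[, t] <- ifelse(restart, new, nxt)
  }
  idx
}

#' Correlation with stationary-bootstrap confidence interval
#'
#' Pearson correlation between a chronology and one climate window, with a
#' 95% percentile confidence interval from the stationary bootstrap of
#' Politis and Romano: years are resampled jointly (paired blocks, so the
#' cross-correlation is preserved within blocks) with geometric block
#' lengths of mean `ceiling(n^(1/3))`.  A window is called significant when
#' the interval excludes zero.  No multiplicity correction is applied
#' across windows.
#'
#' @param x,y Paired numeric vectors (chronology values and one predictor
#'   column); pairs with missing values are dropped, >= 20 must remain.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so a caller can seed once for a whole table).
#' @param conf Confidence level (default 0.95).
#' @return One-row data.frame: `r`, `ci_low`, `ci_high`, `significant`, `n`.
#' @export
bootstrap_correlation <- function(x, y, n_boot = 1000L, seed = NULL,
                                  conf = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 20L) stop("need >= 20 paired years, got ", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the inputs")
  if (!is.null(seed)) set.seed(seed)

  r <- stats::cor(x, y)
  idx <- .stationary_boot_indices(n, n_boot, ceiling(n^(1 / 3)))
  X <- matrix(x[idx], n_boot, n)
  Y <- matrix(y[idx], n_boot, n)
  mx <- rowMeans(X); my <- rowMeans(Y)
  sx <- rowMeans(X * X) - mx^2
  sy <- rowMeans(Y * Y) - my^2
  rb <- (rowMeans(X * Y) - mx * my) / sqrt(sx * sy)
  rb <- rb[is.finite(rb)]
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(rb, c(alpha, 1 - alpha), names = FALSE)
  data.frame(r = r, ci_low = ci[1L], ci_high = ci[2L],
             significant = ci[1L] > 0 || ci[2L] < 0, n = n)
}

#' Correlation function of a chronology against monthly environments
#'
#' Screens every monthly and seasonal window of every supplied environment
#' variable (see [monthly_predictors()]) against the chronology with
#' [bootstrap_correlation()].  Constant windows are skipped with a warning.
#' The whole table is deterministic under a fixed `seed`.
#'
#' @param chron A [build_chronology()] result (residual flavor is the
#'   conventional choice).
#' @param env_list A [monthly_env()] or list of them.
#' @param n_boot Bootstrap resamples per window (default 1000).
#' @param seed Integer seed for the whole table (default `NULL`).
#' @param min_years Minimum paired years per window (default 20); windows
#'   with fewer are skipped with a warning.
#' @return An object of classes `"correlation_function"` and `"data.frame"`
#'   with columns `variable`, `window`, `r`, `ci_low`, `ci_high`,
#'   `significant`, `n`.  Note the absence of any multiple-testing
#'   correction: with 28 windows per variable, some isolated
#'   "significant" cells are expected by chance.
#' @export
correlation_function <- function(chron, env_list, n_boot = 1000L,
                                 seed = NULL, min_years = 20L) {
  stopifnot(inherits(chron, "chronology"))
  if (inherits(env_list, "monthly_env")) env_list <- list(env_list)
  if (!is.null(seed)) set.seed(seed)

  rows <- list()
  for (env in env_list) {
    # analyse the chronology/environment overlap: years whose previous and
    # current calendar year both fall inside the environment's record
    ys <- chron$year[chron$year >= min(env$years) + 1L &
                       chron$year <= max(env$years)]
    if (length(ys) < min_years) {
      warning("variable ", env$variable, " skipped: only ", length(ys),
              " year(s) of overlap with the chronology")
      next
    }
    rwi <- chron$rwi[match(ys, chron$year)]
    pred <- monthly_predictors(env, ys)
    for (cn in colnames(pred)) {
      p <- pred[, cn]
      ok <- is.finite(rwi) & is.finite(p)
      if (sum(ok) < min_years) {
        warning("window ", cn, " skipped: only ", sum(ok), " paired year(s)")
        next
      }
      if (stats::sd(p[ok]) == 0) {
        warning("window ", cn, " skipped: constant predictor")
        next
      }
      b <- bootstrap_correlation(rwi[ok], p[ok], n_boot = n_boot)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(variable = env$variable,
                   window = sub(paste0("^", env$variable, "\\."), "", cn)),
        b)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variable = character(0), window = character(0),
               r = numeric(0), ci_low = numeric(0), ci_high = numeric(0),
               significant = logical(0), n = integer(0))
  rownames(out) <- NULL
  structure(out, class = c("correlation_function", "data.frame"),
            n_boot = n_boot)
}

#' @export
print.correlation_function <- function(x, ...) {
  cat(sprintf("correlation function: %d window(s), %d significant (no multiplicity correction)\n",
              nrow(x), sum(x$significant)))
  if (nrow(x)) {
    sig <- x[x$significant, ]
    if (nrow(sig)) {
      cat("significant windows:\n")
      print.data.frame(sig, digits = 3, row.names = FALSE)
    }
  }
  invisible(x)
}

#' Plot a correlation function as a bar panel per variable
#' @param x A `correlation_function`.
#' @param ... Unused.
#' @export
plot.correlation_function <- function(x, ...) {
  vars <- unique(x$variable)
  op <- graphics::par(mfrow = c(length(vars), 1), mar = c(6, 4, 2, 1))
  on.exit(graphics::par(op))
  for (v in vars) {
    d <- x[x$variable == v, ]
    bp <- graphics::barplot(d$r, names.arg = d$window, las = 2,
                            cex.names = 0.6, ylim = range(0, d$ci_low,
                                                          d$ci_high),
                            col = ifelse(d$significant, "steelblue",
                                         "grey80"),
                            main = v, ylab = "r")
    graphics::arrows(bp, d$ci_low, bp, d$ci_high, angle = 90, code = 3,
                     length = 0.02)
    graphics::abline(h = 0)
  }
  invisible(x)
}
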