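# Shared test scaffolding: small deterministic builders used across files.

# a ring_series with lognormal noise around a negative-exponential curve
make_noisy_series <- function(id = "S1", n = 120, first_year = 1900,
                              sigma = 0.3, species = "TADI") {
  t <- seq_len(n)
  w <- (3 * exp(-t / 40) + 0.3) *
    exp(stats::rnorm(n, 0, sigma) - sigma^2 / 2)
  ring_series(id, w, first_year, species_code = species)
}

# a single-species config with the isotope census disabled, for cheap
# simulations that do not exercise the isotope stage
small_config <- function(seed, n = 20L, species = "TADI", ...) {
  n_trees <- stats::setNames(as.integer(n), species)
  sim_config(seed = seed, n_trees = n_trees,
             iwue = list(baseline = 85, age_slope = -0.1, year_trend = 0.3,
                         trend_start = 1930L, temp_effect = 2, noise_sd = 3,
                         n_isotope_trees = 0L, census = NULL),
             ...)
}

# write Tucson-format lines to a temp file and return the path
write_rwl_lines <- function(lines) {
  f <- tempfile(fileext = ".rwl")
  writeLines(lines, f)
  f
}

# independent biweight oracle: root of the psi-function estimating equation
biweight_root_oracle <- function(x, c = 9) {
  s <- stats::median(abs(x - stats::median(x)))
  psi_sum <- function(m) {
    u <- (x - m) / (c * s)
    sum(ifelse(abs(u) < 1, (x - m) * (1 - u^2)^2, 0))
  }
  stats::uniroot(Vectorize(psi_sum), range(x), tol = 1e-12)$root
}

# brute-force OLS via normal equations, for cross-checking lm-based fits
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  unname(solve(t(X) %*% X, t(X) %*% y)[2L, 1L])
}
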