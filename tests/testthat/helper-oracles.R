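# shared fixtures and independent oracles, all built in code

# the six published study curves (two trials at 1 and 6 months, one cohort
# at 12 and 48 months); constants taken as given, see load_coefficient_table()
published_six <- function() {
  tibble::tibble(
    label = c("PARAGON-A", "PARAGON-A", "GUSTO-IIB", "GUSTO-IIB", "Hyde", "Hyde"),
    follow_up_months = c(1, 6, 1, 6, 12, 48),
    beta  = c(0.42, 0.45, 0.62, 0.54, 0.54, 0.48),
    delta = c(1.09, 1.23, 0.92, 1.09, 1.56, 1.79)
  )
}

# exact power-law curve sampled at given ST values
power_curve <- function(beta, delta, st, base = 10) {
  tibble::tibble(st_mm = st,
                 probability_percent = base^(delta + beta * log(st, base)))
}

# brute-force OLS through the normal equations (independent of lm)
normal_equations_fit <- function(x, y) {
  X <- cbind(1, x)
  est <- solve(t(X) %*% X, t(X) %*% y)
  list(intercept = est[1], slope = est[2])
}

# piecewise-quadratic oracle: same nearest-3-knot window convention, but the
# parabola is obtained by solving the local Vandermonde system directly
vandermonde_resample <- function(x, y, grid) {
  n <- length(x)
  vapply(grid, function(g) {
    j <- which.min(abs(x - g))
    i0 <- min(max(j - 1L, 1L), n - 2L)
    xs <- x[i0:(i0 + 2L)]
    V <- cbind(1, xs, xs^2)
    ab <- solve(V, y[i0:(i0 + 2L)])
    ab[1] + ab[2] * g + ab[3] * g^2
  }, numeric(1))
}

# scalar bisection inverse of the allometric law, independent of vf_invert
bisect_invert <- function(beta, delta, p, lower = 0.1, upper = 10, tol = 1e-12) {
  f <- function(st) 10^(delta + beta * log10(st)) - p
  for (i in 1:200) {
    mid <- (lower + upper) / 2
    if (f(lower) * f(mid) <= 0) upper <- mid else lower <- mid
    if (upper - lower < tol) break
  }
  (lower + upper) / 2
}
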