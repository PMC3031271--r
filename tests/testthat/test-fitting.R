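test_that("quadratic resampling reproduces quadratics exactly and hits the knots", {
  # a quadratic interpolates a quadratic exactly
  quad <- tibble::tibble(st_mm = c(0.5, 1, 2), probability_percent = 10 * c(0.5, 1, 2)^2)
  rs <- resample_quadratic(quad)
  expect_equal(nrow(rs), 61)
  expect_equal(rs$st_mm[c(1, 61)], c(0.5, 2))
  expect_equal(rs$probability_percent, 10 * rs$st_mm^2, tolerance = 1e-9)

  # interpolant passes through knots lying on the grid
  knots <- tibble::tibble(st_mm = c(0.5, 1, 2), probability_percent = c(8, 12.3, 16.5))
  rs2 <- resample_quadratic(knots)
  expect_identical(rs2$probability_percent[rs2$st_mm == 1], 12.3)
  expect_identical(rs2$probability_percent[rs2$st_mm == 0.5], 8)
  expect_identical(rs2$probability_percent[rs2$st_mm == 2], 16.5)
})

test_that("piecewise quadratic on >3 points matches a local Vandermonde oracle", {
  x <- c(0.4, 0.9, 1.4, 2.1)
  y <- 2 + 3 * x - 1.5 * x^2 + 0.8 * x^3     # a cubic: piecewise choice matters
  curve <- tibble::tibble(st_mm = x, probability_percent = y)
  rs <- resample_quadratic(curve)
  expect_equal(rs$probability_percent,
               vandermonde_resample(x, y, rs$st_mm), tolerance = 1e-10)
})

test_that("resampling a curve already on the grid returns it unchanged", {
  g <- seq(0.5, 2, by = 0.025)
  curve <- tibble::tibble(st_mm = g, probability_percent = 5 + sin(g))
  rs <- resample_quadratic(curve)
  expect_equal(rs$probability_percent, curve$probability_percent, tolerance = 1e-12)
})

test_that("resampling refuses sparse input and extrapolation", {
  two <- tibble::tibble(st_mm = c(0.5, 2), probability_percent = c(5, 20))
  expect_error(resample_quadratic(two), class = "allovf_insufficient_data_error")
  narrow <- tibble::tibble(st_mm = c(0.6, 1, 1.8), probability_percent = c(5, 10, 20))
  expect_error(resample_quadratic(narrow), class = "allovf_extrapolation_error")
})

test_that("noise-free power-law data is recovered exactly, with and without resampling", {
  # on the default grid resampling is the identity, so recovery is exact
  grid_curve <- power_curve(0.48, 1.79, seq(0.5, 2, by = 0.025))
  sparse_curve <- power_curve(0.48, 1.79, c(0.5, 1, 1.3, 2))
  for (curve in list(grid_curve, sparse_curve)) {
    fit <- fit_allometric(curve, resample = identical(curve, grid_curve))
    expect_equal(fit$coefficients$beta, 0.48, tolerance = 1e-9)
    expect_equal(fit$coefficients$delta, 1.79, tolerance = 1e-9)
    expect_equal(fit$adj_r_squared, 1, tolerance = 1e-12)
  }
  # base-e fitting: beta unchanged, delta scales by ln 10
  fe <- fit_allometric(grid_curve, log_base = "e")
  expect_equal(fe$coefficients$beta, 0.48, tolerance = 1e-9)
  expect_equal(fe$coefficients$delta, 1.79 * log(10), tolerance = 1e-9)
})

test_that("resampling sparse power-law points perturbs the refit only slightly", {
  # a parabola through 3-4 off-grid power-law points is not the power law,
  # so coefficients recovered through resampling shift a little; the shift
  # stays well below the 2-decimal reporting precision
  fit <- fit_allometric(power_curve(0.48, 1.79, c(0.5, 1, 1.3, 2)), resample = TRUE)
  expect_lt(abs(fit$coefficients$beta - 0.48), 0.01)
  expect_lt(abs(fit$coefficients$delta - 1.79), 0.01)
  expect_gt(fit$adj_r_squared, 0.999)
})

test_that("fit agrees with a normal-equations oracle on random noisy inputs", {
  withr::with_seed(2203, {
    for (i in 1:10) {
      beta <- runif(1, 0.2, 1); delta <- runif(1, 0.5, 1.8)
      st <- sort(runif(8, 0.4, 2.5))
      curve <- power_curve(beta, delta, st)
      curve$probability_percent <- curve$probability_percent * 10^rnorm(8, 0, 0.03)
      fit <- fit_allometric(curve, resample = FALSE, range_mm = range(st))
      oracle <- normal_equations_fit(log10(curve$st_mm), log10(curve$probability_percent))
      expect_equal(fit$coefficients$beta, oracle$slope, tolerance = 1e-10)
      expect_equal(fit$coefficients$delta, oracle$intercept, tolerance = 1e-10)
      expect_lte(fit$adj_r_squared, fit$r_squared)
    }
  })
})

test_that("slope recovery under multiplicative noise stays close to truth", {
  withr::with_seed(77, {
    grid <- seq(0.5, 2, by = 0.025)
    curve <- power_curve(0.62, 0.92, grid)
    curve$probability_percent <- curve$probability_percent * 10^rnorm(61, 0, 0.02)
    fit <- fit_allometric(curve, resample = FALSE)
    expect_lt(abs(fit$coefficients$beta - 0.62), 0.05)
  })
})

test_that("fitted slope of a two-segment power law lies between the segment exponents", {
  st <- seq(0.5, 2, by = 0.025)
  p <- ifelse(st <= 1, 10^(1 + 0.3 * log10(st)), 10^(1 + 0.8 * log10(st)))
  fit <- fit_allometric(tibble::tibble(st_mm = st, probability_percent = p), resample = FALSE)
  expect_gt(fit$coefficients$beta, 0.3)
  expect_lt(fit$coefficients$beta, 0.8)
})

test_that("fit is invariant under reordering of the input points", {
  curve <- power_curve(0.5, 1.2, c(0.5, 0.8, 1, 1.4, 2))
  curve$probability_percent <- curve$probability_percent + c(0.3, -0.2, 0.1, 0, -0.1)
  shuffled <- curve[c(4, 1, 5, 3, 2), ]
  f1 <- fit_allometric(curve)
  f2 <- fit_allometric(shuffled)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-12)
})

test_that("fitting rejects non-positive probabilities and degenerate designs", {
  bad <- tibble::tibble(st_mm = c(0.5, 1, 2), probability_percent = c(0, 5, 10))
  expect_error(fit_allometric(bad), class = "allovf_domain_error")
  dup <- tibble::tibble(st_mm = c(1, 1, 1), probability_percent = c(5, 6, 7))
  expect_error(fit_allometric(dup), class = "allovf_validation_error")
})

test_that("tidy and glance expose the fit in broom shape", {
  fit <- fit_allometric(power_curve(0.48, 1.79, seq(0.5, 2, by = 0.025)))
  td <- tidy(fit)
  expect_equal(td$term, c("beta", "delta"))
  expect_equal(td$estimate, c(0.48, 1.79), tolerance = 1e-9)
  gl <- glance(fit)
  expect_equal(gl$n_points, 61)
  expect_equal(gl$adj.r.squared, 1, tolerance = 1e-12)
  expect_s3_class(autoplot(fit), "ggplot")
})
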