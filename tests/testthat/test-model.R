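test_that("vf_predict reproduces known single-curve values", {
  # 1-month curve at 2 mm: 12.78 -> rounds to 13
  p <- vf_predict(tibble::tibble(beta = 0.62, delta = 0.92), st_mm = 2)
  expect_equal(p$probability_percent, 10^(0.92 + 0.62 * log10(2)), tolerance = 1e-12)
  expect_equal(round(p$probability_percent), 13)

  # at 1 mm the log term vanishes: prediction is exactly base^delta
  p1 <- vf_predict(tibble::tibble(beta = 0.37, delta = 1.79), st_mm = 1)
  expect_identical(p1$probability_percent, 10^1.79)

  # 48-month and 12-month curves at 1.5 mm round to 75 and 45
  p48 <- vf_predict(tibble::tibble(beta = 0.48, delta = 1.79), st_mm = 1.5)
  expect_equal(round(p48$probability_percent), 75)
  p12 <- vf_predict(tibble::tibble(beta = 0.54, delta = 1.56), st_mm = 1.5)
  expect_equal(round(p12$probability_percent, 1), 45.2)
})

test_that("predict is vectorised over curves and ST values and keeps annotation", {
  out <- vf_predict(published_six(), st_mm = c(0.5, 1, 1.5, 2))
  expect_s3_class(out, "tbl_df")
  expect_equal(nrow(out), 24)
  expect_true(all(c("label", "follow_up_months", "st_mm", "probability_percent") %in% names(out)))
})

test_that("power-law structure: monotonicity, unit point, scale relation, base change", {
  st <- sort(c(10^runif(50, -1, 1), 1))
  for (beta in c(0.42, 0.62, -0.3)) {
    coeffs <- tibble::tibble(beta = beta, delta = 1.1)
    p <- vf_predict(coeffs, st_mm = st)$probability_percent
    if (beta > 0) expect_true(all(diff(p[order(st)]) > 0)) else expect_true(all(diff(p[order(st)]) < 0))
    # unit point
    expect_identical(vf_predict(coeffs, st_mm = 1)$probability_percent, 10^1.1)
    # defining scale relation p(k*st)/p(st) = k^beta
    k <- 1.7
    ratio <- vf_predict(coeffs, st_mm = k * st)$probability_percent / p
    expect_equal(ratio, rep(k^beta, length(st)), tolerance = 1e-12)
  }
  # base-10 curve re-expressed in base e predicts identically
  b10 <- tibble::tibble(beta = 0.54, delta = 1.09)
  be <- tibble::tibble(beta = 0.54, delta = 1.09 * log(10))
  expect_equal(vf_predict(be, st_mm = st, log_base = "e")$probability_percent,
               vf_predict(b10, st_mm = st)$probability_percent, tolerance = 1e-12)
})

test_that("invert is the exact inverse of predict and matches a bisection oracle", {
  withr::with_seed(101, {
    for (i in 1:10) {
      coeffs <- tibble::tibble(beta = runif(1, 0.2, 1.2), delta = runif(1, 0.5, 2))
      st <- 10^runif(5, -1, 1)
      p <- suppressWarnings(vf_predict(coeffs, st_mm = st))
      back <- vf_invert(coeffs, probability_percent = p$probability_percent)
      expect_equal(back$st_mm, st, tolerance = 1e-9)
    }
  })
  # against an independent bisection on predict
  expect_equal(vf_invert(tibble::tibble(beta = 0.62, delta = 0.92), 12.78)$st_mm,
               bisect_invert(0.62, 0.92, 12.78), tolerance = 1e-8)
  # identity law
  expect_equal(vf_invert(tibble::tibble(beta = 1, delta = 0), 1)$st_mm, 1)
})

test_that("components collapse into log-log coefficients consistently", {
  expect_equal(components_to_coefficients(tibble::tibble(alpha = 1, beta = 0.5, gamma = 1)),
               tibble::tibble(beta = 0.5, delta = 0))
  expect_equal(components_to_coefficients(tibble::tibble(alpha = 10, beta = 1, gamma = 1)),
               tibble::tibble(beta = 1, delta = 1))
  # predict through the collapsed coefficients equals alpha*(gamma*st)^beta directly
  co <- components_to_coefficients(tibble::tibble(alpha = 2, beta = 0.46, gamma = 3))
  st <- c(0.5, 1, 2)
  expect_equal(vf_predict(co, st_mm = st)$probability_percent,
               2 * (3 * st)^0.46, tolerance = 1e-9)
})

test_that("model functions reject invalid domains and warn past 100%", {
  coeffs <- tibble::tibble(beta = 0.5, delta = 1)
  expect_error(vf_predict(coeffs, st_mm = 0), class = "allovf_domain_error")
  expect_error(vf_predict(coeffs, st_mm = -1), class = "allovf_domain_error")
  expect_error(vf_predict(tibble::tibble(beta = NA_real_, delta = 1), 1),
               class = "allovf_validation_error")
  expect_error(vf_invert(coeffs, probability_percent = 0), class = "allovf_domain_error")
  expect_error(vf_invert(tibble::tibble(beta = 0, delta = 1), 10),
               class = "allovf_degenerate_curve_error")
  expect_error(components_to_coefficients(tibble::tibble(alpha = 0, beta = 1, gamma = 1)),
               class = "allovf_domain_error")
  expect_warning(vf_predict(tibble::tibble(beta = 0.48, delta = 1.79), st_mm = 5),
                 "exceeds 100")
})
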