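#' Resample a sparse study curve by piecewise quadratic interpolation
#'
#' Clinical event-rate tables typically report only three or four ST bins
#' (e.g. 0.5, 1 and 2 mm). To fit the allometric law on a common support, the
#' curve is resampled onto a regular grid by quadratic interpolation: the
#' value at each grid point is taken from the parabola through the three
#' input knots nearest to it (the unique interpolating quadratic when the
#' curve has exactly three points). Knots that fall on the grid are
#' reproduced exactly, and a curve already on the target grid is returned
#' unchanged. No extrapolation is performed: the requested range must lie
#' within the span of the input points.
#'
#' @param curve Data frame with numeric columns `st_mm` (> 0, distinct) and
#'   `probability_percent`; at least 3 rows. Optional `label` and
#'   `follow_up_months` columns are carried through.
#' @param range_mm Closed interval `(low, high)` to resample over; default
#'   `c(0.5, 2)` mm, the window the allometric fits use.
#' @param step_mm Grid step in mm; default 0.025 (61 points for the default
#'   range, endpoints inclusive).
#'
#' @return A tibble with the same columns as `curve`, one row per grid point.
#' @examples
#' curve <- tibble::tibble(st_mm = c(0.5, 1, 2),
#'                         probability_percent = c(8, 12.3, 16.5))
#' resample_quadratic(curve)
#' @export
resample_quadratic <- function(curve, range_mm = c(0.5, 2), step_mm = 0.025) {
  check_curve(curve, min_points = 3L)
  curve <- dplyr::arrange(dplyr::as_tibble(curve), .data$st_mm)
  grid <- st_grid(range_mm, step_mm)
  x <- curve$st_mm
  y <- curve$probability_percent
  if (range_mm[1] < min(x) || range_mm[2] > max(x)) {
    abort(sprintf("Requested range [%g, %g] mm extends outside the data span [%g, %g] mm; extrapolation is not supported.",
                  range_mm[1], range_mm[2], min(x), max(x)),
          class = "allovf_extrapolation_error")
  }
  n <- length(x)
  vals <- vapply(grid, function(g) {
    j <- which.min(abs(x - g))            # nearest knot
    i0 <- min(max(j - 1L, 1L), n - 2L)    # 3-knot window, clamped at the ends
    xs <- x[i0:(i0 + 2L)]
    ys <- y[i0:(i0 + 2L)]
    # Lagrange form of the parabola through the three knots
    ys[1] * (g - xs[2]) * (g - xs[3]) / ((xs[1] - xs[2]) * (xs[1] - xs[3])) +
    ys[2] * (g - xs[1]) * (g - xs[3]) / ((xs[2] - xs[1]) * (xs[2] - xs[3])) +
    ys[3] * (g - xs[1]) * (g - xs[2]) / ((xs[3] - xs[1]) * (xs[3] - xs[2]))
  }, numeric(1))
  out <- tibble(st_mm = grid, probability_percent = vals)
  for (col in intersect(c("label", "follow_up_months"), names(curve))) {
    out[[col]] <- curve[[col]][1]
  }
  dplyr::relocate(out, dplyr::any_of(c("label", "follow_up_months")))
}

#' Fit the allometric law to a study curve by log-log least squares
#'
#' Estimates the allometric exponent `beta` (slope) and intercept `delta` of
#' the power law `P = base^(delta + beta * log_base(st))` by ordinary least
#' squares of `log(probability)` on `log(st)`. By default the curve is first
#' resampled with [resample_quadratic()] onto the 0.5-2.0 mm grid in steps of
#' 0.025 mm, mirroring the resolution-enhancement step of the original
#' fitting procedure; set `resample = FALSE` to regress on the raw points
#' (restricted to `range_mm`).
#'
#' @inheritParams resample_quadratic
#' @param log_base Base for both logarithms: 10 (default) or `"e"`. The
#'   fitted `delta` depends on the base; `beta` does not.
#' @param resample Logical; resample onto the regular grid before fitting
#'   (default `TRUE`).
#'
#' @return An object of class `vf_fit`: a list with elements
#'   `coefficients` (tibble with `beta`, `delta` and any `label` /
#'   `follow_up_months` annotation), `r_squared`, `adj_r_squared` (the usual
#'   two-parameter adjustment `1 - (1 - r2)(n - 1)/(n - 2)`), `n_points`,
#'   `fit_range_mm`, `step_mm`, `log_base`, the fitted `data`, and the
#'   underlying `lm` object. Supports [tidy()], [glance()], [autoplot()] and
#'   `print()`.
#'
#' @examples
#' curve <- vf_predict(tibble::tibble(beta = 0.48, delta = 1.79),
#'                     st_mm = c(0.5, 1, 2))
#' fit <- fit_allometric(curve)
#' glance(fit)
#' @export
fit_allometric <- function(curve, log_base = 10, resample = TRUE,
                           range_mm = c(0.5, 2), step_mm = 0.025) {
  base <- resolve_base(log_base)
  check_curve(curve, min_points = 2L)
  if (any(curve$probability_percent <= 0)) {
    abort("All probabilities must be > 0: the log-log fit cannot take the log of a zero event rate.",
          class = "allovf_domain_error")
  }
  curve <- dplyr::arrange(dplyr::as_tibble(curve), .data$st_mm)
  pts <- if (resample) {
    resample_quadratic(curve, range_mm = range_mm, step_mm = step_mm)
  } else {
    dplyr::filter(curve, .data$st_mm >= range_mm[1], .data$st_mm <= range_mm[2])
  }
  if (nrow(pts) < 3) {
    abort("At least 3 points are required inside the fitting window.",
          class = "allovf_insufficient_data_error")
  }
  if (any(pts$probability_percent <= 0)) {
    abort("Resampled probabilities must stay > 0 inside the fitting window.",
          class = "allovf_domain_error")
  }
  lx <- log(pts$st_mm, base)
  ly <- log(pts$probability_percent, base)
  if (max(lx) - min(lx) < .Machine$double.eps^0.5) {
    abort("Degenerate design: all ST values coincide, the log-log slope is unidentifiable.",
          class = "allovf_singular_fit_error")
  }
  model <- lm(ly ~ lx)
  # summary.lm warns on zero-residual fits; noise-free curves are legitimate here
  sm <- suppressWarnings(summary(model))
  coefs <- tibble(beta = unname(coef(model)[2]), delta = unname(coef(model)[1]))
  for (col in intersect(c("label", "follow_up_months"), names(pts))) {
    coefs[[col]] <- pts[[col]][1]
  }
  structure(
    list(
      coefficients = dplyr::relocate(coefs, dplyr::any_of(c("label", "follow_up_months"))),
      r_squared = sm$r.squared,
      adj_r_squared = sm$adj.r.squared,
      n_points = nrow(pts),
      fit_range_mm = range_mm,
      step_mm = if (resample) step_mm else NA_real_,
      resampled = resample,
      log_base = if (identical(log_base, "e")) "e" else base,
      data = pts,
      model = model
    ),
    class = "vf_fit"
  )
}

#' @export
print.vf_fit <- function(x, ...) {
  cat(sprintf("Allometric log-log fit (base %s)\n",
              if (identical(x$log_base, "e")) "e" else format(x$log_base)))
  cat(sprintf("  beta  (exponent)  : %.4f\n", x$coefficients$beta))
  cat(sprintf("  delta (intercept) : %.4f\n", x$coefficients$delta))
  cat(sprintf("  adjusted r-square : %.4f   (n = %d points, window %g-%g mm%s)\n",
              x$adj_r_squared, x$n_points, x$fit_range_mm[1], x$fit_range_mm[2],
              if (x$resampled) sprintf(", step %g mm", x$step_mm) else ", raw points"))
  invisible(x)
}

#' Tidy an allometric fit
#'
#' @param x A `vf_fit` object from [fit_allometric()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`beta`, `delta`) and columns
#'   `term`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @export
tidy.vf_fit <- function(x, ...) {
  cm <- suppressWarnings(summary(x$model))$coefficients
  tibble(
    term = c("delta", "beta"),
    estimate = unname(cm[, "Estimate"]),
    std.error = unname(cm[, "Std. Error"]),
    statistic = unname(cm[, "t value"]),
    p.value = unname(cm[, "Pr(>|t|)"])
  )[c(2, 1), ]
}

#' One-row summary of an allometric fit
#'
#' @inheritParams tidy.vf_fit
#' @return A one-row tibble: `beta`, `delta`, `r.squared`, `adj.r.squared`,
#'   `n_points`, `fit_low_mm`, `fit_high_mm`, `step_mm`.
#' @export
glance.vf_fit <- function(x, ...) {
  tibble(
    beta = x$coefficients$beta,
    delta = x$coefficients$delta,
    r.squared = x$r_squared,
    adj.r.squared = x$adj_r_squared,
    n_points = x$n_points,
    fit_low_mm = x$fit_range_mm[1],
    fit_high_mm = x$fit_range_mm[2],
    step_mm = x$step_mm
  )
}

#' Plot an allometric fit in log-log coordinates
#'
#' @param object A `vf_fit` object.
#' @param ... Unused.
#' @return A ggplot: fitted points and the fitted power law, on log10 scales.
#' @export
autoplot.vf_fit <- function(object, ...) {
  pred <- vf_predict(object$coefficients[, c("beta", "delta")],
                     st_mm = object$data$st_mm,
                     log_base = object$log_base)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$st_mm, y = .data$probability_percent)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_line(data = pred, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "ST deviation (mm)", y = "VF probability (%)",
                  title = sprintf("beta = %.2f, delta = %.2f, adj. r² = %.4f",
                                  object$coefficients$beta, object$coefficients$delta,
                                  object$adj_r_squared))
}
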