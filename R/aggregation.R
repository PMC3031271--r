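# Two curve-combination conventions are provided and deliberately kept
# distinct: mean_curve_refit() averages in probability space and refits
# (matching the published per-horizon mean coefficients, half-SD band),
# while overall_average_band() averages in log10 space (geometric mean,
# SEM band). They answer different questions and do not commute.

# evaluate each coefficient row on the grid; columns = curves
eval_curve_matrix <- function(coeffs, grid) {
  vapply(seq_len(nrow(coeffs)),
         function(i) 10^(coeffs$delta[i] + coeffs$beta[i] * log10(grid)),
         numeric(length(grid)))
}

new_vf_aggregate <- function(df, band_kind, space, source_labels) {
  structure(
    df,
    band_kind = band_kind,
    space = space,
    source_labels = source_labels,
    class = c("vf_aggregate", class(tibble())))
}

#' Average a family of curves in probability space and refit
#'
#' Evaluates each input curve on a regular ST grid (base 10), takes the
#' pointwise arithmetic mean of the probabilities, attaches a half-standard-
#' deviation dispersion band (sample SD across curves at each grid point,
#' divided by 2, in probability space), and refits the allometric law to the
#' mean curve with [fit_allometric()] (no further resampling: the mean curve
#' is already on the grid). This is the convention that turns the per-study
#' 1- and 6-month coefficient pairs into the published per-horizon mean
#' coefficients.
#'
#' @param coeffs Data frame of two or more curves with columns `beta`,
#'   `delta` (optional `label`, `follow_up_months`).
#' @param range_mm,step_mm Grid specification; defaults `c(0.5, 2)` mm and
#'   0.025 mm.
#'
#' @return An object of class `vf_mean_refit`: list with `fit` (a [vf_fit][fit_allometric()]
#'   for the mean curve) and `curve`, a `vf_aggregate` tibble with columns
#'   `st_mm`, `mean_percent`, `band_low_percent`, `band_high_percent`
#'   (`band_kind = "half_sd"`, `space = "probability"`).
#' @examples
#' one_month <- tibble::tibble(label = c("PARAGON-A", "GUSTO-IIB"),
#'                             beta = c(0.42, 0.62), delta = c(1.09, 0.92))
#' agg <- mean_curve_refit(one_month)
#' glance(agg$fit)
#' @export
mean_curve_refit <- function(coeffs, range_mm = c(0.5, 2), step_mm = 0.025) {
  check_coefficients(coeffs)
  if (nrow(coeffs) < 2) {
    abort("At least 2 curves are required to average.", class = "allovf_validation_error")
  }
  grid <- st_grid(range_mm, step_mm)
  pm <- eval_curve_matrix(coeffs, grid)
  mean_p <- rowMeans(pm)
  half_sd <- apply(pm, 1, sd) / 2
  curve <- new_vf_aggregate(
    tibble(st_mm = grid,
           mean_percent = mean_p,
           band_low_percent = mean_p - half_sd,
           band_high_percent = mean_p + half_sd),
    band_kind = "half_sd", space = "probability",
    source_labels = curve_labels(coeffs))
  mean_df <- tibble(st_mm = grid, probability_percent = mean_p)
  if ("follow_up_months" %in% names(coeffs) &&
      dplyr::n_distinct(coeffs$follow_up_months) == 1) {
    mean_df$follow_up_months <- coeffs$follow_up_months[1]
  }
  fit <- fit_allometric(mean_df, log_base = 10, resample = FALSE,
                        range_mm = range_mm, step_mm = step_mm)
  structure(list(fit = fit, curve = curve), class = "vf_mean_refit")
}

#' Geometric-mean curve with a standard-error-of-the-mean band
#'
#' Evaluates each input curve on a regular ST grid, and at every grid point
#' computes the mean `m` and SEM `s` of the log10 probabilities across curves
#' (sample SD, `n - 1` divisor, divided by `sqrt(n)`). Returns the centre
#' curve `10^m` — the pointwise geometric mean, itself an exact power law
#' whose exponent is the mean of the input exponents — with the
#' multiplicatively symmetric band `[10^(m - s), 10^(m + s)]`. This is the
#' convention behind a single overall risk curve spanning all follow-up
#' horizons, with the band quantifying between-study spread.
#'
#' @inheritParams mean_curve_refit
#' @return A `vf_aggregate` tibble with columns `st_mm`, `mean_percent`,
#'   `band_low_percent`, `band_high_percent` (`band_kind = "sem"`,
#'   `space = "log10"`).
#' @examples
#' six <- tibble::tibble(beta  = c(0.42, 0.45, 0.62, 0.54, 0.54, 0.48),
#'                       delta = c(1.09, 1.23, 0.92, 1.09, 1.56, 1.79))
#' band <- overall_average_band(six)
#' band_at(band, 1.5)
#' @export
overall_average_band <- function(coeffs, range_mm = c(0.5, 2), step_mm = 0.025) {
  check_coefficients(coeffs)
  if (nrow(coeffs) < 2) {
    abort("At least 2 curves are required: the SEM of a single curve is undefined.",
          class = "allovf_validation_error")
  }
  grid <- st_grid(range_mm, step_mm)
  lm10 <- log10(eval_curve_matrix(coeffs, grid))
  m <- rowMeans(lm10)
  s <- apply(lm10, 1, sd) / sqrt(nrow(coeffs))
  new_vf_aggregate(
    tibble(st_mm = grid,
           mean_percent = 10^m,
           band_low_percent = 10^(m - s),
           band_high_percent = 10^(m + s)),
    band_kind = "sem", space = "log10",
    source_labels = curve_labels(coeffs))
}

curve_labels <- function(coeffs) {
  if (!"label" %in% names(coeffs)) return(NULL)
  if ("follow_up_months" %in% names(coeffs)) {
    paste0(coeffs$label, " (", coeffs$follow_up_months, " mo)")
  } else {
    coeffs$label
  }
}

#' Read an aggregate curve and its band at chosen ST values
#'
#' Linear interpolation on the aggregate's grid (exact at grid points).
#'
#' @param aggregate A `vf_aggregate` tibble from [overall_average_band()] or
#'   the `$curve` element of [mean_curve_refit()].
#' @param st_mm ST deviations (mm) within the aggregate's grid range.
#' @return A tibble with `st_mm`, `mean_percent`, `band_low_percent`,
#'   `band_high_percent`.
#' @export
band_at <- function(aggregate, st_mm) {
  if (!inherits(aggregate, "vf_aggregate")) {
    abort("`aggregate` must be a `vf_aggregate` (see overall_average_band()).",
          class = "allovf_validation_error")
  }
  rng <- range(aggregate$st_mm)
  if (any(st_mm < rng[1] | st_mm > rng[2])) {
    abort(sprintf("`st_mm` must lie within the aggregate grid [%g, %g] mm.", rng[1], rng[2]),
          class = "allovf_extrapolation_error")
  }
  tibble(
    st_mm = st_mm,
    mean_percent = approx(aggregate$st_mm, aggregate$mean_percent, st_mm)$y,
    band_low_percent = approx(aggregate$st_mm, aggregate$band_low_percent, st_mm)$y,
    band_high_percent = approx(aggregate$st_mm, aggregate$band_high_percent, st_mm)$y
  )
}

#' @export
print.vf_mean_refit <- function(x, ...) {
  cat("Probability-space mean curve (half-SD band) with log-log refit\n")
  if (!is.null(attr(x$curve, "source_labels"))) {
    cat("  curves:", paste(attr(x$curve, "source_labels"), collapse = ", "), "\n")
  }
  print(x$fit)
  invisible(x)
}

#' @describeIn mean_curve_refit tidy the refit coefficients.
#' @param x,... passed to the `vf_fit` tidier.
#' @export
tidy.vf_mean_refit <- function(x, ...) tidy(x$fit, ...)

#' @describeIn mean_curve_refit one-row fit summary.
#' @export
glance.vf_mean_refit <- function(x, ...) glance(x$fit, ...)

#' Plot an aggregate curve with its dispersion band
#'
#' @param object A `vf_aggregate` tibble.
#' @param ... Unused.
#' @return A ggplot: ribbon for the band, line for the centre curve.
#' @export
autoplot.vf_aggregate <- function(object, ...) {
  kind <- switch(attr(object, "band_kind"),
                 half_sd = "mean ± SD/2", sem = "geometric mean ± SEM",
                 "band")
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$st_mm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$band_low_percent,
                                      ymax = .data$band_high_percent),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_percent), colour = "steelblue4") +
    ggplot2::labs(x = "ST deviation (mm)", y = "VF probability (%)", title = kind)
}

#' @rdname autoplot.vf_aggregate
#' @export
autoplot.vf_mean_refit <- function(object, ...) {
  autoplot(object$curve) +
    ggplot2::geom_line(
      data = vf_predict(object$fit$coefficients[, c("beta", "delta")],
                        st_mm = object$curve$st_mm),
      ggplot2::aes(y = .data$probability_percent), linetype = 2, colour = "firebrick")
}
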