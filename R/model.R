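#' Predict ventricular-fibrillation probability from an allometric curve
#'
#' Evaluates the allometric law `P = base^(delta + beta * log_base(st))` for
#' every combination of curve (row of `coeffs`) and ST deviation. `beta` is the
#' allometric exponent (the slope of the log-log line) and `delta` the log-log
#' intercept, i.e. the log of the probability, in percent, at 1 mm deviation.
#'
#' The probability is on a 0-100 percent scale. Because the law is an
#' extrapolating power function, predictions can mathematically exceed 100%;
#' such values trigger a warning but are not clamped.
#'
#' @param coeffs Data frame of curves with numeric columns `beta` and `delta`;
#'   optional columns `label` and `follow_up_months` are carried through.
#' @param st_mm Numeric vector of ST-segment deviations in mm (magnitude, at
#'   the standard calibration of 10 mm = 1 mV); all values must be > 0.
#' @param log_base Base of the logarithms the coefficients are expressed in:
#'   10 (default) or `"e"`.
#'
#' @return A tibble with one row per curve x ST value: the coefficient columns,
#'   `st_mm`, and `probability_percent`.
#'
#' @examples
#' curves <- tibble::tibble(label = "GUSTO-IIB", follow_up_months = 1,
#'                          beta = 0.62, delta = 0.92)
#' vf_predict(curves, st_mm = c(1, 1.5, 2))
#' @seealso [vf_invert()] for the algebraic inverse, [fit_allometric()] for
#'   estimating `beta` and `delta` from observed event rates.
#' @export
vf_predict <- function(coeffs, st_mm, log_base = 10) {
  check_coefficients(coeffs)
  base <- resolve_base(log_base)
  if (!is.numeric(st_mm) || length(st_mm) == 0 || any(!is.finite(st_mm))) {
    abort("`st_mm` must be a non-empty finite numeric vector.", class = "allovf_domain_error")
  }
  if (any(st_mm <= 0)) {
    abort("`st_mm` must be strictly positive (ST deviation magnitude in mm).",
          class = "allovf_domain_error")
  }
  out <- expand_rows(coeffs, st_mm = st_mm) |>
    dplyr::mutate(
      probability_percent = base^(.data$delta + .data$beta * log(.data$st_mm, base))
    )
  if (any(out$probability_percent > 100)) {
    warn("Predicted probability exceeds 100%: the power law is extrapolating beyond its meaningful range.")
  }
  out
}

#' Invert an allometric curve: ST deviation at a given probability
#'
#' Algebraic inverse of [vf_predict()]: returns the ST deviation at which a
#' curve attains a given event probability,
#' `st = base^((log_base(p) - delta) / beta)`.
#'
#' @inheritParams vf_predict
#' @param probability_percent Numeric vector of probabilities in percent; all
#'   values must be > 0.
#'
#' @return A tibble with one row per curve x probability: the coefficient
#'   columns, `probability_percent`, and `st_mm`.
#' @examples
#' curves <- tibble::tibble(beta = 0.62, delta = 0.92)
#' vf_invert(curves, probability_percent = 12.78)
#' @export
vf_invert <- function(coeffs, probability_percent, log_base = 10) {
  check_coefficients(coeffs)
  base <- resolve_base(log_base)
  if (!is.numeric(probability_percent) || length(probability_percent) == 0 ||
      any(!is.finite(probability_percent)) || any(probability_percent <= 0)) {
    abort("`probability_percent` must be finite and strictly positive.",
          class = "allovf_domain_error")
  }
  if (any(coeffs$beta == 0)) {
    abort("`beta` = 0 gives a flat curve that cannot be inverted.",
          class = "allovf_degenerate_curve_error")
  }
  expand_rows(coeffs, probability_percent = probability_percent) |>
    dplyr::mutate(
      st_mm = base^((log(.data$probability_percent, base) - .data$delta) / .data$beta)
    )
}

#' Combine mechanistic proportionality constants into log-log coefficients
#'
#' The allometric law can be written mechanistically as
#' `P = alpha * (gamma * st)^beta`, where `gamma` converts ST deviation (mm)
#' into a number of diseased ventricular fibers and `alpha` scales fiber count
#' into an event probability. In log-log form this collapses to the two-
#' parameter line with slope `beta` and intercept
#' `delta = log_base(alpha) + beta * log_base(gamma)`.
#'
#' @param components Data frame with numeric columns `alpha`, `beta`, `gamma`
#'   (`alpha > 0`, `gamma > 0`); other columns are carried through.
#' @inheritParams vf_predict
#'
#' @return A tibble with columns `beta` and `delta` (plus carried columns),
#'   usable directly as the `coeffs` argument of [vf_predict()].
#' @examples
#' components_to_coefficients(tibble::tibble(alpha = 2, beta = 0.46, gamma = 3))
#' @export
components_to_coefficients <- function(components, log_base = 10) {
  if (!is.data.frame(components) ||
      !all(c("alpha", "beta", "gamma") %in% names(components))) {
    abort("`components` must be a data frame with columns `alpha`, `beta`, `gamma`.",
          class = "allovf_validation_error")
  }
  base <- resolve_base(log_base)
  with(components, {
    if (any(!is.finite(alpha)) || any(alpha <= 0) || any(!is.finite(gamma)) || any(gamma <= 0)) {
      abort("`alpha` and `gamma` must be finite and > 0.", class = "allovf_domain_error")
    }
    if (any(!is.finite(beta))) {
      abort("`beta` must be finite.", class = "allovf_validation_error")
    }
  })
  dplyr::as_tibble(components) |>
    dplyr::mutate(delta = log(.data$alpha, base) + .data$beta * log(.data$gamma, base)) |>
    dplyr::select(-"alpha", -"gamma")
}
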