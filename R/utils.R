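# internal validation + grid helpers shared across the package

# regular ST grid with inclusive endpoints; integer point count avoids
# floating-step accumulation (61 points for the 0.5-2.0 mm, 0.025 mm default)
st_grid <- function(range_mm, step_mm) {
  if (length(range_mm) != 2 || !all(is.finite(range_mm)) || range_mm[1] >= range_mm[2]) {
    abort("`range_mm` must be a finite increasing pair (low, high).", class = "allovf_validation_error")
  }
  if (!is.finite(step_mm) || step_mm <= 0) {
    abort("`step_mm` must be a positive number.", class = "allovf_validation_error")
  }
  n <- round((range_mm[2] - range_mm[1]) / step_mm) + 1L
  g <- range_mm[1] + (seq_len(n) - 1L) * step_mm
  g[n] <- range_mm[2]
  g
}

# all curve x value combinations, preserving input row and value order
# (tidyr::crossing() would sort, breaking positional correspondence)
expand_rows <- function(coeffs, ...) {
  vals <- list(...)
  stopifnot(length(vals) == 1)
  v <- vals[[1]]
  out <- dplyr::as_tibble(coeffs)[rep(seq_len(nrow(coeffs)), each = length(v)), ]
  out[[names(vals)]] <- rep(v, times = nrow(coeffs))
  out
}

# log in an arbitrary base; base may be the string "e" or a number
resolve_base <- function(log_base) {
  if (identical(log_base, "e")) return(exp(1))
  if (!is.numeric(log_base) || length(log_base) != 1 || !is.finite(log_base) || log_base <= 1) {
    abort("`log_base` must be a number > 1 (typically 10) or \"e\".", class = "allovf_validation_error")
  }
  log_base
}

check_coefficients <- function(coeffs, arg = "coeffs") {
  if (!is.data.frame(coeffs)) {
    abort(sprintf("`%s` must be a data frame with columns `beta` and `delta`.", arg),
          class = "allovf_validation_error")
  }
  missing_cols <- setdiff(c("beta", "delta"), names(coeffs))
  if (length(missing_cols)) {
    abort(sprintf("`%s` is missing column(s): %s.", arg, paste(missing_cols, collapse = ", ")),
          class = "allovf_validation_error")
  }
  if (nrow(coeffs) == 0) {
    abort(sprintf("`%s` must contain at least one row.", arg), class = "allovf_validation_error")
  }
  if (!all(is.finite(coeffs$beta)) || !all(is.finite(coeffs$delta))) {
    abort("Coefficients `beta` and `delta` must all be finite.", class = "allovf_validation_error")
  }
  if ("follow_up_months" %in% names(coeffs)) {
    fu <- coeffs$follow_up_months
    if (any(!is.na(fu) & fu <= 0)) {
      abort("`follow_up_months`, when present, must be > 0.", class = "allovf_validation_error")
    }
  }
  invisible(coeffs)
}

check_curve <- function(curve, arg = "curve", min_points = 2L) {
  if (!is.data.frame(curve)) {
    abort(sprintf("`%s` must be a data frame with columns `st_mm` and `probability_percent`.", arg),
          class = "allovf_validation_error")
  }
  missing_cols <- setdiff(c("st_mm", "probability_percent"), names(curve))
  if (length(missing_cols)) {
    abort(sprintf("`%s` is missing column(s): %s.", arg, paste(missing_cols, collapse = ", ")),
          class = "allovf_validation_error")
  }
  if (nrow(curve) < min_points) {
    abort(sprintf("`%s` needs at least %d points, got %d.", arg, min_points, nrow(curve)),
          class = "allovf_insufficient_data_error")
  }
  if (any(!is.finite(curve$st_mm)) || any(curve$st_mm <= 0)) {
    abort("`st_mm` values must be finite and > 0.", class = "allovf_domain_error")
  }
  if (anyDuplicated(curve$st_mm)) {
    abort("`st_mm` values must be distinct.", class = "allovf_validation_error")
  }
  if (any(!is.finite(curve$probability_percent))) {
    abort("`probability_percent` values must be finite.", class = "allovf_domain_error")
  }
  invisible(curve)
}
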