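#' Read a study curve from a delimited text file
#'
#' Reads a comma-separated file with header `st_mm,probability_percent` (one
#' curve per file) and validates it: at least two rows, distinct positive ST
#' values, finite probabilities.
#'
#' @param path Path to the CSV file.
#' @param label Optional free-text study label attached as a column.
#' @param follow_up_months Optional follow-up horizon in months (> 0),
#'   attached as a column.
#' @return A tibble with columns `st_mm`, `probability_percent` and any
#'   requested annotation columns, sorted by `st_mm`.
#' @seealso [write_study_curve()]
#' @export
read_study_curve <- function(path, label = NULL, follow_up_months = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "allovf_io_error")
  }
  curve <- readr::read_csv(path, col_types = readr::cols(
    st_mm = readr::col_double(),
    probability_percent = readr::col_double()
  ), progress = FALSE)
  probs <- readr::problems(curve)
  if (nrow(probs) > 0) {
    abort(sprintf("Malformed curve file %s (first problem at line %d: %s).",
                  path, probs$row[1] + 1L, probs$expected[1]),
          class = "allovf_parse_error")
  }
  if (nrow(curve) == 0) {
    abort(sprintf("Curve file %s contains no data rows.", path), class = "allovf_parse_error")
  }
  check_curve(curve, arg = path)
  curve <- dplyr::arrange(curve, .data$st_mm)
  if (!is.null(follow_up_months)) {
    if (!is.numeric(follow_up_months) || follow_up_months <= 0) {
      abort("`follow_up_months` must be > 0.", class = "allovf_validation_error")
    }
    curve <- dplyr::mutate(curve, follow_up_months = follow_up_months, .before = 1)
  }
  if (!is.null(label)) curve <- dplyr::mutate(curve, label = as.character(label), .before = 1)
  curve
}

#' Write a study curve to a delimited text file
#'
#' Writes the `st_mm` and `probability_percent` columns as CSV, the format
#' [read_study_curve()] reads back.
#'
#' @param curve Data frame with columns `st_mm` and `probability_percent`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_study_curve <- function(curve, path) {
  check_curve(curve)
  readr::write_csv(curve[, c("st_mm", "probability_percent")], path, progress = FALSE)
  invisible(path)
}

#' Load a table of fitted allometric coefficients
#'
#' Reads a CSV with header `label,follow_up_months,beta,delta` (optionally
#' `adjusted_r_square`). With no `path`, loads the packaged table of the nine
#' published coefficient pairs: the PARAGON-A and GUSTO-IIb study curves at 1
#' and 6 months, their per-horizon means, the 12- and 48-month cohort curves,
#' and the overall average curve (whose `follow_up_months`, spanning 1-48, is
#' recorded as `NA`). The study-specific rows and the overall average row are
#' constants taken as given — the raw per-bin event tables they were fitted
#' to are not publicly available — whereas the per-horizon mean rows are
#' recomputable from the study rows via [mean_curve_refit()].
#'
#' @param path Path to a coefficient CSV; `NULL` (default) for the packaged
#'   table.
#' @return A tibble with columns `label`, `follow_up_months`, `beta`,
#'   `delta` and (if present) `adjusted_r_square`.
#' @examples
#' tab <- load_coefficient_table()
#' dplyr::filter(tab, label == "GUSTO-IIB")
#' @export
load_coefficient_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "published_coefficients.csv", package = "allovf",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "allovf_io_error")
  }
  tab <- readr::read_csv(path, col_types = readr::cols(
    label = readr::col_character(),
    follow_up_months = readr::col_double(),
    .default = readr::col_double()
  ), progress = FALSE)
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    abort(sprintf("Malformed coefficient table %s (first problem at line %d: %s).",
                  path, probs$row[1] + 1L, probs$expected[1]),
          class = "allovf_parse_error")
  }
  if (nrow(tab) == 0) {
    abort(sprintf("Coefficient table %s contains no data rows.", path),
          class = "allovf_parse_error")
  }
  required <- c("label", "follow_up_months", "beta", "delta")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    abort(sprintf("Coefficient table is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "allovf_parse_error")
  }
  key <- paste(tab$label, tab$follow_up_months, sep = "\r")
  if (anyDuplicated(key)) {
    abort("Duplicate (label, follow_up_months) rows in coefficient table.",
          class = "allovf_validation_error")
  }
  check_coefficients(tab, arg = path)
  tab
}
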