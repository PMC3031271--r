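#' Configure a synthetic ST-bin event-rate study
#'
#' Builds the configuration for [generate_study()]: a ground-truth allometric
#' law per follow-up window, the ST bins at which event rates are observed,
#' the cohort size per bin, and the noise model. The generator emulates the
#' shape of published acute-coronary-syndrome event tables: a handful of ST
#' bins (0.5, 1 and 2 mm by default, the 2 mm bin standing in for an open
#' "at least 2 mm" class), event proportions at fixed follow-up horizons, and
#' sampling noise from a finite patient cohort.
#'
#' @param truth Data frame defining the ground-truth law: either log-log
#'   coefficients (`beta`, `delta`, base 10) or mechanistic components
#'   (`alpha`, `beta`, `gamma`, converted via
#'   [components_to_coefficients()]). One row applies to every follow-up
#'   window; multiple rows must carry a `follow_up_months` column covering
#'   `follow_up_months`. The default is a four-horizon family of published
#'   coefficient pairs (1 mo: 0.50/1.01; 6 mo: 0.49/1.16; 12 mo: 0.54/1.56;
#'   48 mo: 0.48/1.79).
#' @param st_bins_mm ST bins in mm; default `c(0.5, 1, 2)`.
#' @param follow_up_months Follow-up horizons in months; default
#'   `c(1, 6, 12, 48)`.
#' @param cohort_size_per_bin Patients observed per ST bin; default 500.
#' @param seed Integer seed fixing the full output; `NULL` uses the current
#'   RNG state.
#' @param noise_model `"binomial"` (default): observed rate = `100 k / n`
#'   with `k ~ Binomial(n, truth/100)`. `"lognormal"`: log10 of the truth is
#'   perturbed by centred Gaussian noise of SD `sigma_log10`.
#' @param sigma_log10 Noise SD on the log10 scale for the lognormal model;
#'   default 0.02.
#'
#' @return A `vf_synth_config` list.
#' @examples
#' cfg <- synthetic_study_config(cohort_size_per_bin = 1000, seed = 7)
#' generate_study(cfg)
#' @export
synthetic_study_config <- function(truth = NULL,
                                   st_bins_mm = c(0.5, 1, 2),
                                   follow_up_months = c(1, 6, 12, 48),
                                   cohort_size_per_bin = 500,
                                   seed = 1L,
                                   noise_model = c("binomial", "lognormal"),
                                   sigma_log10 = 0.02) {
  noise_model <- match.arg(noise_model)
  if (is.null(truth)) {
    truth <- tibble(
      follow_up_months = c(1, 6, 12, 48),
      beta  = c(0.50, 0.49, 0.54, 0.48),
      delta = c(1.01, 1.16, 1.56, 1.79)
    )
  }
  if (all(c("alpha", "gamma") %in% names(truth))) {
    truth <- components_to_coefficients(truth)
  }
  check_coefficients(truth, arg = "truth")
  if (!is.numeric(st_bins_mm) || length(st_bins_mm) == 0 || any(st_bins_mm <= 0) ||
      anyDuplicated(st_bins_mm)) {
    abort("`st_bins_mm` must be distinct positive ST deviations.", class = "allovf_validation_error")
  }
  if (!is.numeric(follow_up_months) || length(follow_up_months) == 0 || any(follow_up_months <= 0)) {
    abort("`follow_up_months` must be positive.", class = "allovf_validation_error")
  }
  if (!is.numeric(cohort_size_per_bin) || length(cohort_size_per_bin) != 1 ||
      cohort_size_per_bin < 1) {
    abort("`cohort_size_per_bin` must be at least 1.", class = "allovf_validation_error")
  }
  st_bins_mm <- sort(st_bins_mm)
  if (nrow(truth) == 1) {
    truth <- tidyr::crossing(dplyr::select(truth, -dplyr::any_of("follow_up_months")),
                             follow_up_months = follow_up_months)
  }
  if (!"follow_up_months" %in% names(truth) ||
      !all(follow_up_months %in% truth$follow_up_months)) {
    abort("Multi-row `truth` must carry `follow_up_months` covering every requested window.",
          class = "allovf_validation_error")
  }
  truth <- dplyr::filter(truth, .data$follow_up_months %in% !!follow_up_months)
  truth_grid <- vf_predict(truth, st_mm = st_bins_mm) |>
    dplyr::rename(truth_percent = "probability_percent")
  if (any(truth_grid$truth_percent > 100 + 1e-12)) {
    abort("Ground-truth probability exceeds 100% at some (bin, window); adjust the truth law or bins.",
          class = "allovf_configuration_error")
  }
  structure(
    list(truth = dplyr::as_tibble(truth), truth_grid = truth_grid,
         st_bins_mm = st_bins_mm, follow_up_months = sort(follow_up_months),
         cohort_size_per_bin = as.integer(round(cohort_size_per_bin)),
         seed = seed, noise_model = noise_model, sigma_log10 = sigma_log10),
    class = "vf_synth_config"
  )
}

#' @export
print.vf_synth_config <- function(x, ...) {
  cat(sprintf("Synthetic ST-bin study: %s noise, %d patients/bin, bins {%s} mm, windows {%s} mo, seed %s\n",
              x$noise_model, x$cohort_size_per_bin,
              paste(x$st_bins_mm, collapse = ", "),
              paste(x$follow_up_months, collapse = ", "),
              if (is.null(x$seed)) "none" else format(x$seed)))
  print(x$truth)
  invisible(x)
}

#' Generate synthetic study curves
#'
#' Draws one observed event-rate curve per follow-up window under the
#' configured ground truth and noise model. With binomial noise an observed
#' bin can have zero events, whose log the fitting pipeline cannot take; such
#' a bin is redrawn once and, if still zero, flagged `excluded = TRUE` (its
#' observed probability is 0 and it should be dropped before fitting).
#' Identical configurations (including `seed`) give identical output.
#'
#' @param config A [synthetic_study_config()] object.
#' @return A tibble with one row per (window, bin): `label`,
#'   `follow_up_months`, `st_mm`, `truth_percent`, `cohort_size`, `events`
#'   (`NA` for lognormal noise), `probability_percent`, `excluded`.
#' @export
generate_study <- function(config) {
  if (!inherits(config, "vf_synth_config")) {
    abort("`config` must come from synthetic_study_config().", class = "allovf_validation_error")
  }
  draw <- function() {
    df <- dplyr::arrange(config$truth_grid, .data$follow_up_months, .data$st_mm)
    n <- config$cohort_size_per_bin
    p <- df$truth_percent / 100
    if (config$noise_model == "binomial") {
      k <- rbinom(length(p), n, p)
      redo <- k == 0
      k[redo] <- rbinom(sum(redo), n, p[redo])
      df$events <- k
      df$probability_percent <- 100 * k / n
      df$excluded <- k == 0
    } else {
      df$events <- NA_integer_
      df$probability_percent <-
        10^(log10(df$truth_percent) + rnorm(length(p), 0, config$sigma_log10))
      df$excluded <- FALSE
    }
    df$cohort_size <- n
    df$label <- sprintf("synthetic-%gmo", df$follow_up_months)
    dplyr::select(df, "label", "follow_up_months", "st_mm", "truth_percent",
                  "cohort_size", "events", "probability_percent", "excluded")
  }
  if (is.null(config$seed)) draw() else withr::with_seed(config$seed, draw())
}

#' Parameter-recovery experiment over replicated synthetic studies
#'
#' Repeatedly generates a synthetic study and refits the allometric law to
#' each follow-up window's curve, summarising how well the fitted exponent
#' and intercept recover the ground truth. Replicates use independent seeds
#' derived deterministically from `config$seed`, so the whole experiment is
#' reproducible. Windows whose curve cannot be fitted (e.g. fewer than three
#' usable bins after zero-event exclusion) are counted as failed replicates.
#'
#' @param config A [synthetic_study_config()] object (a non-`NULL` seed is
#'   required for reproducibility).
#' @param n_replicates Number of replicate studies (at least 2).
#' @param log_base,resample,range_mm,step_mm Passed to [fit_allometric()].
#' @return A tibble with one row per (follow-up window, parameter):
#'   `follow_up_months`, `parameter` (`"beta"` or `"delta"`), `truth`,
#'   `bias` (mean error), `sd` (sample SD of the estimates), `rmse`
#'   (root-mean-square error, `1/n` divisor), `n_ok`, `n_failed`.
#' @examples
#' cfg <- synthetic_study_config(follow_up_months = 1, seed = 42)
#' recovery_experiment(cfg, n_replicates = 20)
#' @export
recovery_experiment <- function(config, n_replicates, log_base = 10,
                                resample = TRUE, range_mm = c(0.5, 2),
                                step_mm = 0.025) {
  if (!inherits(config, "vf_synth_config")) {
    abort("`config` must come from synthetic_study_config().", class = "allovf_validation_error")
  }
  if (!is.numeric(n_replicates) || length(n_replicates) != 1 || n_replicates < 2) {
    abort("`n_replicates` must be at least 2.", class = "allovf_validation_error")
  }
  if (is.null(config$seed)) {
    abort("`config$seed` must be set for a reproducible experiment.",
          class = "allovf_validation_error")
  }
  n_replicates <- as.integer(n_replicates)
  rep_seeds <- withr::with_seed(config$seed,
                                sample.int(.Machine$integer.max - 1L, n_replicates))
  fit_one_window <- function(curve) {
    curve <- dplyr::filter(curve, !.data$excluded)
    tryCatch({
      fit <- fit_allometric(curve, log_base = log_base, resample = resample,
                            range_mm = range_mm, step_mm = step_mm)
      tibble(beta = fit$coefficients$beta, delta = fit$coefficients$delta, ok = TRUE)
    }, error = function(e) tibble(beta = NA_real_, delta = NA_real_, ok = FALSE))
  }
  estimates <- purrr::map_dfr(seq_len(n_replicates), function(i) {
    cfg_i <- config
    cfg_i$seed <- rep_seeds[i]
    generate_study(cfg_i) |>
      dplyr::group_by(.data$follow_up_months) |>
      dplyr::group_modify(~ fit_one_window(.x)) |>
      dplyr::ungroup() |>
      dplyr::mutate(replicate = i)
  })
  truth_long <- config$truth |>
    dplyr::select("follow_up_months", "beta", "delta") |>
    tidyr::pivot_longer(c("beta", "delta"), names_to = "parameter", values_to = "truth")
  estimates |>
    tidyr::pivot_longer(c("beta", "delta"), names_to = "parameter", values_to = "estimate") |>
    dplyr::left_join(truth_long, by = c("follow_up_months", "parameter")) |>
    dplyr::mutate(error = .data$estimate - .data$truth) |>
    dplyr::group_by(.data$follow_up_months, .data$parameter) |>
    dplyr::summarise(
      truth = .data$truth[1],
      bias = mean(.data$error[.data$ok]),
      sd = sd(.data$estimate[.data$ok]),
      rmse = sqrt(mean(.data$error[.data$ok]^2)),
      n_ok = sum(.data$ok),
      n_failed = sum(!.data$ok),
      .groups = "drop"
    )
}
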