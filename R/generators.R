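#' Default Hill parameters of the proliferation assay
#'
#' Fitted coefficients of the reference (full-length receptor) and mutant
#' (truncated receptor) dose-response curves, with the shared baseline
#' `y0 = 0.349`. These are the defaults of [generate_dose_response()].
#'
#' @return A list with `hill_curve`s `ref` and `mut`.
#' @examples
#' hill_defaults()$ref
#' @export
hill_defaults <- function() {
  list(
    ref = hill_curve(0.349, 0.449, 20.802, -23.309, 11.149),
    mut = hill_curve(0.349, 0.479, 21.075, -23.278, 28.255)
  )
}

#' Generate a synthetic proliferation (MTT) dose-response data set
#'
#' Emulates the absorbance readout of the proliferation assay: Hill-curve
#' means for the reference and mutant receptor lines plus independent
#' Gaussian plate noise, in triplicate per dose. With `noise_sd = 0` the
#' exact curve values are returned.
#'
#' @param doses Dose grid in ng/ml (default 13 log-spaced doses, 1e-3 to 100).
#' @param replicates Replicates per dose (default 3).
#' @param noise_sd Absorbance noise SD (default 0.02).
#' @param ref_curve,mut_curve `hill_curve`s for the two arms; defaults are
#'   [hill_defaults()].
#' @param ref_label,mut_label Group labels.
#' @param seed Optional integer seed.
#' @return Tibble with columns `group`, `dose`, `replicate`, `absorbance`.
#' @examples
#' generate_dose_response(seed = 1)
#' @export
generate_dose_response <- function(doses = 10^seq(-3, 2, length.out = 13),
                                   replicates = 3, noise_sd = 0.02,
                                   ref_curve = hill_defaults()$ref,
                                   mut_curve = hill_defaults()$mut,
                                   ref_label = "TypeI", mut_label = "D715",
                                   seed = NULL) {
  check_number(doses, "doses", lower = 1e-12, allow_vector = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  stopifnot(replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  one <- function(curve, label) {
    grid <- tidyr::expand_grid(dose = doses, replicate = seq_len(replicates))
    mu <- predict(curve, grid$dose)
    tibble(group = label, dose = grid$dose, replicate = grid$replicate,
           absorbance = mu + rnorm(nrow(grid), 0, noise_sd))
  }
  bind_rows(one(ref_curve, ref_label), one(mut_curve, mut_label))
}

#' Generate a synthetic G1/G0 time series
#'
#' Emulates the flow-cytometry cell-cycle readout: after release from a
#' starvation block both lines start at a high G1/G0 percentage and relax over
#' a short transient to their asymptotic values (`phi_ref`, `phi_mut`,
#' separated by ~6 percentage points at the high G-CSF dose). Each time point
#' measures `cells` cells, so the observed percentage carries binomial noise
#' that shrinks as the cell count grows.
#'
#' @param phi_ref,phi_mut Asymptotic G1/G0 percentages (0-100); defaults give
#'   the 6.05 percentage-point separation of the 100 ng/ml condition.
#' @param times_h Sampling times in hours.
#' @param transient_h Relaxation time constant of the initial transient
#'   (hours); points at or after 1 h are effectively post-transient.
#' @param start_pct Common G1/G0 percentage at release (default 85).
#' @param cells Cells measured per time point (default 1e4).
#' @param ref_label,mut_label Group labels.
#' @param seed Optional integer seed.
#' @return Tibble with columns `group`, `time_h`, `n_cells`, `g1_count`,
#'   `g1_pct`.
#' @examples
#' generate_g1_series(seed = 1)
#' @export
generate_g1_series <- function(phi_ref = 70, phi_mut = 63.95,
                               times_h = seq(0, 48, by = 2),
                               transient_h = 0.5, start_pct = 85,
                               cells = 1e4,
                               ref_label = "TypeI", mut_label = "D715",
                               seed = NULL) {
  check_number(phi_ref, "phi_ref", lower = 1e-6, upper = 100 - 1e-6)
  check_number(phi_mut, "phi_mut", lower = 1e-6, upper = 100 - 1e-6)
  if (!is.null(seed)) set.seed(seed)
  one <- function(target, label) {
    mean_pct <- target + (start_pct - target) * exp(-times_h / transient_h)
    cnt <- rbinom(length(times_h), size = cells, prob = mean_pct / 100)
    tibble(group = label, time_h = times_h, n_cells = cells,
           g1_count = cnt, g1_pct = 100 * cnt / cells)
  }
  bind_rows(one(phi_ref, ref_label), one(phi_mut, mut_label))
}

#' Post-transient G1/G0 fractions from a generated series
#'
#' Mean G1/G0 fraction (0-1 scale) per group over the post-transient window,
#' the quantities fed into [estimate_selection()].
#'
#' @param data Output of [generate_g1_series()].
#' @param after_h Discard time points before this (default 1 h).
#' @return Tibble with columns `group`, `phi`.
#' @examples
#' g1_series_phi(generate_g1_series(seed = 1))
#' @export
g1_series_phi <- function(data, after_h = 1) {
  stopifnot(all(c("group", "time_h", "g1_pct") %in% names(data)))
  data |>
    dplyr::filter(.data$time_h >= after_h) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(phi = mean(.data$g1_pct) / 100, .groups = "drop")
}
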