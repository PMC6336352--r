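#' Exponential growth rate from interdivision time and division efficiency
#'
#' In the constant-interdivision-time cell-cycle model, a population whose
#' cells divide every `T` days with division efficiency `alpha` (probability
#' that a progeny cell re-enters the cycle) grows exponentially at rate
#' \deqn{\lambda = \ln(2\alpha) / T.}
#'
#' @param T Interdivision time in days (> 0).
#' @param alpha Division efficiency in (0.5, 1]; `2 * alpha > 1` is required
#'   for growth.
#' @return Growth rate per day.
#' @examples
#' growth_rate(4, 1) # 0.173 / day
#' @export
growth_rate <- function(T = 4, alpha = 1) {
  check_number(T, "T", lower = 1e-12)
  check_number(alpha, "alpha", allow_vector = TRUE)
  if (any(2 * alpha <= 1)) abort("need 2 * alpha > 1 (non-growing population)")
  log(2 * alpha) / T
}

#' Asymptotic G1/G0 fraction of an exponentially growing population
#'
#' Fraction of cells residing in the G1/G0 phase (residence time `T1`) in a
#' population growing at rate `lambda` with interdivision time `T`:
#' \deqn{\varphi = \frac{1 - e^{-\lambda T_1}}{1 - e^{-\lambda T}}.}
#'
#' @param lambda Growth rate per day.
#' @param T1 G1/G0 residence time, `0 < T1 <= T`.
#' @param T Interdivision time.
#' @return G1/G0 fraction in (0, 1].
#' @examples
#' g1_fraction(growth_rate(4, 1), 0.6215 * 4, 4) # ~0.70
#' @export
g1_fraction <- function(lambda, T1, T = 4) {
  check_number(lambda, "lambda", lower = 1e-12)
  check_number(T, "T", lower = 1e-12)
  check_number(T1, "T1", lower = 0, upper = T, allow_vector = TRUE)
  -expm1(-lambda * T1) / -expm1(-lambda * T)
}

#' G1 share of the cell cycle from an observed G1/G0 fraction
#'
#' Algebraic inverse of [g1_fraction()]: solves for `psi = T1 / T` given the
#' observed fraction `phi` and the division efficiency `alpha`,
#' \deqn{\psi = \frac{\ln\{1 - \varphi\,[1 - (2\alpha)^{-1}]\}}{-\ln(2\alpha)}.}
#'
#' @param phi Observed G1/G0 fraction in (0, 1).
#' @param alpha Division efficiency (`2 * alpha > 1`).
#' @return `psi = T1/T` in (0, 1).
#' @examples
#' psi_from_phi(0.7) # 0.621
#' @export
psi_from_phi <- function(phi, alpha = 1) {
  check_number(phi, "phi", lower = 0, upper = 1, allow_vector = TRUE)
  check_number(alpha, "alpha", allow_vector = TRUE)
  if (any(2 * alpha <= 1)) abort("need 2 * alpha > 1")
  arg <- 1 - phi * (1 - 1 / (2 * alpha))
  if (any(arg <= 0)) abort("phi * (1 - (2 alpha)^-1) >= 1: log argument not positive")
  log(arg) / (-log(2 * alpha))
}

#' G1-phase shortening between two cell populations
#'
#' Under the assumption that the entire interdivision-time difference between
#' a reference and a faster ("asterisked") population is a shortening of the
#' G1/G0 phase, \eqn{T - T^* = T_1 - T_1^* = \Delta}, the shortening is
#' \deqn{\Delta = \frac{\psi - \psi^*}{1 - \psi^*}\, T.}
#'
#' @param psi,psi_star G1 shares (`T1/T` ratios) of the reference and mutant
#'   populations; `psi_star < 1`.
#' @param T Reference interdivision time in days.
#' @return `Delta` in days.
#' @examples
#' delta_from_psi(0.6215, 0.567, 4) # ~0.503
#' @export
delta_from_psi <- function(psi, psi_star, T = 4) {
  check_number(psi, "psi", lower = 0, upper = 1, allow_vector = TRUE)
  check_number(psi_star, "psi_star", lower = 0, upper = 1 - 1e-12,
               allow_vector = TRUE)
  check_number(T, "T", lower = 1e-12)
  (psi - psi_star) / (1 - psi_star) * T
}

#' Selection coefficient from G1/G0 cell-cycle measurements
#'
#' Chains the cell-cycle estimator: observed G1/G0 fractions are inverted to
#' G1 shares (`psi`, `psi_star`), the G1 shortening `Delta` follows, growth
#' rates are `lambda = ln(2 alpha)/T` and
#' `lambda* = ln(2 alpha*)/(T - Delta)`, and the Moran selection coefficient
#' is the relative growth-rate excess
#' \deqn{s = r - 1 = (\lambda^* - \lambda)/\lambda.}
#'
#' The mutant arm may be specified either by its observed fraction `phi_star`
#' or directly by its G1 share `psi_star` (the published worked example quotes
#' `psi_star = 0.567`, which does not correspond exactly to its quoted
#' `phi_star = 0.66`; both entry points are therefore provided).
#'
#' @param phi Reference G1/G0 fraction in (0, 1).
#' @param phi_star Mutant G1/G0 fraction (used if `psi_star` is `NULL`).
#' @param psi_star Mutant G1 share, overriding `phi_star`.
#' @param T Interdivision time of the reference population, days (default 4).
#' @param alpha,alpha_star Division efficiencies of the two populations.
#' @return A one-row tibble of class `selection_estimate` with columns `phi`,
#'   `phi_star`, `psi`, `psi_star`, `Delta`, `lambda`, `lambda_star`, `s`.
#' @examples
#' estimate_selection(phi = 0.70, psi_star = 0.567) # s = 0.144
#' @export
estimate_selection <- function(phi, phi_star = NULL, psi_star = NULL,
                               T = 4, alpha = 1, alpha_star = alpha) {
  check_number(phi, "phi", lower = 1e-9, upper = 1 - 1e-9)
  if (is.null(psi_star)) {
    if (is.null(phi_star)) abort("supply either `phi_star` or `psi_star`")
    check_number(phi_star, "phi_star", lower = 1e-9, upper = 1 - 1e-9)
    psi_star <- psi_from_phi(phi_star, alpha_star)
  }
  psi <- psi_from_phi(phi, alpha)
  Delta <- delta_from_psi(psi, psi_star, T)
  if (Delta >= T) abort("Delta >= T: mutant interdivision time not positive")
  lambda <- growth_rate(T, alpha)
  lambda_star <- growth_rate(T - Delta, alpha_star)
  out <- tibble(
    phi = phi, phi_star = if (is.null(phi_star)) NA_real_ else phi_star,
    psi = psi, psi_star = psi_star, Delta = Delta,
    lambda = lambda, lambda_star = lambda_star,
    s = lambda_star / lambda - 1
  )
  class(out) <- c("selection_estimate", class(out))
  out
}

#' Tidy a selection estimate
#'
#' @param x A `selection_estimate`.
#' @param ... Unused.
#' @return Long tibble of the inference chain's intermediates.
#' @method tidy selection_estimate
#' @export
tidy.selection_estimate <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(unclass(x)), dplyr::everything(),
                      names_to = "quantity", values_to = "value")
}
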