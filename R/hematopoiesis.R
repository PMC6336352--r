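#' Body growth curve from birth to adulthood
#'
#' Monotone body-weight curve used to scale the marrow stem/progenitor pool
#' with age. Postnatal weights follow a Hyman-filtered monotone cubic spline
#' through standard pediatric reference weights from `birth_weight` (3.4 kg)
#' to a plateau at `adult_weight` (75 kg) around age 23; the exact published
#' parameterisation of the pediatric growth formula is not reproduced here, so
#' the curve is pluggable via `knots`. For negative ages (the last ~90 days of
#' gestation, when marrow hematopoiesis is active) the weight decays
#' exponentially below `birth_weight` at `fetal_rate`, chosen by default so
#' that the implied cell pool ramps geometrically from `n0` cells at
#' `fetal_onset_days` to the birth pool — consistent with the exponential
#' fetal expansion model.
#'
#' @param birth_weight,adult_weight Weight endpoints in kg.
#' @param knots Two-column matrix (age_days, kg) of postnatal reference
#'   points; must be monotone. Defaults span birth to the adult plateau.
#' @param n0 Initiating fetal cell count used to set the default fetal ramp.
#' @param fetal_onset_days Age (negative) at which marrow hematopoiesis
#'   starts; default -90.
#' @param cells_per_kg Pool density used for the fetal ramp default.
#' @return An object of class `body_growth_curve`.
#' @examples
#' curve <- body_growth_curve()
#' body_weight(c(0, 365, 7300), curve)
#' @export
body_growth_curve <- function(birth_weight = 3.4, adult_weight = 75,
                              knots = NULL, n0 = 1, fetal_onset_days = -90,
                              cells_per_kg = scn_constants()$cells_per_kg) {
  check_number(birth_weight, "birth_weight", lower = 0.1)
  check_number(adult_weight, "adult_weight", lower = birth_weight)
  if (is.null(knots)) {
    knots <- cbind(
      age_days = c(0, 182, 365, 730, 1460, 2555, 3650, 4745, 5475,
                   6570, 7300, 8395, 12000, 20000),
      kg = c(3.4, 7.8, 10, 12.5, 16.5, 22, 32, 45, 55,
             66, 72, 75, 75, 75)
    )
    # affine rescale if non-default endpoints requested
    knots[, 2] <- birth_weight +
      (knots[, 2] - 3.4) * (adult_weight - birth_weight) / (75 - 3.4)
  }
  if (any(diff(knots[, 2]) < 0)) abort("`knots` weights must be nondecreasing")
  # Hyman filter needs strictly monotone y; collapse the plateau to its start
  iplat <- which(knots[, 2] >= max(knots[, 2]))[1]
  fit_knots <- knots[seq_len(iplat), , drop = FALSE]
  fn <- if (iplat >= 2L) {
    splinefun(fit_knots[, 1], fit_knots[, 2], method = "hyman")
  } else {
    function(x) rep(adult_weight, length(x)) # flat curve
  }
  plateau_age <- fit_knots[iplat, 1]
  fetal_rate <- log(cells_per_kg * birth_weight / n0) / abs(fetal_onset_days)
  structure(
    list(weight_fn = fn, plateau_age = plateau_age,
         birth_weight = birth_weight, adult_weight = adult_weight,
         fetal_rate = fetal_rate, fetal_onset_days = fetal_onset_days,
         knots = knots),
    class = "body_growth_curve"
  )
}

#' Evaluate a body growth curve
#'
#' @param age_days Age in days; negative ages use the fetal ramp.
#' @param curve A [body_growth_curve()] object.
#' @return Body weight in kg (vectorised).
#' @export
body_weight <- function(age_days, curve = body_growth_curve()) {
  stopifnot(inherits(curve, "body_growth_curve"))
  w <- numeric(length(age_days))
  neg <- age_days < 0
  w[neg] <- curve$birth_weight * exp(curve$fetal_rate * age_days[neg])
  if (any(!neg)) {
    a <- pmin(age_days[!neg], curve$plateau_age)
    w[!neg] <- pmin(curve$weight_fn(a), curve$adult_weight)
  }
  w
}

# Default age profile of the HSC interdivision time Tp(t) in days: days-scale
# around birth, lengthening to hundreds of days in adults (telomere-based
# estimates). Monotone spline in log(Tp).
default_tp_profile <- function() {
  ages <- c(-90, 0, 182, 365, 1095, 1825, 3650, 6570, 14610)
  tp <- c(1, 2.5, 12, 30, 60, 100, 180, 280, 300)
  fn <- splinefun(ages, log(tp), method = "hyman")
  function(age_days) {
    exp(fn(pmin(pmax(age_days, -90), 14610)))
  }
}

#' Calibrate the age-dependent compartment schedule
#'
#' Solves pointwise for the HSC self-renewal probability `c(t)` and the CMP
#' self-renewal probability `d(t)` such that the HSC pool `P(t)` and CMP pool
#' `C(t)` track `hsc_fraction` and `1 - hsc_fraction` of the target pool
#' `cells_per_kg * weight(t)`, given a monotone HSC-slowing profile
#' `Tp(t) = 1/a(t)` and a fixed CMP proliferation rate `b`. The governing
#' expectation equations are
#' \deqn{dP/dt = (2c - 1)\,a\,P, \qquad
#'       dC/dt = 2(1 - c)\,a\,m\,P + (2d - 1)\,b\,C,}
#' with `m` the fraction of committed flux entering the granulocyte lineage,
#' so the calibration is
#' `c = (1 + g/a)/2` and `d = (1 + (g - 2(1-c) a m P/C)/b)/2`, `g` being the
#' per-capita growth rate of the target pool.
#'
#' @param curve A [body_growth_curve()].
#' @param hsc_fraction HSC share of the pooled HSC + CMP density (default
#'   1e-3; downstream results depend only on `C(t)` and are insensitive to
#'   this within wide bounds).
#' @param tp_profile Function of age (days) returning the HSC interdivision
#'   time in days; default spans ~1 d prenatally to ~300 d in adults.
#' @param b CMP proliferation rate per day (default 0.25, a 4-day cycle).
#' @param m Granulocyte-lineage fraction of committed flux (default 1/4).
#' @param cells_per_kg Target pool density (default 1.98e8 cells/kg).
#' @param age_grid Ages (days) at which to calibrate; default is daily through
#'   the first year and every 5 days to age 40 yr, starting at -90 d.
#' @return A tibble of class `compartment_schedule` with columns `age_days`,
#'   `weight`, `target`, `P`, `C`, `a`, `b`, `c`, `d`, `m`, `betaG`.
#' @examples
#' sched <- calibrate_schedule()
#' range(sched$c)
#' @export
calibrate_schedule <- function(curve = body_growth_curve(),
                               hsc_fraction = 1e-3,
                               tp_profile = default_tp_profile(),
                               b = 0.25, m = 0.25,
                               cells_per_kg = scn_constants()$cells_per_kg,
                               age_grid = NULL) {
  check_number(hsc_fraction, "hsc_fraction", lower = 1e-9, upper = 0.5)
  check_number(b, "b", lower = 1e-6)
  check_number(m, "m", lower = 1e-9, upper = 1)
  if (is.null(age_grid)) {
    # refined around birth, where the growth rate is discontinuous
    age_grid <- c(seq(curve$fetal_onset_days, -1, by = 1),
                  seq(-0.5, -0.05, by = 0.05),
                  seq(0, 365, by = 1),
                  seq(370, 14610, by = 5))
  }
  weight <- body_weight(age_grid, curve)
  target <- cells_per_kg * weight
  P <- hsc_fraction * target
  C <- (1 - hsc_fraction) * target
  # growth rate of the target pool; the fetal ramp meets the postnatal curve
  # with a kink at birth, so differentiate the two segments separately
  g <- numeric(length(age_grid))
  pre <- age_grid < 0
  if (sum(pre) >= 3) g[pre] <- finite_diff(age_grid[pre], log(target[pre]))
  g[!pre] <- finite_diff(age_grid[!pre], log(target[!pre]))
  a <- 1 / tp_profile(age_grid)
  c_t <- (1 + g / a) / 2
  influx <- 2 * (1 - c_t) * a * m * P / C
  d_t <- (1 + (g - influx) / b) / 2
  bad <- c_t < -0.02 | c_t > 1.02 | d_t < -0.02 | d_t > 1.02
  if (any(bad)) {
    abort(sprintf(
      "infeasible tracking: c or d outside [0, 1] at age %g d (c = %.3f, d = %.3f)",
      age_grid[which(bad)[1]], c_t[which(bad)[1]], d_t[which(bad)[1]]))
  }
  clip <- c_t < 0 | c_t > 1 | d_t < 0 | d_t > 1
  if (any(clip)) {
    warn(sprintf("c/d clipped to [0, 1] at %d of %d ages",
                 sum(clip), length(clip)))
    c_t <- pmin(pmax(c_t, 0), 1)
    d_t <- pmin(pmax(d_t, 0), 1)
  }
  out <- tibble(
    age_days = age_grid, weight = weight, target = target,
    P = P, C = C, a = a, b = b, c = c_t, d = d_t, m = m,
    betaG = 2 * (1 - d_t) * b * C
  )
  class(out) <- c("compartment_schedule", class(out))
  attr(out, "hsc_fraction") <- hsc_fraction
  attr(out, "cells_per_kg") <- cells_per_kg
  out
}

#' Integrate the compartment equations over age
#'
#' Deterministic, tolerance-controlled integration of the two-compartment
#' expectation equations (see [calibrate_schedule()]) with the time-varying
#' rates interpolated from a schedule. Starting from the schedule's initial
#' `P` and `C`, returns the HSC count, CMP count and granulocyte production
#' rate `betaG(t) = 2(1 - d) b C` along the age grid.
#'
#' @param schedule A `compartment_schedule` (from [calibrate_schedule()]) or
#'   any data frame with columns `age_days`, `a`, `b`, `c`, `d`, `m`, `P`, `C`
#'   (initial conditions taken from the first row).
#' @param ages Output ages (days); defaults to the schedule grid.
#' @param rtol,atol Integration tolerances passed to [deSolve::ode()].
#' @return A tibble of class `compartment_trajectory` with columns `age_days`,
#'   `P`, `C`, `betaG`.
#' @examples
#' traj <- integrate_compartments(calibrate_schedule())
#' @export
integrate_compartments <- function(schedule, ages = NULL,
                                   rtol = 1e-8, atol = 1e-6) {
  need <- c("age_days", "a", "b", "c", "d", "m", "P", "C")
  if (!all(need %in% names(schedule))) {
    abort(paste("`schedule` must have columns:", paste(need, collapse = ", ")))
  }
  if (is.null(ages)) ages <- schedule$age_days
  a_fn <- approxfun(schedule$age_days, schedule$a, rule = 2)
  c_fn <- approxfun(schedule$age_days, schedule$c, rule = 2)
  d_fn <- approxfun(schedule$age_days, schedule$d, rule = 2)
  b_fn <- approxfun(schedule$age_days, schedule$b, rule = 2)
  m_fn <- approxfun(schedule$age_days, schedule$m, rule = 2)
  deriv <- function(t, y, parms) {
    a <- a_fn(t); cc <- c_fn(t); d <- d_fn(t); b <- b_fn(t); m <- m_fn(t)
    dP <- (2 * cc - 1) * a * y[1]
    dC <- 2 * (1 - cc) * a * m * y[1] + (2 * d - 1) * b * y[2]
    list(c(dP, dC))
  }
  sol <- deSolve::ode(
    y = c(P = schedule$P[1], C = schedule$C[1]),
    times = ages, func = deriv, parms = NULL,
    rtol = rtol, atol = atol
  )
  sol <- as.data.frame(sol)
  if (any(sol$P < 0) || any(sol$C < 0)) {
    bad_age <- sol$time[which(sol$P < 0 | sol$C < 0)[1]]
    abort(sprintf("schedule drives a compartment negative at age %g d", bad_age))
  }
  out <- tibble(
    age_days = sol$time, P = sol$P, C = sol$C,
    betaG = 2 * (1 - d_fn(sol$time)) * b_fn(sol$time) * sol$C
  )
  class(out) <- c("compartment_trajectory", class(out))
  out
}

#' Plot a compartment trajectory
#'
#' Log-log age trajectories of the HSC count, CMP count and daily granulocyte
#' output, mirroring the usual presentation of hematopoiesis models.
#'
#' @param object A `compartment_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot compartment_trajectory
#' @export
autoplot.compartment_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::filter(as_tibble(object), .data$age_days > 0),
    c("P", "C", "betaG"),
    names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$age_days / 365, .data$value,
                                   colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "age (years)", y = "cells (or cells/day)",
                  colour = NULL)
}
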