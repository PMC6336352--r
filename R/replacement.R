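# Hybrid stochastic/deterministic Moran process with variable population
# size, recurrent mutation, and selection switched on at G-CSF start.

# Advance the deterministic mutant frequency f from t_from to t_to under
# df/dt = b [ s f (1 - f) + mu (1 - f) ]. For f >> mu/s the mutation term is
# negligible and the logistic closed form is used; in the neutral window the
# linear mutation drift is used.
advance_frequency <- function(f, t_from, t_to, s, b, mu) {
  dt <- t_to - t_from
  if (dt <= 0) return(f)
  if (s > 0 && f > 100 * mu / max(s, 1e-12)) {
    odds <- f / (1 - f) * exp(s * b * dt)
    odds / (1 + odds)
  } else {
    min(f + b * (s * f * (1 - f) + mu * (1 - f)) * dt, 1)
  }
}

# Time (days) for the logistic frequency to travel from f0 to f1 at rate s*b.
logistic_time <- function(f0, f1, s, b) {
  (log(f1 / (1 - f1)) - log(f0 / (1 - f0))) / (s * b)
}

#' Simulate replacement of wild-type CMPs by the truncation mutant
#'
#' Moran-type dynamics of the mutant clone in the CMP compartment whose size
#' `N(t)` follows a calibrated trajectory. A hybrid scheme is used, since a
#' per-cell simulation at N ~ 1e10 is infeasible:
#'
#' * **Stochastic phase** — while the mutant count `M` is below
#'   `min(exact_threshold, frac_threshold * N(t))`, the mutant lineage is a
#'   tau-leaping continuous-time branching process with per-capita birth rate
#'   `b (1 + s(t))`, death rate `b - d ln N/dt` (so neutral lineages are
#'   critical at constant `N` and track the population's net growth when `N`
#'   changes), plus Poisson influx of newly mutated cells at rate
#'   `mu b (N - M)` (recurrent mutation at wild-type divisions).
#' * **Deterministic phase** — once `M` crosses the threshold, the mutant
#'   frequency follows `df/dt = b[s(t) f(1-f) + mu(1-f)]`, whose logistic
#'   closed form gives the replacement age directly.
#'
#' Selection is a step function: `s(t) = 0` before `t_gcsf` (G-CSF start,
#' default 182.5 d = 6 months) and `s_gcsf` after. Replacement is declared
#' when the mutant frequency reaches `replacement_fraction` (default 0.99;
#' pass 1 for full fixation, operationalised as `1 - 0.5/N`). With recurrent
#' mutation and positive selection fixation is certain; only its timing is
#' random. Runs that do not replace within `t_max_yr` are returned censored.
#'
#' @param trajectory A `compartment_trajectory` (or any data frame with
#'   columns `age_days` and `C`) covering the simulated age range.
#' @param mu Mutation probability per cell division.
#' @param s_gcsf Selection coefficient of the mutant under G-CSF.
#' @param t_gcsf Treatment start age in days (default 182.5).
#' @param m0 Initial mutant count at `t_start` (default 0).
#' @param exact_threshold Mutant count above which the deterministic engine
#'   takes over (default 1e4).
#' @param frac_threshold Cap on the switch threshold as a fraction of `N(t)`
#'   (default 0.01), keeping the branching approximation in its
#'   small-frequency regime at small population sizes.
#' @param replacement_fraction Mutant fraction defining replacement.
#' @param b CMP division rate per day (default 0.25).
#' @param dt Tau-leap step in days (default 0.5).
#' @param t_start Start age in days; defaults to the start of the trajectory.
#' @param t_max_yr Simulation horizon in years (default 40).
#' @param seed Optional integer seed.
#' @return An object of class `replacement_sim`: a list with
#'   `age_at_replacement_yr` (NA if censored), `censored`,
#'   `mutant_count_age1`, `engine_switch_age_days`, `m_final`, `f_final`,
#'   and a coarse `series` tibble of the stochastic phase.
#' @examples
#' traj <- integrate_compartments(calibrate_schedule())
#' sim <- simulate_replacement(traj, mu = 2.5e-9, s_gcsf = 0.02, seed = 1)
#' sim$age_at_replacement_yr
#' @export
simulate_replacement <- function(trajectory, mu, s_gcsf,
                                 t_gcsf = 182.5, m0 = 0,
                                 exact_threshold = 1e4,
                                 frac_threshold = 0.01,
                                 replacement_fraction = 0.99,
                                 b = 0.25, dt = 0.5,
                                 t_start = NULL, t_max_yr = 40,
                                 seed = NULL) {
  stopifnot(all(c("age_days", "C") %in% names(trajectory)))
  check_number(mu, "mu", lower = 0, upper = 1)
  check_number(s_gcsf, "s_gcsf", lower = -0.99)
  check_number(replacement_fraction, "replacement_fraction",
               lower = 1e-6, upper = 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(t_start)) t_start <- min(trajectory$age_days)
  t_max <- t_max_yr * 365
  times <- seq(t_start, t_max, by = dt)
  N_fn <- approxfun(trajectory$age_days, trajectory$C, rule = 2)
  lg <- finite_diff(trajectory$age_days, log(trajectory$C))
  g_fn <- approxfun(trajectory$age_days, lg, rule = 2)
  # outside the trajectory range the population is held flat
  g_fn_safe <- function(t) ifelse(t < min(trajectory$age_days) |
                                    t > max(trajectory$age_days), 0, g_fn(t))
  Nt <- N_fn(times)
  gam <- g_fn_safe(times)
  st <- ifelse(times >= t_gcsf, s_gcsf, 0)
  thr <- pmin(exact_threshold, pmax(frac_threshold * Nt, 10))
  res <- cpp_branch_path(Nt, gam, st, thr, mu, b, dt, m0)
  path <- res$path
  sw <- res$switch_idx
  f_target <- if (replacement_fraction >= 1) {
    1 - 0.5 / max(Nt)
  } else {
    replacement_fraction
  }

  idx_age1 <- which(times >= 365)[1]
  mutant_count_age1 <- if (!is.na(idx_age1) && idx_age1 <= length(path) &&
                           (sw == 0 || idx_age1 < sw)) {
    path[idx_age1]
  } else {
    NA_real_ # filled below if the deterministic engine was already active
  }

  age_repl <- NA_real_
  censored <- TRUE
  engine_switch_age <- NA_real_
  f_final <- NA_real_
  m_final <- res$M

  # replacement reached inside the stochastic phase itself (possible when the
  # switch threshold exceeds the replacement count at small N)
  hit <- which(!is.na(path) & path >= f_target * Nt)
  if (length(hit) > 0 && (sw == 0 || hit[1] < sw)) {
    age_repl <- times[hit[1]] / 365
    censored <- FALSE
    f_final <- path[hit[1]] / Nt[hit[1]]
    m_final <- path[hit[1]]
    if (sw > 0) engine_switch_age <- times[sw]
    keep <- seq(1, hit[1], by = max(1, round(30 / dt)))
    return(structure(
      list(age_at_replacement_yr = age_repl, censored = censored,
           mutant_count_age1 = mutant_count_age1,
           engine_switch_age_days = engine_switch_age,
           m_final = m_final, f_final = f_final,
           params = list(mu = mu, s_gcsf = s_gcsf, t_gcsf = t_gcsf, b = b,
                         dt = dt, exact_threshold = exact_threshold,
                         frac_threshold = frac_threshold,
                         replacement_fraction = replacement_fraction,
                         t_max_yr = t_max_yr),
           series = tibble(age_days = times[keep], mutants = path[keep])),
      class = "replacement_sim"
    ))
  }

  if (sw > 0) {
    t_sw <- times[sw]
    engine_switch_age <- t_sw
    f <- res$M / N_fn(t_sw)
    # carry the (nearly frequency-preserving) neutral window to t_gcsf
    if (t_sw < t_gcsf) {
      if (is.na(mutant_count_age1) && 365 >= t_sw && 365 < t_gcsf) {
        mutant_count_age1 <- f * N_fn(365)
      }
      f <- advance_frequency(f, t_sw, t_gcsf, 0, b, mu)
      t_sw <- t_gcsf
    }
    if (is.na(mutant_count_age1) && !is.na(idx_age1)) {
      f1 <- advance_frequency(f, t_sw, 365, if (365 >= t_gcsf) s_gcsf else 0,
                              b, mu)
      mutant_count_age1 <- f1 * N_fn(365)
    }
    if (s_gcsf > 0 && f < f_target) {
      t_repl <- t_sw + logistic_time(f, f_target, s_gcsf, b)
      if (t_repl <= t_max) {
        age_repl <- t_repl / 365
        censored <- FALSE
      }
      f_final <- if (censored) {
        advance_frequency(f, t_sw, t_max, s_gcsf, b, mu)
      } else {
        f_target
      }
    } else if (f >= f_target) {
      age_repl <- t_sw / 365
      censored <- FALSE
      f_final <- f
    } else {
      f_final <- f
    }
    m_final <- f_final * N_fn(t_max)
  }

  keep <- seq(1, if (sw > 0) sw else length(times), by = max(1, round(30 / dt)))
  structure(
    list(
      age_at_replacement_yr = age_repl,
      censored = censored,
      mutant_count_age1 = mutant_count_age1,
      engine_switch_age_days = engine_switch_age,
      m_final = m_final,
      f_final = f_final,
      params = list(mu = mu, s_gcsf = s_gcsf, t_gcsf = t_gcsf, b = b,
                    dt = dt, exact_threshold = exact_threshold,
                    frac_threshold = frac_threshold,
                    replacement_fraction = replacement_fraction,
                    t_max_yr = t_max_yr),
      series = tibble(age_days = times[keep], mutants = path[keep])
    ),
    class = "replacement_sim"
  )
}

#' @export
print.replacement_sim <- function(x, ...) {
  cat("<replacement_sim>\n")
  if (x$censored) {
    cat(sprintf("  censored at %g yr (mutant fraction %.3g)\n",
                x$params$t_max_yr, x$f_final))
  } else {
    cat(sprintf("  age at replacement: %.2f yr\n", x$age_at_replacement_yr))
  }
  cat(sprintf("  mutant count at age 1 yr: %.3g\n", x$mutant_count_age1))
  invisible(x)
}

#' Tidy a replacement simulation
#'
#' @param x A `replacement_sim`.
#' @param ... Unused.
#' @return One-row tibble with the headline outcomes.
#' @method tidy replacement_sim
#' @export
tidy.replacement_sim <- function(x, ...) {
  tibble(
    mu = x$params$mu, s_gcsf = x$params$s_gcsf,
    age_at_replacement_yr = x$age_at_replacement_yr,
    censored = x$censored,
    mutant_count_age1 = x$mutant_count_age1,
    engine_switch_age_days = x$engine_switch_age_days
  )
}

#' Plot the stochastic phase of a replacement simulation
#'
#' @param object A `replacement_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot replacement_sim
#' @export
autoplot.replacement_sim <- function(object, ...) {
  df <- dplyr::filter(object$series, !is.na(.data$mutants),
                      .data$mutants > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$age_days / 365, .data$mutants)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "age (years)", y = "mutant CMP count")
}

# Mean replacement age (years) over replicates with per-replicate derived
# seeds; censored runs contribute the horizon (lower bound) with a warning.
mean_replacement_age <- function(trajectory, mu, s, reps, seed, ...) {
  ages <- vapply(seq_len(reps), function(j) {
    sim <- simulate_replacement(trajectory, mu = mu, s_gcsf = s,
                                seed = seed + 97L * j, ...)
    if (sim$censored) sim$params$t_max_yr else sim$age_at_replacement_yr
  }, numeric(1))
  mean(ages)
}

#' Replacement-age nomogram over a mutation-rate / selection grid
#'
#' Mean age at replacement for every combination of `mu_grid` and `s_grid`,
#' each estimated from `reps` replicates with common per-replicate seeds
#' across grid cells (paired comparisons).
#'
#' @inheritParams simulate_replacement
#' @param mu_grid,s_grid Positive parameter grids.
#' @param reps Replicates per cell.
#' @param seed Base integer seed.
#' @param ... Passed to [simulate_replacement()].
#' @return A tibble with `mu`, `s`, `mean_age_yr`, `censor_rate`.
#' @examples
#' \donttest{
#' traj <- integrate_compartments(calibrate_schedule())
#' sweep_nomogram(traj, c(1e-9, 1e-8), c(0.01, 0.05), reps = 5, seed = 1)
#' }
#' @export
sweep_nomogram <- function(trajectory, mu_grid, s_grid, reps = 20,
                           seed = 1, ...) {
  check_number(mu_grid, "mu_grid", lower = 0, allow_vector = TRUE)
  check_number(s_grid, "s_grid", lower = 1e-12, allow_vector = TRUE)
  grid <- tidyr::expand_grid(mu = mu_grid, s = s_grid)
  purrr::pmap_dfr(grid, function(mu, s) {
    sims <- purrr::map(seq_len(reps), function(j) {
      simulate_replacement(trajectory, mu = mu, s_gcsf = s,
                           seed = seed + 97L * j, ...)
    })
    ages <- purrr::map_dbl(sims, function(x) {
      if (x$censored) x$params$t_max_yr else x$age_at_replacement_yr
    })
    tibble(mu = mu, s = s, mean_age_yr = mean(ages),
           censor_rate = mean(purrr::map_lgl(sims, "censored")))
  })
}

#' Selection coefficient producing a target replacement age
#'
#' Monotone root finding on the mean replacement age as a function of `s`
#' (larger selection, earlier replacement), with common random numbers across
#' evaluations. Mirrors reading the nomogram backwards: "which selection
#' coefficient puts replacement at age X for this mutation rate?".
#'
#' @inheritParams simulate_replacement
#' @param target_age_yr Target mean replacement age in years (> `t_gcsf`).
#' @param reps Replicates per objective evaluation.
#' @param interval Search bracket for `s`.
#' @param tol Root tolerance on `s`.
#' @param seed Base integer seed.
#' @param ... Passed to [simulate_replacement()].
#' @return A list with `s`, `target_age_yr`, `mu`, and bracket diagnostics.
#' @examples
#' \donttest{
#' traj <- integrate_compartments(calibrate_schedule())
#' selection_for_age(traj, mu = 2.5e-9, target_age_yr = 13, reps = 5)
#' }
#' @export
selection_for_age <- function(trajectory, mu, target_age_yr, reps = 20,
                              interval = c(0.002, 0.5), tol = 2e-4,
                              seed = 1, t_gcsf = 182.5, ...) {
  check_number(target_age_yr, "target_age_yr", lower = t_gcsf / 365)
  obj <- function(s) {
    mean_replacement_age(trajectory, mu, s, reps, seed,
                         t_gcsf = t_gcsf, ...) - target_age_yr
  }
  f_lo <- obj(interval[1])
  f_hi <- obj(interval[2])
  if (f_lo < 0 || f_hi > 0) {
    abort(sprintf(
      "target age %.3g yr unreachable for s in [%g, %g] (bracket values %.3g, %.3g)",
      target_age_yr, interval[1], interval[2], f_lo, f_hi))
  }
  root <- uniroot(obj, interval = interval, f.lower = f_lo, f.upper = f_hi,
                  tol = tol)
  list(s = root$root, target_age_yr = target_age_yr, mu = mu,
       bracket = interval, bracket_values = c(f_lo, f_hi),
       objective_at_root = root$f.root, iterations = root$iter)
}

#' Mutant burden at a given age in the pre-selection regime
#'
#' Replicate summary of the mutant CMP count at `age_yr` with selection off
#' (`s = 0`): fetal-expansion mutants plus postnatal recurrent mutation,
#' carried by neutral drift on the growing compartment.
#'
#' @inheritParams simulate_replacement
#' @param age_yr Age at which to read the count (default 1).
#' @param reps Number of replicates.
#' @param seed Base integer seed.
#' @param ... Passed to [simulate_replacement()].
#' @return A tibble with `mu`, `age_yr`, `reps`, `mean`, `median`, `q10`,
#'   `q90`.
#' @examples
#' \donttest{
#' traj <- integrate_compartments(calibrate_schedule())
#' mutants_at_age(traj, mu = 1e-9, reps = 10)
#' }
#' @export
mutants_at_age <- function(trajectory, mu, age_yr = 1, reps = 50,
                           seed = 1, ...) {
  counts <- vapply(seq_len(reps), function(j) {
    sim <- simulate_replacement(trajectory, mu = mu, s_gcsf = 0,
                                t_max_yr = age_yr, seed = seed + 97L * j, ...)
    if (age_yr == 1 && !is.na(sim$mutant_count_age1)) {
      sim$mutant_count_age1
    } else {
      sim$m_final
    }
  }, numeric(1))
  tibble(
    mu = mu, age_yr = age_yr, reps = reps,
    mean = mean(counts), median = median(counts),
    q10 = quantile(counts, 0.1), q90 = quantile(counts, 0.9)
  )
}

#' Compare simplified and comprehensive selection-coefficient estimates
#'
#' For each (target fixation age, mutation rate) pair, reports the selection
#' coefficient implied by the constant-size proof-of-principle model
#' (inverting `age = (2 ln N - ln i)/s / divisions_per_year` with
#' `i = mu N_b ln N_b`) next to the coefficient found by root-finding on the
#' age-structured simulation, plus their ratio. The two models are expected to
#' disagree by a small factor; the function reports the ratio rather than
#' asserting its direction.
#'
#' @inheritParams selection_for_age
#' @param ages_yr Target fixation ages (years).
#' @param mus Mutation rates, same length as `ages_yr`.
#' @param N Adult pool for the simplified model.
#' @param birth_pool Fetal expansion endpoint for the count inversion.
#' @param divisions_per_year Calendar conversion for the simplified model.
#' @return A tibble with `age_yr`, `mu`, `s_simple`, `s_comprehensive`,
#'   `ratio`.
#' @export
compare_selection_models <- function(trajectory,
                                     ages_yr = c(4, 13, 22),
                                     mus = c(1e-9, 2.5e-9, 5e-9),
                                     reps = 20, seed = 1,
                                     N = scn_constants()$adult_pool,
                                     birth_pool = scn_constants()$birth_pool,
                                     divisions_per_year = 365 / 4, ...) {
  stopifnot(length(ages_yr) == length(mus))
  s_simple <- vapply(seq_along(ages_yr), function(k) {
    i <- mus[k] * birth_pool * log(birth_pool)
    (2 * log(N) - log(i)) / (ages_yr[k] * divisions_per_year)
  }, numeric(1))
  s_comp <- vapply(seq_along(ages_yr), function(k) {
    selection_for_age(trajectory, mu = mus[k], target_age_yr = ages_yr[k],
                      reps = reps, seed = seed, ...)$s
  }, numeric(1))
  tibble(age_yr = ages_yr, mu = mus, s_simple = s_simple,
         s_comprehensive = s_comp, ratio = s_comp / s_simple)
}
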