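#' Fixation probability of the Moran process with directional selection
#'
#' Probability that a mutant lineage with relative fitness r = 1 + s,
#' starting from `i` copies in a constant population of `N` cells, reaches
#' fixation before loss:
#' \deqn{P[T_N < T_0] = \frac{1 - (1-s)^i}{1 - (1-s)^N}.}
#' The computation is done in log space so it remains stable for populations
#' as large as the adult marrow pool (~1.5e10 cells), where `(1-s)^N`
#' underflows for any positive `s`.
#'
#' Note that this closed form is itself a large-population approximation of
#' the exact birth-death chain value, which uses `(1+s)^{-i}` in place of
#' `(1-s)^i`; see [exact_fixation_oracle()] for the exact small-`N` solution
#' and the methods vignette for the size of the discrepancy.
#'
#' @param N Total population size (>= 1; need not be integer in analytic use).
#' @param s Selection coefficient, `> -1`. At `s = 0` the neutral limit
#'   `i / N` is returned with a warning rather than an error, so parameter
#'   sweeps crossing zero do not fail.
#' @param i Initial mutant count, in `[0, N]`; may be non-integer.
#' @return Fixation probability in `[0, 1]`, vectorised over `i` and `s`.
#' @examples
#' fixation_probability(1.485e10, 0.005, 240.193) # ~0.7
#' @seealso [required_initial_mutants()], [conditional_fixation_time()]
#' @export
fixation_probability <- function(N, s, i) {
  check_number(N, "N", lower = 1)
  check_number(s, "s", allow_vector = TRUE)
  check_number(i, "i", lower = 0, upper = N, allow_vector = TRUE)
  if (any(s <= -1)) abort("`s` must be > -1 (relative fitness must be positive)")
  res <- mapply(function(s1, i1) {
    if (s1 == 0) {
      warn("s = 0: returning the neutral fixation probability i/N")
      return(i1 / N)
    }
    l <- log1p(-s1) # log(1 - s)
    if (s1 > 0) {
      # l < 0: expm1 terms are in (-1, 0]; no overflow possible.
      -expm1(i1 * l) / -expm1(N * l)
    } else {
      # l > 0: guard against overflow of expm1 for huge N.
      if (N * l < 700) {
        expm1(i1 * l) / expm1(N * l)
      } else {
        exp((i1 - N) * l) * (-expm1(-i1 * l)) / (-expm1(-N * l))
      }
    }
  }, s, i)
  unname(res)
}

#' Initial mutant count required for a target fixation probability
#'
#' Inverts [fixation_probability()] for `i`:
#' \deqn{i = \log_{1-s}\{1 - p\,[1 - (1-s)^N]\}.}
#' Used to regenerate the published table of initial counts: the unrounded
#' value feeds the conditional-time and mutation-rate computations, the
#' rounded value (half away from zero) is the printed column.
#'
#' @param N Population size.
#' @param s Selection coefficient in (0, 1) (the log base `1 - s` requires it).
#' @param p_target Target fixation probability in (0, 1). Default 0.7, the
#'   fraction of SCN-derived sMDS cases carrying a CSF3R truncation mutation.
#' @return A tibble with columns `s`, `i_real`, `i_rounded`.
#' @examples
#' required_initial_mutants(1.485e10, 0.005) # i_rounded = 240
#' @export
required_initial_mutants <- function(N, s, p_target = 0.7) {
  check_number(N, "N", lower = 1)
  check_number(s, "s", allow_vector = TRUE)
  check_number(p_target, "p_target")
  if (any(s <= 0) || any(s >= 1)) abort("`s` must lie in (0, 1)")
  if (p_target <= 0 || p_target >= 1) abort("`p_target` must lie in (0, 1)")
  l <- log1p(-s)
  den <- -expm1(N * l) # 1 - (1-s)^N
  i_real <- log1p(-p_target * den) / l
  tibble(s = s, i_real = i_real, i_rounded = round_half_away(i_real))
}

#' Expected conditional fixation time of an advantageous Moran mutant
#'
#' Asymptotic expectation of the fixation time, conditional on fixation, for
#' large `N` and small initial count `i`:
#' \deqn{E[T_N \mid T_N < T_0] = \frac{2\ln N - \ln i}{s}}
#' in units of cell divisions (one division per cell per interdivision time),
#' converted to years with `divisions_per_year` (default 365/4 = 91.25, the
#' 4-day CMP cycle).
#'
#' @inheritParams fixation_probability
#' @param divisions_per_year Cell divisions per year used for the calendar
#'   conversion. The default 91.25 reproduces the published fixation ages to
#'   within 0.2%; a flat 90 divisions/yr is sometimes quoted and can be
#'   supplied instead.
#' @return A tibble with `s`, `i`, `p_fix`, `t_fix_divisions`, `t_fix_years`
#'   and `divisions_per_year`.
#' @examples
#' conditional_fixation_time(1.485e10, 0.02, 59.595)$t_fix_years # ~23.4
#' @export
conditional_fixation_time <- function(N, s, i,
                                      divisions_per_year = 365 / 4) {
  check_number(N, "N", lower = 1)
  check_number(s, "s", allow_vector = TRUE)
  check_number(i, "i", allow_vector = TRUE)
  if (any(s <= 0)) abort("`s` must be positive for the conditional-time formula")
  if (any(i <= 0) || any(i >= N)) {
    abort("`i` must satisfy 0 < i < N (process not yet absorbed)")
  }
  t_div <- (2 * log(N) - log(i)) / s
  tibble(
    s = s, i = i,
    p_fix = fixation_probability(N, s, i),
    t_fix_divisions = t_div,
    t_fix_years = divisions_to_years(t_div, divisions_per_year),
    divisions_per_year = divisions_per_year
  )
}

#' Convert a count of cell divisions to calendar years
#'
#' @param divisions Number of divisions (>= 0).
#' @param divisions_per_year Divisions per year (default 365/4).
#' @return Years, `divisions / divisions_per_year`.
#' @examples
#' divisions_to_years(91.25) # 1
#' @export
divisions_to_years <- function(divisions, divisions_per_year = 365 / 4) {
  check_number(divisions, "divisions", lower = 0, allow_vector = TRUE)
  check_number(divisions_per_year, "divisions_per_year", lower = 1e-12)
  divisions / divisions_per_year
}

#' Exact absorbing-chain solution of the finite Moran process
#'
#' Brute-force validator for small populations. Builds the birth-death chain
#' with per-step transition probabilities
#' `p_up(k) = r k (N-k) / ((r k + N - k) N)` and
#' `p_down(k) = k (N-k) / ((r k + N - k) N)` (one death, one fitness-biased
#' replacement per step) and solves the absorbing-chain linear systems for the
#' fixation probability and the conditional expected absorption time, using a
#' sparse tridiagonal solve.
#'
#' Time is returned both in elementary Moran steps (one division per step) and
#' in generations (`steps / N`; one generation = every cell divides once =
#' one interdivision time).
#'
#' @param N Population size, integer `2 <= N <= 5000` (dense state space).
#' @param s Selection coefficient `> -1` (`s = 0` allowed: neutral chain).
#' @param i Initial mutant count, integer in `[0, N]`.
#' @return A list with `p_fix`, `t_fix_steps`, `t_fix_generations`.
#' @examples
#' exact_fixation_oracle(10, 0, 3)$p_fix # exactly 0.3
#' @export
exact_fixation_oracle <- function(N, s, i) {
  check_number(N, "N", lower = 2, upper = 5000)
  check_number(s, "s", lower = -1 + 1e-12)
  check_number(i, "i", lower = 0, upper = N)
  N <- as.integer(N)
  if (i != round(i)) abort("`i` must be an integer state of the chain")
  if (i == 0) return(list(p_fix = 0, t_fix_steps = NA_real_,
                          t_fix_generations = NA_real_))
  if (i == N) return(list(p_fix = 1, t_fix_steps = 0, t_fix_generations = 0))
  r <- 1 + s
  k <- seq_len(N - 1)
  denom <- (r * k + (N - k)) * N
  p_up <- r * k * (N - k) / denom
  p_dn <- k * (N - k) / denom
  stay <- 1 - p_up - p_dn
  n_tr <- N - 1L
  # I - Q for the transient states 1..N-1 (Q tridiagonal incl. self-loops)
  ii <- c(k, k[-n_tr], k[-1])
  jj <- c(k, k[-n_tr] + 1L, k[-1] - 1L)
  xx <- c(1 - stay, -p_up[-n_tr], -p_dn[-1])
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n_tr, n_tr))
  u <- Matrix::solve(A, c(rep(0, n_tr - 1L), p_up[n_tr]))   # fixation prob
  w <- Matrix::solve(A, u)                                   # E[steps * 1_fix]
  u <- as.numeric(u); w <- as.numeric(w)
  steps <- w[i] / u[i]
  list(p_fix = u[i], t_fix_steps = steps, t_fix_generations = steps / N)
}

#' Stochastic simulation of the constant-size Moran process
#'
#' Iterates the elementary Moran step (uniform death, replacement drawn with
#' odds r = 1 + s in favour of the mutant) until absorption or `max_steps`.
#' Self-loop steps are aggregated with geometric holding times, so runtime
#' scales with the number of state changes. Uses R's RNG: results are
#' reproducible under `set.seed()` or the `seed` argument.
#'
#' @param N Population size (`<= 1e5`; direct simulation is for validation).
#' @param s Selection coefficient `> -1`.
#' @param i Initial mutant count.
#' @param reps Number of independent replicates.
#' @param max_steps Step budget per replicate; replicates that fail to absorb
#'   are flagged (`fixed = NA`), not errors.
#' @param seed Optional integer seed.
#' @return A tibble with columns `rep`, `fixed` (TRUE/FALSE/NA) and `steps`
#'   (elementary Moran steps to absorption).
#' @examples
#' sims <- simulate_moran(50, 0.1, 5, reps = 100, seed = 1)
#' mean(sims$fixed)
#' @export
simulate_moran <- function(N, s, i, reps = 1L, max_steps = 1e9,
                           seed = NULL) {
  check_number(N, "N", lower = 2, upper = 1e5)
  check_number(s, "s", lower = -1 + 1e-12)
  check_number(i, "i", lower = 0, upper = N)
  if (!is.null(seed)) set.seed(seed)
  out <- cpp_moran_sim(as.integer(N), 1 + s, as.integer(i),
                       as.double(max_steps), as.integer(reps))
  tibble(
    rep = seq_len(reps),
    fixed = ifelse(out[, 1] < 0, NA, out[, 1] > 0),
    steps = out[, 2]
  )
}

#' Regenerate the proof-of-principle fixation table
#'
#' One call produces, for each selection coefficient, the initial mutant count
#' required for the target fixation probability, the mutation rate that yields
#' that count by the end of fetal expansion, and the expected age at fixation.
#' This is the single-command reproduction of the published table.
#'
#' @param s Vector of selection coefficients (default: the seven published
#'   values).
#' @param p_target Target fixation probability (default 0.7).
#' @param N Adult pool size (default 1.98e8 cells/kg x 75 kg).
#' @param birth_pool Cell count at the end of fetal expansion used for the
#'   mutation-rate inversion (default 5.94e8 = 1.98e8 x 3 kg; pass
#'   `scn_constants()$cells_per_kg * 5` for the 5 kg convention).
#' @param divisions_per_year Calendar conversion (default 365/4).
#' @param use_rounded_i If `TRUE`, feed the rounded instead of the unrounded
#'   count into the time and mutation-rate computations. Default `FALSE`,
#'   which matches the printed values more closely.
#' @return A tibble with columns `s`, `i_real`, `i_rounded`, `mu`,
#'   `t_fix_years`.
#' @examples
#' moran_table()
#' @export
moran_table <- function(s = c(0.005, 0.01, 0.02, 0.03, 0.04, 0.05, 0.1),
                        p_target = 0.7,
                        N = scn_constants()$adult_pool,
                        birth_pool = scn_constants()$birth_pool,
                        divisions_per_year = 365 / 4,
                        use_rounded_i = FALSE) {
  req <- required_initial_mutants(N, s, p_target)
  i_use <- if (use_rounded_i) req$i_rounded else req$i_real
  ct <- conditional_fixation_time(N, s, i_use, divisions_per_year)
  tibble(
    s = s,
    i_real = req$i_real,
    i_rounded = req$i_rounded,
    mu = mutation_rate_for_target(i_use, birth_pool),
    t_fix_years = ct$t_fix_years
  )
}
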