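#' Expected cell counts during fetal marrow expansion
#'
#' Expectations of the time-continuous Markov branching process of fetal
#' bone-marrow expansion with irreversible mutation: wild-type cells divide at
#' rate `lambda` (exponential interdivision times) and at each wild-type
#' division one daughter acquires the truncation mutation with probability
#' `mu`; mutants are selectively neutral during expansion. The expected counts
#' are
#' \deqn{N(t) = N_0 e^{(1-\mu)\lambda t}, \qquad
#'       i(t) = N_0\{e^{\lambda t} - e^{(1-\mu)\lambda t}\}.}
#'
#' @param t Time in days (vectorised, >= 0).
#' @param N0 Initiating wild-type count (default 1).
#' @param lambda Division rate per day.
#' @param mu Mutation probability per division.
#' @return A tibble with columns `t`, `n_wildtype`, `i_mutant`, `n_total`.
#' @examples
#' expected_counts(c(0, 40, 80), lambda = 0.25, mu = 1e-8)
#' @export
expected_counts <- function(t, N0 = 1, lambda = 0.25, mu = 0) {
  check_number(t, "t", lower = 0, allow_vector = TRUE)
  check_number(N0, "N0", lower = 1)
  check_number(lambda, "lambda", lower = 1e-12)
  check_number(mu, "mu", lower = 0, upper = 1)
  wt <- N0 * exp((1 - mu) * lambda * t)
  tot <- N0 * exp(lambda * t)
  tibble(t = t, n_wildtype = wt, i_mutant = tot - wt, n_total = tot)
}

#' Expected mutant count when the expanding population reaches a given size
#'
#' Eliminating time from the branching-process expectations gives the mutant
#' count as a function of the final population size:
#' \deqn{i = N - N_0^{\mu} N^{1-\mu} \approx \mu N \ln N,}
#' the right-hand approximation holding for moderate `N0` and small `mu`.
#' Both forms are returned; the approximation is the default basis of the
#' mutation-rate inversion ([mutation_rate_for_target()]).
#'
#' @param N_final Final population size (> `N0`).
#' @param mu Mutation probability per division (vectorised).
#' @param N0 Initiating count (default 1).
#' @return A tibble with columns `mu`, `N_final`, `i_exact`, `i_approx`.
#' @examples
#' expected_mutants_at_size(5.94e8, 2.01e-8) # ~240 mutants at birth
#' @export
expected_mutants_at_size <- function(N_final, mu, N0 = 1) {
  check_number(N_final, "N_final", lower = 1)
  check_number(mu, "mu", lower = 0, upper = 1, allow_vector = TRUE)
  check_number(N0, "N0", lower = 1, upper = N_final)
  # exact form, conditioned to return exactly 0 at mu = 0:
  # N - N0^mu N^(1-mu) = -N expm1(mu log(N0/N))
  i_exact <- -N_final * expm1(mu * log(N0 / N_final))
  tibble(
    mu = mu, N_final = N_final,
    i_exact = i_exact,
    i_approx = mu * N_final * log(N_final)
  )
}

#' Mutation rate required for a target mutant count at the end of expansion
#'
#' Inverts the branching-process approximation `i = mu * N * ln N`:
#' `mu = i / (N ln N)`. Round-trips with [expected_mutants_at_size()]'s
#' approximate form to machine precision.
#'
#' @param i_target Target expected mutant count (> 0, vectorised).
#' @param N_final Population size at the end of expansion (> e).
#' @return Mutation probability per division.
#' @examples
#' mutation_rate_for_target(240.193, 5.94e8) # ~2.0e-8
#' @export
mutation_rate_for_target <- function(i_target, N_final) {
  check_number(i_target, "i_target", lower = 0, allow_vector = TRUE)
  check_number(N_final, "N_final", lower = exp(1) + 1e-9)
  i_target / (N_final * log(N_final))
}

#' Time for the expanding population to reach a given size
#'
#' Inverts the wild-type expectation `N(t) = N0 exp((1-mu) lambda t)`:
#' `t = ln(N_final / N0) / ((1 - mu) lambda)`.
#'
#' @inheritParams expected_counts
#' @param N_final Target size (>= `N0`).
#' @return Time in days.
#' @examples
#' time_to_size(1024, N0 = 1, lambda = log(2)) # 10 doublings -> 10 days
#' @export
time_to_size <- function(N_final, N0 = 1, lambda = 0.25, mu = 0) {
  check_number(N_final, "N_final", lower = 1)
  check_number(N0, "N0", lower = 1)
  if (N_final < N0) abort("`N_final` must be >= `N0`")
  check_number(lambda, "lambda", lower = 1e-12)
  check_number(mu, "mu", lower = 0, upper = 1 - 1e-12)
  log(N_final / N0) / ((1 - mu) * lambda)
}

#' Exact event-by-event simulation of the fetal expansion
#'
#' Simulates the branching process division by division. Because there is no
#' cell death, the embedded jump chain is a Yule process: each division picks
#' a uniformly random living cell and the population grows by one. A wild-type
#' division produces one mutant daughter with probability `mu`; mutant
#' lineages breed true. The simulation stops when the population first reaches
#' `N_stop` and returns the mutant count.
#'
#' @param N_stop Stopping population size (`<= 1e6`; per-event simulation).
#' @param mu Mutation probability per wild-type division.
#' @param N0 Initiating wild-type count.
#' @param reps Number of replicates.
#' @param seed Optional integer seed.
#' @return A tibble with columns `rep`, `mutants`.
#' @examples
#' simulate_expansion_exact(1e4, mu = 0.01, reps = 10, seed = 1)
#' @export
simulate_expansion_exact <- function(N_stop, mu, N0 = 1, reps = 1L,
                                     seed = NULL) {
  check_number(N_stop, "N_stop", lower = 2, upper = 1e6)
  check_number(mu, "mu", lower = 0, upper = 1)
  check_number(N0, "N0", lower = 1, upper = N_stop)
  if (!is.null(seed)) set.seed(seed)
  m <- cpp_yule_sim(as.integer(N0), mu, as.integer(N_stop), as.integer(reps))
  tibble(rep = seq_len(reps), mutants = m)
}

#' Fast large-population sampler of the mutant count after expansion
#'
#' Scales to realistic pool sizes (up to ~1e10 cells) by sampling mutation
#' events and clone sizes instead of individual divisions. Mutation events are
#' Poisson-thinned over the `N_stop - N0` divisions (each division mutates
#' with probability ~`mu`, wild-type cells dominating throughout). A clone
#' founded by a single cell when the population has size `k + 1` and grows
#' neutrally without death to `N_stop` has final size
#' `1 + BetaBinomial(N_stop - k - 1; 1, k)` — the Polya-urn (uniform
#' attachment) share of one cell among `k + 1`, sampled as `p ~ Beta(1, k)`
#' followed by a binomial draw (normal approximation above 1e9 remaining
#' divisions). The returned mutant count is the sum of clone sizes; it agrees
#' in distribution with [simulate_expansion_exact()] at overlapping scales
#' (property-tested).
#'
#' @inheritParams simulate_expansion_exact
#' @param N_stop Stopping population size (up to ~1e10).
#' @return A tibble with columns `rep`, `mutants`.
#' @examples
#' simulate_expansion_fast(5.94e8, mu = 1e-8, reps = 20, seed = 1)
#' @export
simulate_expansion_fast <- function(N_stop, mu, N0 = 1, reps = 1L,
                                    seed = NULL) {
  check_number(N_stop, "N_stop", lower = 2, upper = 1e10 + 1)
  check_number(mu, "mu", lower = 0, upper = 1)
  check_number(N0, "N0", lower = 1, upper = N_stop)
  if (!is.null(seed)) set.seed(seed)
  n_div <- N_stop - N0
  mutants <- vapply(seq_len(reps), function(rep) {
    n_ev <- rpois(1, mu * n_div)
    if (n_ev == 0) return(0)
    # population size just before the mutating division, uniform over sizes
    k <- floor(stats::runif(n_ev, min = N0, max = N_stop))
    remaining <- N_stop - k - 1
    p <- rbeta(n_ev, 1, k)
    extra <- numeric(n_ev)
    small <- remaining <= 1e9
    if (any(small)) {
      extra[small] <- rbinom(sum(small), size = as.integer(remaining[small]),
                             prob = p[small])
    }
    if (any(!small)) {
      m <- remaining[!small] * p[!small]
      sdv <- sqrt(pmax(remaining[!small] * p[!small] * (1 - p[!small]), 0))
      extra[!small] <- pmin(pmax(round(rnorm(sum(!small), m, sdv)), 0),
                            remaining[!small])
    }
    sum(1 + extra)
  }, numeric(1))
  tibble(rep = seq_len(reps), mutants = mutants)
}
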