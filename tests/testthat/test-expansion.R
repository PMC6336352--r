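# Fetal branching-process expansion: expectations, inversion, samplers.

test_that("expected counts: no mutants at t = 0 and identities round-trip", {
  ec <- expected_counts(0, N0 = 3, lambda = 0.3, mu = 1e-4)
  expect_equal(ec$i_mutant, 0)
  expect_equal(ec$n_total, 3)
  # time_to_size is the inverse of the wild-type expectation
  t <- time_to_size(5.94e8, N0 = 10, lambda = 0.25, mu = 1e-8)
  ec2 <- expected_counts(t, N0 = 10, lambda = 0.25, mu = 1e-8)
  expect_equal(ec2$n_wildtype, 5.94e8, tolerance = 1e-9)
  expect_equal(time_to_size(1024, N0 = 1, lambda = log(2)), 10)
  # ~90 days of marrow expansion before birth at the default division rate
  expect_equal(time_to_size(5.94e8, N0 = 10, lambda = 0.25), 71.5,
               tolerance = 0.01)
  expect_error(time_to_size(5, N0 = 10), ">=")
})

test_that("mutant expectation: exact and approximate forms, monotonicity", {
  expect_equal(expected_mutants_at_size(9.9e8, 0)$i_exact, 0)
  ex <- expected_mutants_at_size(5.94e8, 2.01e-8)
  expect_equal(ex$i_approx, 241.21, tolerance = 1e-4)
  # the approximation mu*N*ln(N) agrees with the exact form to 2% when the
  # expansion starts from a single cell; for N0 > 1 its relative error is
  # ~ln(N0)/ln(N) (the approximation drops the ln(N0) term)
  grid <- expand.grid(mu = c(1e-8, 1e-7, 1e-6), N0 = c(1, 5, 10),
                      N = c(1e6, 1e8, 1e10))
  for (r in seq_len(nrow(grid))) {
    v <- expected_mutants_at_size(grid$N[r], grid$mu[r], grid$N0[r])
    bound <- 0.02 + 1.1 * log(grid$N0[r]) / log(grid$N[r])
    expect_lt(abs(v$i_approx / v$i_exact - 1), bound)
  }
  # increasing in mu and N
  v_mu <- expected_mutants_at_size(1e8, c(1e-9, 1e-8, 1e-7))
  expect_true(all(diff(v_mu$i_exact) > 0))
  i_n <- vapply(c(1e6, 1e7, 1e8), function(N)
    expected_mutants_at_size(N, 1e-8)$i_exact, numeric(1))
  expect_true(all(diff(i_n) > 0))
})

test_that("mutation-rate inversion round-trips and matches the published rates", {
  mu <- mutation_rate_for_target(240.193, 5.94e8)
  expect_equal(mu, 2.0016e-8, tolerance = 1e-4)
  expect_equal(mutation_rate_for_target(119.794, 5.94e8), 1.00e-8,
               tolerance = 2e-3)
  expect_equal(mutation_rate_for_target(11.427, 5.94e8), 9.57e-10,
               tolerance = 6e-3)
  for (i in c(1, 11.4, 240, 5000)) {
    back <- expected_mutants_at_size(5.94e8,
                                     mutation_rate_for_target(i, 5.94e8))
    expect_equal(back$i_approx, i, tolerance = 1e-9)
  }
})

test_that("event-by-event simulator matches the closed-form mean (3 SE)", {
  expect_equal(simulate_expansion_exact(1e4, mu = 0, reps = 5)$mutants,
               rep(0, 5))
  sims <- simulate_expansion_exact(1e4, mu = 0.01, reps = 1000, seed = 3)
  target <- expected_mutants_at_size(1e4, 0.01)$i_exact
  se <- sd(sims$mutants) / sqrt(nrow(sims))
  expect_lt(abs(mean(sims$mutants) - target), 3 * se)
  # jackpot clones: right-skewed counts
  expect_lt(median(sims$mutants), mean(sims$mutants))
})

test_that("fast sampler agrees with the exact simulator in distribution", {
  set.seed(5)
  a <- simulate_expansion_exact(1e5, mu = 1e-3, reps = 300)$mutants
  b <- simulate_expansion_fast(1e5, mu = 1e-3, reps = 300)$mutants
  ks <- suppressWarnings(stats::ks.test(a, b))
  expect_gt(ks$p.value, 0.01)
  # same estimand: means agree within 3 SE of the difference
  se_diff <- sqrt(var(a) / length(a) + var(b) / length(b))
  expect_lt(abs(mean(a) - mean(b)), 3 * se_diff)
  expect_equal(simulate_expansion_fast(1e6, mu = 0, reps = 5)$mutants,
               rep(0, 5))
})

test_that("fast sampler at marrow scale: every mutation event leaves a clone", {
  # no cell death during expansion, so the fraction of replicates with zero
  # mutants equals the Poisson probability of zero mutation events
  sims <- simulate_expansion_fast(5.94e8, mu = 1e-8, reps = 200, seed = 4)
  p_zero <- exp(-1e-8 * (5.94e8 - 1))
  expect_lt(abs(mean(sims$mutants == 0) - p_zero),
            3 * sqrt(p_zero * (1 - p_zero) / 200) + 0.01)
  expect_lt(median(sims$mutants), mean(sims$mutants))
  expect_true(all(sims$mutants >= 0))
})
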