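# Constant-size Moran process: analytic formulas, exact oracle, simulator.

test_that("fixation probability is stable at marrow-scale N and handles edges", {
  k <- scn_constants()
  expect_equal(fixation_probability(k$adult_pool, 0.005, 240.193), 0.7,
               tolerance = 1e-4)
  expect_equal(fixation_probability(1e10, 0.05, 0), 0)
  expect_equal(fixation_probability(1e10, 0.05, 1e10), 1)
  expect_warning(p0 <- fixation_probability(100, 0, 30), "neutral")
  expect_equal(p0, 0.3)
  # deleterious side stays finite and tiny for large N
  expect_lt(fixation_probability(1e6, -0.01, 10), 1e-40)
  expect_error(fixation_probability(100, -1.5, 10), "-1")
})

test_that("fixation probability is increasing in i and in s", {
  for (N in c(100, 1e4, 1e8)) {
    # strict increase tested where p is away from its floating-point ceiling
    i <- seq(1, min(N - 1, 80), length.out = 20)
    p <- fixation_probability(N, rep(0.03, 20), i)
    expect_true(all(diff(p) > 0))
    s <- seq(0.005, 0.2, length.out = 25)
    p2 <- fixation_probability(N, s, rep(5, 25))
    expect_true(all(diff(p2) > 0))
  }
})

test_that("required_initial_mutants inverts fixation_probability to 1e-9", {
  grid <- expand.grid(s = c(0.005, 0.02, 0.1, 0.5),
                      p = c(0.1, 0.5, 0.7, 0.95),
                      N = c(1e3, 1e6, 1.485e10))
  for (r in seq_len(nrow(grid))) {
    req <- required_initial_mutants(grid$N[r], grid$s[r], grid$p[r])
    p_back <- fixation_probability(grid$N[r], grid$s[r], req$i_real)
    expect_equal(p_back, grid$p[r], tolerance = 1e-9)
  }
  expect_error(required_initial_mutants(100, -0.1, 0.7), "\\(0, 1\\)")
  expect_error(required_initial_mutants(100, 0.1, 1.2), "\\(0, 1\\)")
})

test_that("neutral oracle reproduces i/N exactly and matches the exact chain formula", {
  o <- exact_fixation_oracle(10, 0, 3)
  expect_equal(o$p_fix, 0.3, tolerance = 1e-12)
  # independent route: sparse linear solve vs the gambler's-ruin product
  # formula with down/up ratio 1/(1+s)
  for (cfg in list(c(100, 0.05, 5), c(200, 0.1, 20), c(400, 0.02, 3))) {
    o <- exact_fixation_oracle(cfg[1], cfg[2], cfg[3])
    r <- 1 + cfg[2]
    p_exact <- (1 - r^(-cfg[3])) / (1 - r^(-cfg[1]))
    expect_equal(o$p_fix, p_exact, tolerance = 1e-10)
  }
  expect_error(exact_fixation_oracle(10000, 0.05, 5), "5000")
})

test_that("closed-form fixation probability deviates from the exact chain as documented", {
  # The closed form replaces (1+s)^-i by (1-s)^i; its relative error decays
  # like i*s^2 * e^-a / (1 - e^-a), a = i log(1+s). Where fixation is nearly
  # certain (a >= 3) the two agree to 2% for s <= 0.1; at small i the error
  # approaches s itself.
  for (N in c(200, 500, 1000)) {
    for (s in c(0.01, 0.02, 0.05, 0.1)) {
      i_vals <- unique(pmin(N - 1, ceiling(c(3, 5) / log(1 + s))))
      for (i in i_vals) {
        o <- exact_fixation_oracle(N, s, i)
        cf <- fixation_probability(N, s, i)
        expect_lt(abs(cf / o$p_fix - 1), 0.02)
      }
      # documented error model at small counts: bounded by ~s, not by 2%
      o1 <- exact_fixation_oracle(N, s, 1)
      cf1 <- fixation_probability(N, s, 1)
      expect_lt(abs(cf1 / o1$p_fix - 1), 1.1 * s)
      expect_gt(cf1, o1$p_fix) # closed form overestimates
    }
  }
})

test_that("stochastic simulator agrees with the oracle (3-SE bands, 1e4 reps)", {
  sims <- simulate_moran(100, 0.05, 5, reps = 1e4, seed = 1)
  o <- exact_fixation_oracle(100, 0.05, 5)
  se <- sqrt(o$p_fix * (1 - o$p_fix) / 1e4)
  expect_lt(abs(mean(sims$fixed) - o$p_fix), 3 * se)

  sims2 <- simulate_moran(200, 0.1, 20, reps = 1e4, seed = 2)
  o2 <- exact_fixation_oracle(200, 0.1, 20)
  fx <- sims2$steps[sims2$fixed]
  expect_lt(abs(mean(fx) - o2$t_fix_steps), 3 * sd(fx) / sqrt(length(fx)))
})

test_that("simulator trivial states and reproducibility", {
  expect_equal(simulate_moran(50, 0.1, 0, seed = 1)$fixed, FALSE)
  expect_equal(simulate_moran(50, 0.1, 0, seed = 1)$steps, 0)
  expect_equal(simulate_moran(50, 0.1, 50, seed = 1)$fixed, TRUE)
  a <- simulate_moran(60, 0.05, 6, reps = 50, seed = 42)
  b <- simulate_moran(60, 0.05, 6, reps = 50, seed = 42)
  expect_identical(a, b)
})

test_that("conditional fixation time follows (2 ln N - ln i)/s and unit conversion", {
  ct <- conditional_fixation_time(1e6, 0.05, 10)
  expect_equal(ct$t_fix_divisions, (2 * log(1e6) - log(10)) / 0.05)
  expect_equal(ct$t_fix_years, ct$t_fix_divisions / 91.25)
  # doubling s halves the time
  ct2 <- conditional_fixation_time(1e6, 0.1, 10)
  expect_equal(ct2$t_fix_divisions, ct$t_fix_divisions / 2)
  expect_error(conditional_fixation_time(100, 0.05, 100), "0 < i < N")
  expect_error(conditional_fixation_time(100, -0.01, 5), "positive")
  expect_equal(divisions_to_years(91.25), 1)
  expect_equal(divisions_to_years(8272.3), 90.655, tolerance = 1e-4)
  expect_equal(divisions_to_years(444.1), 4.867, tolerance = 1e-3)
})

test_that("one call regenerates the published fixation table", {
  tab <- moran_table()
  expect_identical(tab$i_rounded, published_fixation_table$i)
  expect_true(all(abs(tab$t_fix_years / published_fixation_table$age_yr - 1)
                  < 0.005))
  expect_true(all(abs(tab$mu / published_fixation_table$mu - 1) < 0.01))
})
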