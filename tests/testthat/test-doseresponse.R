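# Hill dose-response fitting and split-dose rank testing.

test_that("noiseless synthetic data recover the generating parameters", {
  dat <- generate_dose_response(noise_sd = 0, seed = 1)
  fit <- fit_hill(dat)
  truth <- hill_defaults()
  for (g in c("TypeI", "D715")) {
    cv <- fit$curves[[g]]
    tr <- if (g == "TypeI") truth$ref else truth$mut
    expect_lt(abs(cv$y0 / tr$y0 - 1), 0.01)
    expect_lt(abs(cv$a / tr$a - 1), 0.01)
    expect_lt(abs(cv$b / tr$b - 1), 0.05)
    expect_lt(abs(cv$c / tr$c - 1), 0.05)
    expect_lt(abs(cv$n / tr$n - 1), 0.05)
  }
  expect_equal(fit$curves$TypeI$y0, fit$curves$D715$y0) # shared baseline
})

test_that("fit is stable under 1% noise in its identifiable parametrisation", {
  # (b, c, n) individually sit on a flat likelihood ridge for very steep
  # curves; the identified combinations are the half-saturation point on the
  # log-dose axis (b + c) and the relative steepness (n / b), plus y0 and a.
  dat <- generate_dose_response(noise_sd = 0.008, seed = 11)
  fit <- fit_hill(dat)
  truth <- hill_defaults()
  for (g in c("TypeI", "D715")) {
    cv <- fit$curves[[g]]
    tr <- if (g == "TypeI") truth$ref else truth$mut
    expect_lt(abs(cv$y0 / tr$y0 - 1), 0.1)
    expect_lt(abs(cv$a / tr$a - 1), 0.1)
    expect_lt(abs((cv$b + cv$c) / (tr$b + tr$c) - 1), 0.1)
    expect_lt(abs((cv$n / cv$b) / (tr$n / tr$b) - 1), 0.1)
  }
})

test_that("flat data yield near-zero amplitude and the data mean as baseline", {
  doses <- 10^seq(-2, 2, length.out = 7)
  dat <- tibble::tibble(
    group = rep(c("A", "B"), each = 21),
    dose = rep(rep(doses, each = 3), 2),
    absorbance = 0.5
  )
  fit <- fit_hill(dat)
  expect_lt(fit$curves$A$a, 0.01)
  expect_lt(fit$curves$B$a, 0.01)
  expect_equal(fit$curves$A$y0, 0.5, tolerance = 0.02)
})

test_that("fitted reference and mutant curves cross near 0.1 ng/ml", {
  hd <- hill_defaults()
  x <- crossing_concentration(hd$ref, hd$mut, bracket = c(0.01, 10))
  expect_gt(x, 0.05)
  expect_lt(x, 0.3)
  expect_error(crossing_concentration(hd$ref, hd$ref), "cross")
  # bracket endpoints honoured
  expect_error(crossing_concentration(hd$ref, hd$mut, bracket = c(1, 10)),
               "cross")
})

test_that("tidiers and input validation", {
  dat <- generate_dose_response(noise_sd = 0, seed = 1)
  fit <- fit_hill(dat)
  td <- tidy(fit)
  expect_equal(nrow(td), 10) # 2 groups x 5 parameters
  gl <- glance(fit)
  expect_lt(gl$rss, 1e-8)
  expect_error(fit_hill(dat[dat$dose > 10, ]), "5 distinct doses")
  expect_error(fit_hill(dplyr::mutate(dat, dose = dose - 10)), "positive")
})

test_that("rank-test conventions: ties, identical and separated samples", {
  # identical samples: midranks + normal approximation, p = 0.5
  d_id <- tibble::tibble(dose = rep(c(0.01, 1), each = 6),
                         absorbance = 1,
                         group = rep(rep(c("TypeI", "D715"), each = 3), 2))
  res <- split_rank_test(d_id, ref = "TypeI", mut = "D715")
  expect_equal(res$p_value, c(0.5, 0.5))
  # complete separation, 3 vs 3, exact test: p = 1/choose(6,3) = 0.05
  d_sep <- tibble::tibble(
    dose = rep(c(1, 0.01), each = 6),
    absorbance = c(1, 2, 3, 4, 5, 6, 6, 5, 4, 3, 2, 1),
    group = rep(rep(c("TypeI", "D715"), each = 3), 2)
  )
  res2 <- split_rank_test(d_sep, ref = "TypeI", mut = "D715")
  expect_equal(res2$p_value, c(0.05, 0.05))
  expect_error(split_rank_test(d_sep[d_sep$dose > 0.1, ]), "fewer than 3")
})

test_that("generated assays show the published effect direction in >= 90% of seeds", {
  p_high <- vapply(1:20, function(s) {
    dat <- generate_dose_response(seed = s)
    split_rank_test(dat, ref = "TypeI", mut = "D715")$p_value[1]
  }, numeric(1))
  expect_gte(mean(p_high < 0.05), 0.9)
})
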