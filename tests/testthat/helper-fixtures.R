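# Shared fixtures, built in code at test time.

# Default calibrated trajectory of the hematopoiesis model (computed once per
# test run; ~0.2 s).
default_traj <- integrate_compartments(calibrate_schedule())

# Constant-size population trajectory for small-scale engine checks.
constant_traj <- function(N, t_end_days = 8000) {
  tibble::tibble(age_days = c(-90, 0, t_end_days), C = N)
}

# Published proof-of-principle fixation table (selection coefficient, initial
# mutant count, mutation rate per division, expected fixation age in years).
published_fixation_table <- tibble::tibble(
  s = c(0.005, 0.01, 0.02, 0.03, 0.04, 0.05, 0.1),
  i = c(240, 120, 60, 40, 29, 23, 11),
  mu = c(2.01e-8, 1.00e-8, 4.99e-9, 3.31e-9, 2.47e-9, 1.97e-9, 9.57e-10),
  age_yr = c(90.57, 46.05, 23.41, 15.75, 11.90, 9.57, 4.86)
)
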