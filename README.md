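# scnclone

Clonal dynamics of *CSF3R*-truncation mutants in severe congenital
neutropenia (SCN).

Children with SCN — most often caused by a germline *ELANE* mutation — are
kept alive by chronic G-CSF therapy, and 30–40% of them progress to secondary
myelodysplastic syndrome (sMDS). The progression is almost always accompanied
by truncating mutations of the G-CSF receptor gene (*CSF3R*, prototypically
D715). `scnclone` implements a two-phase population-genetic model of that
progression, together with the experimental estimator used to bound the
mutant's selective advantage:

* **Phase 1 — fetal expansion.** Marrow hematopoiesis expands exponentially
  over the last ~90 days of gestation. Modelled as a Markov branching process
  with irreversible mutation (division rate λ, mutation probability μ per
  division), the expected mutant count when the pool reaches *N* cells is
  *i* ≈ μ·*N*·ln *N* — tens to hundreds of pre-existing mutant cells at birth
  for ordinary human mutation rates (μ ~ 10⁻⁹–10⁻⁸).
* **Phase 2 — selective takeover under G-CSF.** In the simplest
  (proof-of-principle) form, a constant-size Moran process with directional
  selection: with relative fitness r = 1 + s, the fixation probability from
  *i* of *N* cells is P = (1 − (1−s)ⁱ)/(1 − (1−s)ᴺ) and the expected
  conditional fixation time is E[T] = (2 ln *N* − ln *i*)/s divisions. In the
  comprehensive form, the Moran process runs on an age-calibrated
  hematopoiesis model (HSC and CMP compartments tracking body weight at
  1.98×10⁸ cells/kg) with recurrent mutation, selection switching on at the
  start of G-CSF treatment (age 6 months).
* **Selection inference from cell-cycle data.** From G1/G0 fractions φ
  (wild-type receptor) and φ\* (mutant) the chain
  ψ = ln{1 − φ[1 − (2α)⁻¹]}/(−ln 2α), Δ = T(ψ − ψ\*)/(1 − ψ\*),
  λ = ln(2α)/T, λ\* = ln(2α\*)/(T − Δ), s = λ\*/λ − 1 converts a shorter G1
  phase into a selection coefficient. Hill-type dose-response fitting with a
  shared baseline and split-dose Wilcoxon rank tests support the proliferation
  (MTT) readout; synthetic generators emulate both assays.

## Worked example

Regenerate the fixation table of the proof-of-principle model — for each
selection coefficient, the initial mutant count needed for a 70% fixation
probability in an adult pool of 1.485×10¹⁰ cells, the fetal mutation rate
that supplies that count, and the expected age at fixation:

```r
library(scnclone)
moran_table()
#> # A tibble: 7 × 5
#>       s i_real i_rounded       mu t_fix_years
#>   <dbl>  <dbl>     <dbl>    <dbl>       <dbl>
#> 1 0.005  240.        240 2.00e- 8       90.7
#> 2 0.01   120.        120 9.98e- 9       46.1
#> 3 0.02    59.6        60 4.97e- 9       23.4
#> 4 0.03    39.5        40 3.29e- 9       15.8
#> 5 0.04    29.5        29 2.46e- 9       11.9
#> 6 0.05    23.5        23 1.96e- 9        9.58
#> 7 0.1     11.4        11 9.52e-10       4.87
```

Reading the s = 0.02 row: 60 mutant cells present when treatment starts (a
mutation rate of ~5×10⁻⁹ per division suffices to create them in utero) fix
in the marrow at age ~23 — within the clinically observed window of sMDS
onset (13 ± 9 years).

The cell-cycle inference chain, from a wild-type G1/G0 fraction of 0.70 and a
mutant G1 share ψ\* = 0.567 (interdivision time 4 d, perfect division
efficiency):

```r
est <- estimate_selection(phi = 0.70, psi_star = 0.567)
tidy(est)
#> # A tibble: 8 × 2
#>   quantity     value
#> 1 phi          0.7
#> 2 phi_star    NA
#> 3 psi          0.621
#> 4 psi_star     0.567
#> 5 Delta        0.503
#> 6 lambda       0.173
#> 7 lambda_star  0.198
#> 8 s            0.144
```

so the mutant shortens G1 by ~0.5 d and grows ~14% faster — an upper bound on
the selection coefficient used in the takeover models.

The comprehensive, age-structured simulation (mutation rate 2.5×10⁻⁹ per
division, selection 0.014 after G-CSF start):

```r
traj <- integrate_compartments(calibrate_schedule())
simulate_replacement(traj, mu = 2.5e-9, s_gcsf = 0.014, seed = 1)
#> <replacement_sim>
#>   age at replacement: 15.54 yr
#>   mutant count at age 1 yr: 1.48e+03
```

`selection_for_age()` inverts this relationship (which s puts replacement at
a given age for a given μ), `sweep_nomogram()` maps the (μ, s) plane, and
`mutants_at_age()` summarises the pre-selection mutant burden.

A command-line wrapper over the same functions lives at
`inst/cli/scnclone` (subcommands `moran-table`, `expansion`,
`hematopoiesis`, `comprehensive`, `estimate-s`, `fit-hill`, `generate`).

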