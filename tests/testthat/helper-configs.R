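# Small configuration factories shared across test files.

# Single-study, single-wave config: fast fits, school + residual only.
quick_config <- function(n_schools = 50, m = 25, icc = 0.08,
                         total_sd = 23.2, seed = 1, ...) {
  total <- total_sd^2
  sim_config(
    phase = "primary",
    n_studies = 1, schools_per_study = n_schools, pupils_per_school = m,
    waves = 0,
    var_study = 0,
    var_school = icc * total,
    var_pupil = 0.8 * (1 - icc) * total,
    var_resid = 0.2 * (1 - icc) * total,
    missing_rate = 0,
    gender_effect = 0,
    seed = seed,
    ...
  )
}

# Two-wave multi-study config with no school transitions (secondary phase,
# so the closed-form wave-pair correlations apply exactly to all stayers).
longitudinal_config <- function(n_studies = 5, n_schools = 10, m = 50,
                                seed = 1, ...) {
  sim_config(
    phase = "secondary",
    n_studies = n_studies, schools_per_study = n_schools,
    pupils_per_school = m, waves = c(0, 1),
    seed = seed, ...
  )
}

expect_all_in_unit <- function(x) {
  expect_true(all(x > 0 & x < 1))
}
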