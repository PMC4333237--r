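# Shared fixtures for the test suite.  The reference absorption rate
# constant (2 1/h) makes absorption fast relative to elimination; it stands
# in for the fixed literature value, which is not part of this model's
# published parameter table.
ref_params <- function(...) rifampicin_params(ka = 2, ...)

ref_regimen <- function() dosing_regimen(600, 24, 5)

# Small deterministic cohort used by estimation tests: identical covariates,
# no covariate sampling noise.
tiny_design <- function(n = 6, bal_times = 4, omit = TRUE, jitter = 0.25) {
  cd <- default_covariate_distributions()
  for (s in names(cd)) cd[[s]]$weight_sd <- cd[[s]]$height_sd <- 1e-9
  study_design_spec(n_subjects = n, n_male = ceiling(n / 2),
                    bal_times = bal_times, time_jitter = jitter,
                    target_counts = if (omit) NULL else
                      c(plasma = 2 * n, ELF = n, AC = n),
                    covariate_distributions = cd)
}

# One-subject structure in the layout of split_dataset(), built directly.
toy_subject <- function(obs_times = c(98, 100),
                        matrices = c("plasma", "plasma"),
                        dv = NULL, params = ref_params(), eta_true = 0) {
  cov <- subject_covariates("T1", "male", 70, 1.75)
  doses <- data.frame(time = seq(0, 96, by = 24), amt = 600)
  sub <- list(cov = cov, doses = doses,
              obs = data.frame(time = obs_times, matrix = matrices,
                               dv = NA_real_, stringsAsFactors = FALSE))
  if (is.null(dv)) {
    sched <- sampling_schedule(obs_times, matrices)
    f <- simulate_individual(cov, params, eta_true,
                             ref_regimen(), sched)$pred
    sub$obs$dv <- f
  } else {
    sub$obs$dv <- dv
  }
  sub
}
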