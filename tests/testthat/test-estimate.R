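test_that("the conditional -2LL matches its closed form", {
  p <- ref_params()
  sub <- toy_subject()
  f <- pulmopk:::subject_predictions(sub, p, 0.2)
  y <- f * c(1.1, 0.9)
  sub$obs$dv <- y
  got <- individual_neg2ll(sub, p, 0.2)
  v <- f^2 * p$sigma_plasma^2
  want <- sum(log(2 * pi * v) + (y - f)^2 / v) +
    0.2^2 / p$omega_cl^2 + log(2 * pi * p$omega_cl^2)
  expect_equal(got, want, tolerance = 1e-8)
  # zero residuals leave only the normalizing terms
  sub$obs$dv <- f
  got0 <- individual_neg2ll(sub, p, 0.2)
  expect_equal(got0, sum(log(2 * pi * v)) + 0.2^2 / p$omega_cl^2 +
                 log(2 * pi * p$omega_cl^2), tolerance = 1e-8)
  # doubling sigma changes the value by the analytic amount
  p2 <- ref_params(sigma_plasma = 2 * p$sigma_plasma)
  sub$obs$dv <- y
  delta <- individual_neg2ll(sub, p2, 0.2) - got
  want_delta <- sum(log(4) - (3 / 4) * (y - f)^2 / v)
  expect_equal(delta, want_delta, tolerance = 1e-8)
})

test_that("the Laplace approximation matches adaptive quadrature", {
  # 1-subject toy instances across variability levels; the approximate
  # marginal -2LL must track the quadrature oracle closely
  for (om in c(0.3, 0.888)) {
    for (sd_seed in 1:2) {
      p <- ref_params(omega_cl = om)
      set.seed(100 + sd_seed)
      sub <- toy_subject(obs_times = c(98, 100, 100, 100),
                         matrices = c("plasma", "plasma", "ELF", "AC"),
                         params = p, eta_true = 0)
      sub$obs$dv <- sub$obs$dv *
        (1 + stats::rnorm(4, 0, 0.2))
      lap <- pulmopk:::subject_laplace(sub, p)
      quad <- marginal_neg2ll_quad(sub, p)
      expect_lt(abs(lap$neg2ll - quad), 0.1)
    }
  }
})

test_that("cohort-level and per-subject Laplace agree", {
  p <- ref_params()
  d <- generate_study(tiny_design(n = 5, bal_times = c(1, 4, 8)), p,
                      seed = 21)
  subs <- split_dataset(d)
  pop <- pulmopk:::population_laplace(subs, p)
  per <- sum(vapply(subs, function(s) {
    pulmopk:::subject_laplace(s, p)$neg2ll
  }, numeric(1)))
  expect_equal(pop$total, per, tolerance = 1e-4)
  # the objective is exchangeable over subjects
  pop_rev <- pulmopk:::population_laplace(rev(subs), p)
  expect_equal(pop$total, pop_rev$total, tolerance = 1e-6)
})

test_that("noise-free data identify the structural parameters exactly", {
  # omega = 0, sigma -> 0: the estimated subset must recover the truth
  truth <- ref_params(omega_cl = 0, sigma_plasma = 1e-5, sigma_elf = 1e-5,
                      sigma_ac = 1e-5)
  d <- generate_study(tiny_design(n = 6, bal_times = c(1, 4, 8)), truth,
                      seed = 8)
  mask <- default_fixed_mask()
  mask[c("omega_cl", "sigma_plasma", "sigma_elf", "sigma_ac")] <- TRUE
  start <- ref_params(omega_cl = 0, sigma_plasma = 1e-5, sigma_elf = 1e-5,
                      sigma_ac = 1e-5,
                      cl_std = 3, vc_std = 60, r_elf_plasma = 0.5,
                      r_ac_plasma = 0.5, fixed_mask = mask)
  f <- fit(d, start, control = list(se = FALSE, maxit = 600,
                                    reltol = 1e-10, restarts = 2))
  expect_equal(unname(f$estimates["cl_std"]), 3.85, tolerance = 1e-3)
  expect_equal(unname(f$estimates["vc_std"]), 76.6, tolerance = 1e-3)
  expect_equal(unname(f$estimates["r_elf_plasma"]), 0.26, tolerance = 1e-3)
  expect_equal(unname(f$estimates["r_ac_plasma"]), 1.1, tolerance = 1e-3)
  # the optimizer never worsens the starting objective
  start_ofv <- pulmopk:::population_laplace(split_dataset(d), start)$total
  expect_lte(f$ofv, start_ofv)
})

test_that("equilibration rates cannot be freed on a single-BAL-time design", {
  p <- ref_params()
  d <- generate_study(tiny_design(n = 4, bal_times = 4), p, seed = 3)
  mask <- default_fixed_mask()
  mask["k_elf"] <- FALSE
  expect_error(fit(d, p, fixed_mask = mask), "distinct BAL")
  # with >= 2 distinct BAL times the same request is structurally allowed
  d2 <- generate_study(tiny_design(n = 4, bal_times = c(1, 8)), p, seed = 3)
  expect_gte(n_distinct_bal_times(d2), 2L)
})

test_that("likelihood-ratio bookkeeping uses the chi-squared threshold", {
  r <- lrt(100.0, 103.9, 1)
  expect_equal(r$delta_ofv, 3.9)
  expect_true(r$significant)
  r2 <- lrt(100.0, 103.8, 1)
  expect_false(r2$significant)
  expect_equal(round(r$threshold, 2), 3.84)
  expect_gt(lrt(0, 10, 2)$threshold, lrt(0, 10, 1)$threshold)
  expect_error(lrt(1, 2, 0), "d_params")
})

test_that("standard errors match the closed form on a quadratic objective", {
  # -2LL quadratic in theta with Hessian H: covariance is 2 * H^{-1}
  H <- matrix(c(8, 1, 1, 4), 2, 2)
  est <- c(a = 2, b = 0.26)
  tab <- pulmopk:::se_from_hessian(H, c("a", "b"), est)
  cov_true <- 2 * solve(H)
  # parameters are log-scaled internally: natural SE = est * SE_log
  expect_equal(tab$se, sqrt(diag(cov_true)) * est, ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(rse_percent(0.26, 0.0112), 4.3, tolerance = 0.01)
  # non-positive-definite curvature yields NA with a warning
  expect_warning(tab2 <- pulmopk:::se_from_hessian(-H, c("a", "b"), est),
                 "positive definite")
  expect_true(all(is.na(tab2$se)))
})

test_that("scaling-mode comparison ranks by OFV then parsimony", {
  p <- ref_params()
  d <- generate_study(study_design_spec(n_subjects = 8, n_male = 4,
                                        bal_times = c(1, 4, 8),
                                        target_counts = NULL), p, seed = 14)
  cmp <- compare_scaling_modes(d, p, modes = c("none", "ffm"),
                               control = list(maxit = 60, se = FALSE))
  expect_identical(nrow(cmp$summary), 2L)
  expect_true(all(is.finite(cmp$summary$ofv)))
  expect_identical(cmp$summary$rank, 1:2)
  expect_identical(cmp$selected, cmp$summary$mode[1])
  expect_lte(cmp$summary$ofv[1], cmp$summary$ofv[2] + 0.01)
})
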