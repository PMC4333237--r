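test_that("fat-free mass follows the sex-specific hyperbolic formula", {
  # frozen value computed by direct evaluation of the formula:
  # 42.92 * 1.75^2 * 70 / (30.93 * 1.75^2 + 70) = 55.857...
  expect_equal(compute_ffm("male", 70, 1.75), 55.857, tolerance = 1e-4)
  # female constants give strictly lower FFM at identical weight and height
  expect_lt(compute_ffm("female", 70, 1.75), compute_ffm("male", 70, 1.75))
  # FFM is bounded above by WHS_MAX * HT^2 and approaches it as WT grows
  ht <- 1.75
  cap <- 42.92 * ht^2
  heavy <- compute_ffm("male", 1e6, ht)
  expect_lt(heavy, cap)
  expect_equal(heavy, cap, tolerance = 1e-3)
  expect_lt(compute_ffm("male", 120, ht), heavy)
  # always strictly positive and below total weight
  for (wt in c(40, 70, 120)) {
    f <- compute_ffm("female", wt, 1.6)
    expect_gt(f, 0)
    expect_lt(f, wt)
  }
  expect_error(compute_ffm("male", -1, 1.7), "weight")
  expect_error(compute_ffm("male", 70, 0), "height")
})

test_that("normal fat mass interpolates between FFM and total weight", {
  expect_identical(compute_nfm(55, 70, 0), 55)
  expect_identical(compute_nfm(55, 70, 1), 70)
  expect_identical(compute_nfm(55, 70, 0.5), 62.5)
  expect_error(compute_nfm(75, 70, 0.5), "exceed")
})

test_that("allometric scaling follows fixed 3/4 and 1 exponents", {
  p <- ref_params(scaling_mode = "bodyweight")
  cov70 <- subject_covariates("a", "male", 70, 1.75)
  tv <- allometric_typical_values(p, cov70)
  expect_equal(tv$cl_typ, 3.85)
  expect_equal(tv$vc_typ, 76.6)
  cov35 <- subject_covariates("b", "male", 35, 1.75)
  tv35 <- allometric_typical_values(p, cov35)
  expect_equal(tv35$cl_typ, 3.85 * 0.5^0.75)
  expect_equal(tv35$vc_typ, 76.6 * 0.5)
  # no scaling ignores covariates entirely
  p_none <- ref_params(scaling_mode = "none")
  tvn <- allometric_typical_values(p_none, cov35)
  expect_equal(tvn$cl_typ, 3.85)
  expect_equal(tvn$vc_typ, 76.6)
})

test_that("all scaling modes agree when the size descriptor equals 70 kg", {
  # choose height so that male FFM equals exactly 70 kg, then weight = FFM
  # forces NFM = 70 for any ffat, and bodyweight = 70 needs weight 70
  ffm_target <- 70
  # solve 42.92 h^2 w / (30.93 h^2 + w) = 70 at w chosen per mode
  p_ffm <- ref_params(scaling_mode = "ffm")
  # find (w, h) with FFM(w, h) = 70: fix h = 1.9, solve for w
  h <- 1.9
  w <- ffm_target * 30.93 * h^2 / (42.92 * h^2 - ffm_target)
  expect_equal(compute_ffm("male", w, h), 70, tolerance = 1e-12)
  cov_ffm <- subject_covariates("x", "male", w, h)
  tv_ffm <- allometric_typical_values(p_ffm, cov_ffm)
  cov_bw <- subject_covariates("y", "male", 70, 1.75)
  tv_bw <- allometric_typical_values(ref_params(scaling_mode = "bodyweight"),
                                     cov_bw)
  tv_none <- allometric_typical_values(ref_params(scaling_mode = "none"),
                                       cov_bw)
  # nfm with weight equal to ffm collapses to ffm = 70 for any ffat
  cov_nfm <- subject_covariates("z", "male", compute_ffm("male", w, h), h)
  # weight slightly below FFM would be unphysical; use weight = FFM exactly
  p_nfm <- ref_params(scaling_mode = "nfm", ffat_cl = 0.7, ffat_v = 0.3)
  tv_nfm <- allometric_typical_values(p_nfm, cov_nfm)
  for (tv in list(tv_ffm, tv_bw, tv_none)) {
    expect_equal(tv$cl_typ, 3.85, tolerance = 1e-10)
    expect_equal(tv$vc_typ, 76.6, tolerance = 1e-10)
  }
  # NFM at weight == FFM: descriptor is FFM(weight, h) which is < 70 here;
  # instead verify the interpolation property directly
  ffm_z <- compute_ffm("male", cov_nfm$weight, cov_nfm$height)
  expect_equal(tv_nfm$cl_typ,
               3.85 * (compute_nfm(ffm_z, cov_nfm$weight, 0.7) / 70)^0.75)
})

test_that("enzyme production multiplier is saturable and bounded", {
  expect_identical(enzyme_production_multiplier(0, 1.04, 0.0705), 1)
  expect_equal(enzyme_production_multiplier(0.0705, 1.04, 0.0705),
               1 + 1.04 / 2)
  # asymptote: frozen limit 1 + emax
  expect_equal(enzyme_production_multiplier(1e9, 1.04, 0.0705), 2.04,
               tolerance = 1e-7)
  cp <- seq(0, 10, by = 0.5)
  mult <- enzyme_production_multiplier(cp, 1.04, 0.0705)
  expect_true(all(diff(mult) > 0))
  expect_true(all(mult <= 2.04))
  expect_error(enzyme_production_multiplier(-1, 1.04, 0.0705), "cp")
})

test_that("unbound ratios divide the total ratio by the plasma free fraction", {
  expect_equal(unbound_ratio(1.1, 0.2), 5.5)
  # the formula value for the ELF ratio is 1.30 (0.26 / 0.2)
  expect_equal(unbound_ratio(0.26, 0.2), 1.30)
  expect_identical(unbound_ratio(0.77, 1), 0.77)
  expect_error(unbound_ratio(1.1, 0), "fu_plasma")
})

test_that("mass is conserved across transit, depot and central compartments", {
  # no elimination; ELF/AC are concentration-driven and carry no mass
  p <- ref_params(cl_std = 1e-12, scaling_mode = "none")
  reg <- dosing_regimen(600, 24, 3)
  sol <- solve_model(p, 1e-12, 76.6, reg, seq(0, 72, by = 1))
  total <- sol[, "transit1"] + sol[, "depot"] + sol[, "central"]
  # rows at event times report the pre-dose state, hence strict inequality
  dosed <- vapply(sol[, "time"],
                  function(t) 600 * sum(dose_times(reg) < t), numeric(1))
  expect_equal(total, dosed, tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("effect compartments equilibrate to ratio times plasma", {
  # constant plasma concentration: preload central, no elimination, no dosing
  p <- ref_params(cl_std = 1e-12, scaling_mode = "none")
  reg <- data.frame(time = 0, amt = 1e-12)  # negligible dose event
  cbar <- 5
  ntr <- 1L
  y0 <- c(transit1 = 0, depot = 0, central = cbar * 76.6, enzyme = 1,
          celf = 0, cac = 0)
  # 20 equilibration half-lives of k = 41.58 1/h
  t_end <- 20 * log(2) / 41.58
  pp <- c(ntr, 2 / p$mtt, 0, 1e-12, 76.6, 0, p$ec50, 0, p$k_elf, p$k_ac,
          p$r_elf_plasma, p$r_ac_plasma)
  sol <- deSolve::lsoda(y0, c(0, t_end), func = "pulmo_derivs", parms = pp,
                        dllname = "pulmopk", initfunc = "pulmo_initmod",
                        rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(sol[2, "celf"]), p$r_elf_plasma * cbar,
               tolerance = 1e-6)
  expect_equal(unname(sol[2, "cac"]), p$r_ac_plasma * cbar,
               tolerance = 1e-6)
})

test_that("the equilibration half-life of the fixed rate constant is ~1 min", {
  p <- ref_params()
  expect_equal(log(2) / p$k_elf * 60, 1, tolerance = 0.01)
})

test_that("enzyme pool stays at baseline without drug", {
  p <- ref_params(scaling_mode = "none")
  reg <- data.frame(time = 1000, amt = 600)  # dose beyond the horizon
  sol <- solve_model(p, 3.85, 76.6, reg, seq(0, 500, by = 50))
  keep <- sol[, "time"] <= 500
  expect_equal(sol[keep, "enzyme"], rep(1, sum(keep)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("without induction the profile matches the linear closed form", {
  # emax = 0: transit1 -> depot -> central is a linear cascade; oracle is
  # the matrix exponential of the rate matrix for a single oral dose
  p <- ref_params(emax = 0, scaling_mode = "none")
  cl <- 3.85; vc <- 76.6
  ktr <- 2 / p$mtt; ka <- p$ka; kel <- cl / vc
  A <- matrix(c(-ktr, 0, 0,
                ktr, -ka, 0,
                0, ka, -kel), nrow = 3, byrow = TRUE)
  y0 <- c(600, 0, 0)
  times <- c(0.25, 0.5, 1, 2, 4, 8, 12, 24)
  oracle <- vapply(times, function(t) {
    (as.matrix(Matrix::expm(A * t)) %*% y0)[3] / vc
  }, numeric(1))
  sol <- solve_model(p, cl, vc, data.frame(time = 0, amt = 600), times)
  got <- sol[match(times, sol[, "time"]), "cp"]
  expect_equal(got, oracle, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("a dominating concentration profile induces at least as much", {
  # over one day, doubling the dose keeps plasma concentrations pointwise
  # above the smaller dose; the enzyme pool must then be ordered the same way
  p <- ref_params(scaling_mode = "none")
  times <- seq(0, 24, by = 0.25)
  hi <- solve_model(p, 3.85, 76.6, data.frame(time = 0, amt = 600), times)
  lo <- solve_model(p, 3.85, 76.6, data.frame(time = 0, amt = 300), times)
  expect_true(all(hi[, "cp"] >= lo[, "cp"] - 1e-10))
  expect_true(all(hi[, "enzyme"] >= lo[, "enzyme"] - 1e-10))
  expect_gt(hi[length(times), "enzyme"], lo[length(times), "enzyme"])
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(ref_params(cl_std = -1), "cl_std")
  expect_error(ref_params(fu_plasma = 1.5), "fu_plasma")
  expect_error(ref_params(n_transit = 1.5), "n_transit")
  expect_error(rifampicin_params(), "ka")
  expect_error(subject_covariates("s", "other", 70, 1.7))
})

test_that("between-subject variability converts to both percent conventions", {
  expect_equal(iiv_percent(0.888), 88.8)
  expect_equal(iiv_percent(0.888, "cv"), 100 * sqrt(exp(0.888^2) - 1))
  expect_gt(iiv_percent(0.888, "cv"), iiv_percent(0.888, "sd"))
  expect_identical(iiv_percent(0), 0)
})
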