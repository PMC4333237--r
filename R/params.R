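#' Population parameters of the pulmonary PK model
#'
#' Constructs and validates the full fixed-effect / variability parameter set
#' of the model: transit-compartment absorption, one-compartment disposition
#' with enzyme turn-over autoinduction of oral clearance, allometric scaling,
#' and ELF/AC effect-compartment penetration.
#'
#' All clearances and volumes are apparent (per bioavailability F); units are
#' mg, L and h throughout, concentrations mg/L.
#'
#' @param cl_std typical pre-induced oral clearance (L/h) standardized to a
#'   70 kg value of the chosen size descriptor.
#' @param vc_std typical apparent central volume of distribution (L) at 70 kg.
#' @param mtt mean transit time of the absorption chain (h).
#' @param n_transit number of transit compartments (non-negative integer).
#' @param ka first-order absorption rate constant (1/h) from the depot to the
#'   central compartment.  There is no default: the value must be supplied
#'   explicitly (see [rifampicin_params()] for the reference configuration).
#' @param emax maximal fold-increase of the enzyme production rate.
#' @param ec50 plasma concentration (mg/L) giving half-maximal induction.
#' @param k_enz first-order enzyme turn-over rate constant (1/h).
#' @param k_elf,k_ac plasma-to-ELF and plasma-to-AC equilibration rate
#'   constants (1/h).
#' @param r_elf_plasma,r_ac_plasma pseudo-steady-state total ELF/plasma and
#'   AC/plasma concentration ratios.
#' @param fu_plasma unbound fraction of drug in plasma, in (0, 1].
#' @param ffat_cl,ffat_v fat-mass contribution parameters of the normal-fat-
#'   mass size descriptor for CL/F and Vc/F respectively, each in \[0, 1\].
#' @param omega_cl standard deviation of the lognormal between-subject
#'   variability on CL/F (eta scale).
#' @param sigma_plasma,sigma_elf,sigma_ac proportional residual-error
#'   standard deviations per observation matrix.
#' @param scaling_mode allometric size descriptor: one of `"none"`,
#'   `"bodyweight"`, `"ffm"`, `"nfm"`.
#' @param fixed_mask named logical vector marking parameters as fixed (TRUE)
#'   or estimable (FALSE).  Defaults to [default_fixed_mask()].
#'
#' @return An object of class `pulmo_params` (a validated named list).
#' @seealso [rifampicin_params()] for the reference rifampicin values.
#' @export
population_parameters <- function(cl_std, vc_std, mtt, n_transit, ka,
                                  emax, ec50, k_enz, k_elf, k_ac,
                                  r_elf_plasma, r_ac_plasma,
                                  fu_plasma = 0.2,
                                  ffat_cl = 0.5, ffat_v = 0.5,
                                  omega_cl, sigma_plasma, sigma_elf, sigma_ac,
                                  scaling_mode = c("ffm", "none", "bodyweight",
                                                   "nfm"),
                                  fixed_mask = default_fixed_mask()) {
  scaling_mode <- match.arg(scaling_mode)
  p <- list(
    cl_std = cl_std, vc_std = vc_std, mtt = mtt, n_transit = n_transit,
    ka = ka, emax = emax, ec50 = ec50, k_enz = k_enz,
    k_elf = k_elf, k_ac = k_ac,
    r_elf_plasma = r_elf_plasma, r_ac_plasma = r_ac_plasma,
    fu_plasma = fu_plasma, ffat_cl = ffat_cl, ffat_v = ffat_v,
    omega_cl = omega_cl, sigma_plasma = sigma_plasma,
    sigma_elf = sigma_elf, sigma_ac = sigma_ac,
    scaling_mode = scaling_mode, fixed_mask = fixed_mask
  )
  class(p) <- "pulmo_params"
  validate_params(p)
  p
}

#' Default estimate/fix flags of the reference model
#'
#' The reference analysis estimates the typical clearance and volume, the two
#' penetration ratios, the between-subject variability on CL/F and the three
#' proportional-error magnitudes; the absorption parameters, the autoinduction
#' parameters, the equilibration rate constants, the unbound fraction and the
#' fat-mass contributions are fixed.
#'
#' @return Named logical vector; `TRUE` means fixed.
#' @export
default_fixed_mask <- function() {
  c(cl_std = FALSE, vc_std = FALSE,
    mtt = TRUE, n_transit = TRUE, ka = TRUE,
    emax = TRUE, ec50 = TRUE, k_enz = TRUE,
    k_elf = TRUE, k_ac = TRUE,
    r_elf_plasma = FALSE, r_ac_plasma = FALSE,
    fu_plasma = TRUE, ffat_cl = TRUE, ffat_v = TRUE,
    omega_cl = FALSE,
    sigma_plasma = FALSE, sigma_elf = FALSE, sigma_ac = FALSE)
}

#' Reference rifampicin parameter set
#'
#' Final-model parameter values for 600 mg oral rifampicin: typical
#' pre-induced oral clearance 3.85 L/h and central volume 76.6 L (both
#' standardized to 70 kg fat-free mass), mean transit time 0.71 h with one
#' transit compartment, Emax-type autoinduction (Emax 1.04, EC50 0.0705 mg/L,
#' enzyme turn-over rate 0.0036 1/h), ELF and AC equilibration rate constants
#' fixed at 41.58 1/h (an equilibration half-life of about one minute,
#' i.e. effectively instantaneous distribution), total ELF/plasma and
#' AC/plasma ratios 0.26 and 1.1, plasma unbound fraction 0.2, 88.8%
#' between-subject variability on CL/F and proportional residual errors of
#' 35.2% (plasma), 40.7% (ELF) and 37.1% (AC).
#'
#' The absorption rate constant `ka` has no published value in this model
#' family's headline table and therefore must be supplied by the caller; the
#' packaged reference configuration uses 2 1/h, chosen so that absorption is
#' fast relative to elimination, standing in for the fixed literature value.
#'
#' @param ka absorption rate constant (1/h); required, no silent default.
#' @param scaling_mode allometric size descriptor (default fat-free mass,
#'   the final model's choice).
#' @param ... overrides passed on to [population_parameters()].
#' @return A `pulmo_params` object.
#' @examples
#' p <- rifampicin_params(ka = 2)
#' p$cl_std
#' @export
rifampicin_params <- function(ka, scaling_mode = "ffm", ...) {
  if (missing(ka)) {
    stop("'ka' must be supplied explicitly: the absorption rate constant ",
         "has no published value in this parameterization", call. = FALSE)
  }
  defaults <- list(
    cl_std = 3.85, vc_std = 76.6, mtt = 0.71, n_transit = 1L, ka = ka,
    emax = 1.04, ec50 = 0.0705, k_enz = 0.0036,
    k_elf = 41.58, k_ac = 41.58,
    r_elf_plasma = 0.26, r_ac_plasma = 1.1,
    fu_plasma = 0.2,
    omega_cl = 0.888, sigma_plasma = 0.352, sigma_elf = 0.407,
    sigma_ac = 0.371,
    scaling_mode = scaling_mode
  )
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(population_parameters, defaults)
}

validate_params <- function(p) {
  stopifnot(inherits(p, "pulmo_params"))
  pos <- c("cl_std", "vc_std", "mtt", "ka", "ec50", "k_enz", "k_elf", "k_ac",
           "r_elf_plasma", "r_ac_plasma")
  for (nm in pos) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
      stop("parameter '", nm, "' must be strictly positive", call. = FALSE)
    }
  }
  nonneg <- c("emax", "omega_cl", "sigma_plasma", "sigma_elf", "sigma_ac")
  for (nm in nonneg) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 0) {
      stop("parameter '", nm, "' must be non-negative", call. = FALSE)
    }
  }
  if (p$n_transit < 0 || p$n_transit != round(p$n_transit)) {
    stop("'n_transit' must be a non-negative integer", call. = FALSE)
  }
  if (p$fu_plasma <= 0 || p$fu_plasma > 1) {
    stop("'fu_plasma' must lie in (0, 1]", call. = FALSE)
  }
  for (nm in c("ffat_cl", "ffat_v")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) {
      stop("'", nm, "' must lie in [0, 1]", call. = FALSE)
    }
  }
  if (!p$scaling_mode %in% c("none", "bodyweight", "ffm", "nfm")) {
    stop("unknown scaling_mode '", p$scaling_mode, "'", call. = FALSE)
  }
  invisible(p)
}

#' Subject covariates
#'
#' @param subject_id identifier (coerced to character).
#' @param sex `"male"` or `"female"`.
#' @param weight body weight (kg), positive.
#' @param height height (m), positive.
#' @return A `pulmo_covariates` list.
#' @export
subject_covariates <- function(subject_id, sex, weight, height) {
  sex <- match.arg(sex, c("male", "female"))
  if (!is.finite(weight) || weight <= 0) {
    stop("'weight' must be strictly positive", call. = FALSE)
  }
  if (!is.finite(height) || height <= 0) {
    stop("'height' must be strictly positive", call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id), sex = sex,
                 weight = weight, height = height),
            class = "pulmo_covariates")
}

#' Fat-free mass from sex, weight and height
#'
#' Computes fat-free mass as
#' \deqn{FFM = \frac{WHS_{max} \, HT^2 \, WT}{WHS_{50} \, HT^2 + WT}}
#' with maximal weight-over-height-squared \eqn{WHS_{max}} = 42.92 kg/m^2 and
#' \eqn{WHS_{50}} = 30.93 kg/m^2 in men, and 37.99 and 35.98 kg/m^2 in women.
#'
#' @param sex `"male"` or `"female"` (vectorized).
#' @param weight body weight WT (kg).
#' @param height height HT (m).
#' @return Fat-free mass (kg), strictly between 0 and `weight`.
#' @examples
#' compute_ffm("male", 70, 1.75)
#' @export
compute_ffm <- function(sex, weight, height) {
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop("'weight' must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(height)) || any(height <= 0)) {
    stop("'height' must be strictly positive", call. = FALSE)
  }
  sex <- match.arg(sex, c("male", "female"), several.ok = TRUE)
  whs_max <- ifelse(sex == "male", 42.92, 37.99)
  whs_50 <- ifelse(sex == "male", 30.93, 35.98)
  whs_max * height^2 * weight / (whs_50 * height^2 + weight)
}

#' Normal fat mass from fat-free mass and total weight
#'
#' \eqn{NFM = FFM + Ffat \cdot (WT - FFM)}: a convex combination of fat-free
#' mass (`ffat = 0`) and total body weight (`ffat = 1`).
#'
#' @param ffm fat-free mass (kg).
#' @param weight total body weight (kg); must be at least `ffm`.
#' @param ffat fat-mass contribution, typically in \[0, 1\].
#' @return Normal fat mass (kg).
#' @export
compute_nfm <- function(ffm, weight, ffat) {
  if (any(ffm <= 0)) stop("'ffm' must be strictly positive", call. = FALSE)
  if (any(ffm > weight)) {
    stop("'ffm' may not exceed total body weight", call. = FALSE)
  }
  ffm + ffat * (weight - ffm)
}

#' Allometrically scaled typical clearance and volume
#'
#' Scales the standardized typical values to an individual by
#' \eqn{TV(CL/F) = (CL/F)_{STD} (MASS/70)^{3/4}} and
#' \eqn{TV(Vc/F) = (Vc/F)_{STD} (MASS/70)^{1}}, where MASS is the size
#' descriptor selected by `params$scaling_mode`: total body weight, fat-free
#' mass, or normal fat mass (with separate fat-mass contributions for CL/F
#' and Vc/F).  With `scaling_mode = "none"` the standardized values are
#' returned unchanged.
#'
#' @param params a `pulmo_params` object.
#' @param cov a `pulmo_covariates` object.
#' @return List with elements `cl_typ` (L/h) and `vc_typ` (L).
#' @export
allometric_typical_values <- function(params, cov) {
  mode <- params$scaling_mode
  if (mode == "none") {
    return(list(cl_typ = params$cl_std, vc_typ = params$vc_std))
  }
  if (mode == "bodyweight") {
    mass_cl <- mass_v <- cov$weight
  } else if (mode == "ffm") {
    mass_cl <- mass_v <- compute_ffm(cov$sex, cov$weight, cov$height)
  } else if (mode == "nfm") {
    ffm <- compute_ffm(cov$sex, cov$weight, cov$height)
    mass_cl <- compute_nfm(ffm, cov$weight, params$ffat_cl)
    mass_v <- compute_nfm(ffm, cov$weight, params$ffat_v)
  } else {
    stop("unknown scaling_mode '", mode, "'", call. = FALSE)
  }
  list(cl_typ = params$cl_std * (mass_cl / 70)^0.75,
       vc_typ = params$vc_std * (mass_v / 70)^1)
}

#' Drug-stimulated enzyme production multiplier
#'
#' Saturable (Emax-type) stimulation of the enzyme production rate by the
#' plasma concentration: `1 + emax * cp / (ec50 + cp)`.  Equal to 1 without
#' drug, half-maximal at `cp = ec50`, bounded above by `1 + emax`.
#'
#' @param cp plasma concentration (mg/L), non-negative; vectorized.
#' @param emax maximal fold-increase of the production rate.
#' @param ec50 concentration of half-maximal stimulation (mg/L).
#' @return Dimensionless multiplier of the baseline production rate.
#' @export
enzyme_production_multiplier <- function(cp, emax, ec50) {
  if (any(cp < 0)) stop("'cp' must be non-negative", call. = FALSE)
  1 + emax * cp / (ec50 + cp)
}

#' Total-to-unbound concentration-ratio conversion
#'
#' Divides a total tissue/plasma concentration ratio by the unbound fraction
#' in plasma, yielding the tissue/unbound-plasma ratio (protein binding in
#' the tissue itself assumed negligible).
#'
#' @param r_total total concentration ratio (tissue over plasma).
#' @param fu_plasma unbound plasma fraction, in (0, 1].
#' @return Unbound concentration ratio.
#' @examples
#' unbound_ratio(1.1, 0.2)  # 5.5
#' @export
unbound_ratio <- function(r_total, fu_plasma) {
  if (any(!is.finite(fu_plasma)) || any(fu_plasma <= 0) ||
      any(fu_plasma > 1)) {
    stop("'fu_plasma' must lie in (0, 1]", call. = FALSE)
  }
  r_total / fu_plasma
}

#' Between-subject variability in percent
#'
#' A lognormal random effect with SD `omega` is conventionally reported
#' either as `100 * omega` (the approximate-SD scale used alongside the
#' reference estimates, e.g. 88.8% for omega = 0.888) or as the exact
#' lognormal coefficient of variation `100 * sqrt(exp(omega^2) - 1)`.
#'
#' @param omega SD of the random effect on the log scale.
#' @param method `"sd"` (default) or `"cv"`.
#' @return Variability in percent.
#' @examples
#' iiv_percent(0.888)          # 88.8
#' iiv_percent(0.888, "cv")    # exact lognormal CV, larger
#' @export
iiv_percent <- function(omega, method = c("sd", "cv")) {
  method <- match.arg(method)
  if (any(omega < 0)) stop("'omega' must be non-negative", call. = FALSE)
  switch(method,
         sd = 100 * omega,
         cv = 100 * sqrt(exp(omega^2) - 1))
}
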