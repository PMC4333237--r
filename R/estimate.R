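#' Split an event table into per-subject structures
#'
#' @param dataset a validated event table.
#' @return A named list, one element per subject, each a list with `cov`
#'   (a `pulmo_covariates`), `doses` (data frame `time`, `amt`) and `obs`
#'   (data frame `time`, `matrix`, `dv`).
#' @export
split_dataset <- function(dataset) {
  validate_event_table(dataset)
  ids <- unique(dataset$id)
  out <- lapply(ids, function(sid) {
    sub <- dataset[dataset$id == sid, ]
    obs <- sub[sub$evid == 0L & sub$mdv == 0L, ]
    list(cov = subject_covariates(sid, sub$sex[1], sub$weight[1],
                                  sub$height[1]),
         doses = data.frame(time = sub$time[sub$evid == 1L],
                            amt = sub$amt[sub$evid == 1L]),
         obs = data.frame(time = obs$time, matrix = obs$matrix, dv = obs$dv,
                          stringsAsFactors = FALSE))
  })
  names(out) <- ids
  out
}

# Variance floor guarding the proportional-error likelihood against a zero
# prediction (e.g. a sample scheduled before the first dose).
.pred_floor <- 1e-10

# Noise-free predictions for one subject at a given eta, from a single ODE
# solve with unit penetration ratios (the effect compartments are linear in
# the ratio, so r_elf / r_ac multiply the unit response outside the solver).
subject_predictions <- function(subject, params, eta_cl) {
  tv <- allometric_typical_values(params, subject$cov)
  sol <- solve_model(params, tv$cl_typ * exp(eta_cl), tv$vc_typ,
                     subject$doses, subject$obs$time, relf = 1, rac = 1)
  idx <- match(subject$obs$time, sol[, "time"])
  f <- numeric(nrow(subject$obs))
  m <- subject$obs$matrix
  f[m == "plasma"] <- sol[idx[m == "plasma"], "cp"]
  f[m == "ELF"] <- params$r_elf_plasma * sol[idx[m == "ELF"], "celf"]
  f[m == "AC"] <- params$r_ac_plasma * sol[idx[m == "AC"], "cac"]
  f
}

#' Conditional -2 log-likelihood of one subject
#'
#' The joint -2 log-density of one subject's observations and random effect,
#' \deqn{\sum_j \log(2\pi v_j) + (y_j - f_j(\eta))^2 / v_j
#'       + \eta^2/\omega^2 + \log(2\pi\omega^2),}
#' with interaction-style residual variance \eqn{v_j = f_j(\eta)^2
#' \sigma_m^2} evaluated at the eta-conditional prediction (sigma chosen by
#' observation matrix).  Minimizing this over eta gives the empirical-Bayes
#' mode used by the Laplace-type marginal approximation.  With
#' `omega_cl = 0` the two prior terms are dropped and `eta_cl` must be 0.
#'
#' @param subject one element of [split_dataset()].
#' @param params `pulmo_params`.
#' @param eta_cl random effect on log clearance.
#' @return Scalar -2 log-likelihood contribution.
#' @export
individual_neg2ll <- function(subject, params, eta_cl) {
  f <- subject_predictions(subject, params, eta_cl)
  conditional_neg2ll(subject$obs$dv, f,
                     sigma_for_matrix(params, subject$obs$matrix),
                     eta_cl, params$omega_cl)
}

conditional_neg2ll <- function(y, f, sig, eta, omega) {
  v <- pmax(abs(f), .pred_floor)^2 * sig^2
  val <- sum(log(2 * pi * v) + (y - f)^2 / v)
  if (omega > 0) {
    val <- val + eta^2 / omega^2 + log(2 * pi * omega^2)
  } else if (eta != 0) {
    stop("'eta_cl' must be 0 when omega_cl is 0", call. = FALSE)
  }
  val
}

# Laplace-approximated -2 log marginal likelihood of one subject:
# j(eta_hat) + log j''(eta_hat) - log(4 pi), with the mode found by a
# safeguarded Newton search on numerically differentiated j.
subject_laplace <- function(subject, params, eta_start = 0,
                            h = 0.02, tol = 1e-4, max_iter = 15L) {
  omega <- params$omega_cl
  y <- subject$obs$dv
  sig <- sigma_for_matrix(params, subject$obs$matrix)
  cache <- new.env(parent = emptyenv())
  jfun <- function(eta) {
    key <- sprintf("%.15g", eta)
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    f <- subject_predictions(subject, params, eta)
    val <- conditional_neg2ll(y, f, sig, eta, omega)
    cache[[key]] <- val
    val
  }
  if (omega == 0) {
    return(list(neg2ll = jfun(0), eta = 0, curvature = NA_real_,
                ok = TRUE, n_solves = 1L))
  }
  eta <- eta_start
  bound <- min(8, 6 * omega + 1)
  eta <- max(min(eta, bound), -bound)
  curv <- NA_real_
  for (it in seq_len(max_iter)) {
    j0 <- jfun(eta)
    jp <- jfun(eta + h)
    jm <- jfun(eta - h)
    g <- (jp - jm) / (2 * h)
    curv <- (jp - 2 * j0 + jm) / h^2
    step <- if (is.finite(curv) && curv > 1e-8) -g / curv else
      -sign(g) * 0.25
    step <- max(min(step, 1), -1)
    eta_new <- max(min(eta + step, bound), -bound)
    if (abs(eta_new - eta) < tol) {
      eta <- eta_new
      break
    }
    # backtrack if the Newton step increased j
    if (jfun(eta_new) > j0 + 1e-12) {
      eta_new <- eta + 0.5 * (eta_new - eta)
      if (jfun(eta_new) > j0) eta_new <- eta + 0.1 * (eta_new - eta) * 2
    }
    eta <- eta_new
  }
  ok <- is.finite(curv) && curv > 0
  n2ll <- jfun(eta) + log(max(curv, 1e-10)) - log(4 * pi)
  list(neg2ll = n2ll, eta = eta, curvature = curv, ok = ok,
       n_solves = length(ls(cache)))
}

#' Exact marginal -2 log-likelihood of one subject by quadrature
#'
#' Integrates the conditional likelihood over the single random effect with
#' adaptive quadrature, providing an independent oracle for the Laplace-type
#' approximation on small instances.
#'
#' @inheritParams individual_neg2ll
#' @return Scalar -2 log marginal likelihood.
#' @export
marginal_neg2ll_quad <- function(subject, params) {
  if (params$omega_cl == 0) return(individual_neg2ll(subject, params, 0))
  jfun <- function(eta) individual_neg2ll(subject, params, eta)
  mode <- stats::optimize(jfun, c(-6 * params$omega_cl - 1,
                                  6 * params$omega_cl + 1), tol = 1e-8)
  jmin <- mode$objective
  integrand <- Vectorize(function(eta) {
    j <- jfun(eta)
    if (!is.finite(j)) return(0)
    exp(-0.5 * (j - jmin))
  })
  # the integrand is negligible beyond ~10 prior SDs from the mode
  lim <- 10 * params$omega_cl + 1
  q <- stats::integrate(integrand, mode$minimum - lim, mode$minimum + lim,
                        rel.tol = 1e-9)
  jmin - 2 * log(q$value)
}

# Cohort-level Laplace approximation: the inner Newton iteration on every
# subject's eta runs in lockstep so each iteration needs only three stacked
# ODE solves (center and the two finite-difference points) for the whole
# population.
population_laplace <- function(subjects, params, eta_start = NULL,
                               h = 0.02, tol = 2e-4, max_iter = 10L,
                               ctx = NULL) {
  m <- length(subjects)
  omega <- params$omega_cl
  use3 <- 3L * m <= .pulmo_max_stack
  if (is.null(ctx)) ctx <- make_population_ctx(subjects, params$n_transit)
  ylist <- lapply(subjects, function(s) s$obs$dv)
  siglist <- lapply(subjects, function(s) {
    sigma_for_matrix(params, s$obs$matrix)
  })
  tv <- lapply(subjects, function(s) allometric_typical_values(params, s$cov))
  cl_typ <- vapply(tv, `[[`, numeric(1), "cl_typ")
  vc_typ <- vapply(tv, `[[`, numeric(1), "vc_typ")
  jfrom <- function(preds, etas, off = 0L) {
    vapply(seq_len(m), function(i) {
      conditional_neg2ll(ylist[[i]], preds[[off + i]], siglist[[i]],
                         etas[i], omega)
    }, numeric(1))
  }
  jvec <- function(etas) {
    preds <- if (m <= .pulmo_max_stack) {
      stacked_predict_ctx(ctx$c1, params, cl_typ * exp(etas), vc_typ)
    } else stacked_predictions(subjects, params, etas, reduced = TRUE)
    jfrom(preds, etas)
  }
  # center and the two finite-difference points share one stacked solve
  jvec3 <- function(etas) {
    if (use3) {
      ee <- c(etas, etas + h, etas - h)
      preds <- stacked_predict_ctx(ctx$c3, params,
                                   rep(cl_typ, 3L) * exp(ee),
                                   rep(vc_typ, 3L))
      list(j0 = jfrom(preds, etas),
           jp = jfrom(preds, etas + h, m),
           jm = jfrom(preds, etas - h, 2L * m))
    } else {
      list(j0 = jvec(etas), jp = jvec(etas + h), jm = jvec(etas - h))
    }
  }
  if (omega == 0) {
    j0 <- jvec(rep(0, m))
    return(list(total = sum(j0), etas = rep(0, m), curv = rep(NA_real_, m)))
  }
  if (is.null(eta_start)) eta_start <- rep(0, m)
  bound <- min(8, 6 * omega + 1)
  etas <- pmin(pmax(eta_start, -bound), bound)
  j0 <- g <- curv <- NULL
  for (it in seq_len(max_iter)) {
    jj <- jvec3(etas)
    j0 <- jj$j0
    jp <- jj$jp
    jm <- jj$jm
    g <- (jp - jm) / (2 * h)
    curv <- (jp - 2 * j0 + jm) / h^2
    step <- ifelse(is.finite(curv) & curv > 1e-8, -g / curv,
                   -sign(g) * 0.25)
    step <- pmin(pmax(step, -1), 1)
    new_etas <- pmin(pmax(etas + step, -bound), bound)
    if (max(abs(new_etas - etas)) < tol) break
    etas <- new_etas
  }
  total <- sum(j0 + log(pmax(curv, 1e-10)) - log(4 * pi))
  list(total = total, etas = etas, curv = curv)
}

# The estimator runs on the reduced (plasma-subsystem) stack contexts; the
# full stiff system is used by the simulator and the VPC.
make_population_ctx <- function(subjects, n_transit) {
  m <- length(subjects)
  if (m > .pulmo_max_stack) return(list(c1 = NULL, c3 = NULL))
  list(c1 = make_stack_context(subjects, n_transit, reduced = TRUE),
       c3 = if (3L * m <= .pulmo_max_stack) {
         make_stack_context(rep(subjects, 3L), n_transit, reduced = TRUE)
       })
}

# ---- outer estimation ------------------------------------------------------

# Parameters that can in principle be freed in the outer optimization; all
# strictly positive, optimized on the log scale, except the ffat fractions
# which live on a logit scale in [0, 1].
.free_candidates <- c("cl_std", "vc_std", "mtt", "ka", "emax", "ec50",
                      "k_enz", "k_elf", "k_ac", "r_elf_plasma",
                      "r_ac_plasma", "omega_cl", "sigma_plasma",
                      "sigma_elf", "sigma_ac", "ffat_cl", "ffat_v")
.logit_pars <- c("ffat_cl", "ffat_v")

transform_par <- function(name, value) {
  if (name %in% .logit_pars) {
    v <- min(max(value, 1e-6), 1 - 1e-6)
    log(v / (1 - v))
  } else log(value)
}

untransform_par <- function(name, value) {
  if (name %in% .logit_pars) 1 / (1 + exp(-value)) else exp(value)
}

#' Count of distinct BAL sampling times in a dataset
#'
#' ELF/AC equilibration rate constants are only identifiable when BAL
#' samples exist at two or more distinct times (within or across subjects);
#' with the classic single-4-h design the rate of distribution cannot be
#' estimated and must stay fixed.  Times are compared after rounding to
#' 0.5 h so jittered versions of one nominal time count once.
#'
#' @param dataset event table.
#' @return Integer number of distinct BAL time points.
#' @export
n_distinct_bal_times <- function(dataset) {
  t_bal <- dataset$time[dataset$evid == 0L & dataset$matrix %in%
                          c("ELF", "AC")]
  length(unique(round(t_bal * 2) / 2))
}

#' Fit the population model by approximate marginal maximum likelihood
#'
#' Maximizes a Laplace-type approximation (FOCE with interaction flavor:
#' residual variance evaluated at the eta-conditional prediction) to the
#' marginal likelihood.  The single random effect per subject is profiled by
#' an inner safeguarded Newton search, warm-started across outer iterations;
#' the outer problem runs Nelder-Mead on log-transformed (positivity) or
#' logit-transformed (fat-fraction) parameters.
#'
#' @param dataset a validated event table.
#' @param start `pulmo_params` giving starting values and, through its
#'   `fixed_mask`, which parameters are estimated.
#' @param fixed_mask optional override of `start$fixed_mask`.
#' @param control list: `maxit` (outer Nelder-Mead iterations, default 500),
#'   `reltol` (default 1e-6), `se` (compute standard errors, default TRUE),
#'   `restarts` (number of Nelder-Mead restarts from the incumbent optimum,
#'   default 0; restarting rebuilds the simplex and polishes the solution),
#'   `trace` (default 0).
#' @return A `pulmo_fit` object: final `params`, free-parameter `estimates`,
#'   `ofv` (-2 log approximate marginal likelihood), `se` table (estimate,
#'   SE, RSE%), per-subject empirical-Bayes `eta`, `convergence` flag,
#'   `n_evals`, and the objective closure for diagnostics.  Non-convergence
#'   is reported through the flag, never as an error.
#' @export
fit <- function(dataset, start, fixed_mask = NULL, control = list()) {
  validate_params(start)
  ctl <- utils::modifyList(list(maxit = 500, reltol = 1e-6, se = TRUE,
                                restarts = 0, trace = 0), control)
  mask <- if (is.null(fixed_mask)) start$fixed_mask else fixed_mask
  free <- intersect(names(mask)[!mask], .free_candidates)
  if (!length(free)) stop("no free parameters to estimate", call. = FALSE)
  if (any(c("k_elf", "k_ac") %in% free) &&
      n_distinct_bal_times(dataset) < 2L) {
    stop("k_elf/k_ac cannot be freed: the design has fewer than two ",
         "distinct BAL sampling times, so the rate of distribution is not ",
         "identifiable", call. = FALSE)
  }
  subjects <- split_dataset(dataset)
  ctx <- make_population_ctx(subjects, start$n_transit)
  warm <- new.env(parent = emptyenv())
  warm$eta <- stats::setNames(rep(0, length(subjects)), names(subjects))
  n_evals <- 0L
  params_at <- function(par_log) {
    p <- start
    for (k in seq_along(free)) {
      p[[free[k]]] <- unname(untransform_par(free[k], par_log[k]))
    }
    p
  }
  objective <- function(par_log) {
    p <- params_at(par_log)
    n_evals <<- n_evals + 1L
    res <- population_laplace(subjects, p, eta_start = warm$eta, ctx = ctx)
    warm$eta[] <- res$etas
    if (!is.finite(res$total)) return(1e10)
    res$total
  }
  par0 <- vapply(free, function(nm) transform_par(nm, start[[nm]]),
                 numeric(1))
  opt <- stats::optim(par0, objective, method = "Nelder-Mead",
                      control = list(maxit = ctl$maxit, reltol = ctl$reltol,
                                     trace = ctl$trace))
  for (r in seq_len(ctl$restarts)) {
    opt <- stats::optim(opt$par, objective, method = "Nelder-Mead",
                        control = list(maxit = ctl$maxit,
                                       reltol = ctl$reltol,
                                       trace = ctl$trace))
  }
  final <- params_at(opt$par)
  # refresh empirical-Bayes etas and curvature diagnostics at the optimum
  ofv <- objective(opt$par)
  est <- vapply(free, function(nm) final[[nm]], numeric(1))
  res <- structure(list(params = final, free = free, estimates = est,
                        par_log = opt$par, ofv = ofv,
                        eta = warm$eta,
                        convergence = opt$convergence,
                        n_evals = n_evals,
                        message = opt$message,
                        objective = objective,
                        n_subjects = length(subjects),
                        n_obs = sum(vapply(subjects,
                                           function(s) nrow(s$obs),
                                           integer(1)))),
                   class = "pulmo_fit")
  if (opt$convergence != 0) {
    res$message <- paste0("outer optimizer did not report convergence ",
                          "(code ", opt$convergence, ")")
  }
  if (isTRUE(ctl$se)) res$se <- standard_errors(res)
  res
}

#' @export
print.pulmo_fit <- function(x, ...) {
  cat("Pulmonary PK model fit (Laplace-type approximate ML)\n")
  cat(sprintf("  subjects: %d  observations: %d\n", x$n_subjects, x$n_obs))
  cat(sprintf("  OFV: %.3f   objective evaluations: %d   converged: %s\n",
              x$ofv, x$n_evals, x$convergence == 0))
  tab <- if (!is.null(x$se)) x$se else
    data.frame(parameter = x$free, estimate = unname(x$estimates))
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Standard errors and relative standard errors of a fit
#'
#' Differentiates the objective numerically at the optimum; the covariance
#' of the transformed parameters is twice the inverse Hessian of the -2
#' log-likelihood.  Delta-method back-transformation gives natural-scale SEs
#' (for log-transformed parameters the RSE% equals 100 times the SE on the
#' log scale).  Fixed parameters get no SE.  A non-positive-definite
#' curvature yields `NA` standard errors with a warning, not an error.
#'
#' @param fit_result a `pulmo_fit`.
#' @return Data frame: parameter, estimate, se, rse_pct.
#' @export
standard_errors <- function(fit_result) {
  stopifnot(inherits(fit_result, "pulmo_fit"))
  H <- stats::optimHess(fit_result$par_log, fit_result$objective,
                        control = list(ndeps = rep(5e-3,
                                                   length(fit_result$free))))
  se_from_hessian(H, fit_result$free, fit_result$estimates)
}

# Shared SE arithmetic, testable against closed-form Hessians.
se_from_hessian <- function(H, free, estimates) {
  se_t <- rep(NA_real_, length(free))
  cov <- try(2 * solve(H), silent = TRUE)
  if (inherits(cov, "try-error") || any(diag(cov) <= 0)) {
    warning("curvature matrix is not positive definite; ",
            "standard errors omitted", call. = FALSE)
  } else {
    se_t <- sqrt(diag(cov))
  }
  scale <- vapply(seq_along(free), function(k) {
    # derivative of the back-transform at the estimate
    if (free[k] %in% .logit_pars) estimates[k] * (1 - estimates[k])
    else estimates[k]
  }, numeric(1))
  se_nat <- se_t * abs(scale)
  data.frame(parameter = free, estimate = unname(estimates),
             se = unname(se_nat),
             rse_pct = rse_percent(unname(estimates), unname(se_nat)))
}

#' Relative standard error in percent
#'
#' @param estimate parameter estimate(s).
#' @param se standard error(s).
#' @return `100 * se / |estimate|`.
#' @export
rse_percent <- function(estimate, se) 100 * se / abs(estimate)

#' Likelihood-ratio test between nested models
#'
#' The OFV difference between nested fits is referred to a chi-squared
#' distribution; with one additional parameter the 5% critical value is
#' 3.84.
#'
#' @param ofv_full OFV of the richer model.
#' @param ofv_reduced OFV of the nested (reduced) model.
#' @param d_params number of additional parameters in the full model (>= 1).
#' @param alpha significance level (default 0.05).
#' @return List: `delta_ofv`, `threshold`, `significant`.
#' @export
lrt <- function(ofv_full, ofv_reduced, d_params = 1L, alpha = 0.05) {
  if (d_params < 1) {
    stop("'d_params' must be a positive integer", call. = FALSE)
  }
  threshold <- stats::qchisq(1 - alpha, df = d_params)
  delta <- ofv_reduced - ofv_full
  list(delta_ofv = delta, threshold = threshold,
       significant = delta > threshold)
}

#' Fit all allometric scaling modes and rank them
#'
#' Convenience replay of structural size-descriptor selection: fits the
#' model with no scaling, total body weight, fat-free mass and normal fat
#' mass (the last freeing the two fat-fraction parameters), and ranks the
#' fits by OFV with ties broken in favor of fewer estimated parameters.
#'
#' @param dataset event table.
#' @param start `pulmo_params` starting values.
#' @param modes subset of the four scaling modes.
#' @param control passed to [fit()].
#' @return List with `summary` (data frame: mode, ofv, n_free, rank),
#'   `selected` (name of the preferred mode) and `fits`.
#' @export
compare_scaling_modes <- function(dataset, start,
                                  modes = c("none", "bodyweight", "ffm",
                                            "nfm"),
                                  control = list()) {
  fits <- lapply(modes, function(m) {
    p <- start
    p$scaling_mode <- m
    mask <- p$fixed_mask
    mask[c("ffat_cl", "ffat_v")] <- m != "nfm"
    p$fixed_mask <- mask
    fit(dataset, p, control = utils::modifyList(control, list(se = FALSE)))
  })
  names(fits) <- modes
  ofv <- vapply(fits, function(f) f$ofv, numeric(1))
  n_free <- vapply(fits, function(f) length(f$free), numeric(1))
  ord <- order(round(ofv, 2), n_free)
  summary <- data.frame(mode = modes, ofv = ofv, n_free = n_free)[ord, ]
  summary$rank <- seq_len(nrow(summary))
  rownames(summary) <- NULL
  list(summary = summary, selected = summary$mode[1L], fits = fits)
}
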