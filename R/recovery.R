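#' Simulation-and-reestimation experiment
#'
#' Replicates the classic stochastic-simulation-and-estimation workflow:
#' for each seed, a synthetic study is generated under the supplied "true"
#' parameters and the model is refitted to it, starting from the generating
#' values (the standard convention for simulation-estimation studies) and
#' freeing the parameters marked estimable in `params$fixed_mask`.
#'
#' The default design is a rich-BAL recovery design: one BAL sample per
#' subject with the BAL times spread over the cohort (`bal_times` recycled
#' across subjects), plasma samples at about 2 and 4 h after the last dose,
#' and no observation thinning.
#'
#' @param params true `pulmo_params` (also the starting values).
#' @param n_subjects cohort size per replicate.
#' @param n_male number of male subjects.
#' @param bal_times nominal BAL times (h post last dose) recycled across
#'   subjects.
#' @param seeds integer vector, one replicate per seed.
#' @param design optional [study_design_spec()] overriding the default
#'   recovery design.
#' @param control passed to [fit()]; defaults favor throughput
#'   (`maxit = 400`, `reltol = 1e-6`, no standard errors).
#' @return Data frame with one row per replicate: `seed`, `converged`,
#'   `ofv` and the free-parameter estimates; the column-wise medians of the
#'   estimates are attached as attribute `medians`.
#' @export
simulation_reestimation <- function(params, n_subjects = 50,
                                    n_male = ceiling(n_subjects / 2),
                                    bal_times = c(1, 4, 8),
                                    seeds = 1:10, design = NULL,
                                    control = list(maxit = 400,
                                                   reltol = 1e-6,
                                                   se = FALSE)) {
  if (is.null(design)) {
    design <- study_design_spec(n_subjects = n_subjects, n_male = n_male,
                                bal_times = bal_times, target_counts = NULL)
  }
  rows <- lapply(seeds, function(s) {
    d <- generate_study(design, params, seed = s)
    f <- fit(d, params, control = control)
    out <- data.frame(seed = s, converged = f$convergence == 0,
                      ofv = f$ofv)
    est <- as.list(f$estimates)
    if (!is.null(f$se)) {
      se <- stats::setNames(f$se$se, paste0("se_", f$se$parameter))
      est <- c(est, as.list(se))
    }
    cbind(out, as.data.frame(est))
  })
  res <- do.call(rbind, rows)
  est_cols <- setdiff(names(res), c("seed", "converged", "ofv",
                                    grep("^se_", names(res), value = TRUE)))
  attr(res, "medians") <- vapply(res[est_cols], stats::median, numeric(1))
  res
}
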