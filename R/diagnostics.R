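#' Prediction-correct observations within bins
#'
#' Rescales each observation by the ratio of its bin's median population
#' prediction to its own population prediction,
#' `y * median(PRED in bin) / PRED`, removing between-subject and
#' between-time variability in the typical prediction before percentiles are
#' compared.  Rows with a zero population prediction cannot be corrected and
#' are dropped with a warning.
#'
#' @param observations numeric vector of observed (or simulated) values.
#' @param population_predictions population (eta = 0) predictions, same
#'   length.
#' @param bins bin labels, same length.
#' @return Data frame `value` (corrected), `bin`, and the logical `kept`
#'   mapping back to the input rows.
#' @export
prediction_correct <- function(observations, population_predictions, bins) {
  stopifnot(length(observations) == length(population_predictions),
            length(observations) == length(bins))
  kept <- population_predictions != 0
  if (any(!kept)) {
    warning(sum(!kept), " observation(s) with zero population prediction ",
            "excluded from prediction correction", call. = FALSE)
  }
  y <- observations[kept]
  pred <- population_predictions[kept]
  b <- as.character(bins)[kept]
  med <- tapply(pred, b, stats::median)
  data.frame(value = y * unname(med[b]) / pred, bin = b,
             kept = which(kept))
}

# Default binning: matrix crossed with sampling time rounded to the nearest
# hour (nominal-time binning; automatic data-driven binning is unstable with
# two sampling times).
default_bins <- function(time, matrix) paste(matrix, round(time), sep = "@")

#' Prediction-corrected visual predictive check
#'
#' Simulates `n_sim` replicate studies at the supplied parameter values
#' (identical design: same subjects, covariates, doses and sampling times;
#' fresh random effects and residual errors), applies the same prediction
#' correction to observed and simulated values, and summarizes, per
#' observation matrix and time bin, the observed 5th/50th/95th percentiles
#' together with 95% confidence bands for each percentile obtained from the
#' replicate distribution.
#'
#' @param dataset event table with the observed study.
#' @param fit_or_params a `pulmo_fit` or a `pulmo_params`: the model at
#'   which population predictions and simulations are computed.
#' @param n_sim number of simulated replicate studies (>= 200 recommended;
#'   default 1000).
#' @param bins optional vector of bin labels, one per observation row (in
#'   `split_dataset()` order); default bins by matrix and rounded time.
#'   Bins with fewer than 3 observations are merged with the nearest bin of
#'   the same matrix (with a message).
#' @param seed seed for the replicate simulations.
#' @return A `pulmo_vpc` object: data frame with one row per matrix/bin
#'   (`matrix`, `bin`, `time_med`, `n`, observed `obs_p5`, `obs_p50`,
#'   `obs_p95`, and `sim_*_lo` / `sim_*_hi` 95% bands for each percentile).
#' @export
pcvpc <- function(dataset, fit_or_params, n_sim = 1000, bins = NULL,
                  seed = 1L) {
  params <- if (inherits(fit_or_params, "pulmo_fit")) {
    fit_or_params$params
  } else fit_or_params
  validate_params(params)
  subjects <- split_dataset(dataset)
  obs <- do.call(rbind, lapply(names(subjects), function(sid) {
    o <- subjects[[sid]]$obs
    if (nrow(o)) o$id <- sid
    o
  }))
  m <- length(subjects)
  ctx <- if (m <= .pulmo_max_stack) {
    make_stack_context(subjects, params$n_transit)
  }
  tv <- lapply(subjects, function(s) allometric_typical_values(params, s$cov))
  cl_typ <- vapply(tv, `[[`, numeric(1), "cl_typ")
  vc_typ <- vapply(tv, `[[`, numeric(1), "vc_typ")
  cohort_preds <- function(etas) {
    if (is.null(ctx)) {
      unlist(stacked_predictions(subjects, params, etas), use.names = FALSE)
    } else {
      unlist(stacked_predict_ctx(ctx, params, cl_typ * exp(etas), vc_typ),
             use.names = FALSE)
    }
  }
  pred_pop <- cohort_preds(rep(0, m))
  if (is.null(bins)) bins <- default_bins(obs$time, obs$matrix)
  bins <- merge_small_bins(bins, obs$matrix, obs$time, min_n = 3L)

  corr_obs <- prediction_correct(obs$dv, pred_pop, bins)
  probs <- c(0.05, 0.5, 0.95)
  obs_pct <- bin_percentiles(corr_obs$value, corr_obs$bin, probs)

  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old), add = TRUE)
  set.seed(seed)
  sim_pct <- array(NA_real_, dim = c(n_sim, nrow(obs_pct), 3))
  sig_obs <- sigma_for_matrix(params, obs$matrix)
  for (r in seq_len(n_sim)) {
    etas <- if (params$omega_cl > 0) {
      stats::rnorm(m, 0, params$omega_cl)
    } else rep(0, m)
    f <- cohort_preds(etas)
    dv_sim <- f * (1 + stats::rnorm(length(f), 0, sig_obs))
    corr_sim <- prediction_correct(dv_sim, pred_pop, bins)
    sim_pct[r, , ] <- as.matrix(
      bin_percentiles(corr_sim$value, corr_sim$bin, probs,
                      bin_order = obs_pct$bin)[, -1])
  }
  band <- function(k, q) apply(sim_pct[, , k, drop = FALSE], 2,
                               stats::quantile, probs = q)
  out <- data.frame(
    matrix = vapply(strsplit(obs_pct$bin, "@", fixed = TRUE), `[`, "", 1L),
    bin = obs_pct$bin,
    time_med = tapply(obs$time, bins, stats::median)[obs_pct$bin],
    n = as.integer(table(corr_obs$bin)[obs_pct$bin]),
    obs_p5 = obs_pct$p5, obs_p50 = obs_pct$p50, obs_p95 = obs_pct$p95,
    sim_p5_lo = band(1, 0.025), sim_p5_hi = band(1, 0.975),
    sim_p50_lo = band(2, 0.025), sim_p50_hi = band(2, 0.975),
    sim_p95_lo = band(3, 0.025), sim_p95_hi = band(3, 0.975))
  rownames(out) <- NULL
  structure(out, class = c("pulmo_vpc", "data.frame"), n_sim = n_sim)
}

bin_percentiles <- function(values, bins, probs, bin_order = NULL) {
  q <- tapply(values, bins, stats::quantile, probs = probs)
  if (is.null(bin_order)) bin_order <- sort(names(q))
  m <- do.call(rbind, q[bin_order])
  data.frame(bin = bin_order, p5 = m[, 1], p50 = m[, 2], p95 = m[, 3],
             row.names = NULL)
}

merge_small_bins <- function(bins, matrix, time, min_n = 3L) {
  bins <- as.character(bins)
  repeat {
    tab <- table(bins)
    small <- names(tab)[tab < min_n]
    if (!length(small)) return(bins)
    b <- small[1L]
    sel <- bins == b
    m <- matrix[sel][1L]
    cand <- setdiff(unique(bins[matrix == m]), b)
    if (!length(cand)) return(bins)  # a lone small bin cannot be merged
    t_b <- stats::median(time[sel])
    t_cand <- vapply(cand, function(x) stats::median(time[bins == x]),
                     numeric(1))
    target <- cand[which.min(abs(t_cand - t_b))]
    message("merging VPC bin '", b, "' (n = ", sum(sel), ") into '",
            target, "'")
    bins[sel] <- target
  }
}

#' Plot a prediction-corrected VPC
#'
#' One panel per observation matrix: observed percentiles as lines over the
#' simulation-based 95% confidence bands of the corresponding percentiles.
#'
#' @param vpc a `pulmo_vpc` from [pcvpc()].
#' @return A ggplot object.
#' @export
plot_vpc <- function(vpc) {
  d <- as.data.frame(vpc)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_med)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_p5_lo,
                                      ymax = .data$sim_p5_hi),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_p50_lo,
                                      ymax = .data$sim_p50_hi),
                         fill = "salmon", alpha = 0.4) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_p95_lo,
                                      ymax = .data$sim_p95_hi),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p50)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p5), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p95), linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$obs_p50)) +
    ggplot2::facet_wrap(~matrix, scales = "free") +
    ggplot2::labs(x = "time (h)",
                  y = "prediction-corrected concentration (mg/L)")
}

#' Write a VPC summary (and optionally its figure) to disk
#'
#' @param vpc a `pulmo_vpc`.
#' @param csv_path output CSV path for the numeric summary.
#' @param fig_path optional figure path (any device `ggplot2::ggsave`
#'   understands).
#' @return `csv_path`, invisibly.
#' @export
write_vpc <- function(vpc, csv_path, fig_path = NULL) {
  utils::write.csv(as.data.frame(vpc), csv_path, row.names = FALSE)
  if (!is.null(fig_path)) {
    ggplot2::ggsave(fig_path, plot_vpc(vpc), width = 9, height = 4)
  }
  invisible(csv_path)
}
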