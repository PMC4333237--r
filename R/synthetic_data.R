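#' Study design specification for synthetic BAL studies
#'
#' Describes a sparse bronchoalveolar-lavage PK study: oral multiple dosing,
#' a small number of plasma samples after the last dose, and a single
#' BAL-derived ELF and AC concentration per subject.  The defaults emulate
#' the reference design: 40 adult subjects (20 men, 20 women, half of each
#' carrying an AIDS label that acts purely as a grouping variable), 600 mg
#' orally once daily for 5 days, plasma sampled at approximately 2 and 4 h
#' after the day-5 dose, one BAL sample at approximately 4 h after the day-5
#' dose, and observation totals thinned to 76 plasma, 32 ELF and 36 AC
#' records.
#'
#' Covariate distributions are plausible adult values (per-sex truncated
#' normals), NOT derived from any clinical dataset.
#'
#' @param n_subjects number of subjects.
#' @param n_male number of male subjects; the rest are female.
#' @param regimen a [dosing_regimen()].
#' @param plasma_times nominal plasma sampling times (h after the last dose).
#' @param bal_times nominal BAL times (h after the last dose); recycled
#'   across subjects, so a vector spreads distinct BAL times over the cohort
#'   (a "rich-BAL" design).
#' @param time_jitter half-width (h) of the uniform jitter applied to every
#'   nominal sampling time ("approximately 2 and 4 h").
#' @param target_counts named vector of retained observation totals per
#'   matrix (`plasma`, `ELF`, `AC`); thinning is completely at random.  Use
#'   `NULL` to keep every observation.
#' @param covariate_distributions per-sex means, SDs and truncation bounds
#'   for weight (kg) and height (m).
#' @return A `pulmo_design` list.
#' @export
study_design_spec <- function(n_subjects = 40, n_male = 20,
                              regimen = dosing_regimen(600, 24, 5),
                              plasma_times = c(2, 4),
                              bal_times = 4,
                              time_jitter = 0.25,
                              target_counts = c(plasma = 76, ELF = 32,
                                                AC = 36),
                              covariate_distributions =
                                default_covariate_distributions()) {
  if (n_male > n_subjects) stop("'n_male' exceeds 'n_subjects'", call. = FALSE)
  if (time_jitter < 0) stop("'time_jitter' must be >= 0", call. = FALSE)
  if (!is.null(target_counts)) {
    nominal <- c(plasma = n_subjects * length(plasma_times),
                 ELF = n_subjects, AC = n_subjects)
    over <- target_counts > nominal[names(target_counts)]
    if (any(over)) {
      stop("target_counts exceed the design's nominal totals for: ",
           paste(names(target_counts)[over], collapse = ", "), call. = FALSE)
    }
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_male = as.integer(n_male),
                 regimen = regimen, plasma_times = plasma_times,
                 bal_times = bal_times, time_jitter = time_jitter,
                 target_counts = target_counts,
                 covariate_distributions = covariate_distributions),
            class = "pulmo_design")
}

#' @rdname study_design_spec
#' @export
default_covariate_distributions <- function() {
  list(male = list(weight_mean = 78, weight_sd = 12,
                   weight_range = c(45, 130),
                   height_mean = 1.76, height_sd = 0.07,
                   height_range = c(1.50, 2.05)),
       female = list(weight_mean = 65, weight_sd = 11,
                     weight_range = c(40, 120),
                     height_mean = 1.62, height_sd = 0.07,
                     height_range = c(1.40, 1.95)))
}

rtruncnorm1 <- function(mean, sd, range) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= range[1] && x <= range[2]) return(x)
  }
}

# Deterministic per-subject sub-seed so a dataset is invariant to subject
# ordering; kept below 2^31 - 1.
subject_seed <- function(master_seed, i) {
  (as.numeric(master_seed) + 1000003 * i) %% 2147483647
}

#' Generate a synthetic BAL study
#'
#' Samples covariates per sex, a lognormal between-subject random effect on
#' clearance per subject, jitters the nominal sampling times uniformly within
#' `+/- time_jitter`, simulates noise-free profiles from the induction-naive
#' state, applies per-matrix proportional residual error, and thins
#' observations completely at random to the design's target totals.  Each
#' subject consumes its own random substream derived from `(seed, subject
#' index)`, so the dataset is reproducible and independent of subject order.
#'
#' @param design a [study_design_spec()].
#' @param params a `pulmo_params` object holding the true values.
#' @param seed master seed (integer).
#' @return A validated event table (see [event_table]) carrying attributes
#'   `truth` (true parameters, per-subject etas and covariates, the seed) and
#'   `n_negative` (count of negative simulated observations, which the
#'   proportional error model can produce and which are retained).
#' @export
generate_study <- function(design, params, seed = 1L) {
  stopifnot(inherits(design, "pulmo_design"))
  validate_params(params)
  last_dose <- design$regimen$start_time +
    design$regimen$interval * (design$regimen$n_doses - 1)
  dt <- dose_times(design$regimen)
  n <- design$n_subjects
  bal <- rep_len(design$bal_times, n)
  rows <- vector("list", n)
  truth_cov <- vector("list", n)
  etas <- numeric(n)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old), add = TRUE)
  for (i in seq_len(n)) {
    set.seed(subject_seed(seed, i))
    sid <- sprintf("S%03d", i)
    sex <- if (i <= design$n_male) "male" else "female"
    aids <- if (i %% 2 == 0) "AIDS" else "no-AIDS"
    cd <- design$covariate_distributions[[sex]]
    wt <- rtruncnorm1(cd$weight_mean, cd$weight_sd, cd$weight_range)
    ht <- rtruncnorm1(cd$height_mean, cd$height_sd, cd$height_range)
    cov <- subject_covariates(sid, sex, wt, ht)
    eta <- if (params$omega_cl > 0) {
      stats::rnorm(1, 0, params$omega_cl)
    } else 0
    jit <- function(x) {
      x + stats::runif(length(x), -design$time_jitter, design$time_jitter)
    }
    t_plasma <- last_dose + jit(design$plasma_times)
    t_bal <- last_dose + jit(bal[i])
    sched <- sampling_schedule(c(t_plasma, t_bal, t_bal),
                               c(rep("plasma", length(t_plasma)),
                                 "ELF", "AC"))
    pred <- simulate_individual(cov, params, eta, design$regimen, sched)
    dv <- apply_residual_error(pred$pred, pred$matrix, params)
    obs <- data.frame(id = sid, time = pred$time, evid = 0L, amt = NA_real_,
                      dv = dv, matrix = pred$matrix, mdv = 0L,
                      sex = sex, weight = wt, height = ht, group = aids,
                      stringsAsFactors = FALSE)
    dose <- data.frame(id = sid, time = dt, evid = 1L,
                       amt = design$regimen$dose_amount, dv = NA_real_,
                       matrix = NA_character_, mdv = 1L,
                       sex = sex, weight = wt, height = ht, group = aids,
                       stringsAsFactors = FALSE)
    rec <- rbind(dose, obs)
    rows[[i]] <- rec[order(rec$time, -rec$evid), ]
    etas[i] <- eta
    truth_cov[[i]] <- data.frame(id = sid, sex = sex, weight = wt,
                                 height = ht, group = aids, eta_cl = eta)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(design$target_counts)) {
    set.seed((as.numeric(seed) + 999331) %% 2147483647)
    for (m in names(design$target_counts)) {
      idx <- which(tab$evid == 0L & tab$matrix == m)
      drop_n <- length(idx) - design$target_counts[[m]]
      if (drop_n > 0) {
        tab <- tab[-sample(idx, drop_n), ]
      }
    }
    rownames(tab) <- NULL
  }
  validate_event_table(tab)
  attr(tab, "truth") <- list(params = params,
                             subjects = do.call(rbind, truth_cov),
                             seed = seed)
  attr(tab, "n_negative") <- sum(tab$dv < 0 & tab$evid == 0L, na.rm = TRUE)
  tab
}

.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write a synthetic study with its truth sidecar
#'
#' Writes the event table as CSV and, when the table carries a `truth`
#' attribute, a YAML sidecar (`<path>.truth.yaml`) recording the generating
#' parameters, per-subject random effects and seed, for parameter-recovery
#' experiments.
#'
#' @param table event table from [generate_study()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_study <- function(table, path) {
  write_event_table(table, path)
  truth <- attr(table, "truth")
  if (!is.null(truth)) {
    num <- truth$params[setdiff(names(truth$params),
                                c("scaling_mode", "fixed_mask"))]
    yaml::write_yaml(
      list(parameters = num, scaling_mode = truth$params$scaling_mode,
           seed = truth$seed,
           subjects = lapply(seq_len(nrow(truth$subjects)), function(i)
             as.list(truth$subjects[i, ]))),
      paste0(path, ".truth.yaml"))
  }
  invisible(path)
}
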