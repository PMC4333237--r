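#' @title NONMEM-style event tables
#' @description
#' The dataset exchanged between the generator, the simulator and the
#' estimator is a long-format table with one row per dosing or observation
#' event, reminiscent of a NONMEM dataset:
#'
#' \describe{
#'   \item{id}{subject identifier (character)}
#'   \item{time}{hours from the first dose of the study; non-negative and
#'     non-decreasing within subject}
#'   \item{evid}{event type: 1 = dose, 0 = observation}
#'   \item{amt}{dose amount (mg); `NA` on observation rows}
#'   \item{dv}{observed concentration (mg/L); `NA` on dose rows.  Negative
#'     values can legitimately occur under a proportional Gaussian residual
#'     error and are retained}
#'   \item{matrix}{observation matrix tag (`plasma`, `ELF`, `AC`); `NA` on
#'     dose rows}
#'   \item{mdv}{missing-data flag: 1 on dose rows and censored observations}
#'   \item{sex, weight, height}{subject covariates, constant within subject}
#' }
#' @name event_table
NULL

event_table_columns <- c("id", "time", "evid", "amt", "dv", "matrix", "mdv",
                         "sex", "weight", "height")

#' Read an event table from CSV
#'
#' Reads, type-checks and validates a dataset in the layout documented under
#' [event_table]. Comma-separated, dot decimal.
#'
#' @param path CSV file path.
#' @return A validated event-table data frame.
#' @export
read_event_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character"),
                         na.strings = c("", "NA"))
  validate_event_table(tab)
}

#' Write an event table to CSV
#'
#' The inverse of [read_event_table()]: writing then reading reproduces the
#' table for all defined columns.
#'
#' @param table event-table data frame.
#' @param path output CSV file path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(table, path) {
  validate_event_table(table)
  utils::write.csv(table[, event_table_columns], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Validate an event table
#'
#' Checks column presence and types, the per-subject ordering of times, the
#' presence of a dose before the first observation of every subject, matrix
#' tags, and within-subject constancy of covariates.  Violations raise an
#' error whose message carries the offending row numbers.
#'
#' @param table candidate data frame.
#' @return The table, invisibly validated (returned for chaining).
#' @export
validate_event_table <- function(table) {
  missing_cols <- setdiff(event_table_columns, names(table))
  if (length(missing_cols)) {
    stop("event table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  fail <- function(rows, what) {
    stop("invalid event table: ", what, " (row ",
         paste(utils::head(rows, 5L), collapse = ", "),
         if (length(rows) > 5L) ", ..." else "", ")", call. = FALSE)
  }
  rn <- seq_len(nrow(table))
  if (any(bad <- !is.finite(table$time) | table$time < 0)) {
    fail(rn[bad], "negative or missing time")
  }
  if (any(bad <- !table$evid %in% c(0L, 1L))) {
    fail(rn[bad], "evid must be 0 (observation) or 1 (dose)")
  }
  obs <- table$evid == 0L
  if (any(bad <- obs & (is.na(table$matrix) | !table$matrix %in%
                          c("plasma", "ELF", "AC")))) {
    fail(rn[bad], "observation rows need a matrix tag in {plasma, ELF, AC}")
  }
  if (any(bad <- table$evid == 1L & (is.na(table$amt) | table$amt <= 0))) {
    fail(rn[bad], "dose rows need a positive amt")
  }
  if (any(bad <- !table$sex %in% c("male", "female"))) {
    fail(rn[bad], "sex must be male or female")
  }
  if (any(bad <- !is.finite(table$weight) | table$weight <= 0 |
            !is.finite(table$height) | table$height <= 0)) {
    fail(rn[bad], "weight and height must be positive")
  }
  for (sid in unique(table$id)) {
    sel <- table$id == sid
    sub <- table[sel, ]
    if (is.unsorted(sub$time)) {
      fail(rn[sel][which(diff(sub$time) < 0) + 1L],
           paste0("times not non-decreasing within subject ", sid))
    }
    first_obs <- suppressWarnings(min(sub$time[sub$evid == 0L]))
    first_dose <- suppressWarnings(min(sub$time[sub$evid == 1L]))
    if (is.finite(first_obs) &&
        (!is.finite(first_dose) || first_dose > first_obs)) {
      fail(rn[sel][1L],
           paste0("subject ", sid, " has an observation before any dose"))
    }
    for (cv in c("sex", "weight", "height")) {
      if (length(unique(sub[[cv]])) != 1L) {
        fail(rn[sel][1L],
             paste0("covariate '", cv, "' varies within subject ", sid))
      }
    }
  }
  invisible(table)
}

#' Serialize a parameter set to / from a YAML configuration
#'
#' The configuration mirrors the model's parameter names; every parameter is
#' written with its value and its fixed/estimated status so a fit can be
#' reproduced from the file alone.
#'
#' @param params `pulmo_params`.
#' @param path YAML file path.
#' @return For `write_params_config`, `path` invisibly; for
#'   `read_params_config`, a `pulmo_params` object.
#' @export
write_params_config <- function(params, path) {
  num <- params[setdiff(names(params), c("scaling_mode", "fixed_mask"))]
  yaml::write_yaml(list(parameters = num,
                        scaling_mode = params$scaling_mode,
                        fixed = as.list(params$fixed_mask)), path)
  invisible(path)
}

#' @rdname write_params_config
#' @export
read_params_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$parameters$ka)) {
    stop("configuration error: required key 'ka' is missing", call. = FALSE)
  }
  mask <- unlist(cfg$fixed)
  do.call(population_parameters,
          c(cfg$parameters, list(scaling_mode = cfg$scaling_mode,
                                 fixed_mask = mask)))
}
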