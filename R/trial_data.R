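#' mpefr: multiple predator effects from functional responses
#'
#' Tools for non-replacement predator feeding trials: functional response
#' classification and fitting (Rogers' random predator equation, Lambert W
#' closed form), multi-predator prediction from a depletion ODE that assumes
#' predator independence, decomposition of interaction strength into trophic
#' and nontrophic components, Latin hypercube sensitivity bands, and the
#' accompanying statistical layer (quasi-binomial analysis of deviance,
#' Tukey post hoc tests, AICc model selection).
#'
#' @docType package
#' @name mpefr-package
#' @aliases mpefr
#' @keywords internal
"_PACKAGE"

# canonical column set for feeding-trial tables
.trial_columns <- c("trial_id", "prey_density_initial", "volume_ml",
                    "predator_count", "prey_eaten", "replicate")

#' Describe a factorial feeding-trial design
#'
#' Captures the structure of a fully crossed feeding-trial experiment:
#' prey density levels, water volume levels, predator density levels,
#' replication, trial duration, and predator-free control replication.
#' Defaults describe a 6 prey density x 2 volume x 4 predator density x
#' 5 replicate design run for 18 hours (0.75 days), with 5 predator-free
#' control replicates per prey density x volume cell.
#'
#' @param prey_density_levels ordered vector of initial prey counts (> 0).
#' @param volume_levels_ml ordered vector of water volumes in ml (> 0).
#' @param predator_density_levels ordered vector of predator counts (> 0).
#' @param replicates_per_cell replicates per design cell (>= 0).
#' @param duration_T trial duration; the unit chosen here (default days)
#'   fixes the units of attack rate and handling time everywhere downstream.
#' @param control_replicates_per_cell predator-free replicates per prey
#'   density x volume cell (>= 0).
#'
#' @return An object of class \code{experiment_design}.
#' @examples
#' d <- experiment_design()
#' n_experimental_units(d)  # 240
#' @export
experiment_design <- function(prey_density_levels = c(2, 4, 8, 16, 32, 64),
                              volume_levels_ml = c(40, 80),
                              predator_density_levels = 1:4,
                              replicates_per_cell = 5,
                              duration_T = 0.75,
                              control_replicates_per_cell = 5) {
  stopifnot(length(prey_density_levels) > 0, all(prey_density_levels > 0),
            length(volume_levels_ml) > 0, all(volume_levels_ml > 0),
            length(predator_density_levels) > 0,
            all(predator_density_levels > 0),
            length(replicates_per_cell) == 1, replicates_per_cell >= 0,
            length(duration_T) == 1, duration_T > 0,
            control_replicates_per_cell >= 0)
  structure(list(prey_density_levels = as.integer(prey_density_levels),
                 volume_levels_ml = as.numeric(volume_levels_ml),
                 predator_density_levels = as.integer(predator_density_levels),
                 replicates_per_cell = as.integer(replicates_per_cell),
                 duration_T = as.numeric(duration_T),
                 control_replicates_per_cell =
                   as.integer(control_replicates_per_cell)),
            class = "experiment_design")
}

#' Number of experimental (non-control) units a design enumerates
#'
#' @param design an \code{\link{experiment_design}}.
#' @return Integer count: prey levels x volumes x predator levels x replicates.
#' @export
n_experimental_units <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  length(design$prey_density_levels) * length(design$volume_levels_ml) *
    length(design$predator_density_levels) * design$replicates_per_cell
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Feeding-trial design:",
      paste0(length(x$prey_density_levels), " prey densities (",
             paste(x$prey_density_levels, collapse = ", "), ")"),
      "\n  x", length(x$volume_levels_ml), "volumes (ml):",
      paste(x$volume_levels_ml, collapse = ", "),
      "\n  x", length(x$predator_density_levels), "predator densities:",
      paste(x$predator_density_levels, collapse = ", "),
      "\n  x", x$replicates_per_cell, "replicates =",
      n_experimental_units(x), "experimental units\n")
  cat("  duration T =", x$duration_T, "; controls:",
      x$control_replicates_per_cell, "per prey x volume cell\n")
  invisible(x)
}

#' Validate a feeding-trial table
#'
#' Checks the canonical schema and the row-level invariants: counts are
#' non-negative integers, \code{prey_eaten <= prey_density_initial}, and
#' (when a design is supplied) prey densities and volumes are drawn from the
#' declared levels. Fractional counts are rejected, not rounded.
#'
#' @param trials data frame with columns \code{trial_id},
#'   \code{prey_density_initial}, \code{volume_ml}, \code{predator_count},
#'   \code{prey_eaten}, \code{replicate}.
#' @param design optional \code{\link{experiment_design}} whose levels the
#'   table must respect.
#' @return The validated table, invisibly.
#' @export
validate_trials <- function(trials, design = NULL) {
  stopifnot(is.data.frame(trials))
  missing_cols <- setdiff(.trial_columns, names(trials))
  if (length(missing_cols) > 0)
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  num_cols <- setdiff(.trial_columns, "trial_id")
  for (cl in num_cols) {
    v <- trials[[cl]]
    if (!is.numeric(v))
      stop("parse error: column '", cl, "' is not numeric", call. = FALSE)
    bad <- which(!is.finite(v))
    if (length(bad) > 0)
      stop("parse error: non-numeric value in column '", cl, "', row ",
           bad[1], call. = FALSE)
  }
  .check_rows <- function(cond, msg) {
    bad <- which(!cond)
    if (length(bad) > 0)
      stop("validation error: ", msg, " (row ", bad[1], ")", call. = FALSE)
  }
  is_int <- function(v) abs(v - round(v)) < 1e-9
  .check_rows(is_int(trials$prey_density_initial) & is_int(trials$prey_eaten) &
                is_int(trials$predator_count) & is_int(trials$replicate),
              "counts must be integers; fractional values are rejected")
  .check_rows(trials$prey_density_initial > 0,
              "prey_density_initial must be > 0")
  .check_rows(trials$predator_count >= 0, "predator_count must be >= 0")
  .check_rows(trials$prey_eaten >= 0, "prey_eaten must be >= 0")
  .check_rows(trials$prey_eaten <= trials$prey_density_initial,
              "prey_eaten exceeds prey_density_initial")
  .check_rows(trials$replicate >= 1, "replicate must be a positive integer")
  .check_rows(trials$volume_ml > 0, "volume_ml must be > 0")
  if (!is.null(design)) {
    stopifnot(inherits(design, "experiment_design"))
    .check_rows(trials$prey_density_initial %in% design$prey_density_levels,
                "prey_density_initial not a declared design level")
    .check_rows(trials$volume_ml %in% design$volume_levels_ml,
                "volume_ml not a declared design level")
    .check_rows(trials$predator_count %in%
                  c(0L, design$predator_density_levels),
                "predator_count not a declared design level (or 0)")
  }
  invisible(trials)
}

#' Read a feeding-trial table from delimited text
#'
#' Reads a CSV (or other single-character-delimited UTF-8 file) into the
#' canonical feeding-trial schema and validates every row. Arbitrary input
#' headers are absorbed by \code{col_map}.
#'
#' @param path file to read.
#' @param col_map optional named character vector mapping canonical names to
#'   the file's headers, e.g. \code{c(prey_density_initial = "prey.density")}.
#'   Canonical names absent from the map must appear verbatim in the file.
#' @param delim field delimiter (default comma).
#' @param design optional \code{\link{experiment_design}} for level checking.
#' @return Validated data frame of feeding trials, input row order preserved.
#' @export
read_trials <- function(path, col_map = NULL, delim = ",", design = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           fileEncoding = "UTF-8")
  if (!is.null(col_map)) {
    stopifnot(!is.null(names(col_map)))
    missing_src <- setdiff(unname(col_map), names(raw))
    if (length(missing_src) > 0)
      stop("schema error: mapped column(s) absent from file: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    for (canon in names(col_map)) names(raw)[names(raw) == col_map[[canon]]] <- canon
  }
  missing_cols <- setdiff(.trial_columns, names(raw))
  if (length(missing_cols) > 0)
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  trials <- raw[, .trial_columns]
  for (cl in setdiff(.trial_columns, "trial_id")) {
    v <- trials[[cl]]
    if (is.character(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0)
        stop("parse error: non-numeric value '", v[bad[1]], "' in column '",
             cl, "', row ", bad[1], call. = FALSE)
      trials[[cl]] <- vn
    }
  }
  trials$trial_id <- as.character(trials$trial_id)
  validate_trials(trials, design)
  message("read_trials: ", nrow(trials), " rows read from ", path)
  trials
}

#' Write a feeding-trial table to delimited text
#'
#' Inverse of \code{\link{read_trials}}: writes the canonical columns as
#' RFC-4180-style delimited text, UTF-8, so that a read/write round trip is
#' the identity on valid tables.
#'
#' @param trials validated feeding-trial table.
#' @param path output file.
#' @param delim field delimiter (default comma).
#' @return \code{path}, invisibly.
#' @export
write_trials <- function(trials, path, delim = ",") {
  validate_trials(trials)
  utils::write.table(trials[, .trial_columns], path, sep = delim,
                     row.names = FALSE, quote = TRUE, qmethod = "double",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Summarize background mortality in predator-free controls
#'
#' Computes per-replicate percent survival 100 (N0 - Ne) / N0 over control
#' trials (predator_count = 0) and reports the mean, sample SD, and count.
#' No mortality correction is applied to experimental trials; instead a flag
#' is raised when mean control survival falls below \code{threshold},
#' signalling that an adjustment should be considered.
#'
#' @param trials feeding-trial table containing at least one control row.
#' @param threshold percent survival below which the flag is raised
#'   (default 90).
#' @return Object of class \code{control_summary}: list with
#'   \code{mean_survival}, \code{sd_survival}, \code{n}, \code{threshold},
#'   \code{low_survival}.
#' @export
summarize_controls <- function(trials, threshold = 90) {
  validate_trials(trials)
  ctrl <- trials[trials$predator_count == 0, , drop = FALSE]
  if (nrow(ctrl) == 0)
    stop("no controls: table contains no predator-free trials", call. = FALSE)
  surv <- 100 * (ctrl$prey_density_initial - ctrl$prey_eaten) /
    ctrl$prey_density_initial
  out <- list(mean_survival = mean(surv),
              sd_survival = if (length(surv) > 1) stats::sd(surv) else 0,
              n = length(surv),
              threshold = threshold,
              low_survival = mean(surv) < threshold)
  class(out) <- "control_summary"
  out
}

#' @export
print.control_summary <- function(x, ...) {
  cat(sprintf("Control survival: mean %.1f%% (SD %.1f%%), n = %d\n",
              x$mean_survival, x$sd_survival, x$n))
  if (x$low_survival)
    cat(sprintf("NOTE: mean survival below %.0f%%;",
                x$threshold),
        "consider whether experimental mortality needs adjustment\n")
  invisible(x)
}

#' Proportion of prey eaten per trial
#'
#' @param trials feeding-trial table (or any data frame with
#'   \code{prey_eaten} and \code{prey_density_initial}).
#' @return Numeric vector Ne / N0 in [0, 1], one element per row.
#' @export
proportion_eaten <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("prey_eaten", "prey_density_initial") %in% names(trials)))
  if (any(trials$prey_density_initial <= 0))
    stop("domain error: prey_density_initial must be > 0", call. = FALSE)
  trials$prey_eaten / trials$prey_density_initial
}
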