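#' Define a validation experimental design
#'
#' A validation design describes the series x level x replicate layout used
#' for calibration and validation standards, together with the tolerance
#' probability `beta` and the acceptance half-width `lambda` used when the
#' accuracy profile is judged.
#'
#' @param n_series Number of independent series (typically days), `p >= 2`.
#' @param n_replicates Number of replicates per series at each level, `n >= 2`.
#' @param nominal_concentrations Strictly increasing, strictly positive vector
#'   of nominal concentrations (ug/mL); its length is the number of levels `m`.
#' @param beta Tolerance probability in (0, 1); the proportion of future
#'   results the beta-expectation interval is expected to contain. Default 0.95.
#' @param lambda Acceptance half-width, in percent relative error. Default 15.
#' @param target_concentration Concentration corresponding to 100% of target,
#'   used to express levels as percent-of-target. Defaults to
#'   `max(nominal_concentrations)/1.2`, i.e. the top level is taken as the
#'   120% level.
#'
#' @return An object of class `"validation_design"`: a list with elements
#'   `n_series`, `n_replicates`, `n_levels`, `nominal_concentrations`,
#'   `beta`, `lambda`, `target_concentration`.
#'
#' @examples
#' validation_design(3, 3, c(10, 50, 100, 300, 600))
#' @export
validation_design <- function(n_series, n_replicates, nominal_concentrations,
                              beta = 0.95, lambda = 15,
                              target_concentration = max(nominal_concentrations) / 1.2) {
  n_series <- as.integer(n_series)
  n_replicates <- as.integer(n_replicates)
  conc <- as.numeric(nominal_concentrations)
  if (is.na(n_series) || n_series < 2L)
    stop("'n_series' must be an integer >= 2", call. = FALSE)
  if (is.na(n_replicates) || n_replicates < 2L)
    stop("'n_replicates' must be an integer >= 2", call. = FALSE)
  if (length(conc) < 2L)
    stop("at least two concentration levels are required", call. = FALSE)
  if (anyNA(conc) || any(conc <= 0))
    stop("nominal concentrations must be strictly positive", call. = FALSE)
  if (any(diff(conc) <= 0))
    stop("nominal concentrations must be strictly increasing", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta >= 1)
    stop("'beta' must be a single probability in (0, 1)", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("'lambda' must be a single positive acceptance half-width", call. = FALSE)
  if (!is.numeric(target_concentration) || target_concentration <= 0)
    stop("'target_concentration' must be positive", call. = FALSE)
  structure(
    list(
      n_series = n_series,
      n_replicates = n_replicates,
      n_levels = length(conc),
      nominal_concentrations = conc,
      beta = beta,
      lambda = lambda,
      target_concentration = as.numeric(target_concentration)
    ),
    class = "validation_design"
  )
}

#' Express concentrations as percent of the target concentration
#'
#' @param concentration Numeric vector of concentrations (ug/mL).
#' @param design A `validation_design`, or a single numeric target
#'   concentration.
#' @return `100 * concentration / target`.
#' @examples
#' percent_of_target(c(10, 600), validation_design(3, 3, c(10, 600)))
#' @export
percent_of_target <- function(concentration, design) {
  target <- if (inherits(design, "validation_design"))
    design$target_concentration else as.numeric(design)
  100 * concentration / target
}

#' @export
print.validation_design <- function(x, ...) {
  cat("Validation design: ", x$n_series, " series x ", x$n_levels,
      " levels x ", x$n_replicates, " replicates\n", sep = "")
  cat("  levels (ug/mL): ", paste(format(x$nominal_concentrations), collapse = ", "),
      "\n", sep = "")
  cat("  percent of target: ",
      paste(format(percent_of_target(x$nominal_concentrations, x)), collapse = ", "),
      "%\n", sep = "")
  cat("  beta = ", x$beta, ", lambda = +/-", x$lambda, "%\n", sep = "")
  invisible(x)
}
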