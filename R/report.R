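#' Write a validation report
#'
#' Writes a machine-readable JSON result file with the full-precision per-level
#' statistics, the LLOQ/ULOQ decision and (optionally) a matrix-effect table,
#' plus accuracy- and linearity-profile plots as PDF. Numbers are serialised at
#' full precision so that [read_report()] reproduces them bit-exactly.
#'
#' @param profile An `accuracy_profile`.
#' @param me Optional matrix-effect table (see [me_table()]), written as CSV.
#' @param path Output directory; created if needed.
#' @param plots Write PDF plots? Default `TRUE`.
#' @return Invisibly, the paths of the files written.
#' @export
write_report <- function(profile, me = NULL, path, plots = TRUE) {
  stopifnot(inherits(profile, "accuracy_profile"))
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok || !dir.exists(path))
    stop("cannot create output directory: ", path, call. = FALSE)
  design <- profile$design
  payload <- list(
    model = profile$model,
    beta = profile$beta,
    lambda = profile$lambda,
    valid = profile$valid,
    lloq = profile$lloq,
    uloq = profile$uloq,
    lloq_pct = if (!is.null(design) && !is.na(profile$lloq))
      percent_of_target(profile$lloq, design) else NULL,
    uloq_pct = if (!is.null(design) && !is.na(profile$uloq))
      percent_of_target(profile$uloq, design) else NULL,
    decision = .decision_string(profile),
    levels = profile$levels
  )
  files <- file.path(path, "accuracy_profile.json")
  # I(17) = 17 *significant* digits, enough for a lossless double round-trip
  jsonlite::write_json(payload, files[1], auto_unbox = TRUE, digits = I(17),
                       na = "null", dataframe = "columns")
  if (!is.null(me)) {
    f <- file.path(path, "matrix_effect.csv")
    utils::write.csv(as.data.frame(me), f, row.names = FALSE)
    files <- c(files, f)
  }
  if (plots) {
    f <- file.path(path, "profiles.pdf")
    grDevices::pdf(f, width = 7, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot(profile)
    lin <- tryCatch(linearity_profile(profile), error = function(e) NULL)
    if (!is.null(lin) && !is.null(profile$backcalc)) {
      graphics::plot(profile$backcalc$introduced, profile$backcalc$backcalc,
                     log = "xy", pch = 1,
                     xlab = "introduced concentration (ug/mL)",
                     ylab = "back-calculated concentration (ug/mL)",
                     main = "Linearity profile")
      graphics::abline(0, 1)
      graphics::abline(lin$intercept, lin$slope, lty = 2, col = "blue")
    }
    files <- c(files, f)
  }
  invisible(files)
}

#' Read back a validation report
#'
#' @param path Directory previously written by [write_report()].
#' @return A list with the report payload; `levels` is a data.frame.
#' @export
read_report <- function(path) {
  f <- file.path(path, "accuracy_profile.json")
  if (!file.exists(f)) stop("no report found under ", path, call. = FALSE)
  out <- jsonlite::fromJSON(f)
  out$levels <- as.data.frame(out$levels)
  out
}
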