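#' @export
print.accuracy_profile <- function(x, digits = 3, ...) {
  cat("Accuracy profile (", x$model, "), beta = ", x$beta,
      ", lambda = +/-", x$lambda, "%\n", sep = "")
  lv <- x$levels
  show <- data.frame(
    conc = lv$nominal_concentration,
    bias = round(lv$relative_bias_pct, digits),
    s_r = round(lv$rsd_repeatability_pct, digits),
    s_R = round(lv$rsd_intermediate_pct, digits),
    eti_low = round(lv$beta_eti_low_pct, digits),
    eti_high = round(lv$beta_eti_high_pct, digits),
    pass = lv$pass
  )
  names(show) <- c("conc(ug/mL)", "bias(%)", "s_r(%)", "s_R(%)",
                   "ETI low(%)", "ETI high(%)", "pass")
  print(show, row.names = FALSE)
  cat(.decision_string(x), "\n")
  invisible(x)
}

.decision_string <- function(x) {
  if (is.na(x$lloq)) return("no level passes the acceptance limits; method not valid")
  rng <- if (!is.null(x$design))
    sprintf("%g-%g%% of target (%g-%g ug/mL)",
            percent_of_target(x$lloq, x$design),
            percent_of_target(x$uloq, x$design), x$lloq, x$uloq)
  else sprintf("%g-%g ug/mL", x$lloq, x$uloq)
  if (x$valid) paste0("valid over ", rng)
  else paste0("partially valid; quantifiable over ", rng)
}

#' @export
summary.accuracy_profile <- function(object, ...) {
  lin <- tryCatch(linearity_profile(object), error = function(e) NULL)
  out <- list(profile = object, linearity = lin,
              lod = tryCatch(lod_from_lloq(object$lloq),
                             error = function(e) NA_real_))
  class(out) <- "summary.accuracy_profile"
  out
}

#' @export
print.summary.accuracy_profile <- function(x, ...) {
  print(x$profile)
  if (!is.null(x$linearity)) print(x$linearity)
  if (!is.na(x$lod))
    cat("LOD (LLOQ/3.3): ", format(x$lod), " ug/mL\n", sep = "")
  invisible(x)
}

#' Plot an accuracy profile
#'
#' Draws the per-level relative bias (points, solid line), the
#' beta-expectation tolerance interval (dashed lines) and the acceptance
#' limits +/- lambda (dotted lines) against concentration on a log axis.
#'
#' @param x An `accuracy_profile`.
#' @param xlab,ylab,main Usual graphics overrides.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.accuracy_profile <- function(x, xlab = "concentration (ug/mL)",
                                  ylab = "relative error (%)",
                                  main = "Accuracy profile", ...) {
  lv <- x$levels
  conc <- lv$nominal_concentration
  ylim <- range(c(lv$beta_eti_low_pct, lv$beta_eti_high_pct,
                  -x$lambda, x$lambda)) * 1.1
  graphics::plot(conc, lv$relative_bias_pct, log = "x", type = "b", pch = 16,
                 ylim = ylim, xlab = xlab, ylab = ylab, main = main, ...)
  graphics::lines(conc, lv$beta_eti_low_pct, lty = 2, col = "blue")
  graphics::lines(conc, lv$beta_eti_high_pct, lty = 2, col = "blue")
  graphics::abline(h = c(-x$lambda, x$lambda), lty = 3)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}
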