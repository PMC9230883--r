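#' Candidate calibration response functions
#'
#' Fits one of four calibration models to (concentration, response) pairs from
#' a single series:
#' \describe{
#'   \item{`ols_linear`}{ordinary least squares of response on concentration;}
#'   \item{`single_point_120`}{through-origin line whose slope is the mean
#'     response at the highest design level divided by that concentration
#'     (a "120% level" single-point calibration);}
#'   \item{`weighted_1overX`}{weighted least squares with weights
#'     1/concentration;}
#'   \item{`sqrt_linear`}{ordinary least squares of sqrt(response) on
#'     sqrt(concentration) (both axes transformed), a common
#'     variance-stabilising choice.}
#' }
#'
#' @param concentration,response Numeric vectors of equal length.
#' @param model One of `"ols_linear"`, `"single_point_120"`,
#'   `"weighted_1overX"`, `"sqrt_linear"`.
#' @param series_id Optional label carried on the fit.
#' @param top_level Concentration regarded as the highest design level for
#'   `single_point_120`; defaults to `max(concentration)`.
#'
#' @return An object of class `"calib_fit"`: list with `model`, `series_id`,
#'   `slope`, `intercept`, `r_squared` (on the fitting scale; `NA` for
#'   `single_point_120`), `n_points`.
#'
#' @details `r_squared` is computed on the scale the model is fitted on, so
#'   for `sqrt_linear` it refers to the square-root-transformed axes.
#'
#' @examples
#' fit <- calib_fit(c(10, 50, 100, 300, 600), 21100 * c(10, 50, 100, 300, 600))
#' coef(fit)
#' back_calculate(fit, 21100 * 50)
#' @export
calib_fit <- function(concentration, response,
                      model = c("ols_linear", "single_point_120",
                                "weighted_1overX", "sqrt_linear"),
                      series_id = NA_character_,
                      top_level = max(concentration)) {
  model <- match.arg(model)
  x <- as.numeric(concentration)
  y <- as.numeric(response)
  if (length(x) != length(y) || length(x) == 0L)
    stop("'concentration' and 'response' must be equal-length, non-empty",
         call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing values in calibration points", call. = FALSE)

  if (model == "single_point_120") {
    at_top <- abs(x - top_level) < 1e-9 * max(abs(top_level), 1)
    if (!any(at_top))
      stop("no calibration point at the top level (", top_level, ")",
           call. = FALSE)
    slope <- mean(y[at_top]) / top_level
    intercept <- 0
    r2 <- NA_real_
    n <- sum(at_top)
  } else {
    if (length(unique(x)) < 2L)
      stop("at least two distinct concentrations are required", call. = FALSE)
    if (model == "sqrt_linear") {
      if (any(x < 0) || any(y < 0))
        stop("sqrt_linear requires non-negative concentrations and responses",
             call. = FALSE)
      xf <- sqrt(x); yf <- sqrt(y); w <- rep(1, length(x))
    } else if (model == "weighted_1overX") {
      if (any(x <= 0))
        stop("weighted_1overX requires strictly positive concentrations",
             call. = FALSE)
      xf <- x; yf <- y; w <- 1 / x
    } else {
      xf <- x; yf <- y; w <- rep(1, length(x))
    }
    cf <- .wls(xf, yf, w)
    slope <- cf[["slope"]]; intercept <- cf[["intercept"]]; r2 <- cf[["r_squared"]]
    n <- length(x)
  }
  if (!is.finite(slope) || slope == 0)
    stop("degenerate fit: slope is zero or non-finite", call. = FALSE)
  structure(
    list(model = model, series_id = series_id, slope = slope,
         intercept = intercept, r_squared = r2, n_points = n),
    class = "calib_fit"
  )
}

# weighted least squares by the closed-form normal equations
.wls <- function(x, y, w) {
  sw <- sum(w)
  xbar <- sum(w * x) / sw
  ybar <- sum(w * y) / sw
  sxx <- sum(w * (x - xbar)^2)
  if (sxx <= 0) stop("degenerate design: no spread in concentrations",
                     call. = FALSE)
  slope <- sum(w * (x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  resid <- y - intercept - slope * x
  sst <- sum(w * (y - ybar)^2)
  r2 <- if (sst > 0) 1 - sum(w * resid^2) / sst else NA_real_
  c(slope = slope, intercept = intercept,
    r_squared = if (is.na(r2)) NA_real_ else min(max(r2, 0), 1))
}

#' @export
print.calib_fit <- function(x, ...) {
  cat("Calibration fit (", x$model, ")",
      if (!is.na(x$series_id)) paste0(" series ", x$series_id), "\n", sep = "")
  cat("  slope = ", format(x$slope), ", intercept = ", format(x$intercept),
      if (!is.na(x$r_squared)) paste0(", r^2 = ", format(x$r_squared)),
      ", n = ", x$n_points, "\n", sep = "")
  invisible(x)
}

#' @export
coef.calib_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predicted response at given concentrations
#'
#' @param object A `calib_fit`.
#' @param newdata Numeric vector of concentrations.
#' @param ... Unused.
#' @return Predicted responses on the original response scale.
#' @export
predict.calib_fit <- function(object, newdata, ...) {
  x <- as.numeric(newdata)
  switch(object$model,
    sqrt_linear = {
      if (any(x < 0)) stop("negative concentration under sqrt_linear",
                           call. = FALSE)
      (object$intercept + object$slope * sqrt(x))^2
    },
    single_point_120 = object$slope * x,
    object$intercept + object$slope * x
  )
}

#' Back-calculate concentrations by inverse prediction
#'
#' Inverts the calibration fit on its own fitting scale:
#' `C = (y - intercept)/slope` for the linear kinds, `C = y/slope` for the
#' single-point model, and `C = ((sqrt(y) - intercept)/slope)^2` for
#' `sqrt_linear`.
#'
#' Negative inverse predictions from the linear kinds are returned as-is
#' (a negative back-calculated concentration is meaningful as bias near the
#' limit of quantitation); the logical attribute `"flagged_negative"` marks
#' them. A square-root domain violation (negative response, or a negative
#' inverse-predicted sqrt-concentration) is an error.
#'
#' @param fit A `calib_fit`.
#' @param response Numeric vector of responses.
#' @return Numeric vector of back-calculated concentrations.
#' @export
back_calculate <- function(fit, response) {
  stopifnot(inherits(fit, "calib_fit"))
  y <- as.numeric(response)
  out <- switch(fit$model,
    sqrt_linear = {
      if (any(y < 0)) stop("negative response under sqrt_linear", call. = FALSE)
      r <- (sqrt(y) - fit$intercept) / fit$slope
      if (any(r < 0))
        stop("inverse prediction outside the sqrt domain (sqrt(C) < 0)",
             call. = FALSE)
      r^2
    },
    single_point_120 = y / fit$slope,
    (y - fit$intercept) / fit$slope
  )
  if (any(out < 0)) attr(out, "flagged_negative") <- out < 0
  out
}

#' Fit one response function per series
#'
#' Fits the chosen model to each series' calibration records only.
#'
#' @param table A `measurement_table` containing calibration records.
#' @param model Model kind, as in [calib_fit()].
#' @return A named list of `calib_fit` objects, one per series, in sorted
#'   series order.
#' @export
fit_all_series <- function(table, model = "ols_linear") {
  stopifnot(inherits(table, "measurement_table"))
  design <- attr(table, "design")
  cal <- table[table$role == "calibration", , drop = FALSE]
  series <- sort(unique(table$series_id))
  fits <- vector("list", length(series))
  names(fits) <- as.character(series)
  top <- max(design$nominal_concentrations)
  for (i in seq_along(series)) {
    sub <- cal[cal$series_id == series[i], , drop = FALSE]
    if (nrow(sub) == 0L)
      stop("no calibration records for series ", series[i], call. = FALSE)
    fits[[i]] <- calib_fit(sub$nominal_concentration, sub$response,
                           model = model, series_id = as.character(series[i]),
                           top_level = top)
  }
  fits
}
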