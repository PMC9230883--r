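#' Variance components from a balanced one-way random-effects layout
#'
#' Method-of-moments (ANOVA) estimates of the within-series and between-series
#' variance components from a balanced p series x n replicates grid:
#' `sigma2_within = MS_within` and
#' `sigma2_between = max(0, (MS_between - MS_within)/n)` (negative moment
#' estimates are truncated at zero).
#'
#' @param x Either a numeric matrix with `p` rows (series) and `n` columns
#'   (replicates), or a numeric vector accompanied by `series`.
#' @param series Series labels parallel to `x` when `x` is a vector; every
#'   series must have the same number of observations.
#' @return A list with `sigma2_within`, `sigma2_between`, `ms_within`,
#'   `ms_between`, `p`, `n`.
#' @examples
#' variance_components(rbind(c(9, 10, 11), c(10, 11, 12), c(11, 12, 13)))
#' @export
variance_components <- function(x, series = NULL) {
  if (is.matrix(x)) {
    m <- x
  } else {
    if (is.null(series))
      stop("'series' is required when 'x' is not a matrix", call. = FALSE)
    if (length(series) != length(x))
      stop("'x' and 'series' lengths differ", call. = FALSE)
    counts <- table(series)
    if (length(unique(counts)) != 1L)
      stop("unbalanced grid: unequal replicates per series", call. = FALSE)
    m <- matrix(x[order(series)], nrow = length(counts), byrow = TRUE)
  }
  p <- nrow(m); n <- ncol(m)
  if (p < 2L || n < 2L)
    stop("at least 2 series and 2 replicates are required", call. = FALSE)
  if (any(!is.finite(m)))
    stop("non-finite values in the grid", call. = FALSE)
  means <- rowMeans(m)
  ms_within <- sum((m - means)^2) / (p * (n - 1))
  ms_between <- n * sum((means - mean(m))^2) / (p - 1)
  list(
    sigma2_within = ms_within,
    sigma2_between = max(0, (ms_between - ms_within) / n),
    ms_within = ms_within,
    ms_between = ms_between,
    p = p, n = n
  )
}

# Interval machinery shared by beta_eti() and level_stats():
# B^2 = (R+1)/(nR+1), Satterthwaite df, t quantile, half-width multiplier.
.eti_components <- function(R, p, n, beta) {
  if (p < 2L) stop("'p' must be >= 2", call. = FALSE)
  B2 <- (R + 1) / (n * R + 1)
  nu <- (R + 1)^2 / ((R + 1 / n)^2 / (p - 1) + (1 - 1 / n) / (p * n))
  qt_ <- stats::qt((1 + beta) / 2, df = nu)
  list(B2 = B2, nu = nu, t_quantile = qt_,
       multiplier = qt_ * sqrt(1 + 1 / (p * n * B2)))
}

#' Beta-expectation tolerance interval for relative error
#'
#' Computes the interval expected to contain a proportion `beta` of future
#' single results, on the relative (percent) scale:
#' `bias +/- Q_t(nu; (1+beta)/2) * sqrt(1 + 1/(p n B^2)) * s_R`, where
#' `B^2 = (R+1)/(nR+1)`,
#' `nu = (R+1)^2 / ((R + 1/n)^2/(p-1) + (1 - 1/n)/(pn))` and
#' `R = sigma2_between / sigma2_within`.
#'
#' When `rsd_intermediate_pct` is zero the interval degenerates to
#' `[bias, bias]` without evaluating the degrees of freedom.
#'
#' @param bias_pct Relative bias, percent.
#' @param rsd_intermediate_pct Intermediate-precision RSD (within- plus
#'   between-series variance), percent.
#' @param variance_ratio `R = sigma2_between/sigma2_within`; use 0 when the
#'   within-series variance is zero or the moment estimate is negative.
#' @param p,n Numbers of series and replicates per series.
#' @param beta Tolerance probability, default 0.95.
#' @return Named numeric `c(lower, upper)` in percent, with attributes
#'   `B_factor` (B, in (0, 1]), `dof` (fractional degrees of freedom) and
#'   `t_quantile`.
#' @examples
#' beta_eti(1.1, 2.6, (2.6^2 - 2.1^2) / 2.1^2, p = 3, n = 3)
#' @export
beta_eti <- function(bias_pct, rsd_intermediate_pct, variance_ratio, p, n,
                     beta = 0.95) {
  if (!is.finite(rsd_intermediate_pct) || rsd_intermediate_pct < 0)
    stop("'rsd_intermediate_pct' must be >= 0", call. = FALSE)
  if (!is.finite(variance_ratio) || variance_ratio < 0)
    stop("'variance_ratio' must be >= 0", call. = FALSE)
  if (beta <= 0 || beta >= 1) stop("'beta' must be in (0, 1)", call. = FALSE)
  if (rsd_intermediate_pct == 0) {
    out <- c(lower = bias_pct, upper = bias_pct)
    attr(out, "B_factor") <- NA_real_
    attr(out, "dof") <- NA_real_
    attr(out, "t_quantile") <- NA_real_
    return(out)
  }
  cmp <- .eti_components(variance_ratio, p, n, beta)
  hw <- cmp$multiplier * rsd_intermediate_pct
  out <- c(lower = bias_pct - hw, upper = bias_pct + hw)
  attr(out, "B_factor") <- sqrt(cmp$B2)
  attr(out, "dof") <- cmp$nu
  attr(out, "t_quantile") <- cmp$t_quantile
  out
}

#' Per-level total-error statistics
#'
#' Back-calculates every validation response at one concentration level
#' through its own series' calibration fit, then computes the level's bias,
#' variance components, repeatability and intermediate-precision RSDs, and
#' beta-expectation tolerance interval.
#'
#' @param table A `measurement_table` with validation records.
#' @param fits Named list of per-series `calib_fit` objects (see
#'   [fit_all_series()]).
#' @param level_index Level to analyse (1-based).
#' @param beta Tolerance probability; defaults to the design's `beta`.
#' @return A one-row data.frame with columns `level_index`,
#'   `nominal_concentration`, `mean_backcalc`, `relative_bias_pct`,
#'   `sigma2_within`, `sigma2_between`, `rsd_repeatability_pct`,
#'   `rsd_intermediate_pct`, `variance_ratio`, `B_factor`, `dof`,
#'   `t_quantile`, `beta_eti_low_pct`, `beta_eti_high_pct`.
#' @export
level_stats <- function(table, fits, level_index, beta = NULL) {
  stopifnot(inherits(table, "measurement_table"))
  design <- attr(table, "design")
  if (is.null(beta)) beta <- design$beta
  val <- table[table$role == "validation" & table$level_index == level_index, ,
               drop = FALSE]
  if (nrow(val) == 0L)
    stop("no validation records at level ", level_index, call. = FALSE)
  series <- sort(unique(table$series_id))
  p <- design$n_series; n <- design$n_replicates
  grid <- matrix(NA_real_, nrow = p, ncol = n)
  for (i in seq_along(series)) {
    sub <- val[val$series_id == series[i], , drop = FALSE]
    if (nrow(sub) != n)
      stop("unbalanced design at level ", level_index, ", series ", series[i],
           ": ", nrow(sub), " of ", n, " replicates", call. = FALSE)
    fit <- fits[[as.character(series[i])]]
    if (is.null(fit))
      stop("no calibration fit for series ", series[i], call. = FALSE)
    grid[i, ] <- back_calculate(fit, sub$response[order(sub$replicate_index)])
  }
  nominal <- val$nominal_concentration[1]
  vc <- variance_components(grid)
  mu_hat <- mean(grid)
  bias_pct <- 100 * (mu_hat - nominal) / nominal
  if (mu_hat <= 0)
    stop("mean back-calculated concentration is not positive at level ",
         level_index, call. = FALSE)
  rsd_r <- 100 * sqrt(vc$sigma2_within) / mu_hat
  rsd_R <- 100 * sqrt(vc$sigma2_within + vc$sigma2_between) / mu_hat
  R <- if (vc$sigma2_within > 0) vc$sigma2_between / vc$sigma2_within else 0
  iv <- beta_eti(bias_pct, rsd_R, R, p, n, beta)
  data.frame(
    level_index = level_index,
    nominal_concentration = nominal,
    mean_backcalc = mu_hat,
    relative_bias_pct = bias_pct,
    sigma2_within = vc$sigma2_within,
    sigma2_between = vc$sigma2_between,
    rsd_repeatability_pct = rsd_r,
    rsd_intermediate_pct = rsd_R,
    variance_ratio = R,
    B_factor = if (rsd_R == 0) 1 else attr(iv, "B_factor"),
    dof = attr(iv, "dof"),
    t_quantile = attr(iv, "t_quantile"),
    beta_eti_low_pct = unname(iv["lower"]),
    beta_eti_high_pct = unname(iv["upper"])
  )
}

#' Fit an accuracy profile
#'
#' The central fitting function of the package. Fits one calibration response
#' function per series, back-calculates the validation standards through their
#' own series' fit, computes per-level total-error statistics and the
#' beta-expectation tolerance intervals, and judges each level against the
#' acceptance limits +/- lambda.
#'
#' The method requires a balanced validation design (the variance-component
#' formulas assume balance); incomplete tables are rejected with the findings
#' from [validate_design()].
#'
#' @param table A `measurement_table` with both calibration and validation
#'   records.
#' @param model Response-function kind; see [calib_fit()].
#' @param beta Tolerance probability; defaults to the design's.
#' @param lambda Acceptance half-width in percent; defaults to the design's.
#' @return An object of class `"accuracy_profile"`: a list with
#'   \item{levels}{data.frame of per-level statistics (see [level_stats()])
#'     plus a logical `pass` column;}
#'   \item{lloq, uloq}{lower/upper limits of quantitation (ug/mL), possibly
#'     `NA` when no level passes;}
#'   \item{valid}{`TRUE` iff every level's interval lies inside
#'     `[-lambda, lambda]`;}
#'   \item{beta, lambda, model, design, fits}{inputs as used;}
#'   \item{backcalc}{data.frame of (series_id, introduced, backcalc) pairs for
#'     the validation standards.}
#' @examples
#' tab <- simulate_validation_dataset(default_truth_spec(), seed = 1)
#' prof <- accuracy_profile(tab)
#' prof
#' @seealso [build_profile()], [linearity_profile()],
#'   [select_response_function()]
#' @export
accuracy_profile <- function(table, model = "ols_linear", beta = NULL,
                             lambda = NULL) {
  stopifnot(inherits(table, "measurement_table"))
  design <- attr(table, "design")
  if (is.null(beta)) beta <- design$beta
  if (is.null(lambda)) lambda <- design$lambda
  findings <- validate_design(table, roles = "validation")
  if (length(findings))
    stop("validation design is not balanced/complete:\n  ",
         paste(findings, collapse = "\n  "), call. = FALSE)
  fits <- fit_all_series(table, model = model)
  stats <- do.call(rbind, lapply(seq_len(design$n_levels), function(l)
    level_stats(table, fits, l, beta = beta)))
  val <- table[table$role == "validation", , drop = FALSE]
  bc <- unlist(lapply(seq_len(nrow(val)), function(i)
    back_calculate(fits[[as.character(val$series_id[i])]], val$response[i])))
  prof <- build_profile(stats, lambda = lambda, beta = beta, design = design,
                        model = model)
  prof$fits <- fits
  prof$backcalc <- data.frame(series_id = val$series_id,
                              introduced = val$nominal_concentration,
                              backcalc = as.numeric(bc))
  prof
}

#' Assemble an accuracy profile from per-level statistics
#'
#' Applies the LLOQ/ULOQ decision logic to a table of per-level statistics:
#' a level passes iff its beta-expectation interval lies inside
#' `[-lambda, +lambda]`. The LLOQ is the lowest concentration when the lowest
#' level passes; otherwise it is interpolated linearly on the concentration
#' axis at the point where the offending interval bound crosses its acceptance
#' limit between the last failing and first passing level. The ULOQ is
#' obtained symmetrically from the top.
#'
#' @param stats A data.frame of per-level statistics as produced by
#'   [level_stats()], sorted by concentration.
#' @param lambda Acceptance half-width, percent.
#' @param beta Tolerance probability (stored on the object).
#' @param design Optional `validation_design` (used for percent-of-target
#'   annotations).
#' @param model Model label stored on the object.
#' @return An `accuracy_profile` object (without `fits`/`backcalc`).
#' @export
build_profile <- function(stats, lambda, beta = 0.95, design = NULL,
                          model = NA_character_) {
  stats <- as.data.frame(stats)
  if (nrow(stats) < 2L)
    stop("at least two levels are required", call. = FALSE)
  if (is.unsorted(stats$nominal_concentration, strictly = TRUE))
    stop("'stats' must be sorted by strictly increasing concentration",
         call. = FALSE)
  stats$pass <- stats$beta_eti_low_pct >= -lambda &
    stats$beta_eti_high_pct <= lambda
  conc <- stats$nominal_concentration
  m <- nrow(stats)

  cross <- function(i_fail, i_pass) {
    # concentration where the offending bound re-enters [-lambda, lambda],
    # linear on the concentration axis; take the latest crossing when both
    # bounds offend
    cc <- numeric(0)
    c1 <- conc[i_fail]; c2 <- conc[i_pass]
    hi1 <- stats$beta_eti_high_pct[i_fail]; hi2 <- stats$beta_eti_high_pct[i_pass]
    lo1 <- stats$beta_eti_low_pct[i_fail];  lo2 <- stats$beta_eti_low_pct[i_pass]
    if (hi1 > lambda)
      cc <- c(cc, c1 + (lambda - hi1) * (c2 - c1) / (hi2 - hi1))
    if (lo1 < -lambda)
      cc <- c(cc, c1 + (-lambda - lo1) * (c2 - c1) / (lo2 - lo1))
    cc
  }

  lloq <- NA_real_; uloq <- NA_real_
  if (any(stats$pass)) {
    i <- which(stats$pass)[1]
    lloq <- if (i == 1L) conc[1] else max(cross(i - 1L, i))
    j <- rev(which(stats$pass))[1]
    uloq <- if (j == m) conc[m] else min(cross(j + 1L, j))
  }
  structure(
    list(levels = stats, lloq = lloq, uloq = uloq,
         valid = all(stats$pass), beta = beta, lambda = lambda,
         model = model, design = design),
    class = "accuracy_profile"
  )
}

#' Limit of detection from the LLOQ
#'
#' Applies the conventional conversion `LOD = LLOQ / 3.3`.
#'
#' @param lloq Lower limit of quantitation (same units returned).
#' @return `lloq / 3.3`.
#' @export
lod_from_lloq <- function(lloq) {
  if (!is.numeric(lloq) || length(lloq) != 1L || !is.finite(lloq) || lloq <= 0)
    stop("'lloq' must be a single positive number", call. = FALSE)
  lloq / 3.3
}

#' Linearity profile: back-calculated versus introduced concentrations
#'
#' Regresses the back-calculated concentrations of the validation standards
#' on the introduced (nominal) concentrations with an unweighted linear model.
#' When called on an `accuracy_profile`, the per-level tolerance bands are the
#' beta-expectation intervals re-expressed on the concentration scale.
#'
#' @param x An `accuracy_profile`, or a numeric vector of introduced
#'   concentrations.
#' @param backcalc Back-calculated concentrations (when `x` is numeric).
#' @return A list of class `"linearity_profile"` with `slope`, `intercept`,
#'   `r_squared`, and `bands` (data.frame with columns `nominal_concentration`,
#'   `low`, `high` on the concentration scale; `NULL` when unavailable).
#' @export
linearity_profile <- function(x, backcalc = NULL) {
  if (inherits(x, "accuracy_profile")) {
    pairs <- x$backcalc
    if (is.null(pairs))
      stop("profile carries no back-calculated pairs", call. = FALSE)
    introduced <- pairs$introduced; bc <- pairs$backcalc
    lv <- x$levels
    bands <- data.frame(
      nominal_concentration = lv$nominal_concentration,
      low = lv$nominal_concentration * (1 + lv$beta_eti_low_pct / 100),
      high = lv$nominal_concentration * (1 + lv$beta_eti_high_pct / 100)
    )
  } else {
    introduced <- as.numeric(x); bc <- as.numeric(backcalc)
    bands <- NULL
  }
  if (length(unique(introduced)) < 2L)
    stop("at least two distinct introduced concentrations are required",
         call. = FALSE)
  cf <- .wls(introduced, bc, rep(1, length(introduced)))
  structure(list(slope = cf[["slope"]], intercept = cf[["intercept"]],
                 r_squared = cf[["r_squared"]], bands = bands),
            class = "linearity_profile")
}

#' @export
print.linearity_profile <- function(x, ...) {
  cat("Linearity (back-calculated vs introduced):\n")
  cat("  slope = ", format(x$slope), ", intercept = ", format(x$intercept),
      ", r^2 = ", format(x$r_squared), "\n", sep = "")
  invisible(x)
}

#' Compare candidate response functions by their accuracy profiles
#'
#' Builds one accuracy profile per candidate model and ranks them: models whose
#' levels all pass come first, then by the smallest maximum absolute interval
#' bound. Candidates that error (e.g. a square-root domain violation) are
#' reported as unavailable. Exact ties keep the candidate order, so
#' `ols_linear` (listed first by default) is preferred on ties; ties are
#' flagged.
#'
#' @param table A `measurement_table`.
#' @param models Character vector of candidate kinds.
#' @param beta,lambda Passed to [accuracy_profile()].
#' @return A list with `profiles` (named list, `NULL` where unavailable),
#'   `ranking` (data.frame with `model`, `available`, `all_pass`,
#'   `n_pass`, `max_abs_bound`, `rank`), `chosen` (model name) and
#'   `tie` (logical).
#' @export
select_response_function <- function(table,
                                     models = c("ols_linear", "weighted_1overX",
                                                "sqrt_linear", "single_point_120"),
                                     beta = NULL, lambda = NULL) {
  profiles <- stats::setNames(vector("list", length(models)), models)
  errs <- stats::setNames(rep(NA_character_, length(models)), models)
  for (mk in models) {
    profiles[mk] <- list(tryCatch(
      accuracy_profile(table, model = mk, beta = beta, lambda = lambda),
      error = function(e) { errs[mk] <<- conditionMessage(e); NULL }))
  }
  avail <- !vapply(profiles, is.null, logical(1))
  rk <- data.frame(
    model = models,
    available = avail,
    all_pass = NA, n_pass = NA_integer_, max_abs_bound = NA_real_,
    error = unname(errs),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(models)) {
    if (!avail[i]) next
    lv <- profiles[[i]]$levels
    rk$all_pass[i] <- all(lv$pass)
    rk$n_pass[i] <- sum(lv$pass)
    rk$max_abs_bound[i] <- max(abs(c(lv$beta_eti_low_pct, lv$beta_eti_high_pct)))
  }
  ord <- order(!rk$available, !isTRUE_vec(rk$all_pass), rk$max_abs_bound)
  rk$rank <- NA_integer_
  rk$rank[ord] <- seq_along(ord)
  rk <- rk[ord, , drop = FALSE]
  rownames(rk) <- NULL
  chosen <- rk$model[rk$available][1]
  tie <- sum(rk$available) > 1 &&
    isTRUE(all.equal(rk$max_abs_bound[1], rk$max_abs_bound[2])) &&
    identical(rk$all_pass[1], rk$all_pass[2])
  list(profiles = profiles, ranking = rk, chosen = chosen, tie = tie)
}

# order() helper that treats NA logicals as FALSE
isTRUE_vec <- function(x) !is.na(x) & x
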