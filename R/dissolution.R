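#' Describe a dissolution run
#'
#' Container for a (possibly two-stage) dissolution experiment: sampled vessel
#' concentrations at given timepoints, the vessel-volume schedule, the sampled
#' aliquot volume (withdrawn and replaced with blank medium), and the dose.
#'
#' The vessel volume is `v_initial` up to the stage change and
#' `v_initial + added_volume` afterwards; when `sample_before_change = TRUE`
#' (default) the sample taken exactly at `change_time` is regarded as taken
#' from the stage-1 volume, before the medium addition.
#'
#' @param time_min Strictly increasing, non-negative sampling times (minutes).
#' @param concentration Sampled vessel concentrations (ug/mL). If the analysed
#'   aliquots were diluted, set `dilution_factor` so that
#'   `concentration * dilution_factor` is the in-vessel concentration.
#' @param dose_mg Dose in the vessel (mg).
#' @param v_initial Stage-1 vessel volume (mL), default 100.
#' @param sample_volume Withdrawn/replaced aliquot volume (mL), default 2.
#' @param change_time Time of the medium addition (min), or `NULL` for a
#'   single-stage run.
#' @param added_volume Volume added at the stage change (mL), default 100.
#' @param sample_before_change Is the sample at `change_time` taken before the
#'   addition? Default `TRUE`.
#' @param dilution_factor Analytical dilution factor already applied to the
#'   reported concentrations, default 1 (i.e. none).
#' @return An object of class `"dissolution_run"`.
#' @export
dissolution_run <- function(time_min, concentration, dose_mg,
                            v_initial = 100, sample_volume = 2,
                            change_time = NULL, added_volume = 100,
                            sample_before_change = TRUE,
                            dilution_factor = 1) {
  time_min <- as.numeric(time_min)
  concentration <- as.numeric(concentration) * dilution_factor
  if (length(time_min) != length(concentration) || length(time_min) == 0L)
    stop("'time_min' and 'concentration' must be equal-length, non-empty",
         call. = FALSE)
  if (any(time_min < 0) || any(diff(time_min) <= 0))
    stop("timepoints must be non-negative and strictly increasing",
         call. = FALSE)
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop("concentrations must be finite and >= 0", call. = FALSE)
  if (!is.finite(dose_mg) || dose_mg <= 0)
    stop("'dose_mg' must be > 0", call. = FALSE)
  if (v_initial <= 0 || added_volume < 0 || sample_volume <= 0)
    stop("volumes must be positive", call. = FALSE)
  if (sample_volume >= v_initial)
    stop("'sample_volume' must be smaller than the vessel volume",
         call. = FALSE)
  volume <- rep(v_initial, length(time_min))
  if (!is.null(change_time)) {
    after <- if (sample_before_change) time_min > change_time else
      time_min >= change_time
    volume[after] <- v_initial + added_volume
  }
  structure(
    list(time_min = time_min, concentration = concentration,
         volume = volume, dose_mg = dose_mg, v_initial = v_initial,
         sample_volume = sample_volume, change_time = change_time,
         added_volume = added_volume,
         sample_before_change = sample_before_change),
    class = "dissolution_run"
  )
}

#' @export
print.dissolution_run <- function(x, ...) {
  cat("Dissolution run: ", length(x$time_min), " samples over ",
      max(x$time_min), " min, dose ", x$dose_mg, " mg\n", sep = "")
  if (!is.null(x$change_time))
    cat("  stage change at ", x$change_time, " min: ", x$v_initial, " -> ",
        x$v_initial + x$added_volume, " mL\n", sep = "")
  invisible(x)
}

#' Apply (or re-apply) a stage change to a dissolution run
#'
#' Updates the vessel-volume schedule for a medium addition of `added_volume`
#' at `t_change`. Analyte mass is conserved across the change, so the in-vessel
#' concentration is expected to be diluted by
#' `v_before / (v_before + added_volume)` (one half for a 100 -> 200 mL
#' addition).
#'
#' @param run A `dissolution_run`.
#' @param t_change Change time (min); must lie within the sampling schedule.
#' @param added_volume Volume added (mL).
#' @return The updated `dissolution_run`, with the expected dilution factor in
#'   element `dilution_at_change`.
#' @export
apply_stage_change <- function(run, t_change, added_volume) {
  stopifnot(inherits(run, "dissolution_run"))
  if (t_change < min(run$time_min) || t_change > max(run$time_min))
    stop("'t_change' is outside the sampling schedule", call. = FALSE)
  if (added_volume < 0) stop("'added_volume' must be >= 0", call. = FALSE)
  run$change_time <- t_change
  run$added_volume <- added_volume
  after <- if (run$sample_before_change) run$time_min > t_change else
    run$time_min >= t_change
  run$volume <- ifelse(after, run$v_initial + added_volume, run$v_initial)
  run$dilution_at_change <- run$v_initial / (run$v_initial + added_volume)
  run
}

#' Cumulative percent dissolved with withdrawal/replacement correction
#'
#' Converts sampled vessel concentrations into cumulative percent of dose
#' dissolved. Each withdrawn aliquot removes analyte that later samples no
#' longer see; the standard mass-balance correction adds it back:
#' `%dissolved_i = 100 (C_i V(t_i) + V_s sum_{j<i} C_j) / dose`,
#' with `V(t)` the stage-appropriate vessel volume. The correction is exact for
#' any sampling schedule, including across the stage change (where the in-vessel
#' mass is conserved and the concentration is diluted by the volume ratio).
#'
#' The cumulative curve is not forced to be non-decreasing (measurement noise
#' can produce small dips); a decrease larger than `monotonicity_tol`
#' percentage points triggers a warning.
#'
#' @param run A `dissolution_run`.
#' @param correct_withdrawal Apply the withdrawal correction? Default `TRUE`
#'   (set `FALSE` to see the uncorrected curve).
#' @param monotonicity_tol Warning threshold for decreases, in percentage
#'   points. Default 0.5.
#' @return Numeric vector of cumulative percent dissolved per timepoint.
#' @examples
#' run <- dissolution_run(c(5, 15), c(400, 450), dose_mg = 50)
#' cumulative_release(run)  # 80.0, 91.6
#' @export
cumulative_release <- function(run, correct_withdrawal = TRUE,
                               monotonicity_tol = 0.5) {
  stopifnot(inherits(run, "dissolution_run"))
  dose_ug <- run$dose_mg * 1000
  withdrawn <- if (correct_withdrawal)
    run$sample_volume * c(0, cumsum(run$concentration)[-length(run$concentration)])
  else 0
  pct <- 100 * (run$concentration * run$volume + withdrawn) / dose_ug
  drops <- diff(pct)
  if (any(drops < -monotonicity_tol))
    warning("cumulative release decreases by more than ", monotonicity_tol,
            " percentage points at timepoint(s) ",
            paste(run$time_min[-1][drops < -monotonicity_tol], collapse = ", "),
            call. = FALSE)
  pct
}

#' Summarise a dissolution profile
#'
#' Linear-interpolated read-outs of a cumulative release curve: the value at
#' a given early timepoint, the time to reach a threshold, and the plateau
#' (mean of the last three points).
#'
#' @param time_min Sampling times (minutes).
#' @param percent Cumulative percent dissolved, same length.
#' @param at Early read-out time, default 5 min.
#' @param threshold Threshold for the time-to read-out, default 85 percent.
#' @return List with `value_at` (percent), `time_to` (min; `NA` when the
#'   threshold is never reached) and `plateau` (percent).
#' @export
profile_summary <- function(time_min, percent, at = 5, threshold = 85) {
  if (length(time_min) != length(percent) || length(time_min) == 0L)
    stop("'time_min' and 'percent' must be equal-length, non-empty",
         call. = FALSE)
  value_at <- if (at < min(time_min) || at > max(time_min)) NA_real_ else
    stats::approx(time_min, percent, xout = at)$y
  time_to <- NA_real_
  hit <- which(percent >= threshold)
  if (length(hit)) {
    i <- hit[1]
    time_to <- if (i == 1L) time_min[1] else
      stats::approx(percent[(i - 1):i], time_min[(i - 1):i],
                    xout = threshold, ties = "ordered")$y
  }
  k <- min(3L, length(percent))
  list(value_at = value_at, time_to = time_to,
       plateau = mean(utils::tail(percent, k)))
}
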