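#' Construct a chromatogram
#'
#' @param time Strictly increasing time axis (minutes).
#' @param intensity Detector signal, same length as `time`.
#' @param metadata Optional named list of labels.
#' @return An object of class `"chromatogram"`.
#' @export
chromatogram <- function(time, intensity, metadata = list()) {
  time <- as.numeric(time); intensity <- as.numeric(intensity)
  if (length(time) != length(intensity) || length(time) < 2L)
    stop("'time' and 'intensity' must be equal-length (>= 2)", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("'time' must be strictly increasing", call. = FALSE)
  if (anyNA(intensity))
    stop("missing intensities", call. = FALSE)
  structure(list(time = time, intensity = intensity, metadata = metadata),
            class = "chromatogram")
}

#' Read a chromatogram from a two-column CSV
#'
#' @param path CSV file with a header row.
#' @param time_col,intensity_col Column names, defaults `time_min` and
#'   `intensity`.
#' @return A `chromatogram`.
#' @export
read_chromatogram <- function(path, time_col = "time_min",
                              intensity_col = "intensity") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path)
  for (col in c(time_col, intensity_col))
    if (is.null(d[[col]])) stop("missing column: ", col, call. = FALSE)
  chromatogram(d[[time_col]], d[[intensity_col]],
               metadata = list(source = path))
}

#' @export
print.chromatogram <- function(x, ...) {
  cat("Chromatogram: ", length(x$time), " points, ",
      format(min(x$time)), "-", format(max(x$time)), " min\n", sep = "")
  invisible(x)
}

.baseline_correct <- function(chrom, baseline) {
  chrom$intensity - (baseline[1] + baseline[2] * chrom$time)
}

#' Detect the main peak in a time window
#'
#' Subtracts a linear baseline anchored at the window endpoints, takes the apex
#' as the maximum of the corrected signal inside the window, and sets the peak
#' bounds where the corrected signal returns to within 3 x noise of the
#' baseline. Noise is estimated from the corrected signal in the outer 10% of
#' the window on each side unless supplied. If more than one resolved maximum
#' exceeds half the apex height, the taller is used and a warning is emitted.
#'
#' @param chrom A `chromatogram` with at least 50 points.
#' @param window Length-2 time range to search; defaults to the whole trace.
#' @param noise Optional known noise standard deviation (detector units).
#' @return An object of class `"peak_region"`: list with `apex_index`,
#'   `apex_time`, `height` (baseline-corrected), `left_index`, `right_index`,
#'   `baseline` (intercept, slope), `noise`.
#' @export
detect_peak <- function(chrom, window = range(chrom$time), noise = NULL) {
  stopifnot(inherits(chrom, "chromatogram"))
  if (length(chrom$time) < 50L)
    stop("at least 50 points are required for peak metrics", call. = FALSE)
  idx <- which(chrom$time >= window[1] & chrom$time <= window[2])
  if (length(idx) < 10L)
    stop("window contains too few points", call. = FALSE)
  i1 <- idx[1]; i2 <- idx[length(idx)]
  t1 <- chrom$time[i1]; t2 <- chrom$time[i2]
  slope <- (chrom$intensity[i2] - chrom$intensity[i1]) / (t2 - t1)
  baseline <- c(chrom$intensity[i1] - slope * t1, slope)
  corrected <- .baseline_correct(chrom, baseline)
  if (is.null(noise)) {
    k <- max(5L, ceiling(length(idx) * 0.1))
    edge <- c(idx[seq_len(k)], idx[seq.int(length(idx) - k + 1L, length(idx))])
    noise <- stats::sd(corrected[edge])
  }
  apex_local <- which.max(corrected[idx])
  apex <- idx[apex_local]
  h <- corrected[apex]
  if (!(h > 3 * noise) || h <= 0)
    stop("no peak detected above the noise in the window", call. = FALSE)

  # count resolved maxima above half the apex height
  ci <- corrected[idx]
  locmax <- which(diff(sign(diff(ci))) == -2) + 1L
  locmax <- locmax[ci[locmax] > 0.5 * h]
  if (length(locmax) > 1L) {
    resolved <- 1L
    for (k2 in seq_len(length(locmax) - 1L)) {
      valley <- min(ci[locmax[k2]:locmax[k2 + 1L]])
      if (valley < 0.5 * min(ci[locmax[k2]], ci[locmax[k2 + 1L]]))
        resolved <- resolved + 1L
    }
    if (resolved > 1L)
      warning("multiple peaks in window; using the tallest", call. = FALSE)
  }

  thr <- 3 * noise
  left <- apex
  while (left > i1 && corrected[left - 1L] > thr) left <- left - 1L
  right <- apex
  while (right < i2 && corrected[right + 1L] > thr) right <- right + 1L
  structure(
    list(apex_index = apex, apex_time = chrom$time[apex], height = h,
         left_index = left, right_index = right, baseline = baseline,
         noise = noise, window = window),
    class = "peak_region"
  )
}

#' Peak width at a height fraction
#'
#' Width of the baseline-corrected peak at `fraction` of its apex height, with
#' sub-sample linear interpolation; returns the total width and the front/back
#' half-widths measured from the apex time.
#'
#' @param chrom A `chromatogram`.
#' @param peak A `peak_region` from [detect_peak()].
#' @param fraction Height fraction in (0, 1), e.g. 0.5 for half height.
#' @return List with `width`, `front`, `back` (minutes).
#' @export
width_at_fraction <- function(chrom, peak, fraction) {
  stopifnot(inherits(chrom, "chromatogram"), inherits(peak, "peak_region"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("'fraction' must be in (0, 1)", call. = FALSE)
  corrected <- .baseline_correct(chrom, peak$baseline)
  thr <- fraction * peak$height
  apex <- peak$apex_index
  t <- chrom$time

  cross_left <- NA_real_
  if (apex >= 2L) for (i in seq.int(apex, 2L)) {
    if (corrected[i - 1L] < thr && corrected[i] >= thr) {
      cross_left <- t[i - 1L] + (thr - corrected[i - 1L]) *
        (t[i] - t[i - 1L]) / (corrected[i] - corrected[i - 1L])
      break
    }
  }
  cross_right <- NA_real_
  if (apex <= length(t) - 1L) for (i in seq.int(apex, length(t) - 1L)) {
    if (corrected[i + 1L] < thr && corrected[i] >= thr) {
      cross_right <- t[i] + (corrected[i] - thr) *
        (t[i + 1L] - t[i]) / (corrected[i] - corrected[i + 1L])
      break
    }
  }
  if (is.na(cross_left) || is.na(cross_right))
    stop("the ", fraction, " height level is not crossed on both sides ",
         "within the trace", call. = FALSE)
  list(width = cross_right - cross_left,
       front = peak$apex_time - cross_left,
       back = cross_right - peak$apex_time)
}

#' Theoretical plate count (half-height formula)
#'
#' Column efficiency by the EP/USP half-height formula
#' `N = 5.54 * (t_R / W_0.5)^2`.
#'
#' @param t_R Retention time.
#' @param width_half Peak width at half height, same units.
#' @return N (dimensionless).
#' @examples
#' theoretical_plates(5.9, 2 * 0.05 * sqrt(2 * log(2)))
#' @export
theoretical_plates <- function(t_R, width_half) {
  if (!is.finite(t_R) || t_R <= 0 || !is.finite(width_half) || width_half <= 0)
    stop("'t_R' and 'width_half' must be > 0", call. = FALSE)
  5.54 * (t_R / width_half)^2
}

#' USP tailing factor
#'
#' `T_f = W_0.05 / (2 f)` with `W_0.05` the full peak width at 5% height and
#' `f` the front half-width at the same height.
#'
#' @param chrom A `chromatogram`.
#' @param peak A `peak_region`.
#' @return T_f; 1 for a symmetric peak, > 1 for tailing, < 1 for fronting.
#' @export
tailing_factor <- function(chrom, peak) {
  w <- width_at_fraction(chrom, peak, 0.05)
  w$width / (2 * w$front)
}

#' Signal-to-noise ratio (peak-to-peak convention)
#'
#' `S/N = 2H/h` with `H` the baseline-corrected peak height and `h` the
#' peak-to-peak amplitude of the linearly detrended signal in a blank noise
#' window (the pharmacopoeial convention). With `convention = "rms"`,
#' `S/N = H / sd(noise)` is returned instead.
#'
#' @param chrom A `chromatogram`.
#' @param peak A `peak_region`.
#' @param noise_window Length-2 time range, disjoint from the peak region,
#'   containing at least 20 points.
#' @param convention `"peak_to_peak"` (default) or `"rms"`.
#' @return The S/N ratio; `Inf` (with a warning) on a noiseless trace.
#' @export
signal_to_noise <- function(chrom, peak, noise_window,
                            convention = c("peak_to_peak", "rms")) {
  convention <- match.arg(convention)
  stopifnot(inherits(chrom, "chromatogram"), inherits(peak, "peak_region"))
  t <- chrom$time
  peak_range <- c(t[peak$left_index], t[peak$right_index])
  if (noise_window[1] < peak_range[2] && noise_window[2] > peak_range[1])
    stop("noise window overlaps the peak region", call. = FALSE)
  idx <- which(t >= noise_window[1] & t <= noise_window[2])
  if (length(idx) < 20L)
    stop("noise window must contain at least 20 points", call. = FALSE)
  yt <- chrom$intensity[idx]
  fitres <- stats::lm.fit(cbind(1, t[idx]), yt)$residuals
  h <- if (convention == "peak_to_peak") diff(range(fitres)) else
    stats::sd(fitres)
  if (h == 0) {
    warning("noiseless trace: S/N is infinite", call. = FALSE)
    return(Inf)
  }
  if (convention == "peak_to_peak") 2 * peak$height / h else peak$height / h
}

#' Concentration at a target signal-to-noise ratio
#'
#' Inverts the peak-to-peak S/N definition: the concentration whose predicted
#' peak height `H = height_slope * C` gives `S/N = 2H/h = target_sn`, i.e.
#' `C = target_sn * h / (2 * height_slope)`. Used for the S/N = 3 limit of
#' detection.
#'
#' @param height_slope Peak height per unit concentration.
#' @param noise_h Peak-to-peak noise amplitude.
#' @param target_sn Target ratio, default 3.
#' @return Concentration.
#' @examples
#' lod_from_sn(300, 4)  # 0.02
#' @export
lod_from_sn <- function(height_slope, noise_h, target_sn = 3) {
  if (!is.finite(height_slope) || height_slope <= 0)
    stop("'height_slope' must be > 0", call. = FALSE)
  if (!is.finite(noise_h) || noise_h <= 0)
    stop("'noise_h' must be > 0", call. = FALSE)
  if (!is.finite(target_sn) || target_sn < 0)
    stop("'target_sn' must be >= 0", call. = FALSE)
  target_sn * noise_h / (2 * height_slope)
}

#' Summarise the main peak of a chromatogram
#'
#' Convenience wrapper computing retention time, baseline-corrected height and
#' area (trapezoidal, between the peak bounds), theoretical plates, tailing
#' factor and (optionally) S/N.
#'
#' @param chrom A `chromatogram`.
#' @param window Peak search window.
#' @param noise_window Optional window for [signal_to_noise()].
#' @return A list of class `"peak_metrics"` with `retention_time`, `height`,
#'   `area`, `plates`, `tailing`, `snr` (NA when no noise window given).
#' @export
peak_metrics <- function(chrom, window = range(chrom$time),
                         noise_window = NULL) {
  peak <- detect_peak(chrom, window)
  corrected <- .baseline_correct(chrom, peak$baseline)
  idx <- seq.int(peak$left_index, peak$right_index)
  area <- sum(diff(chrom$time[idx]) *
              (corrected[idx][-1] + corrected[idx][-length(idx)]) / 2)
  wh <- width_at_fraction(chrom, peak, 0.5)
  snr <- if (is.null(noise_window)) NA_real_ else
    signal_to_noise(chrom, peak, noise_window)
  structure(
    list(retention_time = peak$apex_time, height = peak$height, area = area,
         plates = theoretical_plates(peak$apex_time, wh$width),
         tailing = tailing_factor(chrom, peak), snr = snr),
    class = "peak_metrics"
  )
}

#' @export
print.peak_metrics <- function(x, ...) {
  cat("Peak: t_R = ", format(x$retention_time), " min, height = ",
      format(x$height), ", area = ", format(x$area), "\n  N = ",
      format(round(x$plates)), ", T_f = ", format(round(x$tailing, 3)),
      if (!is.na(x$snr)) paste0(", S/N = ", format(round(x$snr, 1))),
      "\n", sep = "")
  invisible(x)
}

#' System suitability evaluation
#'
#' Judges replicate injections against the usual gates: RSD of retention time
#' and of peak area at most `rsd_max` percent, plate count above `plates_min`,
#' and tailing factor at most `tailing_max`.
#'
#' @param retention_times,areas Numeric vectors from replicate injections
#'   (at least 2; 6 is the customary design).
#' @param plates,tailing Representative plate count and tailing factor
#'   (optional, `NA` to skip those gates).
#' @param criteria Named list overriding `rsd_max` (default 2), `plates_min`
#'   (default 5000) and `tailing_max` (default 1.5).
#' @return An object of class `"sst_report"`: data.frame with columns
#'   `criterion`, `value`, `limit`, `pass`, and attribute `overall_pass`.
#' @export
sst_evaluate <- function(retention_times, areas, plates = NA_real_,
                         tailing = NA_real_, criteria = list()) {
  if (length(retention_times) < 2L || length(areas) < 2L)
    stop("at least two replicate injections are required", call. = FALSE)
  crit <- utils::modifyList(
    list(rsd_max = 2, plates_min = 5000, tailing_max = 1.5), criteria)
  rows <- data.frame(
    criterion = c("retention time RSD (%)", "peak area RSD (%)",
                  "theoretical plates", "tailing factor"),
    value = c(rsd_pct(retention_times), rsd_pct(areas), plates, tailing),
    limit = c(crit$rsd_max, crit$rsd_max, crit$plates_min, crit$tailing_max),
    direction = c("<=", "<=", ">", "<=")
  )
  rows$pass <- ifelse(rows$direction == "<=", rows$value <= rows$limit,
                      rows$value > rows$limit)
  rows <- rows[!is.na(rows$value), , drop = FALSE]
  structure(rows, overall_pass = all(rows$pass),
            class = c("sst_report", "data.frame"))
}

#' @export
print.sst_report <- function(x, ...) {
  cat("System suitability:\n")
  print(as.data.frame(x), row.names = FALSE)
  cat("overall:", if (attr(x, "overall_pass")) "PASS" else "FAIL", "\n")
  invisible(x)
}
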