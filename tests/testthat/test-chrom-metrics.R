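test_that("peak detection finds a clean Gaussian apex and rejects flat traces", {
  ch <- gaussian_chrom()
  peak <- detect_peak(ch, window = c(5.4, 6.4))
  expect_lt(abs(peak$apex_time - 5.9), 1 / 250 + 1e-12)
  expect_equal(peak$height, 300, tolerance = 1e-3)

  flat <- chromatogram(seq(0, 12, by = 0.01), rep(2, 1201))
  expect_error(detect_peak(flat, c(5.4, 6.4)), "no peak")
})

test_that("with two peaks in the window the taller wins, with a warning", {
  ch <- simulate_chromatogram(
    peaks = data.frame(rt = c(5.7, 6.1), sigma = c(0.04, 0.04), tau = 0,
                       height = c(200, 300)),
    noise_sd = 0, seed = 1)
  expect_warning(peak <- detect_peak(ch, c(5.4, 6.4)), "multiple peaks")
  expect_lt(abs(peak$apex_time - 6.1), 0.01)
})

test_that("half-height width matches the Gaussian closed form", {
  ch <- gaussian_chrom(sigma = 0.05, points_per_min = 1000)
  peak <- detect_peak(ch, c(5.4, 6.4))
  w <- width_at_fraction(ch, peak, 0.5)
  fwhm <- 2 * 0.05 * sqrt(2 * log(2))
  expect_equal(w$width, fwhm, tolerance = 1e-3)
  expect_equal(w$front, w$back, tolerance = 1e-2)
  expect_error(width_at_fraction(ch, peak, 1.5), "fraction")

  # peak truncated at the trace edge never crosses the level on one side
  tt <- seq(5.4, 5.9, by = 0.002)
  short <- chromatogram(tt, 300 * exp(-(tt - 5.9)^2 / (2 * 0.05^2)))
  pk <- structure(list(apex_index = length(tt), apex_time = 5.9, height = 300,
                       left_index = 1L, right_index = length(tt),
                       baseline = c(0, 0), noise = 0,
                       window = range(tt)),
                  class = "peak_region")
  expect_error(width_at_fraction(short, pk, 0.05), "not crossed")
})

test_that("plate count follows the half-height formula and its scaling law", {
  fwhm <- 2 * 0.05 * sqrt(2 * log(2))
  n1 <- theoretical_plates(5.9, fwhm)
  # 5.54/(8 ln 2) = 0.99926..., so N is within 0.1% of (t_R/sigma)^2
  expect_equal(n1, (5.9 / 0.05)^2, tolerance = 1e-3)
  expect_gt(n1, 13000)
  expect_equal(theoretical_plates(1, 1), 5.54)
  expect_equal(theoretical_plates(11.8, fwhm), 4 * n1, tolerance = 1e-12)
  expect_error(theoretical_plates(-1, 1))
  # full pipeline on a sampled Gaussian
  ch <- gaussian_chrom(points_per_min = 1000)
  pm <- peak_metrics(ch, window = c(5.4, 6.4))
  expect_equal(pm$plates, (5.9 / 0.05)^2, tolerance = 5e-3)
})

test_that("tailing factor is 1 for a Gaussian and matches the EMG oracle", {
  ch <- gaussian_chrom(points_per_min = 1000)
  peak <- detect_peak(ch, c(5.4, 6.4))
  expect_equal(tailing_factor(ch, peak), 1, tolerance = 0.005)

  # dense numeric oracle: 1e4-point evaluation of the same EMG shape,
  # 5% crossings located by root bracketing on the interpolant
  oracle_tf <- function(sigma, tau) {
    t <- seq(5, 7.5, length.out = 10000)
    y <- emg_peak(t, 5.9, sigma, tau, 300)
    apex <- which.max(y)
    thr <- 0.05 * y[apex]
    fl <- approxfun(t, y - thr)
    left <- uniroot(fl, c(t[1], t[apex]), tol = 1e-12)$root
    right <- uniroot(fl, c(t[apex], t[length(t)]), tol = 1e-12)$root
    (right - left) / (2 * (t[apex] - left))
  }
  for (tau in c(0.05, 0.10, 0.20)) {
    ch2 <- simulate_chromatogram(
      peaks = data.frame(rt = 5.9, sigma = 0.05, tau = tau, height = 300),
      noise_sd = 0, points_per_min = 1000)
    pk2 <- detect_peak(ch2, c(5.4, 7.2))
    tf <- tailing_factor(ch2, pk2)
    expect_gt(tf, 1)
    expect_equal(tf, oracle_tf(0.05, tau), tolerance = 0.01)
  }
  # mirrored (fronting) peak: T_f < 1 by reflection
  ch3 <- simulate_chromatogram(
    peaks = data.frame(rt = 5.9, sigma = 0.05, tau = 0.10, height = 300),
    noise_sd = 0, points_per_min = 1000)
  mirrored <- chromatogram(ch3$time, rev(ch3$intensity))
  pk3 <- detect_peak(mirrored, 12 - c(7.2, 5.4))
  expect_lt(tailing_factor(mirrored, pk3), 1)
})

test_that("tailing increases with tau/sigma", {
  tfs <- vapply(c(0.02, 0.05, 0.1, 0.2), function(tau) {
    ch <- simulate_chromatogram(
      peaks = data.frame(rt = 5.9, sigma = 0.05, tau = tau, height = 300),
      noise_sd = 0, points_per_min = 500)
    tailing_factor(ch, detect_peak(ch, c(5.4, 7.5)))
  }, numeric(1))
  expect_true(all(diff(tfs) > 0))
})

test_that("signal-to-noise follows the 2H/h convention", {
  # deterministic sawtooth noise of known peak-to-peak amplitude 2
  t <- seq(0, 12, by = 0.004)
  y <- 30 * exp(-(t - 5.9)^2 / (2 * 0.05^2)) + rep(c(-1, 1), length.out = length(t))
  ch <- chromatogram(t, y)
  peak <- detect_peak(ch, c(5.4, 6.4), noise = 0.05)
  snr <- signal_to_noise(ch, peak, noise_window = c(8, 10))
  expect_equal(snr, 2 * peak$height / 2, tolerance = 0.05)

  clean <- gaussian_chrom()
  pk <- detect_peak(clean, c(5.4, 6.4))
  expect_warning(s <- signal_to_noise(clean, pk, c(8, 10)), "noiseless")
  expect_identical(s, Inf)
  expect_error(signal_to_noise(clean, pk, c(5.8, 8)), "overlap")
})

test_that("S/N on white noise tracks the extreme-value expectation", {
  # peak-to-peak of ~3000 N(0, sigma) draws concentrates near 6.6 sigma,
  # so S/N should be within 20% of 2H/(6.6 sigma) on average
  set.seed(31)
  H <- 300; sigma <- 2
  vals <- vapply(1:12, function(i) {
    ch <- simulate_chromatogram(noise_sd = sigma,
      peaks = data.frame(rt = 5.9, sigma = 0.05, tau = 0, height = H))
    pk <- detect_peak(ch, c(5.4, 6.4))
    signal_to_noise(ch, pk, c(8, 10))
  }, numeric(1))
  expect_lt(abs(mean(vals) - 2 * H / (6.6 * sigma)) / (2 * H / (6.6 * sigma)),
            0.20)
})

test_that("S/N-based LOD inverts the definition and scales with noise", {
  expect_equal(lod_from_sn(300, 4), 0.02)
  expect_equal(lod_from_sn(300, 4, target_sn = 0), 0)
  expect_equal(lod_from_sn(300, 8), 2 * lod_from_sn(300, 4))
  expect_error(lod_from_sn(-1, 4))
  expect_error(lod_from_sn(300, 0))
})

test_that("system suitability gates replicate injections", {
  rt <- c(5.90, 5.92, 5.88, 5.91, 5.89, 5.90)
  area <- 211000 * c(1.00, 1.01, 0.99, 1.005, 0.995, 1.002)
  rep1 <- sst_evaluate(rt, area, plates = 13000, tailing = 1.1)
  expect_true(attr(rep1, "overall_pass"))

  area_bad <- 211000 * c(1, 1.05, 0.95, 1.04, 0.96, 1.03)  # RSD > 2%
  rep2 <- sst_evaluate(rt, area_bad, plates = 13000, tailing = 1.1)
  expect_false(attr(rep2, "overall_pass"))
  expect_false(rep2$pass[rep2$criterion == "peak area RSD (%)"])

  rep3 <- sst_evaluate(rt, area, plates = 4000, tailing = 1.1)
  expect_false(attr(rep3, "overall_pass"))
  expect_false(rep3$pass[rep3$criterion == "theoretical plates"])
  expect_error(sst_evaluate(5.9, 211000), "at least two")
})
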