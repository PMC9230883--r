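# Fixtures built in code: noiseless designs, toy grids, clean chromatograms.

noiseless_truth <- function(bias_pct = 0, slope = 21100, intercept = 0,
                            conc = c(10, 50, 100, 300, 600)) {
  truth_spec(validation_design(3, 3, conc),
             bias_pct = bias_pct, cv_within_pct = 0, cv_between_pct = 0,
             slope = slope, intercept = intercept,
             cv_cal_pct = 0, cv_day_slope_pct = 0)
}

noiseless_table <- function(...) {
  simulate_validation_dataset(noiseless_truth(...), seed = 1)
}

# 3 series x 3 replicates grid with MS_within = 1, MS_between = 3
toy_grid <- function() rbind(c(9, 10, 11), c(10, 11, 12), c(11, 12, 13))

gaussian_chrom <- function(rt = 5.9, sigma = 0.05, height = 300,
                           points_per_min = 250, noise_sd = 0, seed = 1) {
  simulate_chromatogram(
    peaks = data.frame(rt = rt, sigma = sigma, tau = 0, height = height),
    baseline = c(0, 0), noise_sd = noise_sd,
    duration = 12, points_per_min = points_per_min, seed = seed
  )
}

# independent one-way ANOVA oracle via stats::aov
aov_components <- function(grid) {
  d <- data.frame(y = as.vector(t(grid)),
                  s = factor(rep(seq_len(nrow(grid)), each = ncol(grid))))
  tab <- summary(stats::aov(y ~ s, data = d))[[1]]
  ms_b <- tab["s", "Mean Sq"]; ms_w <- tab["Residuals", "Mean Sq"]
  list(ms_within = ms_w, ms_between = ms_b,
       sigma2_within = ms_w,
       sigma2_between = max(0, (ms_b - ms_w) / ncol(grid)))
}
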