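test_that("cumulative release reproduces the hand mass balance", {
  # 100 mL vessel, 2 mL samples, 50 mg dose, 400 then 450 ug/mL:
  # 450*100 + 2*400 = 45800 ug of 50000 -> 91.6%
  run <- dissolution_run(c(5, 15), c(400, 450), dose_mg = 50)
  expect_equal(cumulative_release(run), c(80.0, 91.6))

  # single timepoint: plain C*V/dose
  one <- dissolution_run(5, 400, dose_mg = 50)
  expect_equal(cumulative_release(one), 80)

  # all analyte in solution, no prior withdrawals: exactly 100%
  full <- dissolution_run(5, 500, dose_mg = 50)
  expect_equal(cumulative_release(full), 100)
})

test_that("run construction validates its schedule", {
  expect_error(dissolution_run(c(5, 5), c(1, 1), 50), "strictly increasing")
  expect_error(dissolution_run(c(-1, 5), c(1, 1), 50), "non-negative")
  expect_error(dissolution_run(5, -1, 50), ">= 0")
  expect_error(dissolution_run(5, 1, 0), "dose")
  expect_error(dissolution_run(5, 1, 50, sample_volume = 200), "smaller")
})

test_that("stage change conserves mass and dilutes concentration by the volume ratio", {
  run <- dissolution_run(c(30, 60, 75), c(500, 500, 250), dose_mg = 60,
                         v_initial = 100, change_time = 60)
  run2 <- apply_stage_change(run, 60, 100)
  expect_equal(run2$dilution_at_change, 0.5)
  expect_equal(run2$volume, c(100, 100, 200))
  # 0.5 mg/mL in 100 mL + 100 mL blank -> 0.25 mg/mL, 50 mg unchanged
  expect_equal(0.5 * 100, 0.25 * 200)
  # identity when nothing is added
  run3 <- apply_stage_change(run, 60, 0)
  expect_equal(run3$volume, rep(100, 3))
  expect_error(apply_stage_change(run, 500, 100), "outside")
})

test_that("release percentage is continuous across a noiseless stage change", {
  # concentration measured just before (100 mL) and just after (200 mL) the
  # change: in-vessel mass identical, cumulative % must agree
  m <- 40 * 1000  # ug in vessel, dose 50 mg
  run <- dissolution_run(c(59.9, 60, 60.0001), c(1, m / 100, m / 200),
                         dose_mg = 50, v_initial = 100, change_time = 60,
                         sample_before_change = TRUE)
  pct <- suppressWarnings(cumulative_release(run, correct_withdrawal = FALSE))
  expect_equal(pct[2], pct[3])
})

test_that("withdrawal correction is exact on simulated two-stage runs", {
  for (sched in list(c(0, 5, 15, 30, 60, 75, 90, 120, 180, 240),
                     c(2, 7, 33, 60, 61, 100, 240),
                     seq(5, 240, by = 5))) {
    run <- simulate_dissolution(k_release = c(0.32, 0.15), dose_mg = 50,
                                timepoints = sched, noise_cv = 0)
    expect_equal(cumulative_release(run), attr(run, "true_release_pct"),
                 tolerance = 1e-9)
  }
  # and without the correction the late points are underestimated
  run <- simulate_dissolution(noise_cv = 0)
  # the uncorrected plateau sags as withdrawals remove mass, hence the warning
  expect_warning(raw <- cumulative_release(run, correct_withdrawal = FALSE),
                 "decreases")
  idx <- 3:length(raw)  # once at least one non-blank aliquot has been taken
  expect_true(all(raw[idx] < attr(run, "true_release_pct")[idx]))
})

test_that("mass conservation holds with zero withdrawals", {
  run <- simulate_dissolution(sample_volume = 1e-12, noise_cv = 0)
  expect_equal(cumulative_release(run), attr(run, "true_release_pct"),
               tolerance = 1e-6)
})

test_that("noisy runs can warn about non-monotonicity", {
  run <- dissolution_run(c(5, 15), c(450, 400), dose_mg = 50)
  expect_warning(cumulative_release(run), "decreases")
})

test_that("profile summaries follow first-order kinetics read-outs", {
  # k = 0.32/min: 100*(1 - exp(-1.6)) ~ 79.8% at 5 min
  run <- simulate_dissolution(k_release = 0.32, noise_cv = 0)
  pct <- cumulative_release(run)
  ps <- profile_summary(run$time_min, pct)
  expect_equal(ps$value_at, 100 * (1 - exp(-1.6)), tolerance = 1e-6)
  expect_lt(ps$time_to, 15)
  expect_gt(ps$time_to, 5)
  expect_equal(ps$plateau, mean(tail(pct, 3)))

  flat <- profile_summary(c(0, 5, 10), c(0, 0, 0))
  expect_equal(flat$value_at, 0)
  expect_true(is.na(flat$time_to))
  expect_equal(flat$plateau, 0)

  # a fast release reaches ~100% at the first sample
  fast <- simulate_dissolution(k_release = 5, noise_cv = 0)
  expect_gt(cumulative_release(fast)[2], 99.9)
})
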