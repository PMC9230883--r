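test_that("variance components match the hand ANOVA on the toy grid", {
  vc <- variance_components(toy_grid())
  expect_equal(vc$ms_within, 1)
  expect_equal(vc$ms_between, 3)
  expect_equal(vc$sigma2_within, 1)
  expect_equal(vc$sigma2_between, 2 / 3)
})

test_that("degenerate grids give zero / truncated components", {
  expect_equal(variance_components(matrix(5, 3, 3))$sigma2_within, 0)
  expect_equal(variance_components(matrix(5, 3, 3))$sigma2_between, 0)
  # equal series means, spread within: negative moment estimate clamps to 0
  g <- rbind(c(9, 11), c(9, 11), c(9, 11))
  expect_equal(variance_components(g)$sigma2_between, 0)
  expect_gt(variance_components(g)$sigma2_within, 0)
  expect_error(variance_components(toy_grid()[1, , drop = FALSE]), "at least 2")
  expect_error(variance_components(c(1, 2, 3, 4), series = c(1, 1, 2)), "length")
  expect_error(variance_components(c(1, 2, 3, 4, 5), series = c(1, 1, 1, 2, 2)),
               "unbalanced")
})

test_that("variance components agree with the aov oracle on random grids", {
  set.seed(99)
  for (i in 1:60) {
    p <- sample(3:5, 1); n <- sample(3:6, 1)
    grid <- matrix(rnorm(p * n, 10, 2), p, n) +
      rnorm(p, 0, runif(1, 0, 3))  # row effects
    vc <- variance_components(grid)
    oracle <- aov_components(grid)
    expect_equal(vc$ms_within, oracle$ms_within, tolerance = 1e-10)
    expect_equal(vc$ms_between, oracle$ms_between, tolerance = 1e-10)
    expect_equal(vc$sigma2_between, oracle$sigma2_between, tolerance = 1e-10)
  }
})

test_that("beta-ETI degenerates to [bias, bias] when s_R = 0", {
  iv <- beta_eti(4.2, 0, 0, p = 3, n = 3)
  expect_equal(as.numeric(iv), c(4.2, 4.2))
})

test_that("beta-ETI half-width at R = 0 matches the closed form", {
  nu0 <- 1 / ((1 / 3)^2 / 2 + (2 / 3) / 9)  # 54/7
  expect_equal(nu0, 54 / 7)
  hw <- qt(0.975, nu0) * sqrt(1 + 1 / 9)
  iv <- beta_eti(0, 1, 0, p = 3, n = 3, beta = 0.95)
  expect_equal(as.numeric(iv), c(-hw, hw), tolerance = 1e-12)
  expect_equal(attr(iv, "dof"), nu0)
})

test_that("the interval contains ~beta of future draws (MC oracle)", {
  # independent Monte-Carlo harness: p x n grids from a hierarchical normal
  # model (series effect + replicate error), future singles from the same
  # model with their own series effect
  set.seed(123)
  p <- 3; n <- 3; n_data <- 3000; n_fut <- 60
  sw <- 1; sb <- 0.8
  hits <- numeric(n_data)
  for (i in seq_len(n_data)) {
    g <- matrix(rnorm(p * n, 100, sw), p, n) + rnorm(p, 0, sb)
    vc <- variance_components(g)
    R <- if (vc$sigma2_within > 0) vc$sigma2_between / vc$sigma2_within else 0
    sR <- 100 * sqrt(vc$sigma2_within + vc$sigma2_between) / mean(g)
    bias <- 100 * (mean(g) - 100) / 100
    iv <- beta_eti(bias, sR, R, p, n, beta = 0.95)
    fut <- rnorm(n_fut, 0, sb) + rnorm(n_fut, 0, sw)
    hits[i] <- mean(fut >= iv[1] & fut <= iv[2])
  }
  se <- sd(hits) / sqrt(n_data)
  expect_lt(abs(mean(hits) - 0.95), 3 * se + 0.01)

  # with a truly zero between-series variance the moment clamp makes the
  # interval mildly conservative: coverage a little above nominal
  hits0 <- numeric(1500)
  for (i in seq_len(1500)) {
    g <- matrix(rnorm(p * n, 100, sw), p, n)
    vc <- variance_components(g)
    R <- if (vc$sigma2_within > 0) vc$sigma2_between / vc$sigma2_within else 0
    sR <- 100 * sqrt(vc$sigma2_within + vc$sigma2_between) / mean(g)
    iv <- beta_eti(100 * (mean(g) - 100) / 100, sR, R, p, n, beta = 0.95)
    fut <- rnorm(n_fut, 0, sw)
    hits0[i] <- mean(fut >= iv[1] & fut <= iv[2])
  }
  expect_gt(mean(hits0), 0.94)
  expect_lt(mean(hits0), 0.99)
})

test_that("interval properties: dof limits and monotone width", {
  cmp_inf <- attr(beta_eti(0, 1, 1e9, 3, 3), "dof")
  expect_equal(cmp_inf, 2, tolerance = 1e-3)     # nu -> p - 1 as R -> Inf
  expect_gt(attr(beta_eti(0, 1, 0, 3, 3), "dof"), 0)
  widths <- vapply(c(1, 2, 4, 8), function(s)
    diff(unname(beta_eti(1, s, 0.5, 3, 3))), numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("level statistics on the toy grid reproduce the hand computation", {
  # grid values are back-calculated concentrations at nominal 10:
  # feed them through an identity calibration (slope 1)
  tab <- as.data.frame(noiseless_table(slope = 1, conc = c(10, 600)))
  grid <- toy_grid()
  for (j in 1:3)
    tab$response[tab$role == "validation" & tab$series_id == j &
                 tab$level_index == 1] <- grid[j, ]
  tab <- measurement_table(tab)
  fits <- fit_all_series(tab)
  ls <- level_stats(tab, fits, 1)
  expect_equal(ls$relative_bias_pct, 10)
  expect_equal(ls$mean_backcalc, 11)
  expect_equal(ls$sigma2_within, 1)
  expect_equal(ls$sigma2_between, 2 / 3)
  expect_equal(ls$rsd_intermediate_pct, 100 * sqrt(5 / 3) / 11, tolerance = 1e-12)
  expect_equal(ls$rsd_repeatability_pct, 100 / 11, tolerance = 1e-12)
  expect_gte(ls$rsd_intermediate_pct, ls$rsd_repeatability_pct)
})

test_that("noiseless data give degenerate profiles at the true bias", {
  prof0 <- accuracy_profile(noiseless_table())
  expect_true(all(abs(prof0$levels$relative_bias_pct) < 1e-9))
  expect_true(all(prof0$levels$rsd_intermediate_pct < 1e-9))

  prof10 <- accuracy_profile(noiseless_table(bias_pct = 10))
  expect_equal(prof10$levels$relative_bias_pct, rep(10, 5), tolerance = 1e-9)
  expect_equal(prof10$levels$beta_eti_low_pct, rep(10, 5), tolerance = 1e-9)
  expect_equal(prof10$levels$beta_eti_high_pct, rep(10, 5), tolerance = 1e-9)
  expect_true(prof10$valid)
})

test_that("unbalanced validation designs are rejected by the profile stage", {
  tab <- noiseless_table()
  drop <- !(tab$role == "validation" & tab$series_id == 2 &
            tab$level_index == 4 & tab$replicate_index == 3)
  tab2 <- measurement_table(as.data.frame(tab)[drop, ],
                            design = attr(tab, "design"))
  expect_error(accuracy_profile(tab2), "not balanced")
})

test_that("LLOQ/ULOQ decision logic passes, interpolates and degrades", {
  mk_stats <- function(lows, highs, conc = c(10, 50, 100, 300, 600)) {
    data.frame(level_index = seq_along(conc), nominal_concentration = conc,
               mean_backcalc = conc, relative_bias_pct = (lows + highs) / 2,
               sigma2_within = 1, sigma2_between = 0,
               rsd_repeatability_pct = 1, rsd_intermediate_pct = 1,
               variance_ratio = 0, B_factor = 1, dof = 6, t_quantile = 2,
               beta_eti_low_pct = lows, beta_eti_high_pct = highs)
  }
  # all levels inside +/-15: limits at the design extremes
  p1 <- build_profile(mk_stats(rep(-10, 5), rep(10, 5)), lambda = 15)
  expect_true(p1$valid)
  expect_equal(p1$lloq, 10)
  expect_equal(p1$uloq, 600)

  # lowest level fails with +20, next passes with +10: LLOQ interpolated
  p2 <- build_profile(mk_stats(rep(-10, 5), c(20, 10, 10, 10, 10)), lambda = 15)
  expect_false(p2$valid)
  expect_gt(p2$lloq, 10); expect_lt(p2$lloq, 50)
  expect_equal(p2$lloq, 10 + (15 - 20) * 40 / (10 - 20))  # = 30
  expect_equal(p2$uloq, 600)

  # all levels fail
  p3 <- build_profile(mk_stats(rep(-40, 5), rep(40, 5)), lambda = 15)
  expect_false(p3$valid)
  expect_true(is.na(p3$lloq) && is.na(p3$uloq))

  # top level fails: ULOQ interpolated from above
  p4 <- build_profile(mk_stats(rep(-10, 5), c(10, 10, 10, 10, 25)), lambda = 15)
  expect_equal(p4$lloq, 10)
  expect_gt(p4$uloq, 300); expect_lt(p4$uloq, 600)
})

test_that("LOD follows the LLOQ/3.3 convention", {
  expect_equal(lod_from_lloq(10), 10 / 3.3)
  expect_equal(lod_from_lloq(3.3), 1)
  expect_error(lod_from_lloq(0))
  expect_error(lod_from_lloq(NA_real_))
})

test_that("linearity profile recovers the identity and a pure bias", {
  conc <- rep(c(10, 50, 100, 300, 600), each = 9)
  lin <- linearity_profile(conc, conc)
  expect_equal(lin$slope, 1, tolerance = 1e-12)
  expect_equal(lin$intercept, 0, tolerance = 1e-9)
  expect_equal(lin$r_squared, 1)
  lin10 <- linearity_profile(conc, 1.10 * conc)
  expect_equal(lin10$slope, 1.10, tolerance = 1e-12)
  expect_equal(lin10$intercept, 0, tolerance = 1e-9)
  # on an accuracy profile the bands are the ETIs on the concentration scale;
  # a bias-free truth at the reference CVs keeps the slope near 1
  truth <- default_truth_spec()
  truth$bias_pct <- rep(0, 5)
  prof <- accuracy_profile(simulate_validation_dataset(truth, seed = 7))
  lp <- linearity_profile(prof)
  expect_equal(lp$bands$low,
               prof$levels$nominal_concentration *
                 (1 + prof$levels$beta_eti_low_pct / 100))
  expect_gt(lp$slope, 0.95); expect_lt(lp$slope, 1.05)
})

test_that("response-function selection ranks candidates and flags ties", {
  sel <- select_response_function(noiseless_table())
  expect_true(all(sel$ranking$all_pass))
  expect_identical(sel$chosen, "ols_linear")  # preferred on exact ties
  expect_true(sel$tie)

  # sqrt candidate unavailable on data with a negative response
  tab <- as.data.frame(noiseless_table())
  tab$response[1] <- -5
  tab <- measurement_table(tab)
  sel2 <- select_response_function(tab)
  rk <- sel2$ranking
  expect_false(rk$available[rk$model == "sqrt_linear"])
  expect_true(all(rk$available[rk$model != "sqrt_linear"]))
})
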