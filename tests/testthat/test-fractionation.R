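test_that("isoeffect pairing reproduces the closed-form alpha/beta", {
  # the two published ED50 schedules
  expect_equal(alpha_beta_from_pair(14.55, 14.55, 27.7, 5.54),
               (27.7 * 5.54 - 14.55 * 14.55) / (14.55 - 27.7))
  expect_equal(alpha_beta_from_pair(14.55, 14.55, 27.7, 5.54), 4.429,
               tolerance = 1e-4)
  # schedules constructed isoeffective at a known ratio are inverted exactly
  for (ab in c(1, 3, 4.49, 10)) {
    for (n2 in c(3, 5, 10)) {
      D1 <- 10
      iso <- isoeffect_curve(ab, schedule(1, D1), n2)
      expect_equal(alpha_beta_from_pair(D1, D1, iso$D_gy, iso$d_gy), ab,
                   tolerance = 1e-9)
    }
  }
  expect_error(alpha_beta_from_pair(10, 10, 10, 2), "degenerate")
  expect_warning(ab_same_d <- alpha_beta_from_pair(10, 2, 20, 2),
                 "outside the isoeffect model")
  expect_equal(ab_same_d, -2)
})

test_that("the alpha/beta profile matches the published per-level estimates", {
  prof <- alpha_beta_profile(fit_1fx(), fit_5fx(), n_fractions = 5,
                             fi_grid = c(3.6, 0.75 * 7.2, 0.9 * 7.2))
  # at FI = A/2 the isoeffect doses are the two ED50s exactly
  expect_equal(prof$D1_gy[1], 14.55)
  expect_equal(prof$D2_gy[1], 27.7)
  expect_equal(prof$alpha_beta_gy, c(4.429, 4.315, 4.253), tolerance = 1e-3)
  expect_error(alpha_beta_profile(fit_1fx(), fit_5fx(), 5, fi_grid = c(0, 3)),
               "strictly inside")
})

test_that("the profile declines monotonically with fibrosis severity", {
  prof <- alpha_beta_profile(fit_1fx(), fit_5fx(), 5,
                             fi_grid = seq(0.5, 7.0, by = 0.05))
  expect_true(all(diff(prof$alpha_beta_gy) < 0))
  expect_equal(attr(prof, "mean_alpha_beta"), mean(prof$alpha_beta_gy))
})

test_that("the Fe plot is exact on LQ-isoeffective schedules", {
  # two-point line equals the pairwise formula
  fe2 <- fe_plot(c(14.55, 5.54), c(14.55, 27.7))
  expect_equal(fe2$alpha_beta, alpha_beta_from_pair(14.55, 14.55, 27.7, 5.54),
               tolerance = 1e-9)
  # 1/D is exactly linear in d under the BED equality: exact recovery and
  # zero residuals on collinear points
  iso <- isoeffect_curve(10, schedule(1, 12), c(1, 2, 5, 10))
  fe <- fe_plot(iso$d_gy, iso$D_gy)
  expect_equal(fe$alpha_beta, 10, tolerance = 1e-9)
  expect_lt(sum(stats::residuals(fe$lm)^2), 1e-18)
  expect_error(fe_plot(c(2, 2, 2), c(10, 20, 30)), "rank-deficient")
})

test_that("LQ fits on exact transformed data recover alpha and beta", {
  # the two-arm schedule set of the study design
  D1 <- c(10.5, 12.5, 14.5, 17.5, 20)
  D5 <- 5 * c(2, 4, 6, 7, 8.5)
  D <- c(D1, D5)
  d <- c(D1, D5 / 5)
  # intercept chosen so every synthetic FI clears the 0.05 transform floor
  for (pars in list(c(0.0480, 0.0107), c(0.0150, 0.0038))) {
    y <- 0.5 - (pars[1] * D + pars[2] * d * D)
    fit <- fit_lq(D, d, fis = 10^(-y))
    expect_equal(fit$alpha, pars[1], tolerance = 1e-9)
    expect_equal(fit$beta, pars[2], tolerance = 1e-9)
    expect_equal(fit$intercept, 0.5, tolerance = 1e-9)
  }
  # published LQ parameter ratios
  expect_equal(0.0150 / 0.0038, 3.9474, tolerance = 1e-4)
  expect_equal(0.0480 / 0.0107, 4.4879, tolerance = 1e-3)
  expect_error(fit_lq(c(10, 20, 30), c(2, 2, 2), c(1, 2, 3)), "collinear")
  expect_error(fit_lq(30, 6, 2), "3 distinct")
})

test_that("the LQ ratio is invariant to the log base", {
  set.seed(9)
  co <- simulate_cohort(study_design(), truth_models(), noise_spec(seed = 9))
  irr <- co[co$total_dose_gy > 0, ]
  f10 <- fit_lq(irr$total_dose_gy, irr$dose_per_fraction_gy, irr$fi)
  fln <- fit_lq(irr$total_dose_gy, irr$dose_per_fraction_gy, irr$fi,
                transform = function(fi) -log(fi))
  expect_equal(fln$alpha, f10$alpha * log(10), tolerance = 1e-9)
  expect_equal(fln$alpha_beta, f10$alpha_beta, tolerance = 1e-9)
})

test_that("isoeffect curves keep the reference BED and show dose sparing", {
  ref <- schedule(1, 14.55)
  curve <- isoeffect_curve(4.49, ref, 1:10)
  expect_equal(curve$d_gy[1], 14.55, tolerance = 1e-9) # n = ref n: unchanged
  expect_equal(curve$d_gy[curve$n == 5], 5.5297, tolerance = 1e-3)
  # every row shares the reference BED (cross-check via bed())
  beds <- bed(curve$D_gy, curve$d_gy, 4.49)
  expect_equal(beds, rep(bed(14.55, 14.55, 4.49), 10), tolerance = 1e-9)
  # LQ sparing: dose per fraction falls, total dose rises with n
  expect_true(all(diff(curve$d_gy) < 0))
  expect_true(all(diff(curve$D_gy) > 0))
})

test_that("exponential decay fits recover known curves", {
  x <- 0:20
  fit <- fit_exp_decay(x, 2 * exp(-x / 5) + 1)
  expect_equal(fit$a, 2, tolerance = 1e-6)
  expect_equal(fit$b, 5, tolerance = 1e-6)
  expect_equal(fit$c, 1, tolerance = 1e-6)

  flat <- fit_exp_decay(x, rep(3, 21))
  expect_equal(flat$a, 0)
  expect_equal(flat$c, 3)

  set.seed(4)
  y <- 2 * exp(-x / 5) + 1 + stats::rnorm(21, 0, 0.05)
  noisy <- fit_exp_decay(x, y)
  ses <- summary(noisy$nls)$coefficients[, "Std. Error"]
  expect_lt(abs(noisy$a - 2), 3 * ses["a"])
  expect_lt(abs(noisy$b - 5), 3 * ses["b"])
  expect_lt(abs(noisy$c - 1), 3 * ses["c"])
})

test_that("schedules enforce the total-dose bookkeeping", {
  s <- schedule(5, 6)
  expect_equal(s$D, 30)
  expect_error(schedule(5, 6, 29), "inconsistent")
})
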