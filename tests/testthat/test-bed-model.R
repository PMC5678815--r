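test_that("bed follows the linear-quadratic equivalent-dose formula", {
  expect_equal(bed(20, 2, 10), 24)
  expect_equal(bed(14.55, 14.55, 4.49), 61.70, tolerance = 1e-4)
  expect_equal(bed(10, 1e-9, 3), 10, tolerance = 1e-9) # d -> 0 limit
  # linear in D at fixed d; strictly increasing in d at fixed D
  D <- seq(10, 60, by = 10)
  expect_equal(bed(2 * D, 2, 5), 2 * bed(D, 2, 5))
  d <- seq(0.5, 10, by = 0.5)
  expect_true(all(diff(bed(rep(30, length(d)), d, 5)) > 0))
  expect_true(all(bed(D, 2, 5) >= D))
  expect_error(bed(20, 2, -1), "positive")
  expect_error(bed(10, 20, 3), "exceed")
})

test_that("the BED logistic recovers exact generating parameters", {
  beds <- seq(5, 120, by = 5)
  fis <- predict_bed_fi(bed_logistic(0, 7.2, 60, 3), beds)
  fit <- fit_bed_logistic(beds, fis)
  expect_equal(fit$A1, 0, tolerance = 1e-6)
  expect_equal(fit$A2, 7.2, tolerance = 1e-6)
  expect_equal(fit$k, 60, tolerance = 1e-6)
  expect_equal(fit$p, 3, tolerance = 1e-6)
  # midpoint identity: FI at BED = k is (A1 + A2) / 2
  expect_equal(predict_bed_fi(fit, fit$k), 3.6, tolerance = 1e-6)
  # fixing the asymptotes leaves the shape parameters intact
  fixed <- fit_bed_logistic(beds, fis, fix_a1 = 0, fix_a2 = 7.2)
  expect_equal(fixed$k, 60, tolerance = 1e-6)
  expect_equal(fixed$p, 3, tolerance = 1e-6)
  expect_error(fit_bed_logistic(c(1, 2, 3, 4), c(1, 2, 3, 4)), "at least 5")
  expect_error(fit_bed_logistic(beds, rep(1, length(beds))), "constant")
})

test_that("maximum-slope landmark matches its closed form across shapes", {
  for (p in c(1.2, 2, 3, 4.5, 6)) {
    for (k in c(30, 60, 90)) {
      fit <- bed_logistic(0, 7.2, k, p)
      lm <- extract_landmarks(fit)
      closed <- k * ((p - 1) / (p + 1))^(1 / p)
      expect_equal(lm$bed_cutoff, closed, tolerance = 1e-9)
      # numeric argmax of the finite-difference slope agrees
      grid <- seq(k / 2000, 2 * k, length.out = 4000)
      slope <- diff(predict_bed_fi(fit, grid)) / diff(grid)
      num <- grid[which.max(slope)]
      expect_equal(num, closed, tolerance = 2e-3)
    }
  }
})

test_that("landmarks are ordered and the curvature point is a local maximum", {
  shapes <- list(c(0, 7.2, 60, 3), c(0, 7.2, 60, 2), c(0, 5, 40, 4),
                 c(0, 7.2, 90, 5))
  for (s in shapes) {
    fit <- bed_logistic(s[1], s[2], s[3], s[4])
    lm <- extract_landmarks(fit)
    expect_lt(lm$bed_tr, lm$bed_cutoff)
    expect_lt(lm$bed_cutoff, lm$bed_ed50)
    expect_equal(lm$bed_ed50, s[3]) # A1 = 0: half-maximum at k
    # numeric curvature oracle: second differences of the fitted curve
    h <- 1e-3
    curv_num <- function(B) {
      f0 <- predict_bed_fi(fit, B); f1 <- predict_bed_fi(fit, B + h)
      fm <- predict_bed_fi(fit, B - h)
      d1 <- (f1 - fm) / (2 * h); d2 <- (f1 - 2 * f0 + fm) / h^2
      d2 / (1 + d1^2)^(3 / 2)
    }
    expect_gt(curv_num(lm$bed_tr), curv_num(lm$bed_tr * 0.95))
    expect_gt(curv_num(lm$bed_tr), curv_num(lm$bed_tr * 1.05))
  }
})

test_that("curvature landmarks rescale with the BED axis and k", {
  base <- extract_landmarks(bed_logistic(0, 7.2, 50, 3))
  scaled <- extract_landmarks(bed_logistic(0, 7.2, 100, 3,
                                           bed_range = c(0, 200)))
  expect_equal(scaled$bed_cutoff, 2 * base$bed_cutoff, tolerance = 1e-9)
  expect_equal(scaled$bed_ed50, 2 * base$bed_ed50, tolerance = 1e-9)
  # raw-axis geometric curvature is not scale-free, but the landmark must
  # stay inside the toe and track the axis scale to first order
  expect_gt(scaled$bed_tr, base$bed_tr)
})

test_that("axis normalization is an explicit, distinct convention", {
  fit <- bed_logistic(0, 7.2, 60, 3)
  raw <- extract_landmarks(fit, normalize_axes = FALSE)
  norm <- extract_landmarks(fit, normalize_axes = TRUE)
  expect_false(isTRUE(all.equal(raw$bed_tr, norm$bed_tr)))
  expect_equal(raw$bed_cutoff, norm$bed_cutoff) # closed form is invariant
  expect_lt(norm$bed_tr, norm$bed_cutoff)
})

test_that("shallow curves without an interior slope maximum are flagged", {
  fit <- bed_logistic(0, 7.2, 60, 0.8)
  expect_warning(lm <- extract_landmarks(fit), "no interior maximum")
  expect_true(is.na(lm$bed_cutoff))
  expect_true(is.na(lm$bed_tr))
  expect_equal(lm$bed_ed50, 60)
})

test_that("synthetic two-arm cohorts mapped through BED recover the implied midpoint", {
  co <- simulate_cohort(study_design(), truth_models(), noise_spec(seed = 21))
  irr <- co[co$total_dose_gy > 0, ]
  ab <- 4.49
  beds <- bed(irr$total_dose_gy, irr$dose_per_fraction_gy, ab)
  sham <- co$fi[co$total_dose_gy == 0]
  fit <- fit_bed_logistic(c(rep(0, length(sham)), beds), c(sham, irr$fi),
                          fix_a1 = 0, fix_a2 = 7.2)
  # the generating ED50s imply BED_ED50 = ED50_1fx (1 + ED50_1fx / (a/b))
  implied <- bed(14.55, 14.55, ab)
  expect_lt(abs(fit$bed_ed50 - implied) / implied, 0.05)
  expect_lt(fit$bed_tr, fit$bed_cutoff)
  expect_lt(fit$bed_cutoff, fit$bed_ed50)
})
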