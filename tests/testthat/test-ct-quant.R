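test_that("region growing plus metrics reproduce phantom truth exactly", {
  for (spec in phantom_suite()) {
    ph <- simulate_phantom(spec)
    mask <- segment_lung(ph$volume, seed_point = ph$truth$seed_point)
    expect_identical(mask$mask, ph$truth$lung_mask)
    m <- lung_metrics(ph$volume, mask)
    expect_identical(m$voxel_count, ph$truth$lung_voxel_count)
    expect_equal(m$volume_mm3, ph$truth$volume_mm3)
    expect_equal(m$mean_hu, ph$truth$mean_hu)
  }
})

test_that("segmentation stops at the seed's connected component", {
  # two disjoint lung-window blocks; the seed selects exactly one
  hu <- array(0, c(20, 20, 20))
  hu[3:6, 3:6, 3:6] <- -500
  hu[14:17, 14:17, 14:17] <- -500
  vol <- voxel_volume(hu, c(0.5, 0.5, 0.5))
  mask <- segment_lung(vol, seed_point = c(4, 4, 4))
  expect_equal(sum(mask$mask), 64L)
  expect_true(all(which(mask$mask) %in% which(hu == -500)))
  # independent dilation-labelling oracle agrees voxel for voxel
  oracle <- grow_oracle(hu >= -900 & hu <= -100, c(4L, 4L, 4L))
  expect_identical(mask$mask, oracle)
  # and a randomized admissible set agrees too
  set.seed(42)
  adm <- array(stats::runif(8000) < 0.4, c(20, 20, 20))
  adm[10, 10, 10] <- TRUE
  hu2 <- array(0, c(20, 20, 20)); hu2[adm] <- -500
  m2 <- segment_lung(voxel_volume(hu2, c(1, 1, 1)),
                     seed_point = c(10, 10, 10))
  expect_identical(m2$mask, grow_oracle(adm, c(10L, 10L, 10L)))
})

test_that("exclusion masks subtract voxels and seed/window errors are raised", {
  spec <- phantom_spec(shape = c(24L, 24L, 24L), lung_voxel_count = 500L)
  ph <- simulate_phantom(spec)
  excl <- array(FALSE, dim(ph$volume$hu))
  excl[which(ph$truth$lung_mask)[1:10]] <- TRUE
  mask <- segment_lung(ph$volume, seed_point = ph$truth$seed_point,
                       exclusion_mask = excl)
  expect_equal(sum(mask$mask), 490L)

  expect_error(segment_lung(ph$volume, seed_point = c(1, 1, 1)),
               "outside window")
  expect_error(segment_lung(ph$volume, lower_hu = -100, upper_hu = -900,
                            seed_point = ph$truth$seed_point), "below")
  all_excl <- array(TRUE, dim(ph$volume$hu))
  expect_error(segment_lung(ph$volume, seed_point = ph$truth$seed_point,
                            exclusion_mask = all_excl), "empty segmentation")
})

test_that("metrics use voxel count times voxel volume, also anisotropically", {
  hu <- array(0, c(10, 10, 10))
  hu[1:4, 1:5, 1:5] <- -500
  vol <- voxel_volume(hu, c(0.5, 0.5, 0.6))
  m <- lung_metrics(vol, hu == -500)
  expect_equal(m$voxel_count, 100L)
  expect_equal(m$volume_mm3, 100 * 0.15) # 15 mm3 by hand
  expect_equal(m$mean_hu, -500)
  # mixed-density region averages arithmetically
  hu[1:4, 1:5, 1:5] <- rep(c(-600, -200), each = 50)
  expect_equal(lung_metrics(voxel_volume(hu, c(0.5, 0.5, 0.6)),
                            hu < -100)$mean_hu, -400)
  expect_error(lung_metrics(vol, array(FALSE, c(10, 10, 10))), "empty")
})

test_that("ppsh finds the dominant mode of masked HU", {
  dims <- c(50, 50, 40)
  mask <- array(TRUE, dims)
  set.seed(1)
  gauss <- array(stats::rnorm(prod(dims), -450, 50), dims)
  p <- ppsh(voxel_volume(gauss, c(1, 1, 1)), mask)
  expect_lte(abs(p$peak_hu - -450), 10)

  set.seed(2)
  n <- prod(dims)
  mix <- array(c(stats::rnorm(0.8 * n, -600, 30),
                 stats::rnorm(0.2 * n, -150, 30)), dims)
  p2 <- ppsh(voxel_volume(mix, c(1, 1, 1)), mask)
  expect_lte(abs(p2$peak_hu - -600), 10)

  const <- array(-500, c(5, 5, 5))
  expect_warning(
    p3 <- ppsh(voxel_volume(const, c(1, 1, 1)), array(TRUE, c(5, 5, 5))),
    "equal"
  )
  expect_equal(p3$peak_hu, -500)
  expect_true(p3$degenerate)
})

test_that("ppsh peak does not move when every bin gains the same count", {
  set.seed(3)
  base <- stats::rnorm(5000, -500, 40)
  lo <- floor(min(base) / 10) * 10
  hi <- ceiling(max(base) / 10) * 10
  flat <- rep(seq(lo + 5, hi - 5, by = 10), times = 20) # 20 counts per bin
  as_vol <- function(v) {
    k <- ceiling(length(v)^(1 / 3)) + 1
    pad <- array(-10000, c(k, k, k)) # padding excluded by the mask
    pad[seq_along(v)] <- v
    list(vol = voxel_volume(pad, c(1, 1, 1)),
         mask = array(seq_len(k^3) <= length(v), c(k, k, k)))
  }
  a <- as_vol(base)
  b <- as_vol(c(base, flat))
  expect_equal(ppsh(a$vol, a$mask)$peak_hu, ppsh(b$vol, b$mask)$peak_hu)
})

test_that("fibrosis index follows the geometric-mean and clamp rules", {
  direct <- function(dhu, dv) {
    fibrosis_index(list(delta_hu = dhu, delta_v = dv), convention = "direct")
  }
  expect_equal(direct(4, 9)$fi, 6)
  expect_equal(direct(0, 5)$fi, 0)
  neg <- direct(2, -0.3) # denser but larger than reference
  expect_equal(neg$fi, 0)
  expect_true(neg$non_fibrotic)
  # degree-1 homogeneity: doubling both deltas doubles FI
  for (dhu in c(0.2, 1, 4)) {
    for (dv in c(0.1, 0.5, 2)) {
      expect_equal(direct(2 * dhu, 2 * dv)$fi, 2 * direct(dhu, dv)$fi)
    }
  }
})

test_that("relative-convention FI matches hand arithmetic and validates refs", {
  treated <- list(volume_mm3 = 300, mean_hu = -440)
  ref <- list(mean_volume_mm3 = 400, mean_hu = -550)
  sc <- fibrosis_index(treated, ref)
  expect_equal(sc$delta_hu, (-440 + 550) / 550)
  expect_equal(sc$delta_v, (400 - 300) / 400)
  expect_equal(sc$fi, sqrt(sc$delta_hu * sc$delta_v))
  # the scale constant multiplies both deltas, hence FI itself
  sc2 <- fibrosis_index(treated, ref, scale = 3)
  expect_equal(sc2$fi, 3 * sc$fi)
  expect_error(fibrosis_index(treated, list(mean_volume_mm3 = 0,
                                            mean_hu = -550)), "positive")
  expect_error(fibrosis_index(treated, list(mean_volume_mm3 = 400,
                                            mean_hu = 0)), "nonzero")
})

test_that("volumes round-trip through NIfTI with spacing preserved", {
  spec <- phantom_spec(shape = c(16L, 16L, 16L), spacing_mm = c(0.5, 0.5, 0.6),
                       lung_voxel_count = 200L)
  ph <- simulate_phantom(spec)
  path <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(path))
  write_volume(ph$volume, path)
  back <- read_volume(path)
  expect_equal(back$hu, ph$volume$hu)
  expect_equal(back$spacing_mm, c(0.5, 0.5, 0.6), tolerance = 1e-6)
})
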