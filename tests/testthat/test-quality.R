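# Quality metrics and screening studies: PSNR/RMS against brute-force
# oracles, normalisation, saturation fractions, histogram peaks,
# segmentation.

test_that("PSNR matches a brute-force evaluation of its defining expression", {
  expect_equal(psnr(matrix(c(2, 0, 0, 0), 2), matrix(0, 2, 2)), 0)
  expect_identical(psnr(matrix(1:4, 2), matrix(1:4, 2)), Inf)
  set.seed(31)
  for (i in 1:10) {
    t_img <- matrix(runif(64), 8)
    n_img <- matrix(runif(64), 8)
    # independent direct expression: peak squared over summed squared error
    direct <- 10 * log10(max(t_img)^2 /
                           sum((as.vector(t_img) - as.vector(n_img))^2))
    expect_equal(psnr(t_img, n_img), direct, tolerance = 1e-12)
    # conventional MSE variant differs by exactly 10 log10(N)
    expect_equal(psnr(t_img, n_img, normalise = "mse"),
                 direct + 10 * log10(64), tolerance = 1e-12)
  }
  expect_error(psnr(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("RMS contrast matches hand arithmetic and the brute-force sum", {
  expect_identical(rms_contrast(c(5, 5, 5, 5)), 0)
  expect_equal(rms_contrast(c(0, 1)), sqrt(0.5))
  expect_equal(rms_contrast(matrix(c(0, 1, 1, 0), 2)), sqrt(4 * 0.25 / 3))
  set.seed(32)
  for (i in 1:10) {
    p <- matrix(runif(64), 8)
    direct <- sqrt(sum((p - mean(p))^2) / (length(p) - 1))
    expect_equal(rms_contrast(p), direct, tolerance = 1e-12)
  }
  expect_error(rms_contrast(3), "2 pixels")
})

test_that("slice normalisation is affine invariant on [0, 1]", {
  expect_equal(normalize_slice(c(0, 5, 10)), c(0, 0.5, 1))
  x <- matrix(runif(64), 8)
  xn <- normalize_slice(x)
  expect_equal(range(xn), c(0, 1))
  expect_equal(normalize_slice(3 * x - 2), xn)
  expect_equal(normalize_slice(xn), xn)
  expect_error(normalize_slice(matrix(1, 4, 4)), "constant")
})

test_that("saturation fraction spans the curve's dynamic range", {
  curve <- quality_curve("n_projections", c(125, 500, 2000, 6000, 24000),
                         psnr_db = c(10, 18, 24, 27, 28))
  expect_equal(saturation_fraction(curve, 24000), 1)
  expect_equal(saturation_fraction(curve, 125), 0)
  expect_equal(saturation_fraction(curve, 6000), (27 - 10) / 18)
  fr <- vapply(c(125, 500, 2000, 6000, 24000),
               function(v) saturation_fraction(curve, v), numeric(1))
  expect_true(all(diff(fr) > 0))
  expect_error(saturation_fraction(curve, 777), "not on the curve")
})

test_that("histogram peak finder resolves a known bimodal mixture", {
  set.seed(33)
  v <- c(rnorm(20000, 0.3, 0.05), rnorm(20000, 0.7, 0.05))
  pk <- histogram_peaks(matrix(v, 200), n_bins = 256)
  expect_false(pk$unimodal)
  expect_lt(abs(pk$background_peak - 0.3), 0.02)
  expect_lt(abs(pk$sample_peak - 0.7), 0.02)
  expect_true(pk$cutoff > 0.3 && pk$cutoff < 0.7)
  # near-uniform data is flagged unimodal with no guessed cutoff
  u <- histogram_peaks(matrix(runif(10000), 100), n_bins = 64)
  expect_true(u$unimodal)
  expect_true(is.na(u$cutoff))
  expect_error(histogram_peaks(matrix(1:4 / 4, 2), n_bins = 8), "16")
})

test_that("phase retrieval separates sample and background histogram modes", {
  sc <- small_cord_scan()
  raw <- reconstruct_scan(sc$pset)
  ret <- reconstruct_scan(sc$pset, retrieval_params(100, pd_mm = 40))
  pk_raw <- histogram_peaks(raw$slice, n_bins = 128)
  pk_ret <- histogram_peaks(ret$slice, n_bins = 128)
  expect_false(pk_ret$unimodal)
  # retrieval increases the mode separation quality
  score <- function(pk) if (pk$unimodal) 0 else pk$prominence_ratio
  expect_gt(score(pk_ret), score(pk_raw))
})

test_that("downsampling study returns aligned, sane curves", {
  sc <- small_cord_scan()
  r <- roi(39, 89, 39, 89)
  curve <- downsampling_study(sc$pset, c(120, 60, 30), study_roi = r,
                              params = retrieval_params(100, pd_mm = 40))
  expect_identical(nrow(curve), 3L)
  expect_identical(curve$n_projections, c(120, 60, 30))
  expect_true(all(is.finite(curve$psnr_db)))
  # PSNR improves with subset size (small dips allowed)
  expect_true(all(diff(rev(curve$psnr_db)) > -0.2))
  expect_error(downsampling_study(sc$pset, c(30, 120), study_roi = r),
               "descending")
})

test_that("delta/beta sweep accepts the published ratio grid", {
  sc <- small_cord_scan()
  r <- roi(39, 89, 39, 89)
  ratios <- c(0, 1, 3, 10, 30, 100, 300, 1000, 3000)
  curve <- sweep_delta_beta(sc$pset, ratios, study_roi = r, n_subset = 60)
  expect_identical(curve$delta_beta, ratios)
  expect_true(all(is.finite(curve$rms_contrast)))
  # ratio 0 equals the unretrieved reconstruction exactly
  raw <- reconstruct_scan(sc$pset, n_subset = 60)
  expect_equal(curve$rms_contrast[1],
               rms_contrast(crop_roi(normalize_slice(raw$slice), r)))
})

test_that("threshold segmentation obeys its cutoff contract", {
  sl <- matrix(runif(64 * 64, 100, 200), 64)
  mask <- matrix(TRUE, 64, 64)
  empty <- threshold_segment(sl, mask, 99, "darker")
  expect_equal(empty$area_um2, 0)
  expect_equal(sum(empty$binary_map), 0)
  all_in <- threshold_segment(sl, mask, 201, "darker", voxel_um = 2)
  expect_equal(all_in$area_um2, 64 * 64 * 4)
  expect_error(threshold_segment(sl, mask & FALSE, 150, "darker"), "empty")
  # area of a single rasterised 10-px disc within 15 percent of pi r^2
  g <- centre_grids(64)
  disc <- sqrt(g$x^2 + g$y^2) <= 5
  seg <- threshold_segment(1 - disc, mask, 0.5, "darker", voxel_um = 1.625)
  expect_equal(seg$area_um2, pi * 25 * 1.625^2, tolerance = 0.15)
  # area conservation: total equals the sum over connected components
  expect_identical(sum(seg$binary_map), sum(disc))
})
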