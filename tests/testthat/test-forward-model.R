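# Forward model: Radon projection, Fresnel propagation, detector statistics
# and artefact injection.

test_that("line integrals match the analytic chord of a uniform disc", {
  n <- 128
  g <- centre_grids(n)
  R <- 40; cval <- 2e-7
  ph <- structure(list(delta = matrix(0, n, n),
                       beta = (sqrt(g$x^2 + g$y^2) < R) * cval,
                       voxel_um = 1.625), class = "phantom")
  pr <- project(ph, c(0, 30, 90, 145))
  central <- pr$B[, n / 2]  # ray through the rotation axis
  expect_equal(central, rep(2 * R * cval * 1.625e-6, 4), tolerance = 0.01)
  # rotational symmetry: a centred disc's sinogram row is angle-invariant
  expect_equal(pr$B[1, ], pr$B[3, ], tolerance = 0.01 * max(pr$B))
  # zero phantom, empty angles
  ph0 <- structure(list(delta = matrix(0, n, n), beta = matrix(0, n, n),
                        voxel_um = 1.625), class = "phantom")
  expect_true(all(project(ph0, c(0, 45))$B == 0))
  expect_error(project(ph, numeric(0)), "empty")
})

test_that("propagation at zero distance is exact Beer-Lambert", {
  lam <- beam_spec(25)$wavelength_m
  B <- runif(64) * 1e-9
  D <- runif(64) * 1e-7
  I <- transmit_and_propagate(D, B, pd_mm = 0)
  expect_equal(I, exp(-4 * pi * B / lam))
  # pure phase object: unity intensity at contact
  expect_equal(transmit_and_propagate(D, rep(0, 64), pd_mm = 0), rep(1, 64))
  expect_error(transmit_and_propagate(D, B, pd_mm = -1), ">= 0")
})

test_that("first Fresnel fringe offset scales like sqrt(lambda PD)", {
  # weak phase step at the line centre, sampled finely enough to resolve the
  # first diffraction maximum at every distance
  n <- 4096
  D <- c(rep(0, n / 2), rep(6e-12, n / 2))
  B <- rep(1e-12, n)
  offsets <- vapply(c(40, 160, 640), function(pd) {
    I <- transmit_and_propagate(D, B, pd_mm = pd, pixel_um = 0.25)
    win <- (n / 2 + 1):(n / 2 + 160)
    win[which.max(I[win])] - (n / 2 + 0.5)
  }, numeric(1))
  # quadrupling PD should double the offset, within discretisation slack
  expect_equal(offsets[2] / offsets[1], 2, tolerance = 0.15)
  expect_equal(offsets[3] / offsets[2], 2, tolerance = 0.15)
})

test_that("fringe contrast at an edge grows with propagation distance", {
  ph <- small_cord_scan()$phantom
  pr <- project(ph, 10)
  contrast <- vapply(c(20, 40, 80, 160, 320), function(pd) {
    I <- transmit_and_propagate(pr$D[1, ], pr$B[1, ], pd_mm = pd,
                                pixel_um = 1.625)
    diff(range(I)) / mean(I)
  }, numeric(1))
  expect_true(all(diff(contrast) > 0))
})

test_that("detector statistics respect the 85 percent flat saturation level", {
  fr <- apply_detector(matrix(1, 64, 64), seed = 1)
  expect_equal(mean(fr), 100 + 0.85 * 2^16, tolerance = 1e-3)
  expect_true(all(fr <= 2^16 - 1))
  # zero beam: darks
  dk <- apply_detector(matrix(0, 64, 64), seed = 2)
  expect_equal(mean(dk), 100, tolerance = 0.05)
  # doubling exposure doubles the counts above dark
  half <- apply_detector(matrix(1, 64, 64), exposure_fraction = 0.425, seed = 3)
  expect_equal(mean(fr) - 100, 2 * (mean(half) - 100), tolerance = 5e-3)
  expect_error(apply_detector(1, exposure_fraction = 0), "exposure")
})

test_that("zinger injection records its ground truth and exceeds the local median", {
  fr <- apply_detector(matrix(1, 64, 64), seed = 4)
  z0 <- inject_zingers(fr, rate_per_frame = 0)
  expect_identical(z0$frame, fr)
  z <- inject_zingers(fr, rate_per_frame = 20, seed = 7)
  expect_identical(max(z$zingers$id), 20L)
  expect_identical(inject_zingers(fr, 20, seed = 7)$frame, z$frame)
  med <- phasetomo:::cpp_medfilt2(z$frame, 3L)
  excess <- (z$frame - med)[cbind(z$zingers$row, z$zingers$col)]
  # streak interiors can be shielded by neighbouring streak pixels, but the
  # large majority must stand clear of the local median by the minimum
  # amplitude scale
  expect_gt(mean(excess > 1500), 0.9)
})

test_that("radial distortion is identity at zero coefficients and grows radially", {
  g <- centre_grids(128)
  img <- exp(-((g$x - 10)^2 + (g$y + 15)^2) / (2 * 20^2))
  mdl0 <- distortion_model(c(63.5, 63.5), 0, 0)
  expect_equal(apply_distortion(img, mdl0), img, tolerance = 1e-12)
  # displacement magnitude grows monotonically with radius
  r <- seq(5, 80, by = 5)
  disp <- r * (1 + 2e-6 * r^2) - r
  expect_true(all(diff(disp) > 0))
  # dot grid: each dot observed at p satisfies p (1 + k1 p^2) = r_true
  k1 <- 2e-6
  mdl <- distortion_model(c(63.5, 63.5), k1)
  dots <- matrix(0, 128, 128)
  pos <- as.matrix(expand.grid(r = c(20, 44, 68, 92, 116), c = c(20, 68, 116)))
  dots[pos] <- 1
  dots <- blur_for_test(dots)
  warped <- apply_distortion(dots, mdl)
  for (i in seq_len(nrow(pos))) {
    r_true <- sqrt(sum((pos[i, ] - 1 - 63.5)^2))
    cm <- dot_centroid(warped, pos[i, ])
    if (is.null(cm)) next  # dot pushed outside the frame
    r_obs <- sqrt(sum((cm - 63.5)^2))
    expect_lt(abs(r_obs * (1 + k1 * r_obs^2) - r_true), 0.2)
  }
})

test_that("photon count is conserved under distortion resampling", {
  set.seed(5)
  img <- matrix(runif(128 * 128, 0.5, 1), 128, 128)
  img <- blur_for_test(img)
  mdl <- distortion_model(c(63.5, 63.5), 5e-7)
  out <- apply_distortion(img, mdl)
  core <- 13:116
  expect_equal(mean(out[core, core]), mean(img[core, core]), tolerance = 5e-3)
})

test_that("ring seeds are fixed-pattern and reproducible", {
  prof <- rep(1, 256)
  expect_identical(bake_ring_seeds(prof, 0), prof)
  p1 <- bake_ring_seeds(prof, 0.05, 0.05, seed = 2)
  expect_identical(bake_ring_seeds(prof, 0.05, 0.05, seed = 2), p1)
  expect_true(any(p1 != 1) && all(abs(p1 - 1) <= 0.05))
})

test_that("simulated scans are deterministic with the expected frame count", {
  sc <- small_cord_scan()
  expect_identical(nrow(sc$pset$frames), length(sc$geometry$angles_deg))
  pset2 <- simulate_scan(sc$phantom, sc$geometry, seed = 3)
  expect_identical(sc$pset$frames, pset2$frames)
  expect_identical(sc$pset$flats, pset2$flats)
  # extra check projection adds one frame at exactly 180 degrees
  geom <- scan_geometry(beam_spec(25), detector_spec(128, 1, 1.625), 0, 60,
                        extra_check_projection = TRUE)
  ps <- simulate_scan(sc$phantom, geom, noise = FALSE, seed = 1)
  expect_identical(nrow(ps$frames), 61L)
  expect_identical(ps$angles_deg[61], 180)
})

test_that("absorption-only scan reproduces Beer-Lambert through the detector", {
  ph <- small_cord_scan()$phantom
  geom <- scan_geometry(beam_spec(25), detector_spec(128, 1, 1.625), 0, 30)
  pset <- simulate_scan(ph, geom, seed = 8)
  tr <- flat_dark_correct(pset$frames, colMeans(pset$flats),
                          colMeans(pset$darks))
  lam <- beam_spec(25)$wavelength_m
  expected <- exp(-4 * pi * project(ph, geom$angles_deg)$B / lam)
  expect_equal(as.vector(tr), as.vector(expected), tolerance = 0.02)
  # with absorption off and PD 0, frames match the flats up to noise
  ph0 <- make_cord_phantom(grid_px = 128, n_vessels = 0, n_somata = 0, seed = 1,
                           materials = material_table(25, overrides = list(
                             wax = c(3.1e-7, 0), tissue = c(3e-7, 0),
                             tissue_grey_li = c(3e-7, 0), air = c(0, 0))))
  ps0 <- simulate_scan(ph0, geom, seed = 9)
  tr0 <- flat_dark_correct(ps0$frames, colMeans(ps0$flats),
                           colMeans(ps0$darks))
  expect_equal(mean(tr0), 1, tolerance = 5e-3)
})
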