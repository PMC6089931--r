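# Correction chain: zinger removal, flat/dark algebra, distortion-centre
# estimation, undistortion round trips, and ring suppression.

test_that("zinger removal recovers injected streaks with few false positives", {
  flat <- apply_detector(matrix(1, 128, 128), seed = 21)
  clean <- remove_zingers(flat, threshold_sigma = 8)
  expect_lt(clean$n_replaced / length(flat), 1e-4)
  z <- inject_zingers(flat, rate_per_frame = 20, seed = 22)
  fixed <- remove_zingers(z$frame, threshold_sigma = 8)
  hit_ids <- unique(z$zingers$id[fixed$replaced[cbind(z$zingers$row,
                                                      z$zingers$col)]])
  expect_gte(length(hit_ids), 19)
  # idempotence: a second pass changes almost nothing
  again <- remove_zingers(fixed$frame, threshold_sigma = 8)
  expect_lt(again$n_replaced / length(flat), 1e-3)
  expect_error(remove_zingers(flat, neighbourhood_px = 4), "odd")
})

test_that("flat/dark correction is the exact normalising identity", {
  flat <- matrix(5e4, 8, 16) + matrix(seq_len(128), 8)
  dark <- matrix(100, 8, 16)
  expect_equal(flat_dark_correct(flat, flat, dark), matrix(1, 8, 16))
  expect_equal(flat_dark_correct(dark, flat, dark),
               matrix(1e-6, 8, 16))  # floored at eps
  mid <- dark + 0.3 * (flat - dark)
  expect_equal(flat_dark_correct(mid, flat, dark), matrix(0.3, 8, 16))
  expect_error(flat_dark_correct(flat, dark, flat), "pixel")
  # row-broadcast form used on sinograms
  fr <- rbind(mid[1, ], mid[1, ])
  expect_equal(flat_dark_correct(fr, flat[1, ], dark[1, ]),
               matrix(0.3, 2, 16))
})

test_that("distortion centre is recovered within 2 px from the 0/180 pair", {
  n <- 256
  truec <- c((n - 1) / 2 + 15, (n - 1) / 2 - 10)
  k1 <- 6.7e-7
  mdl <- distortion_model(truec, k1 = k1)
  ph <- make_cord_phantom(grid_px = n, n_vessels = 12, n_somata = 3, seed = 7)
  F <- normalize_slice(ph$beta)
  first <- apply_distortion(F, mdl)
  last <- apply_distortion(F[, n:1], mdl)
  est <- estimate_distortion_center(first, last, k1 = k1)
  expect_lt(max(abs(est$center_xy - truec)), 2)
  expect_error(estimate_distortion_center(matrix(1, 16, 16),
                                          matrix(1, 16, 16)),
               "featureless")
  # zero distortion: tie-break returns the frame centre
  est0 <- estimate_distortion_center(first, first[, n:1], k1 = 0)
  expect_equal(est0$center_xy, c((n - 1) / 2, (n - 1) / 2))
})

test_that("undistortion inverts the distortion to sub-percent accuracy", {
  n <- 128
  g <- centre_grids(n)
  smooth <- exp(-((g$x - 15)^2 + (g$y + 10)^2) / (2 * 25^2)) +
    0.4 * sin(g$x / 12) * cos(g$y / 15)
  mdl <- distortion_model(c(70, 55), k1 = 2e-6, k2 = 1e-11)
  rt <- undistort(apply_distortion(smooth, mdl), mdl)
  core <- 6:(n - 5)
  expect_lt(max(abs(rt[core, core] - smooth[core, core])) /
              diff(range(smooth)), 0.01)
  # identity model leaves the frame untouched
  expect_equal(undistort(smooth, distortion_model(c(63.5, 63.5), 0, 0)),
               smooth, tolerance = 1e-12)
  # dot-grid lattice restored within 0.2 px
  dots <- matrix(0, n, n)
  pos <- as.matrix(expand.grid(r = c(24, 64, 104), c = c(24, 64, 104)))
  dots[pos] <- 1
  dots <- blur_for_test(dots)
  restored <- undistort(apply_distortion(dots, mdl), mdl)
  for (i in seq_len(nrow(pos))) {
    cm0 <- dot_centroid(dots, pos[i, ])
    cm1 <- dot_centroid(restored, pos[i, ])
    expect_lt(sqrt(sum((cm1 - cm0)^2)), 0.2)
  }
})

test_that("ring suppression removes column bias but preserves structure", {
  # analytic ring-free transmission sinogram of an absorbing disc
  n <- 128; na <- 240
  u <- seq_len(n) - 1 - (n - 1) / 2
  chord <- ifelse(abs(u) < 38.4, 2 * sqrt(pmax(38.4^2 - u^2, 0)), 0)
  tr <- matrix(rep(exp(-0.003 * chord), each = na), na, n)
  # constant added to one column is removed almost entirely
  spiked <- tr
  spiked[, 60] <- spiked[, 60] + 0.2
  fixed <- suppress_rings(spiked)
  expect_lt(mean(fixed[, 60] - tr[, 60]), 0.01)
  # the ring-free sinogram is barely touched (tangent kinks survive the
  # running-median bias reference)
  calm <- suppress_rings(tr)
  expect_lt(sqrt(mean((calm - tr)^2)) / stats::sd(tr), 0.01)
  # global mean preserved
  expect_equal(mean(fixed), mean(spiked), tolerance = 1e-12)
  expect_error(suppress_rings(tr, smoothing_window_px = 999), "smaller")
})

test_that("baked ring seeds reconstruct as rings and suppression removes them", {
  ph <- make_cord_phantom(grid_px = 128, n_vessels = 0, n_somata = 0,
                          stain_contrast = 0, seed = 1)
  geom <- scan_geometry(beam_spec(25), detector_spec(128, 1, 1.625), 0, 240)
  pset <- simulate_scan(ph, geom,
                        artefacts = list(rings = TRUE, ring_density = 0.08),
                        noise = FALSE, seed = 2)
  raw <- reconstruct_scan(pset)$slice
  fixed <- reconstruct_scan(pset, corrections = list(rings = TRUE))$slice
  ring_score <- function(sl) {
    g <- centre_grids(nrow(sl))
    rr <- round(sqrt(g$x^2 + g$y^2))
    # uniform annuli; the cord-rim step itself is excluded
    keep <- (rr >= 5 & rr <= 33) | (rr >= 44 & rr <= 57)
    prof <- tapply(sl[keep], rr[keep], mean)
    hp <- prof - stats::runmed(prof, 11)
    mean(hp^2)
  }
  expect_gt(ring_score(raw) / ring_score(fixed), 5)
})

test_that("full correction chain strictly improves reconstruction fidelity", {
  sc <- small_cord_scan()
  mdl <- distortion_model(c(63.5, 0), k1 = 2e-6)
  dirty <- simulate_scan(sc$phantom, sc$geometry,
                         artefacts = list(zingers = 20, rings = TRUE,
                                          distortion = mdl),
                         seed = 3)
  ref <- reconstruct_scan(sc$pset)$slice  # artefact-free, same noise seed
  unc <- reconstruct_scan(dirty)$slice
  cor <- reconstruct_scan(dirty, corrections = list(zingers = TRUE,
                                                    rings = TRUE,
                                                    distortion = mdl))$slice
  expect_gt(psnr(ref, cor), psnr(ref, unc))
  # the chain order is recorded
  rep <- correct_projection_set(dirty, distortion = mdl)$report
  expect_identical(rep$order, c("zingers", "flat_dark", "undistort", "rings"))
  expect_gt(rep$zingers_removed, 0)
  expect_true(rep$rings_suppressed)
})
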