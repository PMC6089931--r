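# Paganin single-distance phase retrieval and filtered back projection,
# plus the evenly-spaced projection-subset machinery used by the
# single-scan iterative downsampling study.

#' Phase-retrieval parameters
#'
#' @param delta_beta_ratio delta/beta ratio (>= 0; 0 disables retrieval and
#'   reduces the filter to the plain absorption logarithm).
#' @param pd_mm propagation distance in millimetres.
#' @param beam a [beam_spec()].
#' @param pixel_um effective pixel size for retrieval, micrometres. The
#'   default mirrors the reconstruction-pipeline value (1.6125 um), which is
#'   marginally finer than the geometric 1.625 um; both are accepted.
#' @return A `retrieval_params` object.
#' @export
retrieval_params <- function(delta_beta_ratio = 0, pd_mm = 160,
                             beam = beam_spec(25), pixel_um = 1.6125) {
  if (delta_beta_ratio < 0) .stopf("delta_beta_ratio must be >= 0")
  if (pd_mm < 0 || pixel_um <= 0)
    .stopf("propagation distance and pixel size must be positive")
  structure(list(delta_beta_ratio = delta_beta_ratio, pd_m = pd_mm * 1e-3,
                 wavelength_m = beam$wavelength_m, pixel_m = pixel_um * 1e-6),
            class = "retrieval_params")
}

paganin_denominator <- function(k2, params) {
  1 + (params$wavelength_m * params$pd_m * params$delta_beta_ratio / (4 * pi)) * k2
}

#' Paganin single-distance phase retrieval filter
#'
#' Divides the transmission spectrum by
#' `1 + (lambda * PD * (delta/beta) / (4 pi)) * |k|^2`, with `|k|` the
#' angular spatial frequency (rad/m) of the detector sampling, then takes
#' the negative logarithm. The output is proportional to the projected
#' thickness times the attenuation coefficient. A vector is filtered in 1-D
#' (one detector line); a matrix is filtered in 2-D.
#'
#' @param transmission positive transmission values (vector or matrix).
#' @param params a [retrieval_params()].
#' @param pad edge-replicate pad to twice the width before the FFT (vectors
#'   only; matrices are filtered periodically).
#' @return `-log` of the filtered transmission, same shape as the input.
#' @examples
#' p <- retrieval_params(0)
#' paganin_filter(c(0.5, 0.5, 0.5, 0.5), p)  # identical to -log(0.5)
#' @export
paganin_filter <- function(transmission, params, pad = TRUE) {
  if (any(transmission <= 0)) .stopf("transmission must be positive")
  if (params$delta_beta_ratio == 0) return(-log(transmission))
  if (is.matrix(transmission)) {
    nr <- nrow(transmission); nc <- ncol(transmission)
    ky <- 2 * pi * fftfreq(nr, d = params$pixel_m)
    kx <- 2 * pi * fftfreq(nc, d = params$pixel_m)
    k2 <- outer(ky^2, kx^2, "+")
    filt <- Re(fft(fft(transmission) / paganin_denominator(k2, params),
                   inverse = TRUE)) / (nr * nc)
  } else {
    n <- length(transmission)
    v <- transmission
    if (isTRUE(pad)) {
      n_pad <- next_pow2(2 * n)
      v <- pad_edge(v, n_pad)
    }
    k <- 2 * pi * fftfreq(length(v), d = params$pixel_m)
    out <- Re(fft(fft(v) / paganin_denominator(k^2, params),
                  inverse = TRUE)) / length(v)
    filt <- if (isTRUE(pad)) out[floor((length(v) - n) / 2) + seq_len(n)] else out
  }
  -log(pmax(filt, 1e-12))
}

ramp_filter_freq <- function(n_pad, window = c("ramp", "hann")) {
  window <- match.arg(window)
  # band-limited (Ram-Lak) ramp built in the spatial domain, so the finite
  # DC term is handled correctly
  f <- numeric(n_pad)
  f[1] <- 0.25
  j <- seq_len(n_pad - 1)
  d <- pmin(j, n_pad - j)  # circular lag
  f[j + 1] <- ifelse(d %% 2 == 1, -1 / (pi * d)^2, 0)
  H <- 2 * Re(fft(f))
  if (window == "hann") {
    fr <- fftfreq(n_pad)
    H <- H * 0.5 * (1 + cos(2 * pi * fr))
  }
  H
}

#' Filtered back projection of a sinogram
#'
#' Ramp-filtered (optionally Hann-apodised) linear-interpolation
#' backprojection over equally spaced angles covering `[0, 180)` degrees,
#' scaled by `pi / (2 n_angles)` so that a sinogram of line integrals taken
#' with unit (one-pixel) ray spacing reconstructs the underlying map in its
#' own units.
#'
#' @param sinogram matrix `(n_angles, n_u)`.
#' @param angles_deg projection angles in degrees (one per sinogram row).
#' @param filter_window `"ramp"` or `"hann"`.
#' @return Reconstructed `(n_u, n_u)` slice matrix.
#' @export
fbp_reconstruct <- function(sinogram, angles_deg,
                            filter_window = c("ramp", "hann")) {
  filter_window <- match.arg(filter_window)
  if (!is.matrix(sinogram)) .stopf("sinogram must be a matrix")
  n_a <- nrow(sinogram)
  if (n_a < 2) .stopf("at least 2 angles are required")
  if (length(angles_deg) != n_a)
    .stopf("angle count (%d) does not match sinogram rows (%d)",
           length(angles_deg), n_a)
  n_u <- ncol(sinogram)
  n_pad <- max(64, next_pow2(2 * n_u))
  H <- ramp_filter_freq(n_pad, filter_window)
  padded <- matrix(0, n_a, n_pad)
  padded[, seq_len(n_u)] <- sinogram
  filt <- t(apply(padded, 1, function(row)
    Re(fft(fft(row) * H, inverse = TRUE)) / n_pad))[, seq_len(n_u), drop = FALSE]
  bp <- cpp_backproject(filt, angles_deg * pi / 180, n_u)
  bp * pi / (2 * n_a)
}

#' Evenly spaced projection subset indices
#'
#' @param n_full full projection count.
#' @param n_subset subset size; must divide `n_full` so the subset's angles
#'   stay equally spaced over `[0, 180)`.
#' @return 1-based indices `1, 1 + s, 1 + 2 s, ...` with stride
#'   `s = n_full / n_subset`; length exactly `n_subset`.
#' @examples
#' subset_projections(8, 4)  # 1 3 5 7
#' @export
subset_projections <- function(n_full, n_subset) {
  if (n_subset < 1 || n_full < 1) .stopf("counts must be positive")
  if (n_full %% n_subset != 0) {
    div <- which(n_full %% seq_len(n_full) == 0)
    lower <- max(div[div < n_subset])
    upper <- min(div[div > n_subset])
    .stopf("%d does not divide %d; nearest valid subset sizes are %d and %d",
           n_subset, n_full, lower, upper)
  }
  s <- n_full / n_subset
  seq(1, n_full, by = s)
}

#' Reconstruct a scan into a tomogram slice
#'
#' Full analysis pipeline for one slice: correction chain -> optional
#' evenly-spaced projection subset -> optional Paganin retrieval (1-D, per
#' sinogram row) -> filtered back projection. Output values are linear
#' attenuation coefficients in 1/m (exactly `4 pi beta / lambda` for a
#' noiseless absorption scan).
#'
#' @param pset a `projection_set`.
#' @param params a [retrieval_params()]; ratio 0 skips retrieval.
#' @param n_subset evenly spaced subset size (`NULL` = all projections).
#' @param corrections list of arguments passed to
#'   [correct_projection_set()] (set `zingers`/`rings` to `FALSE` or pass a
#'   `distortion` model); `NULL` applies flat/dark only.
#' @param filter_window FBP apodisation, `"ramp"` or `"hann"`.
#' @return A `tomogram`: `slice` matrix, `voxel_um`, and `provenance`
#'   (projection count, propagation distance, delta/beta ratio, corrections,
#'   filter window).
#' @export
reconstruct_scan <- function(pset, params = retrieval_params(0),
                             n_subset = NULL, corrections = NULL,
                             filter_window = "ramp") {
  corr_args <- utils::modifyList(list(zingers = FALSE, rings = FALSE,
                                      distortion = NULL),
                                 if (is.null(corrections)) list() else corrections)
  corr <- do.call(correct_projection_set, c(list(pset = pset), corr_args))
  tr <- corr$transmission
  angles <- corr$angles_deg
  if (!is.null(n_subset)) {
    idx <- subset_projections(nrow(tr), n_subset)
    tr <- tr[idx, , drop = FALSE]
    angles <- angles[idx]
  }
  sino <- if (params$delta_beta_ratio > 0)
    t(apply(tr, 1, paganin_filter, params = params))
  else -log(tr)
  pixel_m <- pset$provenance$voxel_um * 1e-6
  slice <- fbp_reconstruct(sino, angles, filter_window) / pixel_m
  structure(list(slice = slice, voxel_um = pset$provenance$voxel_um,
                 provenance = list(n_projections = nrow(tr),
                                   pd_mm = pset$geometry$propagation_distance_mm,
                                   delta_beta = params$delta_beta_ratio,
                                   corrections = corr$report,
                                   filter_window = filter_window)),
            class = "tomogram")
}

#' @export
print.tomogram <- function(x, ...) {
  p <- x$provenance
  cat(sprintf(
    "<tomogram> %d x %d px, %d projection(s), PD %.4g mm, delta/beta %.4g\n",
    nrow(x$slice), ncol(x$slice), p$n_projections, p$pd_mm, p$delta_beta))
  invisible(x)
}
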