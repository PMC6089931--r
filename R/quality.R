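# Image-quality metrics (PSNR in its summed-squared-error form, RMS
# contrast as a sample standard deviation), the single-scan iterative
# downsampling study, propagation-distance and delta/beta screening sweeps,
# histogram peak separation, and grey-level threshold segmentation.

#' Rectangular region of interest
#'
#' 0-based, half-open pixel bounds `[x0, x1) x [y0, y1)` on a slice
#' (x = column, y = row).
#'
#' @param x0,x1,y0,y1 integer bounds.
#' @return An `roi` object with `n_x`, `n_y` dimensions.
#' @export
roi <- function(x0, x1, y0, y1) {
  if (x1 <= x0 || y1 <= y0) .stopf("ROI bounds must be non-empty")
  if ((x1 - x0) * (y1 - y0) < 2) .stopf("ROI must contain at least 2 pixels")
  structure(list(x0 = as.integer(x0), x1 = as.integer(x1),
                 y0 = as.integer(y0), y1 = as.integer(y1),
                 n_x = as.integer(x1 - x0), n_y = as.integer(y1 - y0)),
            class = "roi")
}

#' Crop a slice to a region of interest
#'
#' @param slice numeric matrix.
#' @param r an [roi()].
#' @return The cropped submatrix.
#' @export
crop_roi <- function(slice, r) {
  if (r$x1 > ncol(slice) || r$y1 > nrow(slice))
    .stopf("ROI exceeds the slice bounds")
  slice[(r$y0 + 1):r$y1, (r$x0 + 1):r$x1, drop = FALSE]
}

#' Peak signal-to-noise ratio between two images
#'
#' `PSNR = 10 log10( max(t)^2 / sum((t - n)^2) )` in decibels: the squared
#' peak of the reference over the *summed* (not mean) squared error. This is
#' the form the screening studies use; the conventional mean-squared-error
#' normalisation is available behind `normalise = "mse"` but is never the
#' default.
#'
#' @param t_image reference ("true") image.
#' @param n_image comparison ("noisy") image, same shape.
#' @param normalise `"sse"` (default) or `"mse"`.
#' @return PSNR in dB; `Inf` when the images are identical.
#' @examples
#' psnr(matrix(c(2, 0, 0, 0), 2), matrix(0, 2, 2))  # 0 dB
#' @export
psnr <- function(t_image, n_image, normalise = c("sse", "mse")) {
  normalise <- match.arg(normalise)
  if (!all(dim(t_image) == dim(n_image)))
    .stopf("images must share a shape")
  err <- sum((t_image - n_image)^2)
  if (normalise == "mse") err <- err / length(t_image)
  if (err == 0) return(Inf)
  10 * log10(max(t_image)^2 / err)
}

#' RMS contrast of a region of interest
#'
#' The sample standard deviation of the pixel values,
#' `sqrt( sum((p - mean(p))^2) / (n - 1) )`.
#'
#' @param roi_pixels numeric vector or matrix of ROI pixel values (>= 2
#'   pixels).
#' @return RMS contrast (dimensionless for normalised input).
#' @export
rms_contrast <- function(roi_pixels) {
  if (length(roi_pixels) < 2) .stopf("ROI must contain at least 2 pixels")
  stats::sd(as.vector(roi_pixels))
}

#' Min-max normalise a slice to [0, 1]
#'
#' @param slice non-constant numeric matrix or vector.
#' @return Rescaled values in `[0, 1]`.
#' @export
normalize_slice <- function(slice) {
  rng <- range(slice)
  if (rng[1] == rng[2]) .stopf("cannot normalise a constant slice")
  (slice - rng[1]) / (rng[2] - rng[1])
}

#' Quality metrics indexed by a swept parameter
#'
#' @param parameter_name swept parameter (`n_projections`, `pd_mm`,
#'   `delta_beta`).
#' @param parameter_values swept values.
#' @param psnr_db,rms_contrast,extras metric vectors aligned with the values
#'   (`psnr_db` optional).
#' @param reference_id identity of the reference image used for PSNR.
#' @return A `quality_curve` object (also a data frame).
#' @export
quality_curve <- function(parameter_name, parameter_values, psnr_db = NULL,
                          rms_contrast = NULL, extras = NULL,
                          reference_id = NA_character_) {
  df <- data.frame(value = parameter_values)
  names(df) <- parameter_name
  if (!is.null(psnr_db)) df$psnr_db <- psnr_db
  if (!is.null(rms_contrast)) df$rms_contrast <- rms_contrast
  if (!is.null(extras)) df <- cbind(df, extras)
  structure(df, class = c("quality_curve", "data.frame"),
            parameter_name = parameter_name, reference_id = reference_id)
}

#' Single-scan iterative downsampling study
#'
#' Reconstructs the full projection set as the reference `t(x, y)`, then
#' each evenly spaced subset as `n(x, y)` on the same slice, and scores PSNR
#' against the reference plus RMS contrast. Each slice is individually
#' min-max normalised as a whole and then cropped to the ROI for the RMS
#' computation, so the contrast scale is set by the full slice while the
#' statistic is not dominated by background.
#'
#' @param pset a `projection_set`.
#' @param subset_sizes descending subset sizes; each must divide the full
#'   projection count (the largest may equal it).
#' @param params a [retrieval_params()] shared by all reconstructions.
#' @param study_roi an [roi()] cropped around the sample.
#' @param corrections correction arguments, as in [reconstruct_scan()].
#' @return A `quality_curve` over `n_projections` with `psnr_db` and
#'   `rms_contrast`.
#' @export
downsampling_study <- function(pset, subset_sizes, params = retrieval_params(0),
                               study_roi, corrections = NULL) {
  if (is.unsorted(rev(subset_sizes)))
    .stopf("subset_sizes must be sorted descending")
  ref <- reconstruct_scan(pset, params, n_subset = NULL,
                          corrections = corrections)
  t_img <- crop_roi(ref$slice, study_roi)
  n_full <- ref$provenance$n_projections
  res <- lapply(subset_sizes, function(ns) {
    tomo <- if (ns == n_full) ref else
      reconstruct_scan(pset, params, n_subset = ns, corrections = corrections)
    n_img <- crop_roi(tomo$slice, study_roi)
    c(psnr = psnr(t_img, n_img),
      rms = rms_contrast(crop_roi(normalize_slice(tomo$slice), study_roi)))
  })
  m <- do.call(rbind, res)
  quality_curve("n_projections", subset_sizes, psnr_db = m[, "psnr"],
                rms_contrast = m[, "rms"],
                reference_id = sprintf("full_%d_projections", n_full))
}

#' Saturation fraction of a quality curve
#'
#' Fraction of the curve's observed dynamic range reached at a given
#' parameter value: `(m(at) - m(smallest)) / (m(largest) - m(smallest))`,
#' using the smallest-parameter metric as the baseline.
#'
#' @param curve a `quality_curve`.
#' @param at_value parameter value to evaluate (must be on the curve).
#' @param metric metric column (`"psnr_db"` or `"rms_contrast"`).
#' @return Fraction in `[0, 1]` for a monotone curve.
#' @export
saturation_fraction <- function(curve, at_value, metric = "psnr_db") {
  pv <- curve[[attr(curve, "parameter_name")]]
  if (length(pv) < 2) .stopf("curve needs at least 2 points")
  i <- match(at_value, pv)
  if (is.na(i)) .stopf("value %s is not on the curve", format(at_value))
  m <- curve[[metric]]
  fin <- is.finite(m)
  lo <- m[fin][which.min(pv[fin])]
  hi <- m[fin][which.max(pv[fin])]
  (m[i] - lo) / (hi - lo)
}

#' Locate background and sample peaks in a slice histogram
#'
#' Smooths the grey-level histogram with a moving average (window
#' `n_bins / 32`) and returns the two most prominent modes in ascending grey
#' order, plus the histogram minimum between them as a segmentation cutoff.
#' Phase retrieval typically turns an ambiguous unimodal histogram into a
#' clearly bimodal one.
#'
#' @param tomogram_slice numeric matrix (finite values).
#' @param n_bins number of histogram bins (>= 16).
#' @return List `background_peak`, `sample_peak`, `cutoff` (grey values),
#'   `prominence_ratio` (second mode's prominence relative to the first) and
#'   `unimodal` flag; for a unimodal histogram the cutoff is `NA`.
#' @export
histogram_peaks <- function(tomogram_slice, n_bins = 256) {
  if (n_bins < 16) .stopf("n_bins must be >= 16")
  v <- as.vector(tomogram_slice)
  if (!all(is.finite(v))) .stopf("slice must be finite")
  h <- graphics::hist(v, breaks = seq(min(v), max(v), length.out = n_bins + 1),
                      plot = FALSE)
  counts <- h$counts
  w <- max(3, 2 * floor(n_bins / 64) + 1)  # odd window ~ n_bins / 32
  hh <- (w - 1) / 2
  padded <- c(rep(counts[1], hh), counts, rep(counts[n_bins], hh))
  s <- as.numeric(stats::filter(padded, rep(1 / w, w), sides = 2))[hh + seq_len(n_bins)]
  # local maxima of the smoothed histogram; ties resolved to the lower bin
  is_peak <- vapply(seq_len(n_bins), function(i) {
    l <- if (i > 1) s[i - 1] else -Inf
    r <- if (i < n_bins) s[i + 1] else -Inf
    s[i] > l && s[i] >= r
  }, logical(1))
  peaks <- which(is_peak)
  unimodal_result <- function() {
    top <- if (length(peaks)) peaks[which.max(s[peaks])] else which.max(s)
    list(background_peak = h$mids[top], sample_peak = NA_real_,
         cutoff = NA_real_, prominence_ratio = NA_real_, unimodal = TRUE)
  }
  if (length(peaks) < 2) return(unimodal_result())
  ord <- order(s[peaks], decreasing = TRUE)
  two <- sort(peaks[ord[1:2]])
  valley <- two[1] + which.min(s[two[1]:two[2]]) - 1
  prom <- min(s[two]) - s[valley]
  # the dip between the modes must clear Poisson counting noise, otherwise
  # the histogram is effectively unimodal and no cutoff is guessed
  if (prom < 5 * sqrt(max(s[valley], 1))) return(unimodal_result())
  list(background_peak = h$mids[two[1]], sample_peak = h$mids[two[2]],
       cutoff = h$mids[valley],
       prominence_ratio = prom / max(s),
       unimodal = FALSE)
}

#' Screen Paganin delta/beta ratios on one scan
#'
#' Reconstructs the scan at each delta/beta ratio and scores RMS contrast on
#' the ROI crop of the individually normalised slice. Ratio 0 is the
#' unretrieved reconstruction.
#'
#' @param pset a `projection_set`.
#' @param ratios delta/beta values (>= 0).
#' @param study_roi an [roi()].
#' @param n_subset optional subset size for speed.
#' @param corrections correction arguments, as in [reconstruct_scan()].
#' @return A `quality_curve` over `delta_beta`.
#' @export
sweep_delta_beta <- function(pset, ratios = c(0, 1, 3, 10, 30, 100, 300, 1000, 3000),
                             study_roi, n_subset = NULL, corrections = NULL) {
  if (any(ratios < 0)) .stopf("ratios must be >= 0")
  pd <- pset$geometry$propagation_distance_mm
  rms <- vapply(ratios, function(r) {
    tomo <- reconstruct_scan(pset, retrieval_params(r, pd_mm = pd),
                             n_subset = n_subset, corrections = corrections)
    rms_contrast(crop_roi(normalize_slice(tomo$slice), study_roi))
  }, numeric(1))
  quality_curve("delta_beta", ratios, rms_contrast = rms)
}

#' Screen propagation distances by simulation
#'
#' Simulates and reconstructs the phantom at each propagation distance with
#' a common seed, reporting the ROI's RMS contrast (on the raw
#' reconstruction, so the shared attenuation scale is preserved across
#' distances) and a fringe-overshoot score: the mean excursion of
#' reconstructed values beyond the true attenuation range of the ROI.
#'
#' @param phantom a `phantom`.
#' @param geometry_template a [scan_geometry()]; its propagation distance is
#'   replaced by each swept value.
#' @param pd_list_mm propagation distances in millimetres (> 0 allowed,
#'   0 gives a pure-absorption baseline).
#' @param study_roi an [roi()].
#' @param seed master seed shared by all simulated scans.
#' @param noise Poisson statistics on or off.
#' @return A `quality_curve` over `pd_mm` with `rms_contrast` and
#'   `overshoot` columns.
#' @export
sweep_propagation_distance <- function(phantom, geometry_template,
                                       pd_list_mm = c(20, 40, 80, 160, 320),
                                       study_roi, seed = 1, noise = TRUE) {
  if (any(pd_list_mm < 0)) .stopf("propagation distances must be >= 0")
  lam <- geometry_template$beam$wavelength_m
  true_mu <- 4 * pi * crop_roi(phantom$beta, study_roi) / lam
  rng <- range(true_mu)
  res <- vapply(pd_list_mm, function(pd) {
    geom <- geometry_template
    geom$propagation_distance_mm <- pd
    pset <- simulate_scan(phantom, geom, noise = noise, seed = seed)
    tomo <- reconstruct_scan(pset)
    sl <- crop_roi(tomo$slice, study_roi)
    over <- mean(pmax(sl - rng[2], 0) + pmax(rng[1] - sl, 0))
    c(rms = rms_contrast(sl), overshoot = over)
  }, numeric(2))
  quality_curve("pd_mm", pd_list_mm, rms_contrast = res["rms", ],
                extras = data.frame(overshoot = res["overshoot", ]))
}

#' Grey-level threshold segmentation within a mask
#'
#' @param tomogram_slice numeric matrix.
#' @param mask logical matrix restricting the segmentation (non-empty).
#' @param cutoff grey-level threshold.
#' @param polarity `"darker"` selects values below the cutoff (e.g.
#'   vasculature), `"brighter"` above.
#' @param voxel_um voxel size for the area conversion.
#' @return List `binary_map` (logical matrix) and `area_um2` (segmented area
#'   of this slice in square micrometres).
#' @export
threshold_segment <- function(tomogram_slice, mask, cutoff,
                              polarity = c("darker", "brighter"),
                              voxel_um = 1.625) {
  polarity <- match.arg(polarity)
  if (!any(mask)) .stopf("mask is empty")
  sel <- if (polarity == "darker") tomogram_slice < cutoff
  else tomogram_slice > cutoff
  out <- sel & mask
  list(binary_map = out, area_um2 = sum(out) * voxel_um^2)
}
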