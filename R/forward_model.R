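# Forward model: parallel-beam projection of the phantom, 1-D Fresnel
# (angular-spectrum) propagation per detector line for inline phase contrast,
# Poisson photon statistics with a flat/dark detector structure, and
# injectable acquisition artefacts (zingers, baked ring seeds, radial lens
# distortion).

#' Scan geometry
#'
#' Equally spaced projection angles over `[0, 180)` degrees, plus beam,
#' detector and propagation-distance settings. An optional extra check frame
#' at exactly 180 degrees can be recorded; it is never used in
#' reconstruction.
#'
#' @param beam a [beam_spec()].
#' @param det a [detector_spec()].
#' @param propagation_distance_mm sample-to-scintillator distance (>= 0).
#' @param n_projections number of equally spaced angles over `[0, 180)`.
#' @param extra_check_projection record an additional 180-degree frame?
#' @return A `scan_geometry` object with an `angles_deg` vector.
#' @export
scan_geometry <- function(beam = beam_spec(25), det = detector_spec(),
                          propagation_distance_mm = 160,
                          n_projections = 1440,
                          extra_check_projection = FALSE) {
  if (propagation_distance_mm < 0) .stopf("propagation distance must be >= 0")
  if (n_projections < 1) .stopf("n_projections must be >= 1")
  structure(list(beam = beam, det = det,
                 propagation_distance_mm = propagation_distance_mm,
                 angles_deg = seq(0, 180, length.out = n_projections + 1)[seq_len(n_projections)],
                 extra_check_projection = isTRUE(extra_check_projection)),
            class = "scan_geometry")
}

#' Parallel-beam line integrals of a phantom
#'
#' Radon transform of the phantom's delta and beta maps at the given angles,
#' sampled on the detector grid with linear interpolation, rotation axis at
#' the grid's centre column. Path lengths are in metres, so each output entry
#' is a path-integrated refractive index component.
#'
#' @param phantom a `phantom` object.
#' @param angles_deg projection angles in degrees.
#' @return List with matrices `D` (integral of delta) and `B` (integral of
#'   beta), each `length(angles_deg) x n_u`.
#' @export
project <- function(phantom, angles_deg) {
  if (length(angles_deg) < 1) .stopf("empty angle list")
  step_m <- phantom$voxel_um * 1e-6
  ang <- angles_deg * pi / 180
  list(D = cpp_radon(phantom$delta, ang) * step_m,
       B = cpp_radon(phantom$beta, ang) * step_m)
}

fftfreq <- function(n, d = 1) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  k / (n * d)
}

pad_edge <- function(v, n_pad) {
  n <- length(v)
  extra <- n_pad - n
  left <- floor(extra / 2)
  c(rep(v[1], left), v, rep(v[n], extra - left))
}

next_pow2 <- function(n) 2^ceiling(log2(n))

#' Transmit a projection line and propagate to the detector
#'
#' Forms the thin-object exit wave
#' `psi0(u) = exp(-(2*pi/lambda) * B(u)) * exp(-1i * (2*pi/lambda) * D(u))`,
#' propagates it over the propagation distance with the 1-D angular-spectrum
#' kernel `exp(-1i * pi * lambda * z * f^2)` (edge-replicated padding to
#' twice the width suppresses wrap-around fringes) and returns the detector
#' intensity `|psi_z|^2`, normalised so a flat field is 1.
#'
#' @param D_line,B_line path integrals of delta and beta along each detector
#'   sample, in metres (vectors of equal length).
#' @param beam a [beam_spec()].
#' @param pd_mm propagation distance in millimetres (>= 0; 0 gives pure
#'   Beer-Lambert attenuation with no fringes).
#' @param pixel_um detector sample spacing in micrometres.
#' @return Numeric vector of normalised intensities.
#' @export
transmit_and_propagate <- function(D_line, B_line, beam = beam_spec(25),
                                   pd_mm = 160, pixel_um = 1.625) {
  if (pd_mm < 0) .stopf("propagation distance must be >= 0")
  lam <- beam$wavelength_m
  amp <- exp(-(2 * pi / lam) * B_line)
  if (pd_mm == 0) return(amp^2)
  phase <- -(2 * pi / lam) * D_line
  psi <- amp * exp(1i * phase)
  n <- length(psi)
  n_pad <- next_pow2(2 * n)
  psi_p <- pad_edge(psi, n_pad)
  f <- fftfreq(n_pad, d = pixel_um * 1e-6)
  kern <- exp(-1i * pi * lam * (pd_mm * 1e-3) * f^2)
  out <- fft(fft(psi_p) * kern, inverse = TRUE) / n_pad
  left <- floor((n_pad - n) / 2)
  Mod(out[left + seq_len(n)])^2
}

#' Convert normalised intensity to raw detector counts
#'
#' Expected counts are `dark_level + intensity * flat_profile *
#' full_well_counts * exposure_fraction`; Poisson noise is sampled with the
#' given seed and values are clipped at the full well. The default exposure
#' fraction of 0.85 emulates choosing the exposure time so flats reach ~85
#' percent of a 16-bit full well.
#'
#' @param intensity normalised intensity vector or matrix (flat = 1).
#' @param flat_profile per-pixel beam/gain profile (default 1 everywhere).
#' @param dark_level detector offset counts.
#' @param full_well_counts saturation level (default `2^16`).
#' @param exposure_fraction flat-field fraction of the full well, in (0, 1].
#' @param seed integer seed for the Poisson draw; `NULL` disables noise
#'   (returns expected counts).
#' @return Counts with the shape of `intensity`.
#' @export
apply_detector <- function(intensity, flat_profile = 1, dark_level = 100,
                           full_well_counts = 2^16, exposure_fraction = 0.85,
                           seed = NULL) {
  if (exposure_fraction <= 0 || exposure_fraction > 1)
    .stopf("exposure_fraction must be in (0, 1]")
  mu <- dark_level + intensity * flat_profile * full_well_counts * exposure_fraction
  counts <- if (is.null(seed)) mu else
    with_seed(seed, {
      out <- rpois(length(mu), lambda = as.vector(mu))
      if (is.matrix(mu)) matrix(out, nrow(mu), ncol(mu)) else out
    })
  pmin(counts, full_well_counts - 1)
}

#' Inject zinger streaks into a frame
#'
#' Zingers are spurious bright pixels or short streaks from stray X-rays and
#' cosmic rays hitting the sensor. Each injected zinger is a short linear run
#' of pixels with a large positive amplitude; ground-truth coordinates are
#' returned for recovery tests.
#'
#' @param frame counts matrix (rows x cols) or vector (one detector line).
#' @param rate_per_frame number of zingers to inject (>= 0).
#' @param amplitude_range added counts, sampled uniformly in this range.
#' @param streak_length_px inclusive range of streak lengths in pixels.
#' @param seed integer seed.
#' @return List `frame` (with zingers) and `zingers` (data frame of pixel
#'   coordinates `row`, `col`, and `id` per streak; 1-based).
#' @export
inject_zingers <- function(frame, rate_per_frame = 20,
                           amplitude_range = c(3000, 20000),
                           streak_length_px = c(1, 5), seed = 1) {
  if (rate_per_frame < 0) .stopf("rate must be >= 0")
  vec <- !is.matrix(frame)
  m <- if (vec) matrix(frame, nrow = 1) else frame
  if (rate_per_frame == 0)
    return(list(frame = frame,
                zingers = data.frame(row = integer(0), col = integer(0),
                                     id = integer(0))))
  zr <- zc <- zi <- integer(0)
  m2 <- with_seed(seed, {
    for (z in seq_len(rate_per_frame)) {
      len <- sample(seq(streak_length_px[1], streak_length_px[2]), 1)
      amp <- runif(1, amplitude_range[1], amplitude_range[2])
      r0 <- sample(nrow(m), 1); c0 <- sample(ncol(m), 1)
      th <- runif(1, 0, 2 * pi)
      rr <- pmin(pmax(round(r0 + (seq_len(len) - 1) * sin(th)), 1), nrow(m))
      cc <- pmin(pmax(round(c0 + (seq_len(len) - 1) * cos(th)), 1), ncol(m))
      keep <- !duplicated(cbind(rr, cc))
      rr <- rr[keep]; cc <- cc[keep]
      m[cbind(rr, cc)] <- m[cbind(rr, cc)] + amp
      zr <- c(zr, rr); zc <- c(zc, cc); zi <- c(zi, rep(z, length(rr)))
    }
    m
  })
  list(frame = if (vec) as.vector(m2) else m2,
       zingers = data.frame(row = zr, col = zc, id = zi))
}

#' Radial distortion model
#'
#' `r_distorted = r * (1 + k1 r^2 + k2 r^4)` about `center_xy` (0-based
#' pixel coordinates, x = column, y = row). `k1 = k2 = 0` is the identity.
#'
#' @param center_xy distortion centre `c(x, y)` in 0-based pixels.
#' @param k1,k2 radial polynomial coefficients (per px^2 and px^4).
#' @return A `distortion_model` object.
#' @export
distortion_model <- function(center_xy, k1 = 0, k2 = 0) {
  structure(list(center_xy = as.numeric(center_xy), k1 = k1, k2 = k2),
            class = "distortion_model")
}

warp_frame <- function(frame, model, invert, tol = 1e-3) {
  vec <- !is.matrix(frame)
  m <- if (vec) matrix(frame, nrow = 1) else frame
  out <- cpp_warp_radial(m, model$center_xy[1], model$center_xy[2],
                         model$k1, model$k2, invert, tol)
  if (vec) as.vector(out) else out
}

#' Apply radial lens distortion to a frame
#'
#' Resamples the frame under the radial model (linear interpolation): each
#' output pixel at radius `r` from the centre takes the input value at radius
#' `r * (1 + k1 r^2 + k2 r^4)`, so displacement grows with distance from the
#' distortion centre and is largest at the frame corners.
#'
#' @param frame numeric matrix (or one-line vector).
#' @param model a [distortion_model()].
#' @return Distorted frame of the same shape.
#' @export
apply_distortion <- function(frame, model) warp_frame(frame, model, invert = FALSE)

#' Bake fixed-pattern gain defects into a flat profile
#'
#' Multiplies the flat profile by seeded per-pixel gain errors emulating
#' scintillator defects. Applied to every projection of a scan (but not to
#' the recorded flat frames) the angle-independent pattern survives
#' flat-field correction and reconstructs as concentric rings.
#'
#' @param flat_profile numeric vector or matrix of relative gains.
#' @param defect_density fraction of pixels affected, in `[0, 1]`.
#' @param defect_contrast maximum relative gain deviation of a defect.
#' @param seed integer seed.
#' @return Flat profile with baked defects.
#' @export
bake_ring_seeds <- function(flat_profile, defect_density = 0.02,
                            defect_contrast = 0.05, seed = 1) {
  if (defect_density < 0 || defect_density > 1)
    .stopf("defect_density must be in [0, 1]")
  if (defect_density == 0) return(flat_profile)
  with_seed(seed, {
    n <- length(flat_profile)
    hit <- runif(n) < defect_density
    gain <- rep(1, n)
    gain[hit] <- 1 + runif(sum(hit), -defect_contrast, defect_contrast)
    flat_profile * if (is.matrix(flat_profile))
      matrix(gain, nrow(flat_profile), ncol(flat_profile)) else gain
  })
}

#' Simulate a full scan of a phantom
#'
#' Runs the complete forward pipeline per projection angle: line integrals,
#' Fresnel propagation, detector counts with Poisson noise, plus optional
#' injected artefacts (zingers per frame, baked ring seeds, radial
#' distortion). Also emits flat and dark frame stacks. Per-frame Poisson
#' seeds derive from the master seed plus the frame index, so projection
#' subsets are independently reproducible.
#'
#' @param phantom a `phantom` object (slice phantom: one detector line per
#'   angle).
#' @param geometry a [scan_geometry()]; its detector width must equal the
#'   phantom grid.
#' @param artefacts list of switches: `zingers` (count per frame, 0 = off),
#'   `zinger_amplitude`, `rings` (logical), `ring_density`, `ring_contrast`,
#'   `distortion` (a [distortion_model()] or `NULL`).
#' @param noise logical; Poisson photon statistics on or off.
#' @param n_flats,n_darks number of flat and dark frames to emit.
#' @param dark_level,full_well_counts,exposure_fraction detector settings,
#'   see [apply_detector()].
#' @param seed master integer seed.
#' @return A `projection_set`: `frames` (n_frames x n_u counts matrix, one
#'   detector line per angle), `flats`, `darks`, `angles_deg`, `geometry` and
#'   a `provenance` list recording every injected artefact.
#' @export
simulate_scan <- function(phantom, geometry,
                          artefacts = list(), noise = TRUE,
                          n_flats = 20, n_darks = 20,
                          dark_level = 100, full_well_counts = 2^16,
                          exposure_fraction = 0.85, seed = 1) {
  n_u <- ncol(phantom$delta)
  art <- utils::modifyList(list(zingers = 0, zinger_amplitude = c(3000, 20000),
                                rings = FALSE, ring_density = 0.02,
                                ring_contrast = 0.05, distortion = NULL),
                           artefacts)
  angles <- geometry$angles_deg
  if (geometry$extra_check_projection) angles <- c(angles, 180)
  lines <- project(phantom, angles)
  pd <- geometry$propagation_distance_mm
  pix <- phantom$voxel_um

  flat_profile <- rep(1, n_u)
  frame_profile <- if (isTRUE(art$rings))
    bake_ring_seeds(flat_profile, art$ring_density, art$ring_contrast,
                    seed = seed + 90000L)
  else flat_profile

  n_a <- length(angles)
  frames <- matrix(0, n_a, n_u)
  for (i in seq_len(n_a)) {
    I <- transmit_and_propagate(lines$D[i, ], lines$B[i, ],
                                beam = geometry$beam, pd_mm = pd,
                                pixel_um = pix)
    if (!is.null(art$distortion)) I <- warp_frame(I, art$distortion, invert = FALSE)
    frames[i, ] <- apply_detector(I, frame_profile, dark_level,
                                  full_well_counts, exposure_fraction,
                                  seed = if (noise) seed + i else NULL)
  }
  # zingers are counted per tomographic slice, i.e. over the whole sinogram
  zinger_log <- data.frame(row = integer(0), col = integer(0), id = integer(0))
  if (art$zingers > 0) {
    z <- inject_zingers(frames, art$zingers, art$zinger_amplitude,
                        seed = seed + 40000L)
    frames <- pmin(z$frame, full_well_counts - 1)
    zinger_log <- z$zingers
  }

  flats <- t(vapply(seq_len(n_flats), function(i)
    apply_detector(rep(1, n_u), flat_profile, dark_level, full_well_counts,
                   exposure_fraction,
                   seed = if (noise) seed + 70000L + i else NULL),
    numeric(n_u)))
  darks <- t(vapply(seq_len(n_darks), function(i)
    apply_detector(rep(0, n_u), flat_profile, dark_level, full_well_counts,
                   exposure_fraction,
                   seed = if (noise) seed + 80000L + i else NULL),
    numeric(n_u)))

  structure(list(frames = frames, flats = flats, darks = darks,
                 angles_deg = angles, geometry = geometry,
                 provenance = list(seed = seed, noise = noise,
                                   artefacts = art, zingers = zinger_log,
                                   dark_level = dark_level,
                                   full_well_counts = full_well_counts,
                                   exposure_fraction = exposure_fraction,
                                   voxel_um = phantom$voxel_um,
                                   phantom_params = phantom$params)),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf("<projection_set> %d frame(s) x %d px, %d flat(s), %d dark(s), PD %.4g mm\n",
              nrow(x$frames), ncol(x$frames), nrow(x$flats), nrow(x$darks),
              x$geometry$propagation_distance_mm))
  invisible(x)
}
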