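#' Beam specification
#'
#' Monochromatic beam description used by the planner and the forward model.
#' The wavelength is derived from the photon energy as `hc / E` with
#' `hc = 1.239842e-9` keV m.
#'
#' @param energy_keV photon energy in keV (scalar, > 0).
#' @return An object of class `beam_spec` with fields `energy_keV` and
#'   `wavelength_m`.
#' @examples
#' beam_spec(25)$wavelength_m  # ~4.959e-11 m
#' @export
beam_spec <- function(energy_keV = 25) {
  w <- kev_to_wavelength(energy_keV)
  structure(list(energy_keV = energy_keV, wavelength_m = w),
            class = "beam_spec")
}

#' Detector specification
#'
#' @param n_u,n_v horizontal and vertical pixel counts (>= 1).
#' @param effective_pixel_um magnified (effective) pixel size in micrometres.
#' @return An object of class `detector_spec`.
#' @export
detector_spec <- function(n_u = 2560, n_v = 2160, effective_pixel_um = 1.625) {
  if (n_u < 1 || n_v < 1) .stopf("detector dimensions must be >= 1")
  if (effective_pixel_um <= 0) .stopf("effective pixel size must be positive")
  structure(list(n_u = as.integer(n_u), n_v = as.integer(n_v),
                 effective_pixel_um = effective_pixel_um),
            class = "detector_spec")
}

#' Convert photon energy to wavelength
#'
#' @param energy_keV photon energy in keV (> 0).
#' @return Wavelength in metres.
#' @examples
#' kev_to_wavelength(25)        # 4.95937e-11
#' kev_to_wavelength(12.39842)  # exactly 1e-10
#' @export
kev_to_wavelength <- function(energy_keV) {
  if (!is.numeric(energy_keV) || any(energy_keV <= 0))
    .stopf("energy_keV must be positive")
  HC_KEV_M / energy_keV
}

#' Maximum propagation distance for a feature size
#'
#' Fresnel-regime bound `PD <= a^2 / lambda` on the sample-to-detector
#' propagation distance at which inline phase contrast still enhances, rather
#' than obscures, features of diameter `a`. The value is returned unrounded;
#' display rounding is left to callers.
#'
#' @param feature_diameter_um feature diameter `a` in micrometres (> 0).
#' @param beam a [beam_spec()].
#' @return Maximum propagation distance in millimetres.
#' @examples
#' max_propagation_distance(3.2, beam_spec(25))   # ~206.5 mm
#' max_propagation_distance(2.82, beam_spec(25))  # ~160 mm
#' @export
max_propagation_distance <- function(feature_diameter_um, beam = beam_spec(25)) {
  if (any(feature_diameter_um <= 0)) .stopf("feature diameter must be positive")
  a_m <- feature_diameter_um * 1e-6
  (a_m^2 / beam$wavelength_m) * 1e3
}

#' Smallest feature whose phase contrast survives a propagation distance
#'
#' Inverse of [max_propagation_distance()]: `a = sqrt(PD * lambda)`.
#'
#' @param pd_mm propagation distance in millimetres (> 0).
#' @param beam a [beam_spec()].
#' @return Feature diameter in micrometres.
#' @examples
#' min_resolvable_feature(160, beam_spec(25))  # ~2.82 um
#' @export
min_resolvable_feature <- function(pd_mm, beam = beam_spec(25)) {
  if (any(pd_mm <= 0)) .stopf("propagation distance must be positive")
  sqrt(pd_mm * 1e-3 * beam$wavelength_m) * 1e6
}

#' Angular Nyquist projection count
#'
#' Minimal number of equally spaced projections over 180 degrees that avoids
#' angular undersampling at the edge of the field of view: the sample (or
#' detector) width in pixels times pi/2, rounded to the nearest integer.
#'
#' @param width_px width in pixels perpendicular to the rotation axis (>= 1).
#' @return Integer projection count.
#' @examples
#' nyquist_projection_count(2560)  # 4021
#' nyquist_projection_count(1300)  # 2042
#' @export
nyquist_projection_count <- function(width_px) {
  if (any(width_px < 1)) .stopf("width_px must be >= 1")
  as.integer(round(width_px * pi / 2))
}

#' Number of concatenated scans to tile a long sample
#'
#' @param sample_length_mm sample length in millimetres (> 0).
#' @param fov_width_mm vertical field-of-view extent of one scan in mm (> 0).
#' @param overlap_fraction fraction of the field of view shared between
#'   neighbouring scans, in `[0, 1)`.
#' @return Integer number of scans, `ceil(L / (fov * (1 - overlap)))`.
#' @examples
#' plan_tiled_scan(100, 3.5, 0.02)  # 30
#' @export
plan_tiled_scan <- function(sample_length_mm, fov_width_mm, overlap_fraction = 0.02) {
  if (sample_length_mm <= 0 || fov_width_mm <= 0)
    .stopf("sample length and field of view must be positive")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    .stopf("overlap_fraction must be in [0, 1)")
  as.integer(ceiling(sample_length_mm / (fov_width_mm * (1 - overlap_fraction))))
}

#' Field of view of a detector
#'
#' @param det a [detector_spec()].
#' @return Named numeric vector `c(width_mm, height_mm)`.
#' @examples
#' fov_from_detector(detector_spec(2560, 2160, 1.625))  # 4.16 x 3.51 mm
#' @export
fov_from_detector <- function(det) {
  c(width_mm = det$n_u * det$effective_pixel_um / 1e3,
    height_mm = det$n_v * det$effective_pixel_um / 1e3)
}

#' Physical width of a feature spanning a number of pixels
#'
#' @param n_pixels feature width in pixels (> 0, may be fractional).
#' @param effective_pixel_um effective pixel size in micrometres.
#' @return Width in micrometres.
#' @examples
#' feature_width_um(4, 1.6)  # 6.4 um capillary
#' @export
feature_width_um <- function(n_pixels, effective_pixel_um) {
  if (any(n_pixels <= 0)) .stopf("n_pixels must be positive")
  n_pixels * effective_pixel_um
}
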