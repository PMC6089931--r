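# On-disk formats. A projection set is a directory of 16-bit TIFF stacks
# (projections.tif holding one detector line per row for slice scans, plus
# flats.tif / darks.tif) with a JSON sidecar holding angles, geometry and
# provenance. Tomograms are single TIFFs with a JSON sidecar recording the
# quantisation range and provenance.

counts_to_tiff <- function(m, path, full_well) {
  tiff::writeTIFF(m / (full_well - 1), path, bits.per.sample = 16L,
                  compression = "none")
}

tiff_to_counts <- function(path, full_well) {
  round(tiff::readTIFF(path) * (full_well - 1))
}

#' Write a projection set to a directory
#'
#' @param pset a `projection_set`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_projection_set <- function(pset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fw <- pset$provenance$full_well_counts
  counts_to_tiff(pset$frames, file.path(path, "projections.tif"), fw)
  counts_to_tiff(pset$flats, file.path(path, "flats.tif"), fw)
  counts_to_tiff(pset$darks, file.path(path, "darks.tif"), fw)
  meta <- list(
    angles_deg = pset$angles_deg,
    geometry = list(energy_keV = pset$geometry$beam$energy_keV,
                    n_u = pset$geometry$det$n_u,
                    n_v = pset$geometry$det$n_v,
                    effective_pixel_um = pset$geometry$det$effective_pixel_um,
                    propagation_distance_mm = pset$geometry$propagation_distance_mm,
                    extra_check_projection = pset$geometry$extra_check_projection),
    provenance = pset$provenance)
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(path)
}

#' Read a projection set from a directory
#'
#' Loads the TIFF-stack dialect written by [write_projection_set()] and
#' enforces the format invariants: all stacks share the detector width, the
#' frame count matches the angle count (plus one when the 180-degree check
#' projection is flagged), and counts are non-negative.
#'
#' @param path directory containing `projections.tif`, `flats.tif`,
#'   `darks.tif` and `metadata.json`.
#' @return A `projection_set`.
#' @export
read_projection_set <- function(path) {
  need <- file.path(path, c("projections.tif", "flats.tif", "darks.tif",
                            "metadata.json"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    .stopf("projection set is missing: %s",
           paste(basename(missing), collapse = ", "))
  meta <- jsonlite::read_json(file.path(path, "metadata.json"),
                              simplifyVector = TRUE)
  if (is.null(meta$angles_deg))
    .stopf("metadata.json lacks the projection angles")
  fw <- meta$provenance$full_well_counts
  frames <- tiff_to_counts(file.path(path, "projections.tif"), fw)
  flats <- tiff_to_counts(file.path(path, "flats.tif"), fw)
  darks <- tiff_to_counts(file.path(path, "darks.tif"), fw)
  if (ncol(frames) != ncol(flats) || ncol(frames) != ncol(darks))
    .stopf("frames, flats and darks do not share detector dimensions")
  n_expected <- length(meta$angles_deg)
  if (nrow(frames) != n_expected)
    .stopf("frame count (%d) does not match angle count (%d)",
           nrow(frames), n_expected)
  if (any(frames < 0)) .stopf("negative counts in projections")
  g <- meta$geometry
  geometry <- scan_geometry(beam_spec(g$energy_keV),
                            detector_spec(g$n_u, g$n_v, g$effective_pixel_um),
                            g$propagation_distance_mm,
                            n_projections = n_expected -
                              as.integer(isTRUE(g$extra_check_projection)),
                            extra_check_projection = isTRUE(g$extra_check_projection))
  structure(list(frames = frames, flats = flats, darks = darks,
                 angles_deg = as.numeric(meta$angles_deg),
                 geometry = geometry, provenance = meta$provenance),
            class = "projection_set")
}

#' Write a tomogram slice as TIFF plus JSON sidecar
#'
#' `float32` stores 32-bit normalised samples, `uint16` 16-bit; either way
#' the sidecar records the exact `(min, max)` used for quantisation together
#' with the tomogram provenance, so [read_tomogram()] restores physical
#' values (to within one quantisation step for `uint16`).
#'
#' @param tomogram a `tomogram`.
#' @param path output TIFF path (the sidecar gets `.json` appended).
#' @param bit_depth `"float32"` or `"uint16"`.
#' @return `path`, invisibly.
#' @export
write_tomogram <- function(tomogram, path, bit_depth = c("float32", "uint16")) {
  bit_depth <- match.arg(bit_depth)
  sl <- tomogram$slice
  if (!all(is.finite(sl))) .stopf("tomogram contains non-finite values")
  rng <- range(sl)
  scaled <- if (rng[1] == rng[2]) sl * 0 else (sl - rng[1]) / (rng[2] - rng[1])
  tiff::writeTIFF(scaled, path,
                  bits.per.sample = if (bit_depth == "float32") 32L else 16L,
                  compression = "none")
  side <- list(bit_depth = bit_depth, min = rng[1], max = rng[2],
               voxel_um = tomogram$voxel_um, provenance = tomogram$provenance)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}

#' Read a tomogram written by [write_tomogram()]
#'
#' @param path TIFF path (sidecar expected at `path.json`).
#' @return A `tomogram`.
#' @export
read_tomogram <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  scaled <- tiff::readTIFF(path)
  slice <- side$min + scaled * (side$max - side$min)
  structure(list(slice = slice, voxel_um = side$voxel_um,
                 provenance = side$provenance),
            class = "tomogram")
}
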