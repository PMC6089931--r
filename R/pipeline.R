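# Config-driven end-to-end runs: simulate -> correct -> retrieve/reconstruct
# -> score, with every seed explicit so a config fully determines all
# outputs.

default_config <- function() {
  list(
    seed = 1,
    output_dir = "phasetomo_run",
    phantom = list(kind = "cord", grid_px = 256, voxel_um = 1.625,
                   embedding = "wax", stain_contrast = 2, n_vessels = 12,
                   n_somata = 3, seed = 1),
    geometry = list(energy_keV = 25, propagation_distance_mm = 160,
                    n_projections = 720, extra_check_projection = FALSE),
    artefacts = list(zingers = 0, rings = FALSE, distortion_k1 = 0,
                     distortion_k2 = 0, distortion_center = NULL),
    noise = TRUE,
    corrections = list(zingers = TRUE, rings = TRUE, distortion = TRUE),
    retrieval = list(delta_beta = 0, pixel_um = 1.6125),
    subset_sizes = NULL,
    roi = NULL,
    bit_depth = "float32"
  )
}

#' Read a run configuration file
#'
#' The configuration is a flat YAML document whose keys mirror
#' [run_pipeline()]'s defaults: `seed`, `output_dir`, `phantom` (kind,
#' grid_px, voxel_um, embedding, stain_contrast, n_vessels, n_somata, seed),
#' `geometry` (energy_keV, propagation_distance_mm, n_projections,
#' extra_check_projection), `artefacts` (zingers, rings, distortion_k1/_k2,
#' distortion_center), `noise`, `corrections` (zingers, rings, distortion),
#' `retrieval` (delta_beta, pixel_um), `subset_sizes`, `roi`
#' (x0, x1, y0, y1) and `bit_depth`.
#'
#' @param path YAML file path.
#' @return A complete configuration list (missing keys take defaults).
#' @export
read_run_config <- function(path) {
  utils::modifyList(default_config(), yaml::read_yaml(path))
}

build_phantom <- function(cfg) {
  p <- cfg$phantom
  if (identical(p$kind, "wire"))
    make_wire_phantom(grid_px = p$grid_px, voxel_um = p$voxel_um,
                      embedding = p$embedding, seed = p$seed)
  else
    make_cord_phantom(grid_px = p$grid_px, voxel_um = p$voxel_um,
                      embedding = p$embedding,
                      stain_contrast = p$stain_contrast,
                      n_vessels = p$n_vessels, n_somata = p$n_somata,
                      seed = p$seed)
}

#' Run the simulate-correct-reconstruct-score pipeline from a config
#'
#' Executes the full chain described by the configuration (see
#' [read_run_config()]): phantom generation, scan simulation with the
#' configured artefacts, pre-reconstruction corrections, optional Paganin
#' retrieval, filtered back projection, optional downsampling study, and
#' writes every artefact (projection set, tomogram, curves as CSV, a JSON
#' report with MD5 checksums) under `output_dir`.
#'
#' @param config a configuration list or a YAML file path.
#' @return The report list, invisibly; also written as `report.json`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config)
  else utils::modifyList(default_config(), config)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  phantom <- build_phantom(cfg)
  g <- cfg$geometry
  geometry <- scan_geometry(beam_spec(g$energy_keV),
                            detector_spec(phantom$params$grid_px, 1,
                                          phantom$voxel_um),
                            g$propagation_distance_mm, g$n_projections,
                            isTRUE(g$extra_check_projection))
  art <- list(zingers = cfg$artefacts$zingers,
              rings = isTRUE(cfg$artefacts$rings))
  dist_model <- NULL
  if (cfg$artefacts$distortion_k1 != 0 || cfg$artefacts$distortion_k2 != 0) {
    ctr <- cfg$artefacts$distortion_center
    if (is.null(ctr)) ctr <- c((phantom$params$grid_px - 1) / 2, 0)
    dist_model <- distortion_model(ctr, cfg$artefacts$distortion_k1,
                                   cfg$artefacts$distortion_k2)
    art$distortion <- dist_model
  }
  message("simulate: ", g$n_projections, " projections at PD ",
          g$propagation_distance_mm, " mm")
  pset <- simulate_scan(phantom, geometry, artefacts = art,
                        noise = isTRUE(cfg$noise), seed = cfg$seed)
  write_projection_set(pset, file.path(out, "projections"))

  corr <- list(zingers = isTRUE(cfg$corrections$zingers),
               rings = isTRUE(cfg$corrections$rings),
               distortion = if (isTRUE(cfg$corrections$distortion)) dist_model)
  params <- retrieval_params(cfg$retrieval$delta_beta,
                             pd_mm = g$propagation_distance_mm,
                             beam = geometry$beam,
                             pixel_um = cfg$retrieval$pixel_um)
  message("reconstruct: delta/beta ", params$delta_beta_ratio)
  tomo <- reconstruct_scan(pset, params, corrections = corr)
  write_tomogram(tomo, file.path(out, "tomogram.tif"), cfg$bit_depth)

  curve_file <- NULL
  if (!is.null(cfg$subset_sizes)) {
    r <- cfg$roi
    study_roi <- if (is.null(r)) {
      q <- round(phantom$params$grid_px * c(0.3, 0.7))
      roi(q[1], q[2], q[1], q[2])
    } else roi(r$x0, r$x1, r$y0, r$y1)
    message("downsampling study: ",
            paste(cfg$subset_sizes, collapse = ", "), " projections")
    curve <- downsampling_study(pset, sort(cfg$subset_sizes, decreasing = TRUE),
                                params, study_roi, corrections = corr)
    curve_file <- file.path(out, "downsampling_curve.csv")
    utils::write.csv(as.data.frame(curve), curve_file, row.names = FALSE)
  }

  files <- c(file.path(out, "projections",
                       c("projections.tif", "flats.tif", "darks.tif",
                         "metadata.json")),
             file.path(out, "tomogram.tif"),
             file.path(out, "tomogram.tif.json"), curve_file)
  report <- list(config = cfg,
                 provenance = tomo$provenance,
                 checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(report)
}
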