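# Digital phantoms: paired delta/beta maps with material labels, the ground
# truth for every downstream simulation test. Structures are rasterised with
# area-weighted (anti-aliased) edges; labels are assigned where coverage
# reaches one half, so interior voxels carry their material's constants
# exactly while boundary voxels blend.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

grid_coords <- function(n) {
  c0 <- (n - 1) / 2
  x <- matrix(rep(seq_len(n) - 1 - c0, each = n), n, n)   # column offsets
  y <- matrix(rep(seq_len(n) - 1 - c0, times = n), n, n)  # row offsets
  list(x = x, y = y)
}

clamp01 <- function(v) pmin(pmax(v, 0), 1)

# Anti-aliased disc coverage: ~linear ramp one pixel wide across the rim.
disc_coverage <- function(xy, cx, cy, radius) {
  r <- sqrt((xy$x - cx)^2 + (xy$y - cy)^2)
  clamp01(radius - r + 0.5)
}

# Rotated ellipse coverage with an approximate signed distance (scaled by the
# smaller semi-axis) driving the anti-aliasing ramp.
ellipse_coverage <- function(xy, cx, cy, a, b, phi_deg = 0) {
  phi <- phi_deg * pi / 180
  dx <- xy$x - cx; dy <- xy$y - cy
  xr <- cos(phi) * dx + sin(phi) * dy
  yr <- -sin(phi) * dx + cos(phi) * dy
  d <- (sqrt((xr / a)^2 + (yr / b)^2) - 1) * min(a, b)
  clamp01(0.5 - d)
}

new_phantom_canvas <- function(grid_px, materials, base_material) {
  i <- material_lookup(materials, base_material)
  list(delta = matrix(materials$delta[i], grid_px, grid_px),
       beta = matrix(materials$beta[i], grid_px, grid_px),
       labels = matrix(i, grid_px, grid_px))
}

# Blend a structure into the canvas; label where coverage >= 0.5.
paint <- function(canvas, coverage, materials, name,
                  delta = NULL, beta = NULL) {
  i <- material_lookup(materials, name)
  d <- if (is.null(delta)) materials$delta[i] else delta
  b <- if (is.null(beta)) materials$beta[i] else beta
  canvas$delta <- coverage * d + (1 - coverage) * canvas$delta
  canvas$beta <- coverage * b + (1 - coverage) * canvas$beta
  canvas$labels[coverage >= 0.5] <- i
  canvas
}

finish_phantom <- function(canvas, materials, voxel_um, truth, seed, params) {
  structure(list(delta = canvas$delta, beta = canvas$beta,
                 labels = canvas$labels, materials = materials,
                 voxel_um = voxel_um, truth = truth, seed = seed,
                 params = params),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d x %d px, voxel %.4g um, %d structure(s), seed %s\n",
              nrow(x$delta), ncol(x$delta), x$voxel_um,
              if (is.null(x$truth)) 0L else nrow(x$truth),
              format(x$seed)))
  invisible(x)
}

#' Logical mask of a phantom material
#'
#' @param phantom a phantom object.
#' @param name material name to select.
#' @return Logical matrix, `TRUE` where the label map carries that material.
#' @export
label_mask <- function(phantom, name) {
  phantom$labels == material_lookup(phantom$materials, name)
}

place_discs <- function(n_discs, radii_px, region_radius, min_gap = 2,
                        exclude = NULL, max_tries = 5000) {
  xs <- ys <- rs <- numeric(0)
  tries <- 0
  while (length(xs) < n_discs) {
    tries <- tries + 1
    if (tries > max_tries)
      .stopf("could not place %d non-overlapping discs (placed %d)",
             n_discs, length(xs))
    r <- radii_px[(length(xs) %% length(radii_px)) + 1]
    if (length(radii_px) > 1) r <- sample(radii_px, 1)
    rho <- (region_radius - r - 1) * sqrt(runif(1))
    th <- runif(1, 0, 2 * pi)
    cx <- rho * cos(th); cy <- rho * sin(th)
    ok <- TRUE
    if (length(xs)) {
      dd <- sqrt((xs - cx)^2 + (ys - cy)^2)
      if (any(dd < rs + r + min_gap)) ok <- FALSE
    }
    if (ok && !is.null(exclude) && nrow(exclude)) {
      dd <- sqrt((exclude$x - cx)^2 + (exclude$y - cy)^2)
      if (any(dd < exclude$r + r + min_gap)) ok <- FALSE
    }
    if (ok) {
      xs <- c(xs, cx); ys <- c(ys, cy); rs <- c(rs, r)
    }
  }
  data.frame(x = xs, y = ys, r = rs)
}

#' Spinal-cord-in-embedding digital phantom
#'
#' Builds a 2-D slice phantom of a cylindrical spinal-cord sample inside an
#' embedding cylinder: a white-matter disc carrying a mirror-symmetric
#' grey-matter "butterfly" (whose absorption exceeds white matter by
#' `stain_contrast`, emulating iodine staining), dark vessels of a few pixels
#' diameter scattered through the parenchyma, and brighter cell bodies
#' (somata) confined to the grey matter. All coordinates are recorded in the
#' returned `truth` table.
#'
#' @param grid_px square grid size in pixels (>= 64).
#' @param voxel_um isotropic voxel size in micrometres.
#' @param embedding embedding material name (`"wax"`, `"epoxy"`, `"agar"`,
#'   `"air"`).
#' @param stain_contrast relative excess of grey-matter beta over white
#'   matter (0 = unstained: grey and white identical).
#' @param vessel_diameters_px candidate vessel diameters in pixels (>= 1).
#' @param n_vessels number of vessels to insert.
#' @param n_somata number of ~`soma_diameter_px` cell bodies in grey matter.
#' @param soma_diameter_px soma diameter in pixels.
#' @param seed integer seed; identical arguments and seed give identical
#'   phantoms.
#' @param materials material table, see [material_table()].
#' @return A `phantom` object: `delta`, `beta`, `labels` matrices, `voxel_um`,
#'   `materials`, and a `truth` data frame (type, x, y, diameter_px,
#'   material); coordinates are offsets from the grid centre in pixels.
#' @examples
#' ph <- make_cord_phantom(grid_px = 128, n_vessels = 5, n_somata = 0, seed = 1)
#' @export
make_cord_phantom <- function(grid_px = 512, voxel_um = 1.625,
                              embedding = "wax", stain_contrast = 2,
                              vessel_diameters_px = c(2, 3, 4, 6, 8),
                              n_vessels = 20, n_somata = 6,
                              soma_diameter_px = 15, seed = 1,
                              materials = material_table(25)) {
  if (grid_px < 64) .stopf("grid_px must be >= 64")
  if (any(vessel_diameters_px < 1)) .stopf("vessel diameters must be >= 1 px")
  n <- as.integer(grid_px)
  cord_r <- 0.30 * n
  embed_r <- 0.49 * n
  if (any(vessel_diameters_px / 2 >= cord_r) ||
      (n_somata > 0 && soma_diameter_px / 2 >= cord_r))
    .stopf("inserted structure does not fit inside the cord")

  xy <- grid_coords(n)
  canvas <- new_phantom_canvas(n, materials, "air")
  canvas <- paint(canvas, disc_coverage(xy, 0, 0, embed_r), materials, embedding)
  cord_cov <- disc_coverage(xy, 0, 0, cord_r)
  canvas <- paint(canvas, cord_cov, materials, "tissue")

  # grey-matter butterfly: central commissure plus dorsal and ventral horn
  # ellipses, mirrored about the vertical (mid-sagittal) axis.
  R <- cord_r
  right <- pmax(
    ellipse_coverage(xy, 0, 0, 0.40 * R, 0.16 * R, 0),
    ellipse_coverage(xy, 0.30 * R, 0.38 * R, 0.27 * R, 0.30 * R, -25),
    ellipse_coverage(xy, 0.25 * R, -0.42 * R, 0.15 * R, 0.38 * R, 20)
  )
  grey_cov <- pmax(right, right[, n:1]) * cord_cov
  ti <- material_lookup(materials, "tissue")
  grey_beta <- materials$beta[ti] * (1 + stain_contrast)
  canvas <- paint(canvas, grey_cov, materials, "tissue_grey_li",
                  delta = materials$delta[ti], beta = grey_beta)

  truth <- NULL
  with_seed(seed, {
    vi <- material_lookup(materials, "vessel")
    vessels <- if (n_vessels > 0)
      place_discs(n_vessels, vessel_diameters_px / 2, 0.88 * cord_r)
    else data.frame(x = numeric(0), y = numeric(0), r = numeric(0))
    for (k in seq_len(nrow(vessels)))
      canvas <- paint(canvas,
                       disc_coverage(xy, vessels$x[k], vessels$y[k], vessels$r[k]),
                       materials, "vessel")

    somata <- data.frame(x = numeric(0), y = numeric(0), r = numeric(0))
    if (n_somata > 0) {
      rs <- soma_diameter_px / 2
      grey_solid <- grey_cov >= 0.999
      cand <- which(grey_solid)
      tries <- 0
      while (nrow(somata) < n_somata) {
        tries <- tries + 1
        if (tries > 10000)
          .stopf("could not place %d somata inside grey matter", n_somata)
        idx <- sample(cand, 1)
        cy <- ((idx - 1) %% n) - (n - 1) / 2
        cx <- ((idx - 1) %/% n) - (n - 1) / 2
        cov <- disc_coverage(xy, cx, cy, rs + 1)
        if (any(cov > 0 & !grey_solid)) next
        if (nrow(vessels) &&
            any(sqrt((vessels$x - cx)^2 + (vessels$y - cy)^2) <
                vessels$r + rs + 2)) next
        if (nrow(somata) &&
            any(sqrt((somata$x - cx)^2 + (somata$y - cy)^2) < 2 * rs + 2)) next
        somata <- rbind(somata, data.frame(x = cx, y = cy, r = rs))
      }
      for (k in seq_len(nrow(somata)))
        canvas <- paint(canvas,
                         disc_coverage(xy, somata$x[k], somata$y[k], somata$r[k]),
                         materials, "soma")
    }
    truth <- rbind(
      if (nrow(vessels)) data.frame(type = "vessel", x = vessels$x,
                                    y = vessels$y,
                                    diameter_px = 2 * vessels$r,
                                    material = "vessel"),
      if (nrow(somata)) data.frame(type = "soma", x = somata$x, y = somata$y,
                                   diameter_px = 2 * somata$r,
                                   material = "soma")
    )
  })
  if (is.null(truth))
    truth <- data.frame(type = character(0), x = numeric(0), y = numeric(0),
                        diameter_px = numeric(0), material = character(0))

  finish_phantom(canvas, materials, voxel_um, truth, seed,
                 params = list(kind = "cord", grid_px = n,
                               embedding = embedding,
                               stain_contrast = stain_contrast,
                               cord_radius_px = cord_r,
                               embed_radius_px = embed_r,
                               n_vessels = n_vessels, n_somata = n_somata))
}

#' Wire-in-insulation standard sample phantom
#'
#' The beamline standard comparison object: several drawn copper pieces
#' inside a plastic-insulation cylinder, embedded in a surrounding medium.
#'
#' @inheritParams make_cord_phantom
#' @param n_wire_pieces number of copper pieces (default 7).
#' @return A `phantom` object (see [make_cord_phantom()]).
#' @export
make_wire_phantom <- function(grid_px = 512, voxel_um = 1.625,
                              embedding = "wax", n_wire_pieces = 7, seed = 1,
                              materials = material_table(25)) {
  if (grid_px < 64) .stopf("grid_px must be >= 64")
  if (n_wire_pieces < 1) .stopf("n_wire_pieces must be >= 1")
  n <- as.integer(grid_px)
  xy <- grid_coords(n)
  canvas <- new_phantom_canvas(n, materials, "air")
  canvas <- paint(canvas, disc_coverage(xy, 0, 0, 0.49 * n), materials, embedding)
  canvas <- paint(canvas, disc_coverage(xy, 0, 0, 0.22 * n), materials, "insulation")

  wire_r <- max(2, 0.018 * n)
  pieces <- with_seed(seed,
    place_discs(n_wire_pieces, wire_r, 0.14 * n, min_gap = 2))
  for (k in seq_len(nrow(pieces)))
    canvas <- paint(canvas,
                    disc_coverage(xy, pieces$x[k], pieces$y[k], pieces$r[k]),
                    materials, "copper")
  truth <- data.frame(type = "wire", x = pieces$x, y = pieces$y,
                      diameter_px = 2 * pieces$r, material = "copper")
  finish_phantom(canvas, materials, voxel_um, truth, seed,
                 params = list(kind = "wire", grid_px = n,
                               embedding = embedding,
                               n_wire_pieces = n_wire_pieces))
}
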