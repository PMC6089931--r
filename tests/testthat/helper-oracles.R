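# Shared oracles and fixture builders, all computed in code at test time.

# Independent flood-fill connected-component count (4-connectivity) used to
# verify phantom structure counts without touching the package's internals.
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  n_comp <- 0L
  nr <- nrow(mask); nc <- ncol(mask)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    n_comp <- n_comp + 1L
    stack <- list(c(i, j))
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      pi <- p[1]; pj <- p[2]
      if (pi < 1 || pi > nr || pj < 1 || pj > nc) next
      if (!mask[pi, pj] || lab[pi, pj] != 0L) next
      lab[pi, pj] <- n_comp
      stack <- c(stack, list(c(pi - 1, pj), c(pi + 1, pj),
                             c(pi, pj - 1), c(pi, pj + 1)))
    }
  }
  n_comp
}

# centre-offset coordinate grids matching the phantom convention
centre_grids <- function(n) {
  c0 <- (n - 1) / 2
  list(x = matrix(rep(seq_len(n) - 1 - c0, each = n), n, n),
       y = matrix(rep(seq_len(n) - 1 - c0, times = n), n, n))
}

# analytic parallel-beam sinogram of a uniform centred disc
disc_sinogram <- function(n, n_angles, radius, value) {
  u <- seq_len(n) - 1 - (n - 1) / 2
  chord <- ifelse(abs(u) < radius, 2 * sqrt(pmax(radius^2 - u^2, 0)), 0) * value
  matrix(rep(chord, each = n_angles), n_angles, n)
}

equispaced_angles <- function(n) seq(0, 180, length.out = n + 1)[seq_len(n)]

# small cached cord scan shared by correction/reconstruction tests
small_cord_scan <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- make_cord_phantom(grid_px = 128, n_vessels = 6, n_somata = 0,
                              seed = 42)
      geom <- scan_geometry(beam_spec(25), detector_spec(128, 1, 1.625),
                            propagation_distance_mm = 40, n_projections = 240)
      cache <<- list(phantom = ph, geometry = geom,
                     pset = simulate_scan(ph, geom, seed = 3))
    }
    cache
  }
})

# 3x3 box blur (replicated edges) so bilinear-resampling tests see smooth data
blur_for_test <- function(m) {
  n <- nrow(m); p <- ncol(m)
  pad <- m[c(1, 1:n, n), c(1, 1:p, p)]
  acc <- matrix(0, n, p)
  for (di in 0:2) for (dj in 0:2)
    acc <- acc + pad[di + 1:n, dj + 1:p]
  acc / 9
}

# intensity-weighted centroid (0-based row, col) of a dot near pos (1-based),
# or NULL if the dot left the window
dot_centroid <- function(img, pos, half = 6) {
  rr <- max(1, pos[1] - half):min(nrow(img), pos[1] + half)
  cc <- max(1, pos[2] - half):min(ncol(img), pos[2] + half)
  w <- img[rr, cc]
  if (sum(w) < 0.1) return(NULL)
  c(sum((rr - 1) * rowSums(w)), sum((cc - 1) * colSums(w))) / sum(w)
}

# the reference study scan: 512 px cord phantom, 160 mm PD, 1440 projections,
# Poisson noise, no injected artefacts; cached because several acceptance
# checks share it
acceptance_scan <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- make_cord_phantom(grid_px = 512, seed = 11)
      geom <- scan_geometry(beam_spec(25), detector_spec(512, 1, 1.625),
                            propagation_distance_mm = 160,
                            n_projections = 1440)
      cache <<- list(phantom = ph, geometry = geom,
                     pset = simulate_scan(ph, geom, seed = 5),
                     roi = roi(156, 356, 156, 356))
    }
    cache
  }
})

# binary erosion by a (2k+1)^2 square: TRUE only where the whole window is
eroded_mask <- function(m, k = 2) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (di in -k:k) for (dj in -k:k) {
    sh <- matrix(FALSE, nr, nc)
    r_src <- (1 + max(0, di)):(nr + min(0, di))
    c_src <- (1 + max(0, dj)):(nc + min(0, dj))
    sh[r_src - di, c_src - dj] <- m[r_src, c_src]
    out <- out & sh
  }
  out
}
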