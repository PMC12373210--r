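# Shared fixtures and independent oracles used across the suite.

# Analytic chord of a ray through an axis-aligned box (slab method),
# independent of the compiled traversal.
box_chord <- function(lo, hi, o, d) {
  t0 <- -Inf; t1 <- Inf
  for (a in 1:3) {
    if (abs(d[a]) < 1e-14) {
      if (o[a] < lo[a] || o[a] > hi[a]) return(0)
    } else {
      ta <- (lo[a] - o[a]) / d[a]; tb <- (hi[a] - o[a]) / d[a]
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
    }
  }
  max(0, t1 - t0)
}

# Fine-step numerical line integral by midpoint sampling of the voxel field,
# independent of the Siddon path.
numeric_line_integral <- function(grid, o, d, step = min(grid$spacing_mm) / 1000) {
  lo <- grid$origin_mm; hi <- lo + grid$dims * grid$spacing_mm
  t0 <- -Inf; t1 <- Inf
  for (a in 1:3) {
    if (abs(d[a]) < 1e-14) {
      if (o[a] < lo[a] || o[a] > hi[a]) return(0)
    } else {
      ta <- (lo[a] - o[a]) / d[a]; tb <- (hi[a] - o[a]) / d[a]
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
    }
  }
  if (t1 <= t0) return(0)
  n <- ceiling((t1 - t0) / step)
  tm <- t0 + (seq_len(n) - 0.5) * (t1 - t0) / n
  pts <- cbind(o[1] + tm * d[1], o[2] + tm * d[2], o[3] + tm * d[3])
  idx <- sweep(pts, 2, lo, "-")
  ii <- pmin(pmax(floor(idx[, 1] / grid$spacing_mm[1]), 0), grid$dims[1] - 1)
  jj <- pmin(pmax(floor(idx[, 2] / grid$spacing_mm[2]), 0), grid$dims[2] - 1)
  kk <- pmin(pmax(floor(idx[, 3] / grid$spacing_mm[3]), 0), grid$dims[3] - 1)
  vals <- grid$values[cbind(ii + 1, jj + 1, kk + 1)]
  sum(vals) * (t1 - t0) / n
}

# Random rays aimed at (or near) a grid from random outside positions.
random_rays_at <- function(grid, n, spread = 1.0, dist = 400) {
  lo <- grid$origin_mm; hi <- lo + grid$dims * grid$spacing_mm
  half <- (hi - lo) / 2
  origins <- matrix(0, n, 3); dirs <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    th <- stats::runif(1, 0, 2 * pi); phl <- stats::runif(1, -0.6, 0.6)
    o <- dist * c(cos(phl) * sin(th), cos(phl) * cos(th), sin(phl))
    tgt <- stats::runif(3, -spread, spread) * half + (lo + hi) / 2
    dd <- tgt - o
    origins[i, ] <- o
    dirs[i, ] <- dd / sqrt(sum(dd^2))
  }
  list(origins = origins, dirs = dirs)
}

# Analytic cone-beam chord-length projection of a uniform unit-density
# sphere (radius rho, centered at the origin): per detector ray, the chord
# 2 * sqrt(rho^2 - h^2) with h the distance from the sphere center to the
# ray line.
sphere_chord_image <- function(setup, pose, rho) {
  rays <- rays_for_detector(setup, pose)
  o <- rays$origins; d <- rays$dirs
  tproj <- rowSums(-o * d)
  closest <- o + tproj * d
  h2 <- rowSums(closest^2)
  chord <- ifelse(h2 < rho^2, 2 * sqrt(pmax(rho^2 - h2, 0)), 0)
  matrix(chord, setup$det_rows, setup$det_cols, byrow = TRUE)
}

# Tiny, fast field configuration used by network-level tests.
tiny_field_cfg <- function(...) {
  field_config(h_layers = 2, h_width = 24, d_layers = 2, d_width = 24,
               m_sh = 4, m_a = 3, enc = encoding_spec(4, 2), ...)
}
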