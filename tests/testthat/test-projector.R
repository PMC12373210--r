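test_that("siddon traversal handles single-voxel and miss cases", {
  g1 <- voxel_grid(array(1, c(1, 1, 1)), spacing_mm = 1)
  # axis-aligned ray through the center of a 1 mm voxel
  tr <- siddon_trace(g1, c(-5, 0, 0), c(1, 0, 0))
  expect_equal(nrow(tr), 1)
  expect_equal(tr$length_mm, 1)
  miss <- siddon_trace(g1, c(-5, 10, 0), c(1, 0, 0))
  expect_equal(nrow(miss), 0)
  expect_error(siddon_trace(g1, c(0, 0, 0), c(2, 0, 0)), "unit")
})

test_that("siddon conserves the box chord and visits voxels once, in order", {
  set.seed(5)
  g <- voxel_grid(array(stats::runif(8^3), c(8, 8, 8)), spacing_mm = 2)
  rr <- random_rays_at(g, 300)
  lo <- g$origin_mm; hi <- lo + g$dims * g$spacing_mm
  for (i in seq_len(nrow(rr$origins))) {
    tr <- siddon_trace(g, rr$origins[i, ], rr$dirs[i, ])
    chord <- box_chord(lo, hi, rr$origins[i, ], rr$dirs[i, ])
    expect_equal(sum(tr$length_mm), chord, tolerance = 1e-6)
    if (nrow(tr) > 1) {
      expect_true(all(diff(tr$t_entry_mm) > 0))
      expect_false(any(duplicated(tr[c("i", "j", "k")])))
    }
  }
})

test_that("line integrals match the fine-step numerical oracle", {
  set.seed(6)
  g <- voxel_grid(array(stats::runif(12^3), c(12, 12, 12)),
                  spacing_mm = c(2, 2.5, 3))
  rr <- random_rays_at(g, 40)
  vals <- line_integral(g, rr)
  for (i in seq_len(40)) {
    ref <- numeric_line_integral(g, rr$origins[i, ], rr$dirs[i, ],
                                 step = min(g$spacing_mm) / 1000)
    if (ref > 1e-9) expect_equal(vals[i], ref, tolerance = 1e-3)
    else expect_lt(abs(vals[i] - ref), 1e-6)
  }
})

test_that("analytic slab and cube-diagonal integrals are exact", {
  gu <- voxel_grid(array(1, c(10, 10, 10)), spacing_mm = 1)
  ray_x <- list(origins = matrix(c(-50, 0.01, 0.01), 1),
                dirs = matrix(c(1, 0, 0), 1))
  expect_equal(line_integral(gu, ray_x), 10)
  d <- c(1, 1, 1) / sqrt(3)
  ray_d <- list(origins = matrix(c(-5, -5, -5) - d, 1), dirs = matrix(d, 1))
  expect_equal(line_integral(gu, ray_d), 10 * sqrt(3), tolerance = 1e-6)
  # linearity in the voxel values
  set.seed(8)
  ga <- voxel_grid(array(stats::runif(5^3), c(5, 5, 5)), spacing_mm = 2)
  gb <- voxel_grid(array(stats::runif(5^3), c(5, 5, 5)), spacing_mm = 2)
  gs <- voxel_grid(ga$values + gb$values, spacing_mm = 2)
  g2 <- voxel_grid(2 * ga$values, spacing_mm = 2)
  rr <- random_rays_at(ga, 20)
  expect_equal(line_integral(gs, rr),
               line_integral(ga, rr) + line_integral(gb, rr),
               tolerance = 1e-9)
  expect_equal(line_integral(g2, rr), 2 * line_integral(ga, rr),
               tolerance = 1e-12)
})

test_that("DRRs of degenerate grids follow the documented conventions", {
  geo <- source_setup(det_rows = 8, det_cols = 8)
  gz <- voxel_grid(array(0, c(4, 4, 4)), spacing_mm = 10)
  expect_true(all(make_drr(gz, geo, pose(0)) == 0))
  expect_true(all(make_drr(gz, geo, pose(0), normalize = FALSE) == 0))
  # constant raw image normalizes to zeros
  expect_true(all(normalize_01(matrix(3, 4, 4)) == 0))
})

test_that("a bright voxel at the isocenter projects to the detector center", {
  vals <- array(0, c(33, 33, 33)); vals[17, 17, 17] <- 1
  g <- voxel_grid(vals, spacing_mm = 4)
  geo <- source_setup(det_rows = 33, det_cols = 33, det_pitch_mm = 4)
  img <- make_drr(g, geo, pose(40), normalize = FALSE)
  w <- which(img == max(img), arr.ind = TRUE)
  expect_true(max(img) > 0)
  expect_equal(unname(w[1, ]), c(17, 17))
})

test_that("voxelized-sphere DRR matches the analytic chord image within 2% RMS", {
  rho <- 60
  n <- 64; fov <- 136   # tight field of view: 2.125 mm voxels at 64^3
  sp <- fov / n
  # partial-volume voxelization: occupancy from 3^3 sub-voxel samples
  sub <- (1:3 - 2) / 3 * sp
  occ <- array(0, c(n, n, n))
  cx <- (seq_len(n) - 0.5) * sp - fov / 2
  for (ox in sub) for (oy in sub) for (oz in sub) {
    r2 <- outer(outer((cx + ox)^2, (cx + oy)^2, "+"), (cx + oz)^2, "+")
    occ <- occ + (r2 < rho^2)
  }
  g <- voxel_grid(occ / 27, spacing_mm = sp)
  geo <- source_setup(det_rows = 64, det_cols = 64, det_pitch_mm = 4.2)
  for (th in c(0, 30)) {
    drr <- make_drr(g, geo, pose(th), normalize = FALSE)
    ana <- sphere_chord_image(geo, pose(th), rho)
    expect_lt(rmse(drr, ana) / sqrt(mean(ana^2)), 0.02)
  }
})

test_that("field rendering is a discrete line integral of the density", {
  geo <- source_setup(det_rows = 8, det_cols = 8)
  g <- voxel_grid(array(1, c(8, 8, 8)), spacing_mm = 20)
  rays <- rays_for_detector(geo, pose(0), bounds = g)
  # constant field c: pixel = c * (t_far - t_near)
  r <- render_patch_from_field(function(p) rep(2.5, nrow(p)), rays, 7, seed = 1)
  hit <- ray_hits(rays)
  chords <- rays$t_far - rays$t_near
  expect_equal(as.vector(t(r$patch))[hit], 2.5 * chords[hit], tolerance = 1e-9)
  # zero field: zero patch, zero densities
  rz <- render_patch_from_field(function(p) numeric(nrow(p)), rays, 7, seed = 1)
  expect_true(all(rz$patch == 0))
  expect_true(all(rz$densities == 0))
  expect_equal(nrow(rz$points), sum(hit) * 7)
})

test_that("grid-lookup rendering converges to the Siddon integral", {
  # smooth random grid: coarse noise interpolated to 16^3
  set.seed(11)
  coarse <- voxel_grid(array(stats::runif(8^3, 0.8, 1.2), c(8, 8, 8)),
                       spacing_mm = 40)
  n <- 16; sp <- 320 / n
  cx <- (seq_len(n) - 0.5) * sp - 160
  pts <- as.matrix(expand.grid(cx, cx, cx))
  fine <- voxel_grid(array(grid_trilinear_fn(coarse)(pts), c(n, n, n)),
                     spacing_mm = sp)
  geo <- source_setup(det_rows = 8, det_cols = 8)
  rays <- rays_for_detector(geo, pose(20), bounds = fine)
  ref <- line_integral(fine, rays)
  r <- render_patch_from_field(grid_lookup_fn(fine), rays, 256, seed = 3)
  got <- as.vector(t(r$patch))
  hit <- ray_hits(rays)
  rel <- abs(got[hit] - ref[hit]) / ref[hit]
  expect_lt(max(rel), 0.01)
})

test_that("stratified rendering is an unbiased estimator of the line integral", {
  # smooth analytic field along a single known ray
  field <- function(p) 1 + 0.5 * sin(p[, 1] / 20) * cos(p[, 2] / 30)
  rays <- list(origins = matrix(c(-100, 5, 0), 1), dirs = matrix(c(1, 0, 0), 1),
               t_near = 0, t_far = 200, rows = 1, cols = 1)
  class(rays) <- "ray_bundle"
  f1 <- function(t) 1 + 0.5 * sin((-100 + t) / 20) * cos(5 / 30)
  truth <- stats::integrate(f1, 0, 200, rel.tol = 1e-10)$value
  set.seed(9)
  est <- replicate(100, render_patch_from_field(field, rays, 8)$patch[1, 1])
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - truth), 3 * se + 1e-12)
})
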