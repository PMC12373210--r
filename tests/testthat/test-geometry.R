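test_that("circular pose rings have the standard sparse-CT spacings", {
  th5 <- vapply(make_circular_poses(5), function(p) p$theta_deg, 0)
  expect_equal(th5, c(0, 72, 144, 216, 288))
  th72 <- vapply(make_circular_poses(72), function(p) p$theta_deg, 0)
  expect_equal(diff(th72), rep(5, 71))
  th1 <- make_circular_poses(1)
  expect_length(th1, 1)
  expect_equal(th1[[1]]$theta_deg, 0)
  expect_error(make_circular_poses(0), "positive")
})

test_that("sources sit on the ring at SAD and face the origin", {
  geo <- source_setup(det_rows = 16, det_cols = 16)
  for (p in make_circular_poses(7, start_deg = 13)) {
    f <- tomofield:::pose_frame(geo, p)
    expect_lt(abs(sqrt(sum(f$source^2)) - geo$sad_mm), 1e-9 * geo$sad_mm)
    expect_equal(f$w, -f$source / geo$sad_mm, tolerance = 1e-12)
    # orthonormal right-handed detector frame
    expect_lt(abs(sum(f$u * f$w)), 1e-12)
    expect_lt(abs(sum(f$v * f$w)), 1e-12)
    expect_lt(abs(sum(f$u^2) - 1), 1e-12)
  }
})

test_that("patch pattern scale bound is min(H,W)/M and degenerate case pins the center", {
  geo <- source_setup(det_rows = 128, det_cols = 128)
  set.seed(7)
  s <- replicate(200, sample_patch_pattern(geo, 32)$scale_s)
  expect_true(all(s >= 1 & s <= 4))
  # M = H = W: scale forced to 1, center forced to the detector center
  geo8 <- source_setup(det_rows = 8, det_cols = 8)
  pat <- sample_patch_pattern(geo8, 8)
  expect_equal(pat$scale_s, 1, tolerance = 1e-9)
  expect_equal(pat$center_uv, c(3.5, 3.5))
  expect_error(sample_patch_pattern(geo8, 9), "exceeds")
})

test_that("patch scale draws are uniform on [1, S] (KS test)", {
  geo <- source_setup(det_rows = 64, det_cols = 64)
  set.seed(42)
  s <- replicate(10000, sample_patch_pattern(geo, 16)$scale_s)
  ks <- suppressWarnings(stats::ks.test(s, "punif", 1, 4))
  expect_gt(ks$p.value, 0.01)
})

test_that("ray bundles have one unit ray per pixel and the right symmetries", {
  geo <- source_setup(det_rows = 128, det_cols = 128)
  pat <- patch_pattern(c(63.5, 63.5), 2, 32, geo)
  rp <- rays_for_patch(geo, pose(0), pat)
  expect_equal(nrow(rp$dirs), 1024)
  expect_equal(max(abs(sqrt(rowSums(rp$dirs^2)) - 1)), 0, tolerance = 1e-9)
  rd <- rays_for_detector(geo, pose(0))
  expect_equal(nrow(rd$dirs), 16384)
  expect_true(all(abs(rd$origins[, 1] - rd$origins[1, 1]) == 0))  # cone beam
  # centered single-pixel pattern: ray passes through the origin
  geo1 <- source_setup(det_rows = 65, det_cols = 65)
  pat1 <- patch_pattern(c(32, 32), 1, 1, geo1)
  r1 <- rays_for_patch(geo1, pose(33, 10), pat1)
  o <- r1$origins[1, ]; d <- r1$dirs[1, ]
  expect_lt(sqrt(sum((o - sum(o * d) * d)^2)), 1e-6)
  # opposite poses give anti-parallel central rays
  r2 <- rays_for_patch(geo1, pose(33 + 180, -10), pat1)
  expect_equal(sum(r1$dirs[1, ] * r2$dirs[1, ]), -1, tolerance = 1e-9)
  # single-pixel detector = the single central ray
  geoa <- source_setup(det_rows = 1, det_cols = 1)
  ra <- rays_for_detector(geoa, pose(90))
  expect_equal(nrow(ra$dirs), 1)
  expect_equal(as.vector(ra$dirs), c(-1, 0, 0), tolerance = 1e-12)
})

test_that("detector magnification follows sid/sad", {
  geo <- source_setup(sad_mm = 570, sid_mm = 1040, det_rows = 33, det_cols = 33)
  f <- tomofield:::pose_frame(geo, pose(25))
  # a centered segment of extent e along the detector u axis at the isocenter
  e <- 100
  for (end in c(-e / 2, e / 2)) {
    p <- end * f$u
    # intersect the ray source -> p with the detector plane
    dd <- p - f$source
    tstar <- geo$sid_mm / sum(dd * f$w)
    hit <- f$source + tstar * dd
    u_coord <- sum((hit - f$det_center) * f$u)
    expect_equal(u_coord, end * geo$sid_mm / geo$sad_mm, tolerance = 1e-9)
  }
})

test_that("a patch covering the full detector reproduces the detector bundle", {
  geo <- source_setup(det_rows = 12, det_cols = 12)
  pat <- patch_pattern(c(5.5, 5.5), 1, 12, geo)
  rp <- rays_for_patch(geo, pose(77, 4), pat)
  rd <- rays_for_detector(geo, pose(77, 4))
  expect_equal(rp$origins, rd$origins)
  expect_equal(rp$dirs, rd$dirs, tolerance = 1e-14)
})

test_that("patterns outside the detector domain are rejected", {
  geo <- source_setup(det_rows = 32, det_cols = 32)
  expect_error(patch_pattern(c(2, 16), 1, 8, geo), "outside")
  expect_error(patch_pattern(c(16, 16), 5, 8, geo), "outside")
  expect_silent(patch_pattern(c(16, 16), 4, 8, geo))
})

test_that("stratified sampling partitions the chord exactly", {
  rays <- list(origins = matrix(c(0, 0, 0), 1), dirs = matrix(c(1, 0, 0), 1),
               t_near = 0, t_far = 4, rows = 1, cols = 1)
  class(rays) <- "ray_bundle"
  set.seed(1)
  ss <- stratified_sample(rays, 4)
  expect_equal(dim(ss$t), c(1, 4))
  for (b in 1:4) {
    expect_gte(ss$t[1, b], b - 1)
    expect_lt(ss$t[1, b], b)
  }
  expect_equal(ss$dt * 4, ss$hit * (4 - 0))
  # q = 1: single sample uniform on the interval
  s1 <- stratified_sample(rays, 1)
  expect_true(s1$t[1, 1] >= 0 && s1$t[1, 1] < 4)
  # missing rays yield no samples
  rays$t_near <- NA_real_; rays$t_far <- NA_real_
  s0 <- stratified_sample(rays, 4)
  expect_equal(nrow(s0$points), 0)
})

test_that("geometry invariants hold: ring closure and bound clipping", {
  geo <- source_setup(det_rows = 8, det_cols = 8)
  g <- voxel_grid(array(1, c(8, 8, 8)), spacing_mm = 10)
  rays <- rays_for_detector(geo, pose(120), bounds = g)
  hit <- ray_hits(rays)
  expect_true(any(hit))
  chords <- rays$t_far[hit] - rays$t_near[hit]
  for (i in which(hit)[1:3]) {
    expect_equal(rays$t_far[i] - rays$t_near[i],
                 box_chord(g$origin_mm, g$origin_mm + g$dims * g$spacing_mm,
                           rays$origins[i, ], rays$dirs[i, ]),
                 tolerance = 1e-9)
  }
})
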