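test_that("real pair extraction is geometrically congruent with rendering", {
  geo <- source_setup(det_rows = 16, det_cols = 16)
  ph <- make_phantom(16, seed = 2)
  p0 <- pose(30)
  drr <- make_drr(ph, geo, p0)
  # full-detector pattern at s = 1: the patch is the projection itself
  pat <- patch_pattern(c(7.5, 7.5), 1, 16, geo)
  pr <- extract_real_pair(ph, drr, p0, geo, pat, q = 8)
  expect_equal(pr$patch, drr, tolerance = 1e-12)
  # V sample lattice is m x m x q; sample count M^2 * Q for all-hit rays
  expect_equal(dim(pr$subvol), c(16, 16, 8))
  expect_equal(nrow(pr$points$points), sum(pr$points$hit) * 8)
  # uniform phantom: V constant inside the object support
  gu <- voxel_grid(array(0.7, c(8, 8, 8)), spacing_mm = 30)
  drr_u <- make_drr(gu, geo, p0)
  pat2 <- patch_pattern(c(7.5, 7.5), 1, 8, geo)
  pu <- extract_real_pair(gu, drr_u, p0, geo, pat2, q = 4)
  inner <- pu$subvol[3:6, 3:6, 2:3]
  expect_true(all(abs(inner - 0.7) < 1e-9))
})

test_that("generated and extracted pairs agree for the ground-truth field", {
  # a field that looks densities up in the phantom reproduces the Siddon
  # patch within stratified-sampling error
  geo <- source_setup(det_rows = 16, det_cols = 16)
  ph <- make_phantom(16, seed = 6)
  p0 <- pose(72)
  pat <- patch_pattern(c(7.5, 7.5), 1, 8, geo)
  rays <- rays_for_patch(geo, p0, pat, bounds = ph)
  set.seed(1)
  r <- render_patch_from_field(grid_lookup_fn(ph), rays, 128)
  ref <- matrix(line_integral(ph, rays), 8, 8, byrow = TRUE)
  expect_lt(max(abs(r$patch - ref)) / max(ref), 0.05)
})

test_that("the augmentation family is deterministic with exact inverses", {
  set.seed(3)
  x2 <- matrix(stats::rnorm(36), 6)
  x3 <- array(stats::rnorm(72), c(6, 6, 2))
  expect_identical(augment(x2, 0), x2)
  expect_identical(augment(x3, 0), x3)
  for (k in 0:4) {
    expect_equal(unaugment(augment(x2, k), k), x2)
    expect_equal(unaugment(augment(x3, k), k), x3)
  }
  # flips are involutions; four 90-degree rotations are the identity
  expect_equal(augment(augment(x2, 1), 1), x2)
  expect_equal(augment(augment(x2, 2), 2), x2)
  r4 <- x2
  for (i in 1:4) r4 <- augment(r4, 3)
  expect_equal(r4, x2)
  # patch and sub-volume transform consistently in the detector plane
  expect_equal(augment(x3, 4)[, , 1], augment(x3[, , 1], 4))
})

test_that("training is reproducible and does not mutate the dataset", {
  ds <- make_dataset(1, dims = 12, n_views = 4, seed = 4,
                     setup = source_setup(det_rows = 12, det_cols = 12))
  snapshot <- ds$patients[[1]]$volume$values
  cfg <- train_config(iters = 8, batch = 1, m = 8, q = 8,
                      disc_channels = c(4, 6), field_cfg = tiny_field_cfg())
  r1 <- train(ds, cfg, seed = 21)
  r2 <- train(ds, cfg, seed = 21)
  expect_identical(r1$history, r2$history)
  expect_identical(unclass(r1$params), unclass(r2$params))
  r3 <- train(ds, cfg, seed = 22)
  expect_false(identical(r1$history$g_loss, r3$history$g_loss))
  expect_identical(ds$patients[[1]]$volume$values, snapshot)
  expect_true(all(is.finite(r1$history$g_loss)))
  expect_error(train(structure(list(patients = list()), class = "ct_dataset"),
                     cfg), "at least one")
})

test_that("discriminators share weights across augmentations but not with each other", {
  ds <- make_dataset(1, dims = 12, n_views = 4, seed = 4,
                     setup = source_setup(det_rows = 12, det_cols = 12))
  cfg <- train_config(iters = 2, batch = 1, m = 8, q = 8,
                      disc_channels = c(4, 6), field_cfg = tiny_field_cfg())
  r <- train(ds, cfg, seed = 5)
  # one parameter set per discriminator; 3D and 2D have distinct shapes
  expect_equal(r$d1$nd, 3)
  expect_equal(r$d2$nd, 2)
  expect_false(identical(dim(r$d1$params$enc1$W), dim(r$d2$params$enc1$W)))
})

test_that("training moves the generator towards the phantom's projections", {
  ds <- make_dataset(1, dims = 12, n_views = 8, seed = 8,
                     setup = source_setup(det_rows = 12, det_cols = 12))
  cfg <- train_config(iters = 150, batch = 2, m = 8, q = 8,
                      disc_channels = c(4, 6), field_cfg = tiny_field_cfg())
  # rendered AP view at the prior mode, before vs after training
  render_ap <- function(params) {
    cds <- list(z_sh = numeric(cfg$field_cfg$m_sh),
                z_a = numeric(cfg$field_cfg$m_a))
    rays <- rays_for_detector(ds$setup, pose(0),
                              bounds = ds$patients[[1]]$volume)
    r <- render_patch_from_field(tomofield:::field_fn(params, pose(0), cds),
                                 rays, 8, jitter = FALSE)
    normalize_01(r$patch)
  }
  set.seed(31)
  init <- init_field(cfg$field_cfg)
  r <- train(ds, cfg, seed = 31)
  ref <- ds$patients[[1]]$drrs[[1]]
  expect_lt(rmse(render_ap(r$params), ref), rmse(render_ap(init), ref))
  # loss history is recorded per iteration and finite
  expect_equal(nrow(r$history), 150)
  expect_true(all(is.finite(r$history$d_loss)))
})

test_that("a field memorizes a fixed patch under the perceptual loss alone", {
  # generator-path smoke oracle: direct optimization against one target
  geo <- source_setup(det_rows = 8, det_cols = 8)
  ph <- make_phantom(12, seed = 9)
  p0 <- pose(0)
  target <- make_drr(ph, geo, p0)
  cfg <- tiny_field_cfg()
  prm <- init_field(cfg, seed = 1)
  cds <- latent_codes(cfg, seed = 1)
  rays <- rays_for_detector(geo, p0, bounds = ph)
  tf <- asNamespace("tomofield")
  idf <- identity_extractor(2)
  opt <- list(p = unclass(prm), z_sh = cds$z_sh, z_a = cds$z_a)
  st <- tf$rmsprop_init(opt)
  set.seed(2)
  loss <- Inf
  for (it in 1:400) {
    prm2 <- structure(opt$p, class = "field_params", config = cfg)
    ss <- stratified_sample(rays, 8, jitter = FALSE)
    fw <- tf$field_forward(prm2, ss$points, p0, list(z_sh = opt$z_sh,
                                                     z_a = opt$z_a))
    pix <- numeric(length(ss$hit))
    pix[ss$hit] <- rowSums(matrix(fw$delta, ncol = 8, byrow = TRUE)) * ss$dt
    raw <- matrix(pix, 8, 8, byrow = TRUE)
    rng <- range(raw); sc <- max(rng[2] - rng[1], 1e-12)
    pred <- (raw - rng[1]) / sc
    pl <- tf$perceptual_loss_grad(pred, target, idf, standardize = FALSE)
    loss <- pl$loss
    if (loss < 1e-3) break
    dpix <- as.vector(t(pl$grad / sc))[ss$hit] * ss$dt
    bk <- tf$field_backward(prm2, fw, rep(dpix, each = 8))
    u <- tf$rmsprop_step(opt, list(p = bk$params, z_sh = bk$z_sh,
                                   z_a = bk$z_a), st, 2e-3)
    opt <- u$p; st <- u$s
  }
  expect_lt(loss, 1e-3)
})
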