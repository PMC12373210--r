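#' Training configuration
#'
#' Hyper-parameters of the adversarial prior-training loop. Defaults follow
#' the standard settings for this architecture: RMSprop with generator step
#' size 5e-4 and discriminator step size 1e-4, batch of 4 (pose, pattern)
#' draws per iteration, 4 extra augmentations weighted by `lambda1 = 0.2`,
#' patch terms weighted by `lambda2 = 0.5`, patch side `m = 32` and `q = 32`
#' samples per ray. Desk-scale experiments shrink `m`, `q`, the iteration
#' budget and the field via `field_cfg`.
#'
#' @param iters Iteration budget.
#' @param batch (pose, pattern) draws averaged per iteration.
#' @param lr_g,lr_d Generator / discriminator RMSprop step sizes.
#' @param n_aug Number of non-identity augmentations n.
#' @param lambda1,lambda2 Loss combination weights.
#' @param m Patch side M (rays per patch = M^2); divisible by 4.
#' @param q Stratified samples per ray; divisible by 4.
#' @param disc_channels Encoder channel widths of both discriminators.
#' @param use_3d Keep the sub-volume (3D-supervision) loss terms
#'   (default `TRUE`; `FALSE` zeroes them, the ablation arm).
#' @param field_cfg A [field_config] for the generator.
#' @param fx_seed Seed of the fixed perceptual extractors.
#' @return An object of class `train_config`.
#' @export
train_config <- function(iters = 500, batch = 4, lr_g = 5e-4, lr_d = 1e-4,
                         n_aug = 4, lambda1 = 0.2, lambda2 = 0.5,
                         m = 32, q = 32, disc_channels = c(8, 16),
                         use_3d = TRUE, field_cfg = field_config(),
                         fx_seed = 1) {
  stopifnot(iters >= 1, batch >= 1, lr_g > 0, lr_d > 0, n_aug >= 2,
            lambda1 >= 0, lambda2 >= 0, m >= 4, q >= 4)
  structure(list(iters = as.integer(iters), batch = as.integer(batch),
                 lr_g = lr_g, lr_d = lr_d, n_aug = as.integer(n_aug),
                 lambda1 = lambda1, lambda2 = lambda2,
                 m = as.integer(m), q = as.integer(q),
                 disc_channels = disc_channels, use_3d = isTRUE(use_3d),
                 field_cfg = field_cfg, fx_seed = fx_seed),
            class = "train_config")
}

# Bilinear sample of image[row, col] at continuous 0-based (col, row)
# coordinates; border-clamped.
bilinear_sample <- function(img, col, row) {
  h <- nrow(img); w <- ncol(img)
  c0 <- pmin(pmax(floor(col), 0), w - 1); r0 <- pmin(pmax(floor(row), 0), h - 1)
  c1 <- pmin(c0 + 1, w - 1); r1 <- pmin(r0 + 1, h - 1)
  fc <- pmin(pmax(col - c0, 0), 1); fr <- pmin(pmax(row - r0, 0), 1)
  v00 <- img[cbind(r0 + 1, c0 + 1)]; v01 <- img[cbind(r0 + 1, c1 + 1)]
  v10 <- img[cbind(r1 + 1, c0 + 1)]; v11 <- img[cbind(r1 + 1, c1 + 1)]
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}

# Arrange per-sample values (ray-major, q per hit ray) into an
# (m_rows, m_cols, q) lattice; rays that missed the volume are zero.
sample_lattice <- function(values, hit, q, rows, cols) {
  full <- numeric(length(hit) * q)
  keep <- rep(hit, each = q)
  full[keep] <- values
  aperm(array(full, c(q, cols, rows)), c(3, 2, 1))
}

# Inverse of sample_lattice for gradients: lattice -> per-sample vector
# (hit rays only).
lattice_to_samples <- function(lat, hit, q) {
  v <- as.vector(aperm(lat, c(3, 2, 1)))
  v[rep(hit, each = q)]
}

#' Extract a real patch / sub-volume training pair
#'
#' Cuts the s-dilated M x M patch out of a real projection at the pattern's
#' continuous center (bilinear interpolation) and samples the ground-truth
#' volume (trilinear) at exactly the ray-by-bin positions the generator
#' renders with, so the real pair (P, V) and the generated pair (P', V') are
#' geometrically congruent. The sub-volume is returned on the fixed
#' `m x m x q` ray-lattice; lattice entries of rays that miss the volume are
#' zero.
#'
#' @param volume A [voxel_grid] (the ground-truth CT).
#' @param projection Matrix, the rendered projection at `pose` (normalized).
#' @param pose A [pose].
#' @param setup A [source_setup].
#' @param pattern A [patch_pattern].
#' @param q Samples per ray (used only when `points` is `NULL`).
#' @param points Optional precomputed stratified sample set (the `ss` list
#'   from [stratified_sample]) to share positions with a generator pass.
#' @return List with `patch` (m x m), `subvol` (m x m x q lattice), `points`.
#' @export
extract_real_pair <- function(volume, projection, pose, setup, pattern,
                              q = 32, points = NULL) {
  validate_pattern(setup, pattern)
  pc <- pattern_pixel_coords(setup, pattern)
  patch <- matrix(bilinear_sample(projection, pc$col, pc$row),
                  pattern$size_m, pattern$size_m, byrow = TRUE)
  if (is.null(points)) {
    rays <- rays_for_patch(setup, pose, pattern, bounds = volume)
    points <- stratified_sample(rays, q)
  }
  vals <- if (nrow(points$points) > 0)
    cpp_trilinear(volume$values, volume$dims, volume$spacing_mm,
                  volume$origin_mm, points$points)
  else numeric(0)
  subvol <- sample_lattice(vals, points$hit, points$q,
                           pattern$size_m, pattern$size_m)
  list(patch = patch, subvol = subvol, points = points)
}

# One discriminator real/fake evaluation with hinge + self-supervised
# reconstruction terms. Inputs already augmented; both are standardized
# internally. Returns loss pieces, parameter grads, and the gradient wrt the
# (unstandardized) fake input for the generator path.
disc_terms <- function(D, real, fake, fx, want_g = TRUE) {
  sr <- standardize(real); sf <- standardize(fake)
  fw_r <- disc_forward(D, sr$z)
  fw_f <- disc_forward(D, sf$z)
  l_h_d <- hinge_loss_d(fw_r$score, fw_f$score)
  rec_err <- fw_r$recon - sr$z
  l_rec <- mean(rec_err^2)
  # D gradients: hinge (real + fake branches) + autoencoder on real
  dsc_r <- if (1 - fw_r$score > 0) -1 else 0
  dsc_f <- if (1 + fw_f$score > 0) 1 else 0
  bk_r <- disc_backward(D, fw_r, dscore = dsc_r,
                        drecon = 2 * rec_err / length(rec_err))
  bk_f <- disc_backward(D, fw_f, dscore = dsc_f)
  g_d <- grad_add(bk_r$grads, bk_f$grads)
  out <- list(l_h_d = l_h_d, l_rec = l_rec, g_d = g_d,
              score_r = fw_r$score, score_f = fw_f$score)
  if (want_g) {
    # Generator terms through a fresh fake pass (same values; reuse fw_f):
    # perceptual between D's decoded reconstruction of the fake and the real
    # target, plus the generator hinge.
    pl <- perceptual_loss_grad(fw_f$recon, sr$z, fx, standardize = TRUE)
    out$l_r <- pl$loss
    out$l_h_g <- hinge_loss_g(fw_f$score)
    bk_g <- disc_backward(D, fw_f, dscore = -1, drecon = pl$grad)
    out$d_fake <- standardize_bwd(sf, bk_g$dx)  # d(loss)/d(fake input)
  }
  out
}

#' Train the generative prior
#'
#' Alternating adversarial training of the conditional density field against
#' the two auto-encoded discriminators on a phantom dataset. Each iteration
#' averages `batch` draws of (patient, pose, patch pattern, latent codes):
#' the generator renders the patch and its sub-volume sample set, the real
#' pair is extracted at the same ray lattice, the augmentation family is
#' applied to both, and the combined objective (sub-volume perceptual +
#' hinge terms, patch terms weighted by `lambda2`, augmented copies by
#' `lambda1/(n-1)`) is backpropagated — discriminators with step size
#' `lr_d`, the field with `lr_g`, both under RMSprop. Poses are drawn from
#' the empirical distribution of the dataset's projection angles. The run is
#' fully reproducible from `seed`.
#'
#' @param dataset A `ct_dataset` from [make_dataset] (>= 1 volume, >= 2
#'   poses).
#' @param cfg A [train_config].
#' @param seed Integer seed.
#' @return List with `params` (trained `field_params`), `d1`, `d2`
#'   (discriminators), and `history` (data.frame of per-iteration generator
#'   and discriminator losses).
#' @export
train <- function(dataset, cfg = train_config(), seed = 1) {
  if (!inherits(dataset, "ct_dataset") || length(dataset$patients) < 1)
    stop("dataset must contain at least one patient volume")
  if (length(dataset$angles_deg) < 2)
    stop("dataset must contain at least two poses")
  setup <- dataset$setup
  m <- cfg$m; q <- cfg$q
  fx2 <- feature_extractor(2, seed = cfg$fx_seed)
  fx3 <- feature_extractor(3, seed = cfg$fx_seed + 1)
  set.seed(seed)
  params <- init_field(cfg$field_cfg)
  d1 <- disc_init(c(m, m, q), cfg$disc_channels)
  d2 <- disc_init(c(m, m), cfg$disc_channels)
  st_g <- rmsprop_init(unclass(params))
  st_d1 <- rmsprop_init(d1$params)
  st_d2 <- rmsprop_init(d2$params)
  n <- cfg$n_aug
  wk <- dag_weights(n, cfg$lambda1)
  hist_g <- hist_d <- numeric(cfg$iters)
  for (it in seq_len(cfg$iters)) {
    acc_g <- NULL; acc_d1 <- NULL; acc_d2 <- NULL
    gl_tot <- dl_tot <- 0
    for (b in seq_len(cfg$batch)) {
      pat <- dataset$patients[[sample.int(length(dataset$patients), 1)]]
      vi <- sample.int(length(pat$poses), 1)
      ps <- pat$poses[[vi]]
      pattern <- sample_patch_pattern(setup, m)
      codes <- list(z_sh = stats::rnorm(cfg$field_cfg$m_sh),
                    z_a = stats::rnorm(cfg$field_cfg$m_a))
      rays <- rays_for_patch(setup, ps, pattern, bounds = pat$volume)
      ss <- stratified_sample(rays, q)
      fw <- field_forward(params, ss$points, ps, codes)
      pix <- numeric(length(ss$hit))
      if (nrow(ss$points) > 0)
        pix[ss$hit] <- rowSums(matrix(fw$delta, ncol = q, byrow = TRUE)) * ss$dt
      p_fake <- matrix(pix, m, m, byrow = TRUE)
      v_fake <- sample_lattice(fw$delta, ss$hit, q, m, m)
      real <- extract_real_pair(pat$volume, pat$drrs[[vi]], ps, setup,
                                pattern, points = ss)
      dP <- matrix(0, m, m); dV <- array(0, c(m, m, q))
      for (k in 0:n) {
        w <- wk[k + 1]
        pr_k <- augment(real$patch, k); pf_k <- augment(p_fake, k)
        t2 <- disc_terms(d2, pr_k, pf_k, fx2)
        dl_k <- cfg$lambda2 * (t2$l_h_d + t2$l_rec)
        gl_k <- cfg$lambda2 * (t2$l_r + t2$l_h_g)
        gd2 <- grad_scale(t2$g_d, w * cfg$lambda2)
        acc_d2 <- if (is.null(acc_d2)) gd2 else grad_add(acc_d2, gd2)
        dP <- dP + w * cfg$lambda2 * unaugment(t2$d_fake, k)
        if (cfg$use_3d) {
          vr_k <- augment(real$subvol, k); vf_k <- augment(v_fake, k)
          t1 <- disc_terms(d1, vr_k, vf_k, fx3)
          dl_k <- dl_k + t1$l_h_d + t1$l_rec
          gl_k <- gl_k + t1$l_r + t1$l_h_g
          gd1 <- grad_scale(t1$g_d, w)
          acc_d1 <- if (is.null(acc_d1)) gd1 else grad_add(acc_d1, gd1)
          dV <- dV + w * unaugment(t1$d_fake, k)
        }
        gl_tot <- gl_tot + w * gl_k
        dl_tot <- dl_tot + w * dl_k
      }
      # route patch and lattice gradients back to the sampled densities
      ddelta <- lattice_to_samples(dV, ss$hit, q)
      dpix <- as.vector(t(dP))[ss$hit] * ss$dt  # row-major pixel -> ray
      ddelta <- ddelta + rep(dpix, each = q)
      bk <- field_backward(params, fw, ddelta)
      acc_g <- if (is.null(acc_g)) bk$params else grad_add(acc_g, bk$params)
    }
    if (!is.finite(gl_tot) || !is.finite(dl_tot))
      stop(sprintf("non-finite loss at iteration %d (g=%g, d=%g)",
                   it, gl_tot, dl_tot))
    upd <- rmsprop_step(unclass(params), grad_scale(acc_g, 1 / cfg$batch),
                        st_g, cfg$lr_g)
    params <- structure(upd$p, class = "field_params",
                        config = cfg$field_cfg)
    st_g <- upd$s
    if (!is.null(acc_d1)) {
      upd1 <- rmsprop_step(d1$params, grad_scale(acc_d1, 1 / cfg$batch),
                           st_d1, cfg$lr_d)
      d1$params <- upd1$p; st_d1 <- upd1$s
    }
    upd2 <- rmsprop_step(d2$params, grad_scale(acc_d2, 1 / cfg$batch),
                         st_d2, cfg$lr_d)
    d2$params <- upd2$p; st_d2 <- upd2$s
    hist_g[it] <- gl_tot / cfg$batch
    hist_d[it] <- dl_tot / cfg$batch
  }
  list(params = params, d1 = d1, d2 = d2,
       history = data.frame(iter = seq_len(cfg$iters),
                            g_loss = hist_g, d_loss = hist_d))
}
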