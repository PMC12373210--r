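#' Patient-specific fine-tuning on sparse-view projections
#'
#' Adapts field parameters (a trained prior or a fresh initialization) and
#' the latent codes to a specific subject's sparse projections. Each
#' iteration draws one reference view uniformly at random, renders the full
#' detector (one ray per pixel) from the current field, and takes an RMSprop
#' step on the combined perceptual / PSNR-hinge / Gaussian-likelihood
#' objective ([inference_loss]). Optimization stops once the rendered
#' projections reach `stop_psnr` dB against every reference view (checked
#' every `check_every` iterations on deterministic bin midpoints), or at
#' `max_iter`. Rendered projections are min-max normalized before comparison
#' with the [0,1] references; the normalization bounds are treated as
#' constants in the gradient.
#'
#' @param params A `field_params` object (prior or [init_field] output).
#' @param codes A [latent_codes]; optimized jointly with the weights.
#' @param projections List of reference projection matrices ([0,1]).
#' @param poses List of [pose] objects, one per projection.
#' @param setup A [source_setup].
#' @param bounds Reconstruction bounding box: a [voxel_grid] or 2 x 3
#'   `rbind(lo, hi)` matrix in mm defining where the field is supported.
#' @param q Stratified samples per ray (default 16).
#' @param stop_psnr Stopping threshold in dB (default 25); must hold on all
#'   views. `stop_mode = "any"` relaxes this to at least one view.
#' @param max_iter Iteration cap (default 1000).
#' @param lr RMSprop step size (default 5e-4).
#' @param fx 2D [feature_extractor] for the perceptual term.
#' @param lambda1,lambda2,lambda3 [inference_loss] weights.
#' @param check_every Stopping-rule check interval (default 25).
#' @param stop_mode `"all"` (default) or `"any"`.
#' @param seed Integer seed; the run is fully reproducible.
#' @param verbose Print progress.
#' @return List with tuned `params`, `codes`, `history` (data.frame of
#'   iteration, loss, view index, view PSNR), `final_psnr` (per view),
#'   `iterations`, and `converged`.
#' @export
finetune <- function(params, codes, projections, poses, setup, bounds,
                     q = 16, stop_psnr = 25, max_iter = 1000, lr = 5e-4,
                     fx = feature_extractor(2),
                     lambda1 = 0.3, lambda2 = 0.1, lambda3 = 0.3,
                     check_every = 25, stop_mode = c("all", "any"),
                     seed = 1, verbose = FALSE) {
  stop_mode <- match.arg(stop_mode)
  nv <- length(projections)
  if (nv < 1) stop("at least one reference projection is required")
  if (length(poses) != nv) stop("projections and poses must pair up")
  cfg <- attr(params, "config")
  set.seed(seed)
  ray_sets <- lapply(poses, function(ps)
    rays_for_detector(setup, ps, bounds = bounds))
  opt <- list(p = unclass(params), z_sh = codes$z_sh, z_a = codes$z_a)
  st <- rmsprop_init(opt)
  it_hist <- list()
  converged <- FALSE
  psnr_all <- rep(-Inf, nv)
  render_view <- function(p, v, jitter) {
    prm <- structure(p$p, class = "field_params", config = cfg)
    cds <- list(z_sh = p$z_sh, z_a = p$z_a)
    rays <- ray_sets[[v]]
    ss <- stratified_sample(rays, q, jitter = jitter)
    fw <- field_forward(prm, ss$points, poses[[v]], cds)
    pix <- numeric(length(ss$hit))
    pix[ss$hit] <- rowSums(matrix(fw$delta, ncol = q, byrow = TRUE)) * ss$dt
    raw <- matrix(pix, ss$rows, ss$cols, byrow = TRUE)
    list(raw = raw, fw = fw, ss = ss)
  }
  check_stop <- function(p) {
    for (v in seq_len(nv)) {
      r <- render_view(p, v, jitter = FALSE)
      psnr_all[v] <<- psnr(normalize_01(r$raw), projections[[v]], 1)
    }
    if (stop_mode == "all") all(psnr_all >= stop_psnr)
    else any(psnr_all >= stop_psnr)
  }
  it <- 0L
  if (check_stop(opt)) converged <- TRUE
  while (!converged && it < max_iter) {
    it <- it + 1L
    v <- sample.int(nv, 1)
    r <- render_view(opt, v, jitter = TRUE)
    rng <- range(r$raw)
    scale <- if (rng[2] - rng[1] > 0) rng[2] - rng[1] else 1
    pred <- (r$raw - rng[1]) / scale
    lg <- inference_loss_grad(pred, projections[[v]], fx,
                              lambda1, lambda2, lambda3, stop_psnr)
    # straight-through the min-max normalization
    draw <- lg$grad / scale
    dpix <- as.vector(t(draw))[r$ss$hit] * r$ss$dt
    ddelta <- rep(dpix, each = q)
    bk <- field_backward(structure(opt$p, class = "field_params",
                                   config = cfg), r$fw, ddelta)
    grads <- list(p = bk$params, z_sh = bk$z_sh, z_a = bk$z_a)
    upd <- rmsprop_step(opt, grads, st, lr)
    opt <- upd$p; st <- upd$s
    it_hist[[it]] <- c(iter = it, loss = lg$loss, view = v, psnr = lg$psnr)
    if (it %% check_every == 0) {
      if (check_stop(opt)) converged <- TRUE
      if (verbose)
        message(sprintf("iter %d: loss %.4f, view PSNR %s dB", it, lg$loss,
                        paste(sprintf("%.1f", psnr_all), collapse = "/")))
    }
  }
  if (!converged) check_stop(opt)  # record final per-view PSNR
  list(params = structure(opt$p, class = "field_params", config = cfg),
       codes = structure(list(z_sh = opt$z_sh, z_a = opt$z_a),
                         class = "latent_codes"),
       history = as.data.frame(do.call(rbind, it_hist)),
       final_psnr = psnr_all, iterations = it, converged = converged)
}

#' Render the full volume from a fitted field
#'
#' Evaluates the density field at every voxel center of the requested grid
#' (the pose input is fixed to the canonical AP view when view conditioning
#' is enabled), producing the reconstructed volume. Densities are
#' non-negative by construction; the volume is scaled by its maximum into
#' [0, 1] to match the data convention (a constant field renders to a
#' constant volume, and the physical zero of air is preserved).
#'
#' @param params A `field_params` object.
#' @param codes A [latent_codes].
#' @param dims Voxel counts (scalar or length 3).
#' @param fov_mm Physical edge length (default 320 mm).
#' @param ref_pose Conditioning pose (default AP).
#' @param normalize Scale by the maximum (default `TRUE`).
#' @return A [voxel_grid].
#' @export
render_volume <- function(params, codes, dims, fov_mm = 320,
                          ref_pose = pose(0), normalize = TRUE) {
  dims <- rep(as.integer(dims), length.out = 3)
  spacing <- fov_mm / dims
  cx <- (seq_len(dims[1]) - 0.5) * spacing[1] - fov_mm / 2
  cy <- (seq_len(dims[2]) - 0.5) * spacing[2] - fov_mm / 2
  cz <- (seq_len(dims[3]) - 0.5) * spacing[3] - fov_mm / 2
  pts <- cbind(rep(cx, times = dims[2] * dims[3]),
               rep(rep(cy, each = dims[1]), times = dims[3]),
               rep(cz, each = dims[1] * dims[2]))
  dens <- field_density(params, pts, ref_pose, codes)
  vals <- array(pmax(dens, 0), dims)
  if (normalize && max(vals) > 0) vals <- vals / max(vals)
  voxel_grid(vals, spacing_mm = spacing)
}

#' Reconstruct a CT volume from sparse projections
#'
#' The full inference pipeline: patient-specific fine-tuning of a field on
#' the supplied projections, followed by full-volume rendering, and — when a
#' reference volume is given — a PSNR/SSIM/RMSE report against it.
#'
#' @param projections List of projection matrices ([0,1]).
#' @param poses List of [pose]s, one per projection.
#' @param setup A [source_setup].
#' @param params Starting `field_params` (default: fresh [init_field] from
#'   `field_cfg`).
#' @param codes Starting [latent_codes] (default: drawn from the prior).
#' @param field_cfg Used when `params` is `NULL`.
#' @param dims Output volume voxel counts.
#' @param fov_mm Physical edge length of the reconstruction (default 320).
#' @param ref_volume Optional ground-truth [voxel_grid] for the metric
#'   report.
#' @param seed Integer seed.
#' @param ... Passed to [finetune] (`q`, `stop_psnr`, `max_iter`, ...).
#' @return List with `volume` (a [voxel_grid]), `params`, `codes`, `fit`
#'   (the [finetune] result) and `metrics` (`NULL` without a reference).
#' @export
reconstruct <- function(projections, poses, setup, params = NULL,
                        codes = NULL, field_cfg = field_config(),
                        dims = 128, fov_mm = 320, ref_volume = NULL,
                        seed = 1, ...) {
  if (is.null(params)) {
    set.seed(seed)
    params <- init_field(field_cfg)
  }
  cfg <- attr(params, "config")
  if (is.null(codes)) codes <- latent_codes(cfg)
  bounds <- rbind(rep(-fov_mm / 2, 3), rep(fov_mm / 2, 3))
  fit <- finetune(params, codes, projections, poses, setup, bounds,
                  seed = seed, ...)
  vol <- render_volume(fit$params, fit$codes, dims, fov_mm)
  metrics <- if (!is.null(ref_volume))
    metric_report(vol$values, ref_volume$values)
  list(volume = vol, params = fit$params, codes = fit$codes,
       fit = fit, metrics = metrics)
}
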