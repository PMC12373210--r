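#' Positional encoding specification
#'
#' The standard NeRF frequency encoding: each input component `p` is expanded
#' to `sin(2^k * pi * p), cos(2^k * pi * p)` for `k = 0 .. n_freq - 1`, with
#' the raw component optionally prepended. Inputs are expected pre-scaled to
#' order 1 (see `coord_scale_mm` in [field_config]).
#'
#' @param n_freq_x Frequency count for 3D locations (default 10).
#' @param n_freq_xi Frequency count for poses (default 4).
#' @param include_identity Prepend the raw components (default `FALSE`).
#' @return An object of class `encoding_spec`.
#' @export
encoding_spec <- function(n_freq_x = 10, n_freq_xi = 4,
                          include_identity = FALSE) {
  stopifnot(n_freq_x >= 0, n_freq_xi >= 0)
  structure(list(n_freq_x = as.integer(n_freq_x),
                 n_freq_xi = as.integer(n_freq_xi),
                 include_identity = isTRUE(include_identity)),
            class = "encoding_spec")
}

#' Frequency-encode a batch of vectors
#'
#' @param p Numeric matrix (n x d) or vector (treated as one row).
#' @param n_freq Number of octaves L; output has `d * (2L + identity)` columns
#'   ordered `[p,] sin(2^0 pi p), cos(2^0 pi p), sin(2^1 pi p), ...`.
#' @param include_identity Prepend the raw components.
#' @return Numeric matrix n x d*(2L + identity).
#' @export
positional_encode <- function(p, n_freq, include_identity = FALSE) {
  if (!is.matrix(p)) p <- matrix(p, nrow = 1)
  stopifnot(all(is.finite(p)))
  parts <- if (include_identity) list(p) else list()
  if (n_freq > 0)
    for (k in seq_len(n_freq) - 1) {
      a <- 2^k * pi * p
      parts <- c(parts, list(sin(a)), list(cos(a)))
    }
  if (length(parts) == 0) return(p[, 0, drop = FALSE])
  do.call(cbind, parts)
}

encoded_dim <- function(d, n_freq, include_identity = FALSE)
  d * (2L * n_freq + as.integer(include_identity))

# Pose angles scaled so that the base frequency sin(pi * p) is 2*pi-periodic
# in the physical angle.
encode_pose <- function(pose, spec) {
  p <- c(pose$theta_deg / 180, pose$phi_deg / 180)
  positional_encode(p, spec$n_freq_xi, spec$include_identity)
}

#' Configuration of the conditional density field
#'
#' The field is a fully connected coordinate network: a shape branch maps the
#' encoded location together with the shape code to a hidden feature `h`; a
#' density head maps `h`, the encoded pose, and the appearance code to a
#' non-negative attenuation density (through a softplus output map).
#' Conditioning the head on the pose and the appearance code mirrors the
#' generative-field design; X-ray attenuation itself is view-independent, so
#' both can be switched off with `use_view` / `use_appearance`.
#'
#' @param h_layers,h_width Depth and width of the shape branch (ReLU).
#' @param d_layers,d_width Depth and width of the density head; the last
#'   layer is linear into softplus.
#' @param m_sh,m_a Lengths of the shape and appearance latent codes.
#' @param enc An [encoding_spec].
#' @param coord_scale_mm Locations are divided by this before encoding so the
#'   volume of interest maps to roughly `[-1, 1]` (default 160 mm, half of a
#'   320 mm thorax field of view).
#' @param use_view,use_appearance Feed the encoded pose / appearance code to
#'   the density head (default `TRUE`, the generative-field design).
#' @return An object of class `field_config`.
#' @export
field_config <- function(h_layers = 8, h_width = 128,
                         d_layers = 2, d_width = 128,
                         m_sh = 128, m_a = 32,
                         enc = encoding_spec(),
                         coord_scale_mm = 160,
                         use_view = TRUE, use_appearance = TRUE) {
  stopifnot(h_layers >= 1, h_width >= 1, d_layers >= 1, d_width >= 1,
            m_sh >= 0, m_a >= 0, coord_scale_mm > 0)
  structure(list(h_layers = as.integer(h_layers), h_width = as.integer(h_width),
                 d_layers = as.integer(d_layers), d_width = as.integer(d_width),
                 m_sh = as.integer(m_sh), m_a = as.integer(m_a),
                 enc = enc, coord_scale_mm = coord_scale_mm,
                 use_view = isTRUE(use_view),
                 use_appearance = isTRUE(use_appearance)),
            class = "field_config")
}

#' Latent shape and appearance codes
#'
#' Drawn from standard Gaussian priors; the shape code conditions the shape
#' branch, the appearance code the density head. Both are optimized jointly
#' with the network during patient-specific fine-tuning.
#'
#' @param config A [field_config] (provides the code lengths).
#' @param seed Optional integer seed for a reproducible draw.
#' @return An object of class `latent_codes` with `z_sh` and `z_a`.
#' @export
latent_codes <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  structure(list(z_sh = stats::rnorm(config$m_sh),
                 z_a = stats::rnorm(config$m_a)),
            class = "latent_codes")
}

#' Initialize field parameters
#'
#' He-initialized weights for the shape branch and density head, fully
#' determined by the seed.
#'
#' @param config A [field_config].
#' @param seed Optional integer seed.
#' @return An object of class `field_params` (nested list of weight
#'   matrices), carrying the config as attribute `config`.
#' @export
init_field <- function(config = field_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  enc_x_dim <- encoded_dim(3L, config$enc$n_freq_x, config$enc$include_identity)
  enc_xi_dim <- encoded_dim(2L, config$enc$n_freq_xi, config$enc$include_identity)
  h_in <- enc_x_dim + config$m_sh
  hs <- list()
  for (i in seq_len(config$h_layers)) {
    hs[[i]] <- nn_dense(if (i == 1) h_in else config$h_width, config$h_width)
  }
  d_in <- config$h_width +
    (if (config$use_view) enc_xi_dim else 0L) +
    (if (config$use_appearance) config$m_a else 0L)
  ds <- list()
  for (i in seq_len(config$d_layers)) {
    n_in <- if (i == 1) d_in else config$d_width
    n_out <- if (i == config$d_layers) 1L else config$d_width
    ds[[i]] <- nn_dense(n_in, n_out)
  }
  structure(list(h = hs, d = ds),
            class = "field_params", config = config)
}

#' @export
print.field_params <- function(x, ...) {
  cfg <- attr(x, "config")
  npar <- sum(rapply(unclass(x), length, how = "unlist"))
  cat(sprintf("<field_params> shape branch %d x %d, density head %d layers, %d parameters\n",
              cfg$h_layers, cfg$h_width, cfg$d_layers, npar))
  invisible(x)
}

# Full forward pass with caches for backprop.
# x: n x 3 points in mm; pose: a pose object; codes: latent_codes.
field_forward <- function(params, x, pose, codes) {
  cfg <- attr(params, "config")
  n <- nrow(x)
  enc_x <- positional_encode(x / cfg$coord_scale_mm, cfg$enc$n_freq_x,
                             cfg$enc$include_identity)
  Xh <- cbind(enc_x, matrix(codes$z_sh, n, cfg$m_sh, byrow = TRUE))
  h_caches <- vector("list", length(params$h))
  A <- Xh
  for (i in seq_along(params$h)) {
    cc <- dense_fwd(params$h[[i]], A)
    h_caches[[i]] <- cc
    A <- relu(cc$Z)
  }
  hfeat <- A
  enc_xi <- encode_pose(pose, cfg$enc)
  Xd <- hfeat
  if (cfg$use_view) Xd <- cbind(Xd, matrix(enc_xi, n, length(enc_xi), byrow = TRUE))
  if (cfg$use_appearance) Xd <- cbind(Xd, matrix(codes$z_a, n, cfg$m_a, byrow = TRUE))
  d_caches <- vector("list", length(params$d))
  A <- Xd
  for (i in seq_along(params$d)) {
    cc <- dense_fwd(params$d[[i]], A)
    d_caches[[i]] <- cc
    A <- if (i == length(params$d)) softplus(cc$Z) else relu(cc$Z)
  }
  delta <- as.vector(A)
  list(delta = delta, h_caches = h_caches, d_caches = d_caches,
       n = n, cfg = cfg,
       dims = list(enc_x = ncol(enc_x), enc_xi = length(enc_xi),
                   hw = ncol(hfeat)))
}

# Backward pass: ddelta is d(loss)/d(density), length n.
# Returns gradients for params plus the latent codes.
field_backward <- function(params, fw, ddelta) {
  cfg <- fw$cfg
  nd <- length(params$d)
  dA <- matrix(ddelta, fw$n, 1) * dsoftplus(fw$d_caches[[nd]]$Z)
  g_d <- vector("list", nd)
  for (i in rev(seq_len(nd))) {
    bb <- dense_bwd(params$d[[i]], fw$d_caches[[i]], dA)
    g_d[[i]] <- list(W = bb$dW, b = bb$db)
    dA <- bb$dX
    if (i > 1) dA <- dA * drelu(fw$d_caches[[i - 1]]$Z)
  }
  # split the density-head input gradient
  hw <- fw$dims$hw
  dXd <- dA
  dh <- dXd[, seq_len(hw), drop = FALSE]
  col0 <- hw
  dz_a <- numeric(cfg$m_a)
  if (cfg$use_view) col0 <- col0 + fw$dims$enc_xi
  if (cfg$use_appearance && cfg$m_a > 0)
    dz_a <- colSums(dXd[, col0 + seq_len(cfg$m_a), drop = FALSE])
  nh <- length(params$h)
  dA <- dh * drelu(fw$h_caches[[nh]]$Z)
  g_h <- vector("list", nh)
  for (i in rev(seq_len(nh))) {
    bb <- dense_bwd(params$h[[i]], fw$h_caches[[i]], dA)
    g_h[[i]] <- list(W = bb$dW, b = bb$db)
    dA <- bb$dX
    if (i > 1) dA <- dA * drelu(fw$h_caches[[i - 1]]$Z)
  }
  dz_sh <- if (cfg$m_sh > 0)
    colSums(dA[, fw$dims$enc_x + seq_len(cfg$m_sh), drop = FALSE])
  else numeric(0)
  list(params = list(h = g_h, d = g_d), z_sh = dz_sh, z_a = dz_a)
}

#' Evaluate the conditional density field
#'
#' Runs the coordinate network at a batch of 3D points for a given pose and
#' latent codes. Evaluation is deterministic, chunked to bound memory, and
#' the softplus output map guarantees non-negative densities.
#'
#' @param params A `field_params` object from [init_field].
#' @param x Point matrix (n x 3, mm) or a length-3 vector.
#' @param pose A [pose] (conditioning view).
#' @param codes A [latent_codes].
#' @param chunk Points per evaluation chunk (default 65536).
#' @return Numeric vector of n densities, all `>= 0`.
#' @export
field_density <- function(params, x, pose, codes, chunk = 65536L) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 3)
  if (ncol(x) != 3) stop("x must have 3 columns")
  n <- nrow(x)
  if (n == 0) return(numeric(0))
  out <- numeric(n)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    out[s:e] <- field_forward(params, x[s:e, , drop = FALSE], pose, codes)$delta
  }
  out
}

# Convenience: a field_fn closure for render_patch_from_field().
field_fn <- function(params, pose, codes) {
  force(params); force(pose); force(codes)
  function(pts) field_density(params, pts, pose, codes)
}
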