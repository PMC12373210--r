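# Auto-encoded convolutional discriminators. Each discriminator is a small
# symmetric encoder-decoder: two strided convolutions down, a linear score
# head on the bottleneck (the real/fake classification), and a mirrored
# nearest-neighbour-upsampling decoder whose output reconstructs the input
# (the self-supervision signal). The first decoded feature map is the tap
# used by the perceptual loss. One 3D instance consumes sub-volume sample
# lattices, one 2D instance consumes projection patches; the two have
# separate weights, while each single instance is shared across all
# augmentations and sample locations.

disc_init <- function(in_dims, channels = c(8, 16), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nd <- length(in_dims)
  stopifnot(nd %in% c(2, 3), length(channels) == 2)
  c1 <- channels[1]; c2 <- channels[2]
  dims1 <- (in_dims + 2 - 3) %/% 2 + 1
  dims2 <- (dims1 + 2 - 3) %/% 2 + 1
  if (!all(dims1 * 2 == in_dims) || !all(dims2 * 2 == dims1))
    stop("discriminator input dims must halve cleanly twice (divisible by 4)")
  params <- list(enc1 = nn_conv(1, c1, 3, nd),
                 enc2 = nn_conv(c1, c2, 3, nd),
                 score = nn_dense(prod(dims2) * c2, 1, scale = 0.05),
                 dec1 = nn_conv(c2, c1, 3, nd),
                 dec2 = nn_conv(c1, 1, 3, nd))
  plans <- list(enc1 = conv_plan(in_dims, 1, 3, 2, 1),
                enc2 = conv_plan(dims1, c1, 3, 2, 1),
                dec1 = conv_plan(dims1, c2, 3, 1, 1),
                dec2 = conv_plan(in_dims, c1, 3, 1, 1))
  structure(list(params = params, plans = plans, in_dims = in_dims, nd = nd,
                 channels = channels),
            class = "discriminator")
}

#' @export
print.discriminator <- function(x, ...) {
  cat(sprintf("<discriminator> %dD auto-encoded CNN, input %s, channels %s\n",
              x$nd, paste(x$in_dims, collapse = "x"),
              paste(x$channels, collapse = ",")))
  invisible(x)
}

# x: array of shape in_dims (already standardized). Returns score (scalar),
# recon (same shape as x), feat (decoded tap) and caches.
disc_forward <- function(D, x) {
  p <- D$params; pl <- D$plans
  xa <- array(x, c(D$in_dims, 1L))
  c_e1 <- conv_fwd(p$enc1, xa, pl$enc1); a1 <- lrelu(c_e1$out)
  c_e2 <- conv_fwd(p$enc2, a1, pl$enc2); a2 <- lrelu(c_e2$out)
  flat <- matrix(as.vector(a2), 1)
  c_sc <- dense_fwd(p$score, flat)
  score <- as.numeric(c_sc$Z)
  u1 <- upsample2_fwd(a2)
  c_d1 <- conv_fwd(p$dec1, u1, pl$dec1); f1 <- lrelu(c_d1$out)
  u2 <- upsample2_fwd(f1)
  c_d2 <- conv_fwd(p$dec2, u2, pl$dec2)
  recon <- array(c_d2$out, D$in_dims)
  list(score = score, recon = recon, feat = f1,
       c_e1 = c_e1, c_e2 = c_e2, c_sc = c_sc, c_d1 = c_d1, c_d2 = c_d2,
       a1 = a1, a2 = a2, u1 = u1, f1 = f1)
}

# Backprop given upstream gradients on score / recon / feat (any may be 0 /
# NULL). Returns parameter gradients and the gradient wrt the input array.
disc_backward <- function(D, fw, dscore = 0, drecon = NULL, dfeat = NULL) {
  p <- D$params; pl <- D$plans
  g <- list()
  # decoder path
  if (is.null(drecon)) drecon <- array(0, D$in_dims)
  dd2 <- conv_bwd(p$dec2, fw$c_d2, array(drecon, c(D$in_dims, 1L)), pl$dec2)
  g$dec2 <- list(W = dd2$dW, b = dd2$db)
  df1 <- upsample2_bwd(dd2$dX, dim(fw$f1))
  if (!is.null(dfeat)) df1 <- df1 + dfeat
  dd1_in <- df1 * dlrelu(fw$c_d1$out)
  dd1 <- conv_bwd(p$dec1, fw$c_d1, dd1_in, pl$dec1)
  g$dec1 <- list(W = dd1$dW, b = dd1$db)
  da2_dec <- upsample2_bwd(dd1$dX, dim(fw$a2))
  # score path
  dflat <- matrix(0, 1, ncol(fw$c_sc$X))
  dsc <- dense_bwd(p$score, fw$c_sc, matrix(dscore, 1, 1))
  g$score <- list(W = dsc$dW, b = dsc$db)
  da2 <- da2_dec + array(dsc$dX, dim(fw$a2))
  # encoder
  de2_in <- da2 * dlrelu(fw$c_e2$out)
  de2 <- conv_bwd(p$enc2, fw$c_e2, de2_in, pl$enc2)
  g$enc2 <- list(W = de2$dW, b = de2$db)
  da1 <- de2$dX * dlrelu(fw$c_e1$out)
  de1 <- conv_bwd(p$enc1, fw$c_e1, da1, pl$enc1)
  g$enc1 <- list(W = de1$dW, b = de1$db)
  # match the parameter list order (walked positionally by the optimizer)
  list(grads = g[names(p)], dx = array(de1$dX, D$in_dims))
}

# --- deterministic augmentation family -------------------------------------

#' Deterministic flip/rotation augmentation
#'
#' The fixed per-index family used by the augmentation-averaged GAN loss:
#' `k = 0` identity, `k = 1` horizontal flip, `k = 2` vertical flip,
#' `k = 3` 90-degree rotation, `k = 4` 180-degree rotation — applied in the
#' detector plane, i.e. to a patch's two axes or to the first two axes of a
#' sub-volume sample lattice, so patch and sub-volume stay congruent.
#' `unaugment()` applies the inverse (used to route gradients back).
#'
#' @param x Matrix (patch) or 3D array (sub-volume lattice).
#' @param k Augmentation index 0-4.
#' @return Transformed array of the same shape.
#' @export
augment <- function(x, k) {
  stopifnot(k %in% 0:4)
  nd <- length(dim(x))
  m <- dim(x)[1]
  stopifnot(dim(x)[2] == m)  # rotations need square patch axes
  f <- switch(as.character(k),
    "0" = function(a) a,
    "1" = function(a) a[, m:1, drop = FALSE],
    "2" = function(a) a[m:1, , drop = FALSE],
    "3" = function(a) aperm2(a)[m:1, , drop = FALSE],
    "4" = function(a) a[m:1, m:1, drop = FALSE])
  apply_plane(x, f, nd)
}

#' @rdname augment
#' @export
unaugment <- function(x, k) {
  stopifnot(k %in% 0:4)
  nd <- length(dim(x))
  m <- dim(x)[1]
  f <- switch(as.character(k),
    "0" = function(a) a,
    "1" = function(a) a[, m:1, drop = FALSE],
    "2" = function(a) a[m:1, , drop = FALSE],
    "3" = function(a) aperm2(a[m:1, , drop = FALSE]),
    "4" = function(a) a[m:1, m:1, drop = FALSE])
  apply_plane(x, f, nd)
}

aperm2 <- function(a) t(a)

apply_plane <- function(x, f, nd) {
  if (nd == 2) return(f(x))
  out <- x
  for (q in seq_len(dim(x)[3])) out[, , q] <- f(x[, , q, drop = TRUE])
  out
}
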