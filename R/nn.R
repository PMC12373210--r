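# Minimal neural-network primitives with explicit forward/backward passes.
# Everything here is plain R arrays + BLAS matmul; no global state. Layers
# are parameter lists, forward passes return caches, backward passes return
# gradients shaped like the parameters. Sufficient for the small MLPs and
# conv encoder-decoders used by the field, feature extractors and
# discriminators.

relu <- function(z) (z + abs(z)) * 0.5
drelu <- function(z) z > 0
lrelu <- function(z, a = 0.2) {
  pos <- (z + abs(z)) * 0.5
  pos + a * (z - pos)
}
dlrelu <- function(z, a = 0.2) a + (1 - a) * (z > 0)
# numerically stable softplus: max(z, 0) + log1p(exp(-|z|))
softplus <- function(z) (z + abs(z)) * 0.5 + log1p(exp(-abs(z)))
dsoftplus <- function(z) 1 / (1 + exp(-z))

nn_dense <- function(n_in, n_out, scale = sqrt(2 / n_in)) {
  list(W = matrix(stats::rnorm(n_in * n_out, 0, scale), n_in, n_out),
       b = numeric(n_out))
}

dense_fwd <- function(layer, X) {
  Z <- X %*% layer$W
  Z <- Z + rep(layer$b, each = nrow(Z))
  list(Z = Z, X = X)
}

dense_bwd <- function(layer, cache, dZ) {
  list(dW = crossprod(cache$X, dZ),
       db = colSums(dZ),
       dX = tcrossprod(dZ, layer$W))
}

# --- standardization (the G / T pre-processing maps) -----------------------

standardize <- function(x, eps = 1e-8) {
  mu <- mean(x)
  sdv <- sqrt(mean((x - mu)^2) + eps)
  list(z = (x - mu) / sdv, mu = mu, sd = sdv)
}

# Exact gradient of a loss through z = (x - mu) / sd with mu, sd functions
# of x (population statistics).
standardize_bwd <- function(st, dz) {
  n <- length(st$z)
  (dz - mean(dz) - st$z * mean(dz * st$z)) / st$sd
}

# --- im2col convolutions ---------------------------------------------------

# Precompute the gather index for an N-d im2col with zero padding.
# dims_in: spatial dims; c_in channels; k kernel side; st stride; pad cells.
conv_plan <- function(dims_in, c_in, k, st, pad) {
  nd <- length(dims_in)
  dims_pad <- dims_in + 2 * pad
  dims_out <- (dims_pad - k) %/% st + 1
  starts <- lapply(dims_out, function(n) (seq_len(n) - 1) * st)
  # linear index of every output-position corner in the padded array
  corner <- as.matrix(expand.grid(starts))           # n_out x nd, 0-based
  offs <- as.matrix(expand.grid(rep(list(seq_len(k) - 1), nd)))  # k^nd x nd
  mult <- cumprod(c(1, dims_pad[-nd]))
  corner_lin <- as.vector(corner %*% mult)           # n_out
  off_lin <- as.vector(offs %*% mult)                # k^nd
  base <- outer(corner_lin, off_lin, "+") + 1        # n_out x k^nd, 1-based
  # replicate across input channels (channel-major blocks of columns)
  chan_stride <- prod(dims_pad)
  idx <- matrix(0L, nrow(base), ncol(base) * c_in)
  for (c in seq_len(c_in))
    idx[, (c - 1) * ncol(base) + seq_len(ncol(base))] <-
      base + (c - 1) * chan_stride
  list(idx = idx, dims_in = dims_in, dims_pad = dims_pad,
       dims_out = dims_out, c_in = c_in, k = k, st = st, pad = pad, nd = nd)
}

pad_array <- function(x, plan) {
  if (plan$pad == 0) return(x)
  out <- array(0, c(plan$dims_pad, plan$c_in))
  p <- plan$pad
  ix <- lapply(plan$dims_in, function(n) p + seq_len(n))
  if (plan$nd == 2) out[ix[[1]], ix[[2]], ] <- x
  else out[ix[[1]], ix[[2]], ix[[3]], ] <- x
  out
}

unpad_grad <- function(dpad, plan) {
  if (plan$pad == 0) return(dpad)
  p <- plan$pad
  ix <- lapply(plan$dims_in, function(n) p + seq_len(n))
  if (plan$nd == 2) dpad[ix[[1]], ix[[2]], , drop = FALSE]
  else dpad[ix[[1]], ix[[2]], ix[[3]], , drop = FALSE]
}

nn_conv <- function(c_in, c_out, k, nd, scale = NULL) {
  fan_in <- c_in * k^nd
  if (is.null(scale)) scale <- sqrt(2 / fan_in)
  list(W = matrix(stats::rnorm(fan_in * c_out, 0, scale), fan_in, c_out),
       b = numeric(c_out))
}

# x: array c(spatial..., c_in). Returns array c(spatial_out..., c_out).
conv_fwd <- function(layer, x, plan) {
  xp <- pad_array(x, plan)
  cols <- matrix(xp[plan$idx], nrow(plan$idx), ncol(plan$idx))
  Z <- cols %*% layer$W
  Z <- Z + rep(layer$b, each = nrow(Z))
  out <- array(Z, c(plan$dims_out, ncol(layer$W)))
  list(out = out, cols = cols, Z = Z)
}

conv_bwd <- function(layer, cache, dout, plan) {
  dZ <- matrix(dout, nrow(cache$Z), ncol(cache$Z))
  dW <- crossprod(cache$cols, dZ)
  db <- colSums(dZ)
  dcols <- tcrossprod(dZ, layer$W)
  dpad <- array(0, c(plan$dims_pad, plan$c_in))
  for (j in seq_len(ncol(plan$idx))) {
    ii <- plan$idx[, j]
    dpad[ii] <- dpad[ii] + dcols[, j]
  }
  list(dW = dW, db = db, dX = unpad_grad(dpad, plan))
}

# --- nearest-neighbour upsampling (x2 per spatial axis) --------------------

upsample2_fwd <- function(x) {
  d <- dim(x)
  nd <- length(d) - 1
  rep_idx <- lapply(d[seq_len(nd)], function(n) rep(seq_len(n), each = 2))
  if (nd == 2) x[rep_idx[[1]], rep_idx[[2]], , drop = FALSE]
  else x[rep_idx[[1]], rep_idx[[2]], rep_idx[[3]], , drop = FALSE]
}

upsample2_bwd <- function(dout, dims_in) {
  nd <- length(dims_in) - 1
  d <- dims_in
  dd <- dim(dout)
  if (nd == 2) {
    arr <- array(dout, c(2, d[1], 2, d[2], d[3]))
    array(colSums(aperm(arr, c(1, 3, 2, 4, 5)), dims = 2), c(d[1], d[2], d[3]))
  } else {
    arr <- array(dout, c(2, d[1], 2, d[2], 2, d[3], d[4]))
    array(colSums(aperm(arr, c(1, 3, 5, 2, 4, 6, 7)), dims = 3), d)
  }
}

# --- RMSprop ---------------------------------------------------------------

# Parameters and gradients are arbitrarily nested lists of numeric arrays.
rmsprop_init <- function(params) rapply(params, function(p) p * 0, how = "replace")

rmsprop_step <- function(params, grads, state, lr, rho = 0.9, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.list(p)) {
      out_p <- p; out_s <- s
      for (i in seq_along(p)) {
        r <- walk(p[[i]], g[[i]], s[[i]])
        out_p[[i]] <- r$p; out_s[[i]] <- r$s
      }
      list(p = out_p, s = out_s)
    } else {
      s2 <- rho * s + (1 - rho) * g * g
      list(p = p - lr * g / (sqrt(s2) + eps), s = s2)
    }
  }
  walk(params, grads, state)
}

# Elementwise sum of two gradient trees (same shape).
grad_add <- function(a, b, wb = 1) {
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- grad_add(a[[i]], b[[i]], wb)
    a
  } else a + wb * b
}

grad_scale <- function(a, s) rapply(a, function(p) p * s, how = "replace")

grad_zero <- function(params) rapply(params, function(p) p * 0, how = "replace")
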