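#' Fixed convolutional feature extractor
#'
#' A deterministic, non-trainable multi-layer convolutional feature map used
#' by the perceptual loss, in a 2D or 3D variant to match its input. The
#' default backbone is a seeded random-weight stack of strided leaky-ReLU
#' convolutions — random perceptual features are a well-established surrogate
#' for pretrained ones and keep the package free of external weight files.
#' `identity_extractor()` gives the degenerate extractor under which the
#' perceptual loss reduces exactly to a mean squared difference.
#'
#' @param ndim 2 or 3 (image or volume features).
#' @param channels Channel widths per layer.
#' @param k Kernel side (default 3).
#' @param stride Stride per layer (default 2).
#' @param seed Seed fixing the random weights (default 1, making two
#'   extractors with equal arguments identical).
#' @return An object of class `feature_extractor`.
#' @export
feature_extractor <- function(ndim = 2, channels = c(8, 16), k = 3,
                              stride = 2, seed = 1) {
  stopifnot(ndim %in% c(2, 3), length(channels) >= 1)
  set.seed(seed)
  layers <- list()
  c_prev <- 1L
  for (c_out in channels) {
    layers[[length(layers) + 1]] <- nn_conv(c_prev, c_out, k, ndim)
    c_prev <- c_out
  }
  structure(list(ndim = ndim, channels = channels, k = k, stride = stride,
                 layers = layers, identity = FALSE),
            class = "feature_extractor")
}

#' @rdname feature_extractor
#' @export
identity_extractor <- function(ndim = 2) {
  structure(list(ndim = ndim, identity = TRUE), class = "feature_extractor")
}

# Forward pass with caches; x is a 2D matrix or 3D array (single channel).
fx_forward <- function(fx, x) {
  if (fx$identity)
    return(list(feat = x, caches = NULL, plans = NULL, dims = dim(x)))
  xa <- array(x, c(dim(x), 1L))
  caches <- list(); plans <- list(); indims <- list()
  for (i in seq_along(fx$layers)) {
    d <- dim(xa)
    plan <- conv_plan(d[-length(d)], d[length(d)], fx$k, fx$stride, 1L)
    cc <- conv_fwd(fx$layers[[i]], xa, plan)
    caches[[i]] <- cc; plans[[i]] <- plan; indims[[i]] <- d
    xa <- lrelu(cc$out)
  }
  list(feat = xa, caches = caches, plans = plans, indims = indims)
}

# Backward: gradient of a loss wrt the extractor input.
fx_backward <- function(fx, fw, dfeat) {
  if (fx$identity) return(dfeat)
  d <- dfeat
  for (i in rev(seq_along(fx$layers))) {
    d <- d * array(dlrelu(fw$caches[[i]]$Z), dim(fw$caches[[i]]$out))
    dim(d) <- dim(fw$caches[[i]]$out)
    d <- conv_bwd(fx$layers[[i]], fw$caches[[i]], d, fw$plans[[i]])$dX
  }
  array(d, fw$indims[[1]][-length(fw$indims[[1]])])
}

#' Perceptual (feature-space) loss
#'
#' Mean squared difference between feature maps of the two inputs after
#' intensity standardization (the pre-processing maps applied to both sides,
#' making the loss invariant to affine intensity scaling):
#' `1/(w h d) * || phi(G(a)) - phi(T(b)) ||^2`. Zero for identical inputs;
#' with the identity extractor it equals the plain MSE of the standardized
#' inputs.
#'
#' @param a,b Numeric arrays of equal shape (2D or 3D to match `fx`).
#' @param fx A [feature_extractor].
#' @param standardize Apply zero-mean/unit-variance standardization before
#'   feature extraction (default `TRUE`).
#' @return Non-negative scalar.
#' @export
perceptual_loss <- function(a, b, fx = feature_extractor(length(dim(a))),
                            standardize = TRUE) {
  perceptual_loss_grad(a, b, fx, standardize, want_grad = FALSE)$loss
}

# Returns loss and (optionally) gradient wrt `a`.
perceptual_loss_grad <- function(a, b, fx, standardize = TRUE,
                                 want_grad = TRUE) {
  check_same_shape(a, b)
  if (standardize) {
    sa <- standardize(a); sb <- standardize(b)
    za <- sa$z; zb <- sb$z
  } else { za <- a; zb <- b }
  fa <- fx_forward(fx, za); fb <- fx_forward(fx, zb)
  diff <- fa$feat - fb$feat
  nfeat <- length(diff)
  loss <- sum(diff^2) / nfeat
  if (!want_grad) return(list(loss = loss, grad = NULL))
  dfeat <- 2 * diff / nfeat
  dza <- fx_backward(fx, fa, dfeat)
  grad <- if (standardize) standardize_bwd(sa, dza) else dza
  dim(grad) <- dim(a)
  list(loss = loss, grad = grad)
}

#' Hinge discriminator loss
#'
#' `E[f(D(fake))] + E[f(-D(real))]` with `f(t) = max(0, 1 + t)`: the
#' discriminator is pushed to score real samples above +1 and fakes below -1.
#'
#' @param real_scores,fake_scores Numeric vectors of discriminator outputs.
#' @return Non-negative scalar.
#' @export
#' @examples
#' hinge_loss_d(real_scores = 5, fake_scores = -5)  # 0, both margins met
#' hinge_loss_d(0, 0)                               # 2
hinge_loss_d <- function(real_scores, fake_scores) {
  stopifnot(length(real_scores) > 0, length(fake_scores) > 0)
  mean(pmax(0, 1 + fake_scores)) + mean(pmax(0, 1 - real_scores))
}

# Generator-side hinge term: raise the discriminator's score on fakes.
hinge_loss_g <- function(fake_scores) -mean(fake_scores)

#' Augmentation-averaged training loss
#'
#' Combines per-augmentation losses into the overall training objective:
#' `L = L(k=0) + lambda1/(n-1) * sum_{k=1}^{n} L(k)` where each
#' `L(k) = L_rV + L_hV + lambda2 * (L_rP + L_hP)` mixes the sub-volume
#' (3D-supervision) and patch terms. `k = 0` is the identity transformation;
#' augmented copies share discriminator weights.
#'
#' @param per_k List of `n + 1` entries (k = 0 .. n), each a list with
#'   `l_r_v`, `l_h_v`, `l_r_p`, `l_h_p`.
#' @param lambda1 Weight of the augmented terms (default 0.2).
#' @param lambda2 Weight of the patch terms inside each `L(k)` (default 0.5,
#'   emphasizing conformal sub-volume rendering).
#' @return Scalar total loss.
#' @export
dag_training_loss <- function(per_k, lambda1 = 0.2, lambda2 = 0.5) {
  n <- length(per_k) - 1L
  if (n < 2) stop("need at least 2 augmentations (n - 1 divides)")
  lk <- vapply(per_k, function(e)
    e$l_r_v + e$l_h_v + lambda2 * (e$l_r_p + e$l_h_p), 0)
  lk[1] + lambda1 / (n - 1) * sum(lk[-1])
}

# Scalar combination weights of dag_training_loss: w_k for k = 0..n.
dag_weights <- function(n, lambda1) c(1, rep(lambda1 / (n - 1), n))

#' Fine-tuning objective for sparse-view reconstruction
#'
#' `lambda1 * L_perceptual + lambda2 * L_PSNR + lambda3 * L_NLL` comparing a
#' rendered projection against a reference view. The PSNR term is
#' `max(0, stop_psnr - PSNR)` — a hinge that vanishes once the rendering
#' reaches the stopping threshold and otherwise decreases as PSNR improves.
#' The likelihood term is a unit-variance Gaussian negative log-likelihood on
#' pixel residuals (half the MSE, up to an additive constant).
#'
#' @param pred,ref Numeric matrices of equal shape ([0,1] projections).
#' @param fx A 2D [feature_extractor] for the perceptual term.
#' @param lambda1,lambda2,lambda3 Term weights (defaults 0.3, 0.1, 0.3).
#' @param stop_psnr PSNR clip/stopping threshold in dB (default 25).
#' @param max_val Dynamic range for the PSNR term.
#' @return Scalar loss (0 for identical inputs at/above the threshold).
#' @export
inference_loss <- function(pred, ref, fx = feature_extractor(2),
                           lambda1 = 0.3, lambda2 = 0.1, lambda3 = 0.3,
                           stop_psnr = 25, max_val = 1) {
  inference_loss_grad(pred, ref, fx, lambda1, lambda2, lambda3,
                      stop_psnr, max_val, want_grad = FALSE)$loss
}

inference_loss_grad <- function(pred, ref, fx, lambda1 = 0.3, lambda2 = 0.1,
                                lambda3 = 0.3, stop_psnr = 25, max_val = 1,
                                want_grad = TRUE) {
  check_same_shape(pred, ref)
  n <- length(pred)
  res <- pred - ref
  mse <- mean(res^2)
  l_nll <- 0.5 * mse
  cur_psnr <- if (mse == 0) Inf else 20 * log10(max_val / sqrt(mse))
  l_psnr <- max(0, stop_psnr - cur_psnr)
  pl <- perceptual_loss_grad(pred, ref, fx, standardize = TRUE,
                             want_grad = want_grad)
  loss <- lambda1 * pl$loss + lambda2 * l_psnr + lambda3 * l_nll
  if (!want_grad) return(list(loss = loss, psnr = cur_psnr))
  g <- lambda3 * res / n
  if (is.finite(cur_psnr) && cur_psnr < stop_psnr) {
    # d(-PSNR)/dpred = (20 / ln 10) * res / (n * mse)
    g <- g + lambda2 * (20 / log(10)) * res / (n * mse)
  }
  g <- g + lambda1 * pl$grad
  list(loss = loss, grad = g, psnr = cur_psnr)
}
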