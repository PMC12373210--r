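#' Image quality metrics
#'
#' Peak signal-to-noise ratio in dB. Identical inputs return `Inf` (the
#' documented sentinel for a zero-error comparison).
#'
#' @param a,b Numeric arrays of equal shape.
#' @param max_val Maximum possible value of the data (1 for normalized data).
#' @return PSNR in dB.
#' @export
#' @examples
#' psnr(matrix(0, 2, 2), matrix(0.1, 2, 2), max_val = 1)  # 20 dB
psnr <- function(a, b, max_val = 1) {
  check_same_shape(a, b)
  stopifnot(max_val > 0)
  r <- rmse(a, b)
  if (r == 0) return(Inf)
  20 * log10(max_val / r)
}

#' Structural similarity (global form)
#'
#' SSIM computed from whole-image means, variances and covariance (no sliding
#' window), with the usual stabilizers `c1 = (k1 L)^2`, `c2 = (k2 L)^2`,
#' `k1 = 0.01`, `k2 = 0.03`. `window` switches to a moving-window mean of
#' local SSIM values (uniform window) for spatially resolved comparisons.
#'
#' @param a,b Numeric arrays of equal shape.
#' @param L Dynamic range of the data (1 for [0,1]-normalized data).
#' @param k1,k2 Stabilizer constants.
#' @param window Optional odd window side for windowed SSIM (2D only);
#'   `NULL` (default) = global statistics.
#' @return SSIM in [-1, 1].
#' @export
ssim <- function(a, b, L = 1, k1 = 0.01, k2 = 0.03, window = NULL) {
  check_same_shape(a, b)
  stopifnot(L > 0)
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  if (is.null(window)) return(ssim_stat(a, b, c1, c2))
  stopifnot(length(dim(a)) == 2, window %% 2 == 1)
  h <- dim(a)[1]; w <- dim(a)[2]; r <- (window - 1) / 2
  vals <- c()
  for (i in seq(1 + r, h - r)) for (j in seq(1 + r, w - r)) {
    ia <- a[(i - r):(i + r), (j - r):(j + r)]
    ib <- b[(i - r):(i + r), (j - r):(j + r)]
    vals <- c(vals, ssim_stat(ia, ib, c1, c2))
  }
  mean(vals)
}

ssim_stat <- function(a, b, c1, c2) {
  mu_a <- mean(a); mu_b <- mean(b)
  va <- mean((a - mu_a)^2); vb <- mean((b - mu_b)^2)
  cab <- mean((a - mu_a) * (b - mu_b))
  ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
}

#' @rdname psnr
#' @return `rmse`: root-mean-square error in the input units (HU when the
#'   inputs are in Hounsfield units).
#' @export
rmse <- function(a, b) {
  check_same_shape(a, b)
  sqrt(mean((a - b)^2))
}

check_same_shape <- function(a, b) {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(da, db)) stop("inputs must have identical shape")
  invisible(TRUE)
}

#' Metric report for a predicted volume or projection
#'
#' @param pred,ref Numeric arrays of equal shape (normalized [0,1] units).
#' @param max_val Dynamic range for PSNR/SSIM.
#' @param hu Also report RMSE after mapping both inputs to Hounsfield units
#'   via [normalized_to_hu] (default `TRUE`).
#' @return Named list with `psnr`, `ssim`, `rmse` (input units) and
#'   optionally `rmse_hu`.
#' @export
metric_report <- function(pred, ref, max_val = 1, hu = TRUE) {
  out <- list(psnr = psnr(pred, ref, max_val),
              ssim = ssim(pred, ref, L = max_val),
              rmse = rmse(pred, ref))
  if (hu) out$rmse_hu <- rmse(normalized_to_hu(pred), normalized_to_hu(ref))
  out
}
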