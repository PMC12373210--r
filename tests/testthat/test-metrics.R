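test_that("psnr follows its closed form and sentinels", {
  a <- matrix(0, 4, 4)
  expect_equal(psnr(a, a + 0.1, max_val = 1), 20)
  expect_equal(psnr(a, a + 0.01, max_val = 1), 40)
  expect_equal(psnr(a, a), Inf)
  expect_error(psnr(a, matrix(0, 2, 2)), "shape")
})

test_that("global ssim matches hand-evaluated degenerate cases and symmetry", {
  set.seed(3)
  a <- matrix(stats::runif(64), 8)
  expect_equal(ssim(a, a), 1)
  # constant 0 vs constant L: zero variances leave only the luminance term
  L <- 0.7
  c1 <- (0.01 * L)^2
  expect_equal(ssim(matrix(0, 5, 5), matrix(L, 5, 5), L = L),
               c1 / (L^2 + c1), tolerance = 1e-12)
  b <- matrix(stats::runif(64), 8)
  expect_equal(ssim(a, b), ssim(b, a), tolerance = 1e-15)
  expect_true(abs(ssim(a, b)) <= 1)
})

test_that("psnr and ssim agree with an independent reference implementation", {
  # frozen values from scikit-image (win_size = image, uniform window,
  # population covariance) on deterministic 9 x 9 pairs
  ij <- expand.grid(i = 1:9, j = 1:9)
  mk <- function(f) matrix(f(ij$i, ij$j), 9, 9)
  a1 <- mk(function(i, j) (sin(i * j + i) + 1) / 2)
  b1 <- mk(function(i, j) (cos(i + 2 * j) + 1) / 2)
  expect_equal(psnr(a1, b1, 1), 5.701645439769, tolerance = 1e-6)
  expect_equal(ssim(a1, b1, 1), -0.048696824794, tolerance = 1e-4)
  a2 <- mk(function(i, j) (sin(3 * i - j) + 1) / 2)
  b2 <- a2 * 0.8 + 0.1
  expect_equal(psnr(a2, b2, 1), 23.083536267654, tolerance = 1e-6)
  expect_equal(ssim(a2, b2, 1), 0.975715869624, tolerance = 1e-4)
  a3 <- mk(function(i, j) (cos(i * 0.5) + 1) / 2)
  b3 <- mk(function(i, j) (cos(i * 0.5 + 0.3) + 1) / 2)
  expect_equal(psnr(a3, b3, 1), 19.007252853357, tolerance = 1e-6)
  expect_equal(ssim(a3, b3, 1), 0.929006775117, tolerance = 1e-4)
})

test_that("rmse matches a naive two-pass loop and its worked cases", {
  set.seed(4)
  a <- array(stats::rnorm(60), c(3, 4, 5))
  b <- array(stats::rnorm(60), c(3, 4, 5))
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - b[i])^2
  expect_equal(rmse(a, b), sqrt(acc / length(a)), tolerance = 1e-12)
  expect_equal(rmse(a, a), 0)
  expect_equal(rmse(a, a + 2), 2)
})

test_that("hinge discriminator loss reproduces its worked cases", {
  expect_equal(hinge_loss_d(5, -5), 0)
  expect_equal(hinge_loss_d(0, 0), 2)
  expect_equal(hinge_loss_d(-1, 1), 4)
  expect_gte(hinge_loss_d(stats::rnorm(5), stats::rnorm(5)), 0)
})

test_that("augmentation-averaged loss follows the printed combination", {
  mk <- function(l) list(l_r_v = l, l_h_v = l, l_r_p = l, l_h_p = l)
  per_k <- rep(list(mk(1)), 5)           # n = 4, all pieces equal 1
  # each L(k) = 1 + 1 + 0.5 * (1 + 1) = 3; total = 3 * (1 + 0.2 * 4 / 3)
  expect_equal(dag_training_loss(per_k, 0.2, 0.5), 3 * (1 + 0.2 * 4 / 3))
  # lambda1 = 0 keeps only the identity transform
  expect_equal(dag_training_loss(per_k, 0, 0.5), 3)
  # lambda2 = 0 keeps only the sub-volume terms
  expect_equal(dag_training_loss(per_k, 0.2, 0), 2 * (1 + 0.2 * 4 / 3))
  expect_error(dag_training_loss(per_k[1:2], 0.2, 0.5), "augmentations")
  # linearity in each per-k loss
  pk2 <- per_k; pk2[[3]] <- mk(2)
  pk3 <- per_k; pk3[[3]] <- mk(3)
  d32 <- dag_training_loss(pk3, 0.2, 0.5) - dag_training_loss(pk2, 0.2, 0.5)
  d21 <- dag_training_loss(pk2, 0.2, 0.5) - dag_training_loss(per_k, 0.2, 0.5)
  expect_equal(d32, d21, tolerance = 1e-12)
})

test_that("perceptual loss reduces to MSE under identity maps and is symmetric", {
  set.seed(5)
  a <- matrix(stats::runif(64), 8); b <- matrix(stats::runif(64), 8)
  idf <- identity_extractor(2)
  expect_equal(perceptual_loss(a, b, idf, standardize = FALSE),
               mean((a - b)^2), tolerance = 1e-12)
  fx <- feature_extractor(2, seed = 2)
  expect_equal(perceptual_loss(a, a, fx), 0)
  expect_equal(perceptual_loss(a, b, fx), perceptual_loss(b, a, fx),
               tolerance = 1e-12)
  expect_gte(perceptual_loss(a, b, fx), 0)
  # standardization makes it invariant to affine intensity changes
  expect_equal(perceptual_loss(2 * a + 3, b, fx), perceptual_loss(a, b, fx),
               tolerance = 1e-6)
  expect_error(perceptual_loss(a, matrix(0, 4, 4), fx), "shape")
})

test_that("feature extractors are deterministic given their seed", {
  f1 <- feature_extractor(2, seed = 9)
  f2 <- feature_extractor(2, seed = 9)
  x <- matrix(stats::rnorm(256), 16)
  expect_identical(tomofield:::fx_forward(f1, x)$feat,
                   tomofield:::fx_forward(f2, x)$feat)
})

test_that("inference loss is zero at identity and decreases towards the reference", {
  set.seed(6)
  ref <- matrix(stats::runif(144), 12)
  fx <- feature_extractor(2, seed = 1)
  expect_equal(inference_loss(ref, ref, fx), 0)
  start <- matrix(stats::runif(144), 12)
  ls <- vapply(seq(0, 0.9, length.out = 10), function(al)
    inference_loss((1 - al) * start + al * ref, ref, fx), 0)
  expect_true(all(diff(ls) < 0))
  # lambda1 = lambda3 = 0 isolates the PSNR hinge
  lp <- inference_loss(start, ref, fx, lambda1 = 0, lambda2 = 1, lambda3 = 0)
  expect_equal(lp, max(0, 25 - psnr(start, ref, 1)), tolerance = 1e-12)
})
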