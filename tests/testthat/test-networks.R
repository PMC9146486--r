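# Network builders, parameter accounting and the numerical engine.

test_that("analytic count equals the builder count across configurations", {
  cfgs <- list(net_config(f = 5, c = 4, n = 1, o = 3),
               net_config(f = 5, c = 8, n = 1, o = 3),
               net_config(f = 5, c = 16, n = 2, o = 9),
               net_config(f = 3, c = 8, n = 2, o = 9),
               net_config(f = 3, c = 32, n = 2, o = 9),
               net_config(h = 128, w = 128, f = 3, c = 2, n = 1, o = 4))
  for (cfg in cfgs) {
    m <- build_compressed_unet(cfg)
    expect_identical(count_trainable_parameters(m), count_params_analytic(cfg))
  }
  u <- build_reference_unet(1, 3)
  expect_identical(count_trainable_parameters(u), count_params_analytic(u$cfg))
})

test_that("a single conv layer has f^2*n_in*n_out + n_out parameters", {
  m <- build_compressed_unet(net_config(f = 5, c = 4, n = 1, o = 3))
  expect_equal(length(m$params$e1_c1_W) + length(m$params$e1_c1_b),
               5^2 * 1 * 4 + 4)
  expect_equal(length(m$params$e2_c1_W) + length(m$params$e2_c1_b),
               5^2 * 4 * 8 + 8)
})

test_that("output-layer arithmetic: o=3 vs o=2 reference U-Net differ by 65", {
  n3 <- count_params_analytic(build_reference_unet(1, 3)$cfg)
  n2 <- count_params_analytic(build_reference_unet(1, 2)$cfg)
  expect_identical(n3 - n2, 64 * 1 + 1)
})

test_that("parameter count scales ~ c^2 for fixed kernel size", {
  for (f in c(3, 5)) {
    n1 <- count_params_analytic(net_config(f = f, c = 8, n = 2, o = 9))
    n2 <- count_params_analytic(net_config(f = f, c = 16, n = 2, o = 9))
    expect_lt(abs(n2 / n1 - 4), 0.2)  # within 5% of the 4x law
  }
})

test_that("forward pass preserves spatial size and softmax normalizes", {
  cfg <- net_config(h = 32, w = 32, n = 1, o = 3, f = 5, c = 2)
  m <- build_compressed_unet(cfg, seed = 2)
  set.seed(1)
  x <- matrix(runif(32 * 32), ncol = 1)
  pr <- predict_probs(m, x)
  expect_identical(dim(pr), c(1024L, 3L))
  expect_lt(max(abs(rowSums(pr) - 1)), 1e-5)
  cm <- predict_classmap(m, matrix(runif(32 * 32), 32, 32))
  expect_identical(dim(cm), c(32L, 32L))
  expect_true(all(cm %in% 1:3))
  # indivisible input size is a config error
  expect_error(net_config(h = 100, w = 100), "divisible")
  # reference U-Net forward pass on a smaller grid keeps the spatial dims
  u <- build_reference_unet(1, 2, h = 32L, w = 32L)
  pu <- predict_probs(u, matrix(runif(1024), ncol = 1))
  expect_identical(dim(pu), c(1024L, 2L))
})

test_that("conv/maxpool kernels agree with naive R oracles", {
  set.seed(11)
  H <- 7L; W <- 6L; f <- 3L; Cin <- 2L; Cout <- 3L
  X <- matrix(rnorm(H * W * Cin), H * W, Cin)
  Wm <- matrix(rnorm(f * f * Cin * Cout), f * f * Cin, Cout)
  b <- rnorm(Cout)
  got <- octlayers:::cpp_conv_fwd(X, H, W, f, Wm, b)
  want <- conv_naive(X, H, W, f, Wm, b)
  expect_equal(got, want, tolerance = 1e-5)

  H <- 6L; W <- 4L
  A <- matrix(rnorm(H * W * 2), H * W, 2)
  pl <- octlayers:::cpp_maxpool_fwd(A, H, W)
  # oracle: block maxima via explicit loops
  for (ch in 1:2) {
    img <- matrix(A[, ch], H, W)
    want <- matrix(0, H / 2, W / 2)
    for (i in 1:(H / 2)) for (j in 1:(W / 2))
      want[i, j] <- max(img[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
    expect_equal(matrix(pl$Y[, ch], H / 2, W / 2), want)
  }
})

test_that("transposed convolution places each 2x2 block at stride 2", {
  # one input pixel lights a single 2x2 output block with the kernel values
  H <- 2L; W <- 2L; Cin <- 1L; Cout <- 1L
  A <- matrix(c(1, 0, 0, 0), 4, 1)      # pixel (r=0,c=0)
  Wt <- matrix(c(10, 20, 30, 40), 1, 4) # sub = ky*2+kx+1
  out <- octlayers:::tconv_fwd(A, H, W, Wt, b = 0)
  img <- matrix(out[, 1], 4, 4)
  # sub-position order is ky*2+kx (row-major within the 2x2 block)
  expect_equal(img[1:2, 1:2], matrix(c(10, 20, 30, 40), 2, 2, byrow = TRUE))
  expect_true(all(img[3:4, ] == 0) && all(img[, 3:4] == 0))
})

test_that("loss gradient w.r.t. logits matches finite differences", {
  set.seed(5)
  N <- 12L; C <- 4L
  Z <- matrix(rnorm(N * C), N, C)
  y <- sample.int(C, N, replace = TRUE)
  w <- runif(C, 0.3, 1)
  lossfn <- function(Z) {
    P <- octlayers:::softmax_rows(Z)
    octlayers:::loss_and_grad(P, y, w, gamma = 2)$loss
  }
  P <- octlayers:::softmax_rows(Z)
  dZ <- octlayers:::loss_and_grad(P, y, w, gamma = 2)$dZ
  h <- 1e-5
  for (k in sample(length(Z), 8)) {
    Zp <- Z; Zp[k] <- Zp[k] + h
    Zm <- Z; Zm[k] <- Zm[k] - h
    fd <- (lossfn(Zp) - lossfn(Zm)) / (2 * h)
    expect_lt(abs(fd - dZ[k]) / max(abs(fd), 1e-8), 1e-4)
  }
})
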