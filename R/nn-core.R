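# Minimal CNN engine for the compressed U-Net family: im2col convolutions
# (BLAS sgemm via the C++ kernels), 2x2 max pooling, 2x2 stride-2 transposed
# convolutions, dropout, softmax, hand-written backward passes and Adam.
# Activations are (H*W) x C matrices with spatial index p = col*H + row.

relu_fwd <- function(z) list(a = pmax(z, 0), mask = z > 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Output pixel indices (1-based) receiving sub-position `sub` of a 2x2
# stride-2 transposed convolution on an H x W grid; sub = ky*2 + kx + 1.
ups_index <- function(H, W) {
  p0 <- 0:(H * W - 1L)
  r <- p0 %% H
  cc <- p0 %/% H
  lapply(0:3, function(sub) {
    ky <- sub %/% 2L
    kx <- sub %% 2L
    (2L * cc + kx) * (2L * H) + (2L * r + ky) + 1L
  })
}

tconv_fwd <- function(A, H, W, Wt, b) {
  cout <- length(b)
  Y4 <- A %*% Wt
  out <- matrix(0, 4L * nrow(A), cout)
  idx <- ups_index(H, W)
  for (sub in 1:4)
    out[idx[[sub]], ] <- Y4[, sub + 4L * (seq_len(cout) - 1L), drop = FALSE]
  sweep(out, 2L, b, "+")
}

tconv_bwd <- function(A, H, W, Wt, dOut) {
  cout <- ncol(Wt) / 4L
  idx <- ups_index(H, W)
  dY4 <- matrix(0, nrow(A), 4L * cout)
  for (sub in 1:4)
    dY4[, sub + 4L * (seq_len(cout) - 1L)] <- dOut[idx[[sub]], , drop = FALSE]
  list(dA = dY4 %*% t(Wt), dW = crossprod(A, dY4), db = colSums(dOut))
}

# He-normal initialization; all biases start at zero.
init_param <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

# Channel plan of the U-Net template (two convs per stage, doubling depth).
unet_channel_plan <- function(cfg) {
  S <- cfg$stages
  enc <- lapply(seq_len(S), function(s) {
    cin <- if (s == 1L) cfg$n else cfg$c * 2^(s - 2L)
    list(cin = cin, cout = cfg$c * 2^(s - 1L))
  })
  dec <- lapply(seq_len(S - 1L), function(u) {
    cin_up <- cfg$c * 2^(S - u)
    cout <- cfg$c * 2^(S - u - 1L)
    list(cin_up = cin_up, cout = cout)
  })
  list(enc = enc, dec = dec)
}

build_unet_params <- function(cfg) {
  plan <- unet_channel_plan(cfg)
  f <- cfg$f
  p <- list()
  for (s in seq_along(plan$enc)) {
    ch <- plan$enc[[s]]
    p[[sprintf("e%d_c1_W", s)]] <- init_param(f * f * ch$cin, ch$cout, f * f * ch$cin)
    p[[sprintf("e%d_c1_b", s)]] <- numeric(ch$cout)
    p[[sprintf("e%d_c2_W", s)]] <- init_param(f * f * ch$cout, ch$cout, f * f * ch$cout)
    p[[sprintf("e%d_c2_b", s)]] <- numeric(ch$cout)
  }
  for (u in seq_along(plan$dec)) {
    ch <- plan$dec[[u]]
    p[[sprintf("d%d_t_W", u)]] <- init_param(ch$cin_up, 4L * ch$cout, ch$cin_up)
    p[[sprintf("d%d_t_b", u)]] <- numeric(ch$cout)
    p[[sprintf("d%d_c1_W", u)]] <- init_param(f * f * 2L * ch$cout, ch$cout,
                                              f * f * 2L * ch$cout)
    p[[sprintf("d%d_c1_b", u)]] <- numeric(ch$cout)
    p[[sprintf("d%d_c2_W", u)]] <- init_param(f * f * ch$cout, ch$cout, f * f * ch$cout)
    p[[sprintf("d%d_c2_b", u)]] <- numeric(ch$cout)
  }
  p[["out_W"]] <- init_param(cfg$c, cfg$o, cfg$c)
  p[["out_b"]] <- numeric(cfg$o)
  p
}

# Forward pass. X is (h*w) x n. Returns per-pixel class probabilities and,
# when `keep_cache`, everything the backward pass needs.
unet_forward <- function(model, X, train = FALSE, keep_cache = train) {
  cfg <- model$cfg
  p <- model$params
  S <- cfg$stages
  H <- cfg$h; W <- cfg$w
  stopifnot(nrow(X) == H * W, ncol(X) == cfg$n)
  cache <- list(enc = vector("list", S), dec = vector("list", S - 1L))
  a <- X
  skips <- vector("list", S)
  for (s in seq_len(S)) {
    x1 <- a
    z1 <- cpp_conv_fwd(x1, H, W, cfg$f, p[[sprintf("e%d_c1_W", s)]],
                       p[[sprintf("e%d_c1_b", s)]])
    r1 <- relu_fwd(z1)
    x2 <- r1$a
    z2 <- cpp_conv_fwd(x2, H, W, cfg$f, p[[sprintf("e%d_c2_W", s)]],
                       p[[sprintf("e%d_c2_b", s)]])
    r2 <- relu_fwd(z2)
    a <- r2$a
    drop_mask <- NULL
    if (train && cfg$dropout_rate > 0 && s %in% cfg$dropout_stages) {
      drop_mask <- matrix(stats::runif(length(a)) >= cfg$dropout_rate,
                          nrow(a), ncol(a)) / (1 - cfg$dropout_rate)
      a <- a * drop_mask
    }
    st <- list(x1 = x1, m1 = r1$mask, x2 = x2, m2 = r2$mask,
               drop = drop_mask, H = H, W = W)
    if (s < S) {
      skips[[s]] <- a
      pl <- cpp_maxpool_fwd(a, H, W)
      st$pool_idx <- pl$idx
      a <- pl$Y
      H <- H %/% 2L; W <- W %/% 2L
    }
    if (keep_cache) cache$enc[[s]] <- st
  }
  for (u in seq_len(S - 1L)) {
    xt <- a
    up <- tconv_fwd(a, H, W, p[[sprintf("d%d_t_W", u)]], p[[sprintf("d%d_t_b", u)]])
    H <- H * 2L; W <- W * 2L
    skip <- skips[[S - u]]
    a <- cbind(skip, up)
    x1 <- a
    z1 <- cpp_conv_fwd(x1, H, W, cfg$f, p[[sprintf("d%d_c1_W", u)]],
                       p[[sprintf("d%d_c1_b", u)]])
    r1 <- relu_fwd(z1)
    x2 <- r1$a
    z2 <- cpp_conv_fwd(x2, H, W, cfg$f, p[[sprintf("d%d_c2_W", u)]],
                       p[[sprintf("d%d_c2_b", u)]])
    r2 <- relu_fwd(z2)
    a <- r2$a
    if (keep_cache)
      cache$dec[[u]] <- list(xt = xt, Ht = H %/% 2L, Wt = W %/% 2L,
                             x1 = x1, m1 = r1$mask, x2 = x2, m2 = r2$mask,
                             n_skip = ncol(skip))
  }
  logits <- sweep(a %*% p[["out_W"]], 2L, p[["out_b"]], "+")
  probs <- softmax_rows(logits)
  if (keep_cache) cache$pre_out <- a
  list(probs = probs, cache = if (keep_cache) cache else NULL)
}

# Backward pass from dL/dlogits; returns gradients named like the parameters.
unet_backward <- function(model, cache, dZ) {
  cfg <- model$cfg
  p <- model$params
  S <- cfg$stages
  g <- list()
  g[["out_W"]] <- crossprod(cache$pre_out, dZ)
  g[["out_b"]] <- colSums(dZ)
  da <- dZ %*% t(p[["out_W"]])
  for (u in rev(seq_len(S - 1L))) {
    st <- cache$dec[[u]]
    H <- st$Ht * 2L; W <- st$Wt * 2L
    dz2 <- da * st$m2
    b2 <- cpp_conv_bwd(st$x2, dz2, H, W, cfg$f, p[[sprintf("d%d_c2_W", u)]])
    g[[sprintf("d%d_c2_W", u)]] <- b2$dW
    g[[sprintf("d%d_c2_b", u)]] <- as.numeric(b2$db)
    dz1 <- b2$dX * st$m1
    b1 <- cpp_conv_bwd(st$x1, dz1, H, W, cfg$f, p[[sprintf("d%d_c1_W", u)]])
    g[[sprintf("d%d_c1_W", u)]] <- b1$dW
    g[[sprintf("d%d_c1_b", u)]] <- as.numeric(b1$db)
    dskip <- b1$dX[, seq_len(st$n_skip), drop = FALSE]
    dup <- b1$dX[, -seq_len(st$n_skip), drop = FALSE]
    bt <- tconv_bwd(st$xt, st$Ht, st$Wt, p[[sprintf("d%d_t_W", u)]], dup)
    g[[sprintf("d%d_t_W", u)]] <- bt$dW
    g[[sprintf("d%d_t_b", u)]] <- bt$db
    # gradient flowing into the encoder skip is deferred via a stash
    cache$enc[[S - u]]$dskip <- dskip
    da <- bt$dA
  }
  for (s in rev(seq_len(S))) {
    st <- cache$enc[[s]]
    if (s < S) {
      da <- cpp_maxpool_bwd(da, st$pool_idx, st$H * st$W)
      da <- da + st$dskip
    }
    if (!is.null(st$drop)) da <- da * st$drop
    dz2 <- da * st$m2
    b2 <- cpp_conv_bwd(st$x2, dz2, st$H, st$W, cfg$f, p[[sprintf("e%d_c2_W", s)]])
    g[[sprintf("e%d_c2_W", s)]] <- b2$dW
    g[[sprintf("e%d_c2_b", s)]] <- as.numeric(b2$db)
    dz1 <- b2$dX * st$m1
    b1 <- cpp_conv_bwd(st$x1, dz1, st$H, st$W, cfg$f, p[[sprintf("e%d_c1_W", s)]])
    g[[sprintf("e%d_c1_W", s)]] <- b1$dW
    g[[sprintf("e%d_c1_b", s)]] <- as.numeric(b1$db)
    da <- b1$dX
  }
  g
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
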