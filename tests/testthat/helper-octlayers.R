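# Shared fixtures and independent oracles, all built in code.

# Small, fast phantom configuration (64 px canvas, scales enlarged 8x so the
# geometry still spans ~6 mm).
tiny_params <- function(..., n_bscans = 3L, seed = 1L) {
  phantom_params(image_height = 64L, image_width = 64L,
                 axial_scale = 3.87 * 8, lateral_scale = 11.7 * 8,
                 n_bscans = n_bscans, seed = seed, ...)
}

# Brute-force per-pixel double-loop focal loss: for each pixel, only the true
# class contributes -w[t] * (1 - p_t)^gamma * log(p_t); aggregation is mean
# over pixels within each class term, then sum over classes.
focal_loop_oracle <- function(P, G, w, gamma, eps = 1e-7) {
  N <- nrow(P); C <- ncol(P)
  per_class <- numeric(C)
  for (cc in seq_len(C)) {
    acc <- 0
    for (i in seq_len(N)) {
      if (G[i, cc] == 1) {
        p <- min(max(P[i, cc], eps), 1 - eps)
        acc <- acc - w[cc] * (1 - p)^gamma * log(p)
      }
    }
    per_class[cc] <- acc / N
  }
  sum(per_class)
}

# Random probability rows summing to 1.
random_probs <- function(n, C) {
  m <- matrix(stats::runif(n * C, 0.05, 1), n, C)
  m / rowSums(m)
}

onehot <- function(y, C) {
  G <- matrix(0, length(y), C)
  G[cbind(seq_along(y), y)] <- 1
  G
}

# Naive same-padded 2-D convolution oracle operating on (H*W) x C
# activations, mirroring the engine's layout (patch column q = ch*f*f +
# ky*f + kx; output pixel (r,c) reads input (r+ky-pad, c+kx-pad)).
conv_naive <- function(X, H, W, f, Wm, b) {
  Cin <- ncol(X)
  Cout <- ncol(Wm)
  pad <- f %/% 2
  Y <- matrix(0, H * W, Cout)
  for (co in seq_len(Cout)) {
    for (c0 in 0:(W - 1)) for (r0 in 0:(H - 1)) {
      acc <- b[co]
      for (ch in 0:(Cin - 1)) for (ky in 0:(f - 1)) for (kx in 0:(f - 1)) {
        rr <- r0 + ky - pad; cc <- c0 + kx - pad
        if (rr >= 0 && rr < H && cc >= 0 && cc < W) {
          q <- ch * f * f + ky * f + kx + 1
          acc <- acc + X[cc * H + rr + 1, ch + 1] * Wm[q, co]
        }
      }
      Y[c0 * H + r0 + 1, co] <- acc
    }
  }
  Y
}
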