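# Shared numeric helpers.

#' Otsu threshold of a grayscale image
#'
#' Maximizes between-class variance over a 256-bin histogram of intensities in
#' \[0, 1\]. Used by the inner-surface estimator to separate tissue from
#' vitreous without a tuned constant.
#'
#' @param x numeric vector or matrix of intensities in \[0, 1\].
#' @param nbins number of histogram bins.
#' @return scalar threshold in \[0, 1\].
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  h <- tabulate(pmin(pmax(floor(x * nbins) + 1L, 1L), nbins), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (seq_len(nbins) - 0.5) / nbins
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  denom <- omega * (1 - omega)
  sigma_b <- (mu_t * omega - mu)^2 / ifelse(denom > 0, denom, NA_real_)
  k <- which.max(sigma_b)
  mids[k]
}

# Separable Gaussian blur with edge replication; radius = ceil(3*sigma).
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur_1d <- function(m) {
    H <- nrow(m)
    acc <- matrix(0, H, ncol(m))
    for (i in seq_along(k)) {
      off <- i - r - 1L
      rows <- pmin(pmax(seq_len(H) + off, 1L), H)
      acc <- acc + k[i] * m[rows, , drop = FALSE]
    }
    acc
  }
  t(blur_1d(t(blur_1d(img))))
}

#' Bilinear image resize
#'
#' Pixel-center aligned bilinear interpolation with edge clamping.
#'
#' @param img numeric matrix (rows = axial, columns = lateral).
#' @param out_h,out_w output dimensions in pixels.
#' @return resized matrix.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  stopifnot(is.matrix(img), out_h >= 1, out_w >= 1)
  cpp_resize_bilinear(img, as.integer(out_h), as.integer(out_w))
}

# PCHIP knot derivatives (Fritsch-Butland weighted harmonic mean, with the
# standard one-sided three-point end conditions). x strictly increasing.
pchip_slopes <- function(x, y) {
  n <- length(x)
  if (n == 2L) {
    d <- (y[2] - y[1]) / (x[2] - x[1])
    return(c(d, d))
  }
  h <- diff(x)
  del <- diff(y) / h
  m <- numeric(n)
  for (k in 2:(n - 1)) {
    d1 <- del[k - 1]; d2 <- del[k]
    if (d1 == 0 || d2 == 0 || sign(d1) != sign(d2)) {
      m[k] <- 0
    } else {
      w1 <- 2 * h[k] + h[k - 1]
      w2 <- h[k] + 2 * h[k - 1]
      m[k] <- (w1 + w2) / (w1 / d1 + w2 / d2)
    }
  }
  edge <- function(h1, h2, d1, d2) {
    d <- ((2 * h1 + h2) * d1 - h1 * d2) / (h1 + h2)
    if (sign(d) != sign(d1)) d <- 0
    else if (sign(d1) != sign(d2) && abs(d) > 3 * abs(d1)) d <- 3 * d1
    d
  }
  m[1] <- edge(h[1], h[2], del[1], del[2])
  m[n] <- edge(h[n - 1], h[n - 2], del[n - 1], del[n - 2])
  m
}

#' Shape-preserving piecewise cubic Hermite (PCHIP) interpolation
#'
#' Interpolates through the knots with locally monotone cubics: on monotone
#' data the interpolant is monotone (no overshoot), and linear spans are
#' reproduced exactly. Outside the knot range the value of the nearest knot is
#' returned (constant extrapolation), matching how surface infill is used.
#'
#' @param x strictly increasing knot positions.
#' @param y knot values.
#' @param xout positions to evaluate.
#' @return numeric vector of interpolated values.
#' @export
pchip <- function(x, y, xout) {
  stopifnot(length(x) == length(y), length(x) >= 2L, !is.unsorted(x, strictly = TRUE))
  m <- pchip_slopes(x, y)
  i <- findInterval(xout, x, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(x) - 1L)
  h <- x[i + 1L] - x[i]
  t <- (xout - x[i]) / h
  h00 <- (1 + 2 * t) * (1 - t)^2
  h10 <- t * (1 - t)^2
  h01 <- t^2 * (3 - 2 * t)
  h11 <- t^2 * (t - 1)
  out <- h00 * y[i] + h10 * h * m[i] + h01 * y[i + 1L] + h11 * h * m[i + 1L]
  out[xout <= x[1]] <- y[1]
  out[xout >= x[length(x)]] <- y[length(y)]
  out
}

# Deterministic sub-seed derivation; keeps results < 2^31 and reproducible.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1048576) * 1009 + as.numeric(k) * 7919) %% 2147483629L
}
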