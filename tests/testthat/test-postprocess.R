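# Postprocessing: adaptive threshold, hole filling, boundary extraction,
# outlier rejection, PCHIP infill, smoothing, ordering, and chain behavior.

test_that("adaptive threshold reproduces hand-iterated cases", {
  m1 <- matrix(0L, 100, 100); m1[1:10, ] <- 1L           # nn=1000, nz=9000
  t1 <- adaptive_threshold(m1, f0 = 2L)
  expect_equal(t1$f, 2L); expect_equal(t1$T, 500)
  m2 <- matrix(1L, 100, 100); m2[1:10, ] <- 0L           # nn=9000, nz=1000
  t2 <- adaptive_threshold(m2, f0 = 2L)
  expect_equal(t2$f, 10L); expect_equal(t2$T, 900)
  expect_equal(adaptive_threshold(matrix(0L, 5, 5))$T, 0)
})

# A stack of flat integer bands: rows 1:10 class1, 11:20 class2, 21:64 class3.
flat_map3 <- function(H = 64L, W = 64L) {
  m <- matrix(3L, H, W)
  m[1:10, ] <- 1L
  m[11:20, ] <- 2L
  m
}

test_that("hole filling repairs small defects and fixes clean maps", {
  m <- flat_map3()
  expect_identical(fill_holes(m), m)  # fixed point on a clean map
  m2 <- m
  m2[15, 30] <- 3L        # 1-px hole inside the class-2 band
  m2[5, 10:11] <- 2L      # 2-px island of class 2 inside class 1
  fixed <- fill_holes(m2)
  expect_identical(fixed, m)
})

test_that("hole filling never touches components at or above threshold", {
  m <- flat_map3(128L, 128L)
  # a large legitimate block of class 2 inside class 3
  m[40:80, 40:80] <- 2L
  fixed <- fill_holes(m)
  expect_identical(fixed[40:80, 40:80], m[40:80, 40:80])
})

test_that("boundary extraction inverts phantom map construction exactly", {
  p <- tiny_params(thickness_jitter_sd = 0, foveal_pit_depth = 0)
  s <- generate_surfaces(p, 1L)
  sv <- ceiling(s$values[1, , ])  # integer surfaces for an exact inverse
  cm <- octlayers:::classmap_from_surfaces(sv, 64L)
  got <- extract_surfaces(cm, p$axial_scale)
  expect_equal(got$values[1, , ], sv)
  # a column fully vitreous has all boundaries missing
  cm2 <- cm; cm2[, 5] <- 1L
  got2 <- extract_surfaces(cm2)
  expect_true(all(is.na(got2$values[1, 5, ])))
  # region 5 absent but region 6 present: b4 missing, b5 present
  cm3 <- cm
  col <- cm3[, 7]
  cm3[col == 5L, 7] <- 6L
  got3 <- extract_surfaces(cm3)
  expect_true(is.na(got3$values[1, 7, 4]))
  expect_false(is.na(got3$values[1, 7, 5]))
})

test_that("Laplacian outlier rejection flags spikes and crossings only", {
  vals <- array(0, c(5, 21, 8))
  for (k in 1:8) vals[, , k] <- 10 * k   # flat, 10 px apart
  ax <- 3.87
  s <- surface_set(vals, ax)
  expect_identical(sum(is.na(remove_outliers(s, 20)$values)), 0L)
  # +50 um spike on boundary 3 at (3, 11)
  vals2 <- vals
  vals2[3, 11, 3] <- vals2[3, 11, 3] + 50 / ax
  out <- remove_outliers(surface_set(vals2, ax), tau_um = 20)
  expect_true(is.na(out$values[3, 11, 3]))       # the spike itself
  expect_true(is.na(out$values[3, 10, 3]))       # 4-neighbors exceed tau too
  expect_true(is.na(out$values[3, 12, 3]))
  expect_true(is.na(out$values[2, 11, 3]))
  expect_true(is.na(out$values[4, 11, 3]))
  # both bounding surfaces of the affected layers are blanked
  expect_true(is.na(out$values[3, 11, 2]) && is.na(out$values[3, 11, 4]))
  # far-away samples survive
  expect_false(is.na(out$values[1, 2, 3]))
  # a crossing (negative thickness) is always flagged regardless of tau
  vals3 <- vals
  vals3[2, 5, 4] <- vals3[2, 5, 3] - 1
  out3 <- remove_outliers(surface_set(vals3, ax), tau_um = 1e9)
  expect_true(is.na(out3$values[2, 5, 4]) && is.na(out3$values[2, 5, 3]))
})

test_that("PCHIP passes knots, reproduces linear data, preserves monotonicity", {
  x <- c(1, 2, 4, 5, 8, 9)
  y <- c(0, 3, 3.5, 10, 10.5, 2)
  expect_equal(pchip(x, y, x), y, tolerance = 1e-12)
  # linear spans are reproduced exactly
  xl <- 1:10
  expect_equal(pchip(xl, 2 * xl + 1, seq(1, 10, by = 0.25)),
               2 * seq(1, 10, by = 0.25) + 1, tolerance = 1e-12)
  # monotone knots give a monotone interpolant (no overshoot)
  y2 <- c(1, 2, 2.1, 7, 7.2, 9)
  fine <- pchip(x, y2, seq(1, 9, by = 0.01))
  expect_true(all(diff(fine) >= -1e-12))
  # frozen values from an independent shape-preserving reference
  xo <- c(1.5, 2.5, 3.0, 4.5, 6.0, 7.0, 8.5)
  ref1 <- c(1.9259040881, 3.1710879349, 3.2431841786, 6.7688198292,
            10.3012467913, 10.4561789512, 7.5833333333)
  ref2 <- c(1.6513480392, 2.0349903689, 2.0486998074, 4.5442592222,
            7.0878309664, 7.1154334801, 7.8398474178)
  expect_equal(pchip(x, y, xo), ref1, tolerance = 1e-9)
  expect_equal(pchip(x, y2, xo), ref2, tolerance = 1e-9)
  # constant extrapolation beyond the outermost knots
  expect_equal(pchip(x, y, c(-5, 20)), c(y[1], y[6]))
})

test_that("interpolate_missing fills gaps and uses the B-scan fallback", {
  vals <- array(NA_real_, c(3, 20, 8))
  for (k in 1:8) vals[, , k] <- matrix(rep(5 * k + 0.5 * (1:20), each = 3), 3, 20)
  vals[1, 8:12, 3] <- NA              # interior gap in linear data
  vals[2, , 5] <- NA                  # whole row missing -> nearest B-scan copy
  vals[2, 4, 5] <- 123                # a single knot is not enough
  s <- interpolate_missing(surface_set(vals, 1))
  expect_equal(s$values[1, 8:12, 3], 15 + 0.5 * (8:12), tolerance = 1e-9)
  expect_equal(s$values[2, , 5], s$values[1, , 5])
  expect_false(anyNA(s$values))
  # a boundary with no usable row anywhere is an error
  vals2 <- vals
  vals2[, , 7] <- NA
  expect_error(interpolate_missing(surface_set(vals2, 1)), "EZ-OS")
})

test_that("3x3 smoothing: constants, bump arithmetic, affine preservation", {
  vals <- array(7, c(5, 9, 8))
  s <- smooth_surfaces(surface_set(vals, 1))
  expect_equal(s$values, vals)  # constants unchanged
  vals2 <- vals
  vals2[3, 5, 1] <- 7 + 9       # +9 bump -> +1 at the center after the mean
  s2 <- smooth_surfaces(surface_set(vals2, 1))
  expect_equal(s2$values[3, 5, 1], 8)
  ramp <- array(rep(1:9, each = 5), c(5, 9, 8))
  s3 <- smooth_surfaces(surface_set(ramp, 1))
  expect_equal(s3$values[2:4, 2:8, ], ramp[2:4, 2:8, ])  # interior affine
})

test_that("ordering enforcement projects and is a fixed point on ordered input", {
  vals <- array(0, c(2, 6, 8))
  for (k in 1:8) vals[, , k] <- 10 * k
  s <- enforce_ordering(surface_set(vals, 1))
  expect_equal(s$values, vals)
  vals2 <- vals
  vals2[1, 3, 3] <- vals2[1, 3, 2] - 2   # b3 dips 2 px above b2
  s2 <- enforce_ordering(surface_set(vals2, 1))
  expect_equal(s2$values[1, 3, 3], vals2[1, 3, 2])
  # fuzz property: random perturbations always end up monotone
  set.seed(8)
  for (rep in 1:20) {
    v <- vals + array(rnorm(length(vals), 0, 5), dim(vals))
    o <- enforce_ordering(surface_set(v, 1))$values
    expect_true(all(o[, , 2:8] - o[, , 1:7] >= 0))
  }
})

test_that("full chain is idempotent on clean flat maps", {
  p <- tiny_params(thickness_jitter_sd = 0, foveal_pit_depth = 0, n_bscans = 4L)
  maps <- lapply(1:4, function(i) {
    sv <- ceiling(generate_surfaces(p, i)$values[1, , ])
    octlayers:::classmap_from_surfaces(sv, 64L)
  })
  r1 <- extract_clean_surfaces(maps, p$axial_scale)
  # feed the cleaned surfaces back through the surface-level chain
  s2 <- enforce_ordering(smooth_surfaces(interpolate_missing(
    remove_outliers(r1$surfaces, 20))))
  expect_lt(max(abs(s2$values - r1$surfaces$values)), 1e-9)
})
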