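# Phantom generator: surface construction, rendering, label collapse,
# determinism and the on-disk dataset layout.

test_that("degenerate no-pit phantom gives flat parallel surfaces at cumulative depths", {
  p <- tiny_params(foveal_pit_depth = 0, thickness_jitter_sd = 0)
  s <- generate_surfaces(p, 1L)$values[1, , ]
  # flat: every boundary constant across A-scans
  expect_true(all(apply(s, 2, function(v) diff(range(v))) < 1e-9))
  # parallel at cumulative mean thicknesses
  th_px <- p$layer_thickness_means / p$axial_scale
  expect_equal(unname(s[1, 2:8] - s[1, 1:7]), unname(th_px), tolerance = 1e-9)
  expect_equal(unname(s[1, 1]), p$ilm_depth_um / p$axial_scale + 1,
               tolerance = 1e-9)
})

test_that("surfaces are strictly ordered and deterministic in the seed", {
  p <- tiny_params(seed = 7L)
  for (i in 1:3) {
    s <- generate_surfaces(p, i)$values[1, , ]
    expect_true(min(s[, 2:8] - s[, 1:7]) >= 0)
  }
  s1 <- generate_surfaces(p, 2L)
  s2 <- generate_surfaces(tiny_params(seed = 7L), 2L)
  expect_identical(s1$values, s2$values)
  s3 <- generate_surfaces(tiny_params(seed = 8L), 2L)
  expect_false(identical(s1$values, s3$values))
  expect_error(phantom_params(image_height = 0), "positive")
})

test_that("inner layers pinch toward zero at the pit center", {
  p <- tiny_params(thickness_jitter_sd = 0)
  s <- generate_surfaces(p, p$fovea_center[1])$values[1, , ]
  j <- p$fovea_center[2]
  inner_at_pit <- (s[j, 5] - s[j, 1]) * p$axial_scale     # mRNFL..OPL stack
  inner_off <- (s[2, 5] - s[2, 1]) * p$axial_scale
  expect_lt(inner_at_pit, inner_off - 0.8 * p$foveal_pit_depth)
})

test_that("noiseless render is piecewise constant: image = reflectivity[classmap9]", {
  p <- tiny_params(speckle_shape = 0, blur_sigma = 0, microcyst_rate = 0)
  r <- generate_bscan(p, 1L)
  expect_equal(r$image,
               matrix(p$layer_reflectivity[r$gt$classmap9], 64, 64))
  # classmap9 reconstructed from surfaces equals the emitted classmap9
  rebuilt <- octlayers:::classmap_from_surfaces(r$gt$surfaces$values[1, , ], 64L)
  expect_identical(rebuilt, r$gt$classmap9)
})

test_that("render is a pure function of (params, seed)", {
  p <- tiny_params(seed = 3L)
  r1 <- generate_bscan(p, 2L)
  r2 <- generate_bscan(tiny_params(seed = 3L), 2L)
  expect_identical(r1$image, r2$image)
  expect_identical(r1$gt$classmap9, r2$gt$classmap9)
})

test_that("label collapse follows the 3-class mapping and conserves counts", {
  m <- matrix(c(1L, 5L, 9L, 1L), 2, 2)
  expect_identical(collapse_labels(m), matrix(c(1L, 2L, 3L, 1L), 2, 2))
  expect_identical(collapse_labels(matrix(1L, 4, 4)), matrix(1L, 4, 4))
  expect_error(collapse_labels(matrix(c(1L, 10L), 1, 2)), "vocabulary")
  r <- generate_bscan(tiny_params(), 1L)
  c9 <- tabulate(r$gt$classmap9, 9L)
  c3 <- tabulate(r$gt$classmap3, 3L)
  expect_identical(c3, c(c9[1], sum(c9[2:8]), c9[9]))
})

test_that("microcysts darken the image only inside the INL and leave labels unchanged", {
  base <- phantom_params(image_height = 96L, image_width = 96L,
                         axial_scale = 7, lateral_scale = 62,
                         ilm_depth_um = 150,
                         n_bscans = 1L, blur_sigma = 0, microcyst_rate = 0,
                         seed = 5L)
  cyst <- base
  cyst$microcyst_rate <- 20
  s <- generate_surfaces(base, 1L)
  r0 <- render_bscan(s, base, seed = 11L)
  r1 <- render_bscan(s, cyst, seed = 11L)
  expect_identical(r0$gt$classmap9, r1$gt$classmap9)
  changed <- which(r0$image != r1$image)
  expect_gt(length(changed), 0)
  expect_true(all(r0$gt$classmap9[changed] == 4L))
})

test_that("class frequencies of a phantom batch are positive for all 9 classes", {
  p <- tiny_params(seed = 2L)
  g <- generate_volume(p)
  counts <- Reduce(`+`, lapply(g$gt$classmap9, tabulate, nbins = 9L))
  expect_true(all(counts > 0))
})

test_that("generate_dataset writes the documented layout and is regenerable", {
  p <- tiny_params(n_bscans = 2L, seed = 13L)
  root <- file.path(tempdir(), "octl_ds")
  unlink(root, recursive = TRUE)
  man <- generate_dataset(p, n_volumes = 2L, root)
  imgs <- list.files(root, pattern = "^bscan_\\d+\\.png$", recursive = TRUE)
  masks <- list.files(root, pattern = "^mask9_\\d+\\.png$", recursive = TRUE)
  expect_length(imgs, 4L)   # 2 volumes x 2 B-scans
  expect_length(masks, 4L)
  expect_true(file.exists(file.path(root, "manifest.json")))
  expect_length(man$volumes, 2L)
  # regeneration from manifest seeds is byte-identical
  root2 <- file.path(tempdir(), "octl_ds2")
  unlink(root2, recursive = TRUE)
  generate_dataset(p, n_volumes = 2L, root2)
  f1 <- file.path(root, imgs[1])
  f2 <- file.path(root2, imgs[1])
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # non-empty output directory is refused before any write
  expect_error(generate_dataset(p, 1L, root), "not empty")
})
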