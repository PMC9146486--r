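# Synthetic macular OCT phantom: smooth ordered boundary surfaces with a
# foveal pit, per-layer reflectivity bands, multiplicative gamma speckle,
# optional thin-RNFL configuration and INL microcysts, with exact ground truth.

#' Boundary and class vocabularies
#'
#' Eight boundary surfaces order top to bottom, the seven intraretinal bands
#' between them, and the nine-class map vocabulary (vitreous, seven layers,
#' below Bruch's membrane).
#' @export
boundary_names <- function() {
  c("ILM", "RNFL-GCL", "IPL-INL", "INL-OPL", "OPL-ONL", "ELM", "EZ-OS", "BM")
}

#' @rdname boundary_names
#' @export
layer_names <- function() c("mRNFL", "GCIPL", "INL", "OPL", "ONL", "MZ", "OL")

#' @rdname boundary_names
#' @export
class_names9 <- function() c("vitreous", layer_names(), "b-BM")

#' Phantom generator parameters
#'
#' Defaults describe a Spectralis-like macular volume: 512 x 512 B-scans at
#' 3.87 um/px axial and 11.7 um/px lateral resolution, 25 B-scans 240 um
#' apart, and layer thickness means close to healthy macular averages
#' (total macula ~340 um). Reflectivity is bright for mRNFL/OPL/MZ/OL and
#' dark for the nuclear layers, as in real B-scans. Speckle is multiplicative
#' gamma noise with configurable shape (0 disables it); `microcyst_rate` is
#' the expected number of hyporeflective INL microcysts per B-scan and
#' `thin_rnfl` emulates advanced neuroaxonal atrophy by scaling the mRNFL
#' band to 40% of its mean.
#'
#' @param image_height,image_width canvas size in pixels.
#' @param axial_scale,lateral_scale um per pixel.
#' @param n_bscans number of B-scans in a volume.
#' @param bscan_spacing distance between B-scans in um.
#' @param layer_thickness_means named or plain numeric vector of 7 mean layer
#'   thicknesses in um (mRNFL, GCIPL, INL, OPL, ONL, MZ, OL).
#' @param thickness_jitter_sd amplitude (um) of the smooth lateral thickness
#'   variation added per layer.
#' @param ilm_depth_um mean depth of the ILM below the image top, um.
#' @param foveal_pit_depth,foveal_pit_sigma Gaussian pit depth and width, um.
#' @param layer_reflectivity 9 mean gray levels in \[0,1\] for the 9 classes.
#' @param speckle_shape gamma shape of the multiplicative speckle (0 = off).
#' @param blur_sigma Gaussian blur sigma in px applied before speckle.
#' @param microcyst_rate expected INL microcysts per B-scan (Poisson).
#' @param thin_rnfl logical; thin-RNFL configuration.
#' @param fovea_center optional c(bscan, ascan) pit position (1-based);
#'   defaults to the volume center.
#' @param seed integer seed; identical seed and parameters give bit-identical
#'   output.
#' @return object of class `phantom_params`.
#' @export
phantom_params <- function(image_height = 512L, image_width = 512L,
                           axial_scale = 3.87, lateral_scale = 11.7,
                           n_bscans = 25L, bscan_spacing = 240,
                           layer_thickness_means = c(mRNFL = 35, GCIPL = 70, INL = 35,
                                                     OPL = 30, ONL = 80, MZ = 30, OL = 60),
                           thickness_jitter_sd = 5,
                           ilm_depth_um = 600,
                           foveal_pit_depth = 120, foveal_pit_sigma = 350,
                           layer_reflectivity = c(0.05, 0.55, 0.40, 0.22, 0.42,
                                                  0.14, 0.35, 0.75, 0.10),
                           speckle_shape = 8, blur_sigma = 1,
                           microcyst_rate = 0.3, thin_rnfl = FALSE,
                           fovea_center = NULL, seed = 1L) {
  if (image_height <= 0 || image_width <= 0 || n_bscans <= 0)
    stop("phantom dimensions must be positive")
  if (length(layer_thickness_means) != 7L || any(layer_thickness_means <= 0))
    stop("layer_thickness_means must be 7 positive values")
  if (length(layer_reflectivity) != 9L ||
      any(layer_reflectivity < 0 | layer_reflectivity > 1))
    stop("layer_reflectivity must be 9 values in [0,1]")
  if (axial_scale <= 0 || lateral_scale <= 0 || bscan_spacing <= 0)
    stop("scales must be positive")
  if (is.null(fovea_center))
    fovea_center <- c(ceiling(n_bscans / 2), ceiling(image_width / 2))
  p <- list(image_height = as.integer(image_height),
            image_width = as.integer(image_width),
            axial_scale = axial_scale, lateral_scale = lateral_scale,
            n_bscans = as.integer(n_bscans), bscan_spacing = bscan_spacing,
            layer_thickness_means = stats::setNames(as.numeric(layer_thickness_means),
                                                    layer_names()),
            thickness_jitter_sd = thickness_jitter_sd,
            ilm_depth_um = ilm_depth_um,
            foveal_pit_depth = foveal_pit_depth,
            foveal_pit_sigma = foveal_pit_sigma,
            layer_reflectivity = as.numeric(layer_reflectivity),
            speckle_shape = speckle_shape, blur_sigma = blur_sigma,
            microcyst_rate = microcyst_rate, thin_rnfl = isTRUE(thin_rnfl),
            fovea_center = as.numeric(fovea_center), seed = as.integer(seed))
  class(p) <- "phantom_params"
  p
}

# Volume-level smooth random fields: one shared baseline undulation and one
# thickness-jitter field per layer, parameterized by low-frequency cosines
# drawn once from the volume seed so surfaces vary smoothly across B-scans.
phantom_fields <- function(params) {
  set.seed(derive_seed(params$seed, 11L))
  width_um <- params$image_width * params$lateral_scale
  depth_um <- params$n_bscans * params$bscan_spacing
  draw <- function(amp_sd, n_comp = 2L) {
    lapply(seq_len(n_comp), function(i) {
      list(amp = stats::rnorm(1, 0, amp_sd),
           kx = 2 * pi / stats::runif(1, width_um / 2.5, width_um * 1.5),
           kz = 2 * pi / stats::runif(1, depth_um / 1.5, depth_um * 2.5),
           phx = stats::runif(1, 0, 2 * pi), phz = stats::runif(1, 0, 2 * pi))
    })
  }
  base <- draw(2 * params$thickness_jitter_sd)
  jit <- lapply(seq_len(7L), function(k) draw(params$thickness_jitter_sd))
  eval_field <- function(comps, x_um, z_um) {
    out <- numeric(length(x_um))
    for (cc in comps)
      out <- out + cc$amp * cos(cc$kx * x_um + cc$phx) * cos(cc$kz * z_um + cc$phz)
    out
  }
  list(base = base, jit = jit, eval_field = eval_field)
}

#' Generate ground-truth boundary surfaces for one B-scan
#'
#' Surfaces are built upward from a gently undulating Bruch's membrane using
#' per-layer thickness fields. The foveal pit is a 2-D Gaussian pinch applied
#' to the four inner layers (mRNFL..OPL), whose removed thickness at the pit
#' center equals `foveal_pit_depth`, so the ILM dips while the outer bands
#' stay flat -- the pattern seen in real macular scans.
#'
#' @param params a [phantom_params()] object.
#' @param bscan_index 1-based B-scan index within the volume.
#' @return a [surface_set()] with 1 B-scan row, `image_width` columns and the
#'   8 boundaries, strictly ordered at every A-scan.
#' @export
generate_surfaces <- function(params, bscan_index = 1L) {
  stopifnot(inherits(params, "phantom_params"))
  if (bscan_index < 1 || bscan_index > params$n_bscans)
    stop("bscan_index out of range")
  W <- params$image_width
  fld <- phantom_fields(params)
  x_um <- (seq_len(W) - params$fovea_center[2]) * params$lateral_scale
  z_um <- rep((bscan_index - params$fovea_center[1]) * params$bscan_spacing, W)
  g <- exp(-(x_um^2 + z_um^2) / (2 * params$foveal_pit_sigma^2))

  means <- params$layer_thickness_means
  if (params$thin_rnfl) means["mRNFL"] <- means["mRNFL"] * 0.4
  th <- sapply(seq_len(7L), function(k) {
    pmax(0.5, means[k] + fld$eval_field(fld$jit[[k]], x_um, z_um))
  })  # W x 7, um

  inner <- 1:4  # mRNFL, GCIPL, INL, OPL pinch toward zero at the pit
  lambda <- min(1, params$foveal_pit_depth / sum(means[inner]))
  pinch <- 1 - lambda * g
  th[, inner] <- th[, inner] * pinch

  und <- fld$eval_field(fld$base, x_um, z_um)
  bm_um <- params$ilm_depth_um + sum(means) + und
  depth_um <- matrix(0, W, 8L)
  depth_um[, 8] <- bm_um
  for (k in 7:1) depth_um[, k] <- depth_um[, k + 1] - th[, k]
  rows <- depth_um / params$axial_scale + 1  # 1-based pixel rows
  vals <- array(NA_real_, c(1L, W, 8L),
                dimnames = list(NULL, NULL, boundary_names()))
  vals[1, , ] <- rows
  surface_set(vals, axial_scale = params$axial_scale)
}

#' Render one B-scan image and its ground truth from surfaces
#'
#' The image is built as per-region mean reflectivity, then optional
#' hyporeflective microcyst ellipses confined to the INL band (labels are not
#' altered), Gaussian blur, multiplicative gamma speckle with mean 1, and a
#' final clip to \[0,1\]. Class maps are derived from the surfaces by the
#' region rule: a pixel at row r belongs to region k+1 when
#' surface_k <= r < surface_(k+1) (region 1 above the ILM, region 9 below BM).
#'
#' @param surfaces a [surface_set()] with one B-scan.
#' @param params a [phantom_params()] object.
#' @param seed integer seed driving the stochastic render steps.
#' @return list with `image` (H x W matrix in \[0,1\]) and `gt` containing
#'   `surfaces`, `classmap9` and `classmap3`.
#' @export
render_bscan <- function(surfaces, params, seed = params$seed) {
  stopifnot(inherits(surfaces, "surface_set"))
  H <- params$image_height
  W <- params$image_width
  s <- surfaces$values[1, , , drop = TRUE]  # W x 8
  if (any(s < 1) || any(s > H + 1))
    stop("surfaces exceed image bounds; cannot render")
  classmap9 <- classmap_from_surfaces(s, H)
  img <- matrix(params$layer_reflectivity[classmap9], H, W)

  if (params$microcyst_rate > 0) {
    set.seed(derive_seed(seed, 3L))
    n_cyst <- stats::rpois(1, params$microcyst_rate)
    if (n_cyst > 0) {
      inl_th <- (s[, 4] - s[, 3]) * params$axial_scale
      ok_cols <- which(inl_th > 15)
      for (i in seq_len(n_cyst)) {
        if (length(ok_cols) == 0) break
        cx <- ok_cols[sample.int(length(ok_cols), 1)]
        cy <- (s[cx, 3] + s[cx, 4]) / 2
        ax_px <- stats::runif(1, 8, 20) / params$axial_scale
        lat_px <- stats::runif(1, 20, 60) / params$lateral_scale
        cols <- max(1, floor(cx - lat_px)):min(W, ceiling(cx + lat_px))
        rows <- max(1, floor(cy - ax_px)):min(H, ceiling(cy + ax_px))
        for (cc in cols) {
          dd <- ((rows - cy) / ax_px)^2 + ((cc - cx) / lat_px)^2
          sel <- rows[dd <= 1 & classmap9[rows, cc] == 4L]
          img[sel, cc] <- img[sel, cc] * 0.25
        }
      }
    }
  }

  img <- gaussian_blur(img, params$blur_sigma)
  if (params$speckle_shape > 0) {
    set.seed(derive_seed(seed, 4L))
    img <- img * matrix(stats::rgamma(H * W, shape = params$speckle_shape,
                                      rate = params$speckle_shape), H, W)
  }
  img <- pmin(pmax(img, 0), 1)
  gt <- list(surfaces = surfaces, classmap9 = classmap9,
             classmap3 = collapse_labels(classmap9))
  list(image = img, gt = gt)
}

# Region rule shared by phantom rendering and tests: region = 1 + number of
# surfaces at or above the pixel row.
classmap_from_surfaces <- function(s, H) {
  W <- nrow(s)
  cm <- matrix(1L, H, W)
  rows <- seq_len(H)
  for (j in seq_len(W))
    cm[, j] <- 1L + findInterval(rows, s[j, ])
  storage.mode(cm) <- "integer"
  cm
}

#' Collapse a 9-class layer map to the 3-class retina map
#'
#' Maps vitreous to 1, the seven retinal bands to 2, and below-BM to 3.
#'
#' @param classmap9 integer matrix with labels in 1..9.
#' @return integer matrix with labels in 1..3.
#' @export
collapse_labels <- function(classmap9) {
  if (any(classmap9 < 1 | classmap9 > 9))
    stop("labels outside the 9-class vocabulary")
  out <- matrix(2L, nrow(classmap9), ncol(classmap9))
  out[classmap9 == 1L] <- 1L
  out[classmap9 == 9L] <- 3L
  out
}

#' Generate one complete phantom B-scan
#'
#' Convenience wrapper chaining [generate_surfaces()] and [render_bscan()]
#' with a per-B-scan seed derived from the volume seed.
#'
#' @inheritParams generate_surfaces
#' @return as [render_bscan()].
#' @export
generate_bscan <- function(params, bscan_index = 1L) {
  s <- generate_surfaces(params, bscan_index)
  render_bscan(s, params, seed = derive_seed(params$seed, 1000L + bscan_index))
}

#' Generate a full phantom volume with ground truth
#'
#' @param params a [phantom_params()] object.
#' @return list with `volume` (an [oct_volume()]) and `gt` containing the
#'   volume [surface_set()] plus per-B-scan 9- and 3-class maps.
#' @export
generate_volume <- function(params) {
  W <- params$image_width
  vals <- array(NA_real_, c(params$n_bscans, W, 8L),
                dimnames = list(NULL, NULL, boundary_names()))
  bscans <- vector("list", params$n_bscans)
  cm9 <- vector("list", params$n_bscans)
  cm3 <- vector("list", params$n_bscans)
  for (i in seq_len(params$n_bscans)) {
    r <- generate_bscan(params, i)
    bscans[[i]] <- r$image
    vals[i, , ] <- r$gt$surfaces$values[1, , ]
    cm9[[i]] <- r$gt$classmap9
    cm3[[i]] <- r$gt$classmap3
  }
  vol <- oct_volume(bscans, axial_scale = params$axial_scale,
                    lateral_scale = params$lateral_scale,
                    bscan_spacing = params$bscan_spacing,
                    fovea = params$fovea_center,
                    volume_id = sprintf("phantom_%d", params$seed))
  list(volume = vol,
       gt = list(surfaces = surface_set(vals, params$axial_scale),
                 classmap9 = cm9, classmap3 = cm3))
}

#' Write a phantom dataset to disk
#'
#' Creates `<root>/<volume_id>/` directories containing `bscan_###.png`
#' (8-bit grayscale), `mask9_###.png` and `mask3_###.png` (labels stored as
#' raw gray levels 1..9), `surfaces.csv` and `meta.json`, plus a root
#' `manifest.json` listing every file with the seed that produced it.
#' Regeneration from the manifest seeds is byte-identical.
#'
#' @param params a [phantom_params()] object; volume v uses the derived seed
#'   recorded in the manifest.
#' @param n_volumes number of volumes to generate.
#' @param path output directory; must not already contain files.
#' @return the manifest, invisibly.
#' @export
generate_dataset <- function(params, n_volumes, path) {
  if (dir.exists(path) && length(list.files(path)) > 0)
    stop("output directory is not empty: ", path)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(n_volumes = n_volumes, volumes = list())
  for (v in seq_len(n_volumes)) {
    pv <- params
    pv$seed <- derive_seed(params$seed, 500L + v)
    vol_id <- sprintf("vol_%03d", v)
    vdir <- file.path(path, vol_id)
    dir.create(vdir)
    gen <- generate_volume(pv)
    files <- character(0)
    for (i in seq_len(pv$n_bscans)) {
      f_img <- sprintf("bscan_%03d.png", i)
      f_m9 <- sprintf("mask9_%03d.png", i)
      f_m3 <- sprintf("mask3_%03d.png", i)
      png::writePNG(gen$volume$bscans[[i]], file.path(vdir, f_img))
      png::writePNG(gen$gt$classmap9[[i]] / 255, file.path(vdir, f_m9))
      png::writePNG(gen$gt$classmap3[[i]] / 255, file.path(vdir, f_m3))
      files <- c(files, f_img, f_m9, f_m3)
    }
    write_surfaces(gen$gt$surfaces, file.path(vdir, "surfaces.csv"))
    meta <- list(volume_id = vol_id, axial_scale = pv$axial_scale,
                 lateral_scale = pv$lateral_scale,
                 bscan_spacing = pv$bscan_spacing, n_bscans = pv$n_bscans,
                 image_height = pv$image_height, image_width = pv$image_width,
                 fovea = pv$fovea_center, seed = pv$seed,
                 thin_rnfl = pv$thin_rnfl)
    jsonlite::write_json(meta, file.path(vdir, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$volumes[[v]] <- list(volume_id = vol_id, seed = pv$seed,
                                  files = c(files, "surfaces.csv", "meta.json"))
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
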