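# Volume standardization: inner-surface estimation, fovea localization via
# parabola fitting, lateral/B-scan cropping to a fixed millimeter extent and
# bilinear resize to the network input size.

#' Estimate the inner retinal surface (ILM) per A-scan
#'
#' Per column, the first row whose median-filtered intensity exceeds an
#' adaptive Otsu threshold computed over the whole B-scan. Columns with no
#' crossing are returned as `NA`; a blank image yields all-`NA` without error.
#'
#' @param bscan numeric H x W matrix with intensities in \[0,1\].
#' @return numeric vector of length W with 1-based row indices (or `NA`).
#' @export
estimate_inner_surface <- function(bscan) {
  H <- nrow(bscan)
  thr <- otsu_threshold(bscan)
  if (!is.finite(thr) || max(bscan) <= min(bscan))
    return(rep(NA_real_, ncol(bscan)))
  apply(bscan, 2L, function(col) {
    sm <- if (H >= 5) stats::runmed(col, 5L) else col
    hit <- which(sm > thr)
    if (length(hit) == 0L) NA_real_ else hit[1L]
  })
}

#' Locate the fovea from an ILM row grid
#'
#' Per B-scan, a least-squares parabola is fit to the ILM row over the
#' central half of the A-scans; the pit is the vertex (the deepest point --
#' the largest row index, since rows grow downward). The foveal B-scan is the
#' one whose fitted vertex is deepest, and the foveal A-scan is that vertex,
#' clamped to the central window. When a fit opens the wrong way (no pit),
#' the method falls back to the deepest raw grid sample and flags it.
#'
#' @param surface_grid numeric matrix `[n_bscans, n_ascans]` of ILM rows
#'   (`NA` allowed), e.g. from [estimate_inner_surface()] per B-scan.
#' @return list with `bscan`, `ascan` (1-based indices) and `fallback` flag.
#' @export
locate_fovea <- function(surface_grid) {
  nb <- nrow(surface_grid)
  na_ <- ncol(surface_grid)
  j0 <- floor(na_ / 4) + 1L
  j1 <- na_ - floor(na_ / 4)
  central <- surface_grid[, j0:j1, drop = FALSE]
  if (mean(is.na(central)) >= 0.5)
    stop("quality error: >=50% of the central ILM grid is missing")
  best <- list(depth = -Inf, bscan = NA_integer_, ascan = NA_real_)
  for (i in seq_len(nb)) {
    y <- surface_grid[i, j0:j1]
    x <- seq.int(j0, j1)
    ok <- !is.na(y)
    if (sum(ok) < 5L) next
    fit <- stats::lm.fit(cbind(1, x[ok], x[ok]^2), y[ok])
    a <- fit$coefficients[3]
    b <- fit$coefficients[2]
    if (!is.finite(a) || a >= 0) next  # upward-opening: no pit shape here
    v <- min(max(-b / (2 * a), j0), j1)
    depth <- fit$coefficients[1] + b * v + a * v^2
    if (depth > best$depth) best <- list(depth = depth, bscan = i, ascan = v)
  }
  if (!is.finite(best$depth)) {
    # no B-scan shows pit curvature: fall back to the deepest grid sample
    message("locate_fovea: no pit-shaped parabola fit; grid fallback used")
    k <- which(central == max(central, na.rm = TRUE), arr.ind = TRUE)[1, ]
    return(list(bscan = unname(k[1]), ascan = unname(k[2] + j0 - 1L),
                fallback = TRUE))
  }
  # refine on the chosen B-scan: the global fit can be dragged by background
  # tilt when the pit sits off-center, so refit a parabola in a local window
  # around the deepest median-smoothed sample of the foveal region
  y_all <- surface_grid[best$bscan, ]
  y_sm <- y_all
  ok_all <- which(!is.na(y_all))
  if (length(ok_all) >= 7L)
    y_sm[ok_all] <- stats::runmed(y_all[ok_all], 7L)
  cen <- j0:j1
  deepest <- cen[which.max(y_sm[cen])]
  half <- max(5L, round(na_ * 0.06))
  r0 <- max(j0, deepest - half)
  r1r <- min(j1, deepest + half)
  y <- surface_grid[best$bscan, r0:r1r]
  x <- seq.int(r0, r1r)
  ok <- !is.na(y)
  best$ascan <- deepest
  if (sum(ok) >= 5L) {
    fit <- stats::lm.fit(cbind(1, x[ok], x[ok]^2), y[ok])
    a <- fit$coefficients[3]
    if (is.finite(a) && a < 0) {
      v <- -fit$coefficients[2] / (2 * a)
      if (v >= r0 && v <= r1r) best$ascan <- v
    }
  }
  list(bscan = best$bscan, ascan = round(best$ascan), fallback = FALSE)
}

#' Crop a volume around the fovea and resize to the network input size
#'
#' The lateral crop spans `extent_mm` centered on the foveal A-scan
#' (width = round(extent_mm * 1000 / lateral_scale) px, edge-replicated when
#' the window leaves the image); the B-scan subset spans `extent_mm` across
#' slices; the full axial range is kept (the retina occupies a small part of
#' it) and each cropped B-scan is resized bilinearly to `out_size`.
#'
#' @param volume an [oct_volume()].
#' @param center list/vector c(bscan, ascan); defaults to `volume$fovea`.
#' @param extent_mm lateral extent of the crop in mm (6.0 by default; use 5.5
#'   for the stricter ONH-free crop).
#' @param out_size c(rows, cols) of the output B-scans.
#' @return list with `volume` (cropped+resized) and `transform`
#'   (a `preprocess_transform` usable with [apply_transform_to_surfaces()]).
#' @export
crop_and_resize <- function(volume, center = NULL, extent_mm = 6.0,
                            out_size = c(512L, 512L)) {
  stopifnot(inherits(volume, "oct_volume"))
  if (is.null(center)) center <- volume$fovea
  if (is.null(center)) stop("fovea unknown: supply `center`")
  center <- as.numeric(unlist(center))[1:2]
  H <- nrow(volume$bscans[[1]])
  W <- ncol(volume$bscans[[1]])
  w_c <- round(extent_mm * 1000 / volume$lateral_scale)
  first_col <- round(center[2]) - floor(w_c / 2)
  cols <- seq.int(first_col, length.out = w_c)
  clamped <- any(cols < 1L | cols > W)
  if (clamped) message("crop window clamped; padding by edge replication")
  cols_cl <- pmin(pmax(cols, 1L), W)

  half_bs <- floor(extent_mm * 1000 / 2 / volume$bscan_spacing)
  b0 <- max(1L, round(center[1]) - half_bs)
  b1 <- min(length(volume$bscans), round(center[1]) + half_bs)
  bsel <- b0:b1

  out_h <- out_size[1]
  out_w <- out_size[2]
  bscans <- lapply(volume$bscans[bsel], function(img)
    resize_bilinear(img[, cols_cl, drop = FALSE], out_h, out_w))
  new_vol <- oct_volume(bscans,
                        axial_scale = volume$axial_scale * H / out_h,
                        lateral_scale = volume$lateral_scale * w_c / out_w,
                        bscan_spacing = volume$bscan_spacing,
                        fovea = c(round(center[1]) - b0 + 1L,
                                  round((center[2] - first_col + 0.5) * out_w / w_c + 0.5)),
                        volume_id = paste0(volume$volume_id, "_pp"))
  tr <- structure(list(crop_rows = c(1L, H),
                       crop_cols = as.integer(c(first_col, first_col + w_c - 1L)),
                       bscan_range = c(b0, b1),
                       resize_factors = c(axial = out_h / H, lateral = out_w / w_c),
                       source_dims = c(H, W), out_size = c(out_h, out_w)),
                  class = "preprocess_transform")
  list(volume = new_vol, transform = tr)
}

# Pixel-center coordinate maps shared by the two surface transforms: a source
# row/col r maps to (r - off - 0.5) * factor + 0.5 in the output grid.
#' Map surfaces between source and preprocessed coordinates
#'
#' `apply_transform_to_surfaces` takes surfaces in source-volume coordinates
#' into the cropped/resized grid by sampling each boundary at the source
#' columns of the output A-scans; `invert_transform_surfaces` maps rows and
#' columns back. Within the crop the round trip reproduces the original
#' values to better than 0.5 px.
#'
#' @param surfaces a [surface_set()] on the relevant grid.
#' @param transform a `preprocess_transform` from [crop_and_resize()].
#' @return a [surface_set()] on the other grid.
#' @export
apply_transform_to_surfaces <- function(surfaces, transform) {
  tr <- transform
  out_h <- tr$out_size[1]
  out_w <- tr$out_size[2]
  fa <- tr$resize_factors["axial"]
  fl <- tr$resize_factors["lateral"]
  bsel <- tr$bscan_range[1]:tr$bscan_range[2]
  W <- tr$source_dims[2]
  # source (sub-pixel) column of each output A-scan
  src_col <- pmin(pmax((seq_len(out_w) - 0.5) / fl + tr$crop_cols[1] - 0.5, 1), W)
  vals <- array(NA_real_, c(length(bsel), out_w, 8L))
  for (bi in seq_along(bsel)) {
    for (k in 1:8) {
      row_src <- surfaces$values[bsel[bi], , k]
      if (all(is.na(row_src))) next
      smp <- stats::approx(seq_len(W), row_src, xout = src_col, rule = 2)$y
      vals[bi, , k] <- (smp - 0.5) * fa + 0.5
    }
  }
  surface_set(vals, surfaces$axial_scale / fa)
}

#' @rdname apply_transform_to_surfaces
#' @export
invert_transform_surfaces <- function(surfaces, transform) {
  tr <- transform
  fa <- tr$resize_factors["axial"]
  fl <- tr$resize_factors["lateral"]
  d <- dim(surfaces$values)
  W <- tr$source_dims[2]
  src_col_of_out <- (seq_len(d[2]) - 0.5) / fl + tr$crop_cols[1] - 0.5
  vals <- array(NA_real_, c(tr$bscan_range[2] - tr$bscan_range[1] + 1L, W, 8L))
  for (bi in seq_len(d[1])) {
    for (k in 1:8) {
      rows_out <- surfaces$values[bi, , k]
      if (all(is.na(rows_out))) next
      rows_src <- (rows_out - 0.5) / fa + 0.5
      vals[bi, , k] <- stats::approx(src_col_of_out, rows_src,
                                     xout = seq_len(W), rule = 2)$y
    }
  }
  surface_set(vals, surfaces$axial_scale * fa)
}

#' Quality gate hook
#'
#' Stand-in for an external learned quality classifier: applies a user
#' predicate to every B-scan and reports which pass. The default predicate
#' accepts everything.
#'
#' @param volume an [oct_volume()].
#' @param predicate function(bscan_matrix) -> logical.
#' @return logical vector, one entry per B-scan.
#' @export
quality_gate <- function(volume, predicate = function(b) TRUE) {
  vapply(volume$bscans, function(b) isTRUE(predicate(b)), logical(1))
}
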