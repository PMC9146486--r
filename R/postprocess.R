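# From 9-class maps to clean ordered boundary surfaces: adaptive hole
# filling, column-wise boundary extraction, Laplacian outlier rejection on
# layer thicknesses, PCHIP infill, 3x3 box smoothing and the anatomical
# ordering constraint, in that order.

#' Hole-filling configuration
#'
#' @param f0_outer start divisor of the adaptive area threshold for the first
#'   and last class (above-ILM / below-BM), default 2.
#' @param f0_inner start divisor for the interior classes, default 10.
#' @param connectivity pixel connectivity (8).
#' @return object of class `holefill_config`.
#' @export
holefill_config <- function(f0_outer = 2L, f0_inner = 10L, connectivity = 8L) {
  stopifnot(f0_outer >= 1L, f0_inner >= 1L, connectivity == 8L)
  structure(list(f0_outer = as.integer(f0_outer),
                 f0_inner = as.integer(f0_inner),
                 connectivity = 8L), class = "holefill_config")
}

#' Adaptive component-area threshold
#'
#' With n_n nonzero and n_z zero pixels of a binary class image, the divisor
#' f starts at `f0` and increases by 1 until n_n / f < n_z; the threshold is
#' T = n_n / f. An empty mask yields 0.
#'
#' @param binary_image logical/0-1 matrix (or anything coercible).
#' @param f0 start divisor.
#' @return list with `T` (area threshold) and `f` (final divisor).
#' @export
adaptive_threshold <- function(binary_image, f0 = 2L) {
  nn <- sum(binary_image != 0)
  nz <- length(binary_image) - nn
  if (nn == 0) return(list(T = 0, f = as.integer(f0)))
  f <- as.integer(f0)
  while (nn / f >= nz) f <- f + 1L
  list(T = nn / f, f = f)
}

# Majority label among the 8-neighborhood pixels bordering a component.
border_majority <- function(classmap, comp_cells) {
  H <- nrow(classmap); W <- ncol(classmap)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  cand <- integer(0)
  inside <- matrix(FALSE, H, W)
  inside[comp_cells] <- TRUE
  for (i in seq_len(nrow(offs))) {
    rr <- comp_cells[, 1] + offs$dr[i]
    cc <- comp_cells[, 2] + offs$dc[i]
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    nb <- cbind(rr[ok], cc[ok])
    nb <- nb[!inside[nb], , drop = FALSE]
    if (nrow(nb) > 0) cand <- c(cand, classmap[nb])
  }
  if (length(cand) == 0) return(NA_integer_)
  as.integer(names(which.max(table(cand))))
}

#' Adaptive hole filling of a class map
#'
#' Per class k, background-connected components (8-connectivity) of the class
#' mask's complement with area below the adaptive threshold are filled into
#' class k, and small foreground islands of class k are reassigned to the
#' majority label of their border neighborhood, so the map remains a
#' partition. The threshold uses `f0_outer` for the first and last class and
#' `f0_inner` otherwise. Pixels belonging to a component whose area meets its
#' own class's threshold are never reassigned, so one class's (large, f0=2)
#' hole threshold cannot swallow another class's legitimate region. Hole-free
#' maps are a fixed point.
#'
#' @param classmap integer matrix with labels 1..K (3- or 9-class).
#' @param cfg a [holefill_config()].
#' @param n_classes vocabulary size K; defaults to the maximum label.
#' @return repaired integer class map.
#' @export
fill_holes <- function(classmap, cfg = holefill_config(), n_classes = NULL) {
  K <- if (is.null(n_classes)) max(classmap) else as.integer(n_classes)
  out <- classmap
  storage.mode(out) <- "integer"
  f0_of <- function(k) if (k == 1L || k == K) cfg$f0_outer else cfg$f0_inner
  # pixels in components at/above their own class threshold are protected
  protected <- matrix(FALSE, nrow(out), ncol(out))
  thr_k <- numeric(K)
  for (k in seq_len(K)) {
    mask <- matrix(as.integer(out == k), nrow(out), ncol(out))
    thr_k[k] <- adaptive_threshold(mask, f0_of(k))$T
    lab <- cpp_label_components(mask)
    big <- which(lab$sizes >= thr_k[k])
    if (length(big) > 0) protected[lab$labels %in% big] <- TRUE
  }
  for (k in seq_len(K)) {
    thr <- thr_k[k]
    if (thr <= 0) next
    # holes: small connected components of the class mask's complement
    mask <- matrix(as.integer(out == k), nrow(out), ncol(out))
    labc <- cpp_label_components(1L - mask)
    small <- which(labc$sizes < thr)
    if (length(small) > 0)
      out[labc$labels %in% small & !protected] <- k
    # islands: small components of the class itself
    mask <- matrix(as.integer(out == k), nrow(out), ncol(out))
    labf <- cpp_label_components(mask)
    small <- which(labf$sizes < thr)
    for (id in small) {
      sel <- labf$labels == id & !protected
      if (!any(sel)) next
      cells <- which(sel, arr.ind = TRUE)
      rep_lab <- border_majority(out, cells)
      if (!is.na(rep_lab)) out[cells] <- rep_lab
    }
  }
  out
}

#' Extract boundary surfaces from a 9-class map
#'
#' Boundary b_k (k = 1..8) at column j is the topmost row of region k+1 in
#' that column (region 2 = mRNFL, so b_1 = ILM; region 9 = below BM, so
#' b_8 = BM); columns where the region is absent are missing.
#'
#' @param classmap9 integer matrix with labels 1..9 (ideally hole-filled).
#' @param axial_scale um per pixel.
#' @return a [surface_set()] with one B-scan (missing allowed).
#' @export
extract_surfaces <- function(classmap9, axial_scale = 1) {
  W <- ncol(classmap9)
  vals <- array(NA_real_, c(1L, W, 8L))
  for (k in 1:8) {
    hit <- classmap9 == (k + 1L)
    first <- rep(NA_real_, W)
    any_col <- colSums(hit) > 0
    first[any_col] <- apply(hit[, any_col, drop = FALSE], 2L, which.max)
    vals[1, , k] <- first
  }
  surface_set(vals, axial_scale)
}

# Stack per-B-scan extractions into one volume surface set.
extract_surfaces_volume <- function(classmaps, axial_scale = 1) {
  nb <- length(classmaps)
  W <- ncol(classmaps[[1]])
  vals <- array(NA_real_, c(nb, W, 8L))
  for (i in seq_len(nb))
    vals[i, , ] <- extract_surfaces(classmaps[[i]], axial_scale)$values[1, , ]
  surface_set(vals, axial_scale)
}

#' Laplacian outlier rejection on layer thicknesses
#'
#' For each of the 7 layers, the thickness map t = (b_(k+1) - b_k) *
#' axial_scale over the (B-scan, A-scan) grid is screened with the discrete
#' 5-point Laplacian (per axis, the second difference where both neighbors
#' are available; axes without complete stencils are skipped). Samples with
#' |Laplacian| > tau_um -- and any sample with negative thickness, which is
#' anatomically impossible -- have both bounding surfaces set to missing.
#'
#' @param surfaces a [surface_set()] (missing allowed).
#' @param tau_um Laplacian threshold in um (default 20).
#' @return a [surface_set()] with outliers blanked.
#' @export
remove_outliers <- function(surfaces, tau_um = 20) {
  S <- surfaces$values
  nb <- dim(S)[1]; W <- dim(S)[2]
  flag <- array(FALSE, c(nb, W, 8L))
  second_diff_rows <- function(t) {
    L <- matrix(NA_real_, nrow(t), ncol(t))
    if (nrow(t) >= 3)
      L[2:(nrow(t) - 1), ] <- t[1:(nrow(t) - 2), ] + t[3:nrow(t), ] -
        2 * t[2:(nrow(t) - 1), ]
    L
  }
  for (k in 1:7) {
    t <- (S[, , k + 1, drop = FALSE][, , 1] - S[, , k, drop = FALSE][, , 1]) *
      surfaces$axial_scale
    t <- matrix(t, nb, W)
    Lv <- second_diff_rows(t)
    Lh <- t(second_diff_rows(t(t)))
    lap <- ifelse(is.na(Lv) & is.na(Lh), NA_real_,
                  ifelse(is.na(Lv), Lh, ifelse(is.na(Lh), Lv, Lv + Lh)))
    bad <- (!is.na(lap) & abs(lap) > tau_um) | (!is.na(t) & t < 0)
    flag[, , k] <- flag[, , k] | bad
    flag[, , k + 1] <- flag[, , k + 1] | bad
  }
  S[flag] <- NA_real_
  surface_set(S, surfaces$axial_scale)
}

#' Fill missing surface samples by shape-preserving interpolation
#'
#' Per B-scan and boundary, 1-D PCHIP through the non-missing knots along the
#' A-scan direction, with nearest-knot constant extrapolation beyond the
#' outermost knots. Rows with fewer than 2 knots are copied from the nearest
#' B-scan that could be interpolated; a boundary with no usable row anywhere
#' is an error.
#'
#' @param surfaces a [surface_set()] with missing values.
#' @return a complete [surface_set()].
#' @export
interpolate_missing <- function(surfaces) {
  S <- surfaces$values
  nb <- dim(S)[1]; W <- dim(S)[2]
  for (k in 1:8) {
    done <- logical(nb)
    for (i in seq_len(nb)) {
      y <- S[i, , k]
      ok <- which(!is.na(y))
      if (length(ok) >= 2L) {
        S[i, , k] <- pchip(ok, y[ok], seq_len(W))
        done[i] <- TRUE
      } else if (length(ok) == W) {
        done[i] <- TRUE
      }
    }
    if (!any(done))
      stop("boundary ", boundary_names()[k], " has no B-scan with >= 2 samples")
    for (i in which(!done)) {
      src <- which(done)[which.min(abs(which(done) - i))]
      S[i, , k] <- S[src, , k]
    }
  }
  surface_set(S, surfaces$axial_scale)
}

#' 3 x 3 box smoothing of each surface
#'
#' Uniform 3 x 3 average over the (B-scan, A-scan) grid with edge
#' replication; affine surfaces are unchanged in the interior.
#'
#' @param surfaces a complete [surface_set()].
#' @return smoothed [surface_set()].
#' @export
smooth_surfaces <- function(surfaces) {
  S <- surfaces$values
  nb <- dim(S)[1]; W <- dim(S)[2]
  for (k in 1:8) {
    m <- matrix(S[, , k], nb, W)
    acc <- matrix(0, nb, W)
    for (di in -1:1) {
      ri <- pmin(pmax(seq_len(nb) + di, 1L), nb)
      for (dj in -1:1) {
        cj <- pmin(pmax(seq_len(W) + dj, 1L), W)
        acc <- acc + m[ri, cj, drop = FALSE]
      }
    }
    S[, , k] <- acc / 9
  }
  surface_set(S, surfaces$axial_scale)
}

#' Enforce the anatomical ordering constraint
#'
#' Sequential top-down projection b_k <- max(b_k, b_(k-1)) per sample, so the
#' boundaries are monotone ordered ILM <= ... <= BM everywhere. Ordered input
#' is a fixed point.
#'
#' @param surfaces a complete [surface_set()].
#' @return ordered [surface_set()].
#' @export
enforce_ordering <- function(surfaces) {
  S <- surfaces$values
  for (k in 2:8) S[, , k] <- pmax(S[, , k], S[, , k - 1])
  surface_set(S, surfaces$axial_scale)
}

#' Full postprocessing chain: class maps to clean surfaces
#'
#' Applies, in order: adaptive hole filling per B-scan, boundary extraction,
#' Laplacian outlier rejection, PCHIP infill, 3 x 3 smoothing and ordering.
#'
#' @param classmaps list of integer 9-class maps, one per B-scan.
#' @param axial_scale um per pixel.
#' @param cfg a [holefill_config()].
#' @param tau_um Laplacian outlier threshold in um.
#' @return list with `surfaces` (complete, ordered [surface_set()]) and
#'   `filled` (the hole-filled class maps).
#' @export
extract_clean_surfaces <- function(classmaps, axial_scale,
                                   cfg = holefill_config(), tau_um = 20) {
  filled <- lapply(classmaps, fill_holes, cfg = cfg, n_classes = 9L)
  s <- extract_surfaces_volume(filled, axial_scale)
  s <- remove_outliers(s, tau_um = tau_um)
  s <- interpolate_missing(s)
  s <- smooth_surfaces(s)
  s <- enforce_ordering(s)
  list(surfaces = s, filled = filled)
}
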