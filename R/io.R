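# Containers and readers/writers for volumes, surfaces and metadata.
#
# Conventions: B-scan pixel intensities live in [0,1]; rows are axial with
# row 1 at the top (vitreous side); columns are 1-based A-scan indices;
# surface positions are (sub-pixel) 1-based row coordinates.

#' Boundary surface container
#'
#' A set of the eight ordered retinal boundary surfaces sampled on the
#' (B-scan, A-scan) grid. Values are row positions in px (sub-pixel allowed),
#' `NA` marks missing samples.
#'
#' @param values numeric array `[n_bscans, n_ascans, 8]` (a `W x 8` matrix is
#'   promoted to a single-B-scan array).
#' @param axial_scale um per pixel in the axial direction.
#' @return object of class `surface_set`.
#' @export
surface_set <- function(values, axial_scale) {
  if (is.matrix(values)) {
    values <- array(values, c(1L, nrow(values), ncol(values)))
  }
  stopifnot(length(dim(values)) == 3L, dim(values)[3] == 8L, axial_scale > 0)
  dimnames(values) <- NULL
  structure(list(values = values, axial_scale = axial_scale),
            class = "surface_set")
}

#' @export
print.surface_set <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("surface_set: %d B-scan(s) x %d A-scans x 8 boundaries (%.3g um/px axial), %d missing\n",
              d[1], d[2], x$axial_scale, sum(is.na(x$values))))
  invisible(x)
}

#' OCT volume container
#'
#' @param bscans list of H x W numeric matrices with intensities in \[0,1\],
#'   ordered by acquisition index.
#' @param axial_scale,lateral_scale um per pixel.
#' @param bscan_spacing distance between consecutive B-scans in um.
#' @param fovea optional c(bscan, ascan) foveal position (1-based).
#' @param volume_id identifier used in the on-disk layout.
#' @return object of class `oct_volume`.
#' @export
oct_volume <- function(bscans, axial_scale, lateral_scale, bscan_spacing,
                       fovea = NULL, volume_id = "volume") {
  stopifnot(is.list(bscans), length(bscans) >= 1L)
  dims <- vapply(bscans, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all B-scans must share one shape")
  if (axial_scale <= 0 || lateral_scale <= 0 || bscan_spacing <= 0)
    stop("scales must be positive")
  structure(list(bscans = bscans, axial_scale = axial_scale,
                 lateral_scale = lateral_scale, bscan_spacing = bscan_spacing,
                 fovea = fovea, volume_id = volume_id),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  cat(sprintf("oct_volume '%s': %d B-scans of %d x %d px (axial %.3g, lateral %.3g um/px)\n",
              x$volume_id, length(x$bscans), nrow(x$bscans[[1]]),
              ncol(x$bscans[[1]]), x$axial_scale, x$lateral_scale))
  invisible(x)
}

#' Write / read an OCT volume
#'
#' Two interchangeable on-disk forms are supported: a directory of indexed
#' 8- or 16-bit grayscale PNGs (`bscan_###.png`) with a `meta.json` carrying
#' the scales, or a single HDF5 container (`.h5`) holding the B-scan stack
#' under `/bscans` with scales as attributes (requires the `rhdf5` package).
#' Integer pixel data are rescaled to \[0,1\] on load; B-scans are always
#' ordered by index and a missing index is reported as an error.
#'
#' @param volume an [oct_volume()].
#' @param path directory or `.h5` file path.
#' @return `read_volume` returns an [oct_volume()].
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  if (grepl("\\.h5$", path)) {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop("HDF5 support requires the rhdf5 package")
    if (file.exists(path)) file.remove(path)
    rhdf5::h5createFile(path)
    arr <- simplify2array(volume$bscans)
    rhdf5::h5write(arr, path, "bscans")
    meta <- list(axial_scale = volume$axial_scale,
                 lateral_scale = volume$lateral_scale,
                 bscan_spacing = volume$bscan_spacing,
                 volume_id = volume$volume_id)
    if (!is.null(volume$fovea)) meta$fovea <- volume$fovea
    rhdf5::h5write(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE,
                                                 digits = NA)),
                   path, "meta_json")
    rhdf5::h5closeAll()
    return(invisible(path))
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(volume$bscans)) {
    img <- pmin(pmax(volume$bscans[[i]], 0), 1)
    # png writes 8-bit; quantize explicitly so write/read round trips exactly
    png::writePNG(round(img * 255) / 255,
                  file.path(path, sprintf("bscan_%03d.png", i)))
  }
  meta <- list(volume_id = volume$volume_id, axial_scale = volume$axial_scale,
               lateral_scale = volume$lateral_scale,
               bscan_spacing = volume$bscan_spacing,
               n_bscans = length(volume$bscans),
               image_height = nrow(volume$bscans[[1]]),
               image_width = ncol(volume$bscans[[1]]))
  if (!is.null(volume$fovea)) meta$fovea <- volume$fovea
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (grepl("\\.h5$", path)) {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop("HDF5 support requires the rhdf5 package")
    arr <- rhdf5::h5read(path, "bscans")
    meta <- jsonlite::fromJSON(rhdf5::h5read(path, "meta_json"))
    rhdf5::h5closeAll()
    bscans <- lapply(seq_len(dim(arr)[3]), function(i) arr[, , i])
    return(oct_volume(bscans, meta$axial_scale, meta$lateral_scale,
                      meta$bscan_spacing, fovea = meta$fovea,
                      volume_id = meta$volume_id))
  }
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop("format error: missing meta.json in ", path)
  meta <- jsonlite::fromJSON(meta_path)
  for (k in c("axial_scale", "lateral_scale", "bscan_spacing"))
    if (is.null(meta[[k]])) stop("format error: meta.json lacks field ", k)
  files <- sort(list.files(path, pattern = "^bscan_\\d+\\.png$"))
  if (length(files) == 0L) stop("format error: no bscan_###.png files in ", path)
  idx <- as.integer(sub("^bscan_(\\d+)\\.png$", "\\1", files))
  expect_idx <- seq_len(max(idx))
  gap <- setdiff(expect_idx, idx)
  if (length(gap) > 0)
    stop("format error: missing B-scan index ", paste(gap, collapse = ", "))
  bscans <- lapply(files[order(idx)], function(f) {
    img <- png::readPNG(file.path(path, f))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  })
  dims <- vapply(bscans, dim, integer(2))
  if (any(dims != dims[, 1])) stop("format error: ragged B-scan shapes")
  oct_volume(bscans, meta$axial_scale, meta$lateral_scale, meta$bscan_spacing,
             fovea = if (!is.null(meta$fovea)) as.numeric(meta$fovea) else NULL,
             volume_id = if (!is.null(meta$volume_id)) meta$volume_id else basename(path))
}

#' Write / read boundary surfaces as CSV
#'
#' Long format with columns `bscan`, `ascan`, `boundary_name`, `row_px`
#' (1-based pixel row, sub-pixel precision preserved to <= 1e-6 px; missing
#' samples are written as empty fields). The axial scale is carried in a
#' leading comment line.
#'
#' @param surfaces a [surface_set()].
#' @param path CSV file path.
#' @param axial_scale fallback scale on read when the file lacks the comment.
#' @return `read_surfaces` returns a [surface_set()].
#' @export
write_surfaces <- function(surfaces, path) {
  stopifnot(inherits(surfaces, "surface_set"))
  d <- dim(surfaces$values)
  df <- expand.grid(bscan = seq_len(d[1]), ascan = seq_len(d[2]),
                    boundary_name = boundary_names(),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$row_px <- as.vector(surfaces$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# axial_scale_um_per_px=%.9g", surfaces$axial_scale), con)
  writeLines("bscan,ascan,boundary_name,row_px", con)
  rp <- ifelse(is.na(df$row_px), "", sprintf("%.9g", df$row_px))
  writeLines(paste(df$bscan, df$ascan, df$boundary_name, rp, sep = ","), con)
  invisible(path)
}

#' @rdname write_surfaces
#' @export
read_surfaces <- function(path, axial_scale = NULL) {
  first <- readLines(path, n = 1L)
  skip <- 0L
  if (grepl("^#", first)) {
    skip <- 1L
    m <- regmatches(first, regexec("axial_scale_um_per_px=([0-9.eE+-]+)", first))[[1]]
    if (length(m) == 2L && is.null(axial_scale)) axial_scale <- as.numeric(m[2])
  }
  if (is.null(axial_scale)) axial_scale <- 1
  df <- utils::read.csv(path, skip = skip, stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$boundary_name), boundary_names())
  if (length(bad) > 0)
    stop("format error: unknown boundary name(s): ", paste(bad, collapse = ", "))
  nb <- max(df$bscan)
  na_ <- max(df$ascan)
  vals <- array(NA_real_, c(nb, na_, 8L))
  k <- match(df$boundary_name, boundary_names())
  vals[cbind(df$bscan, df$ascan, k)] <- df$row_px
  surface_set(vals, axial_scale)
}
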