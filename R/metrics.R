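# Evaluation: per-class Dice, per-boundary MAE, macular thickness/volume
# parameters in a circular foveal region, and one-way-ANOVA ICC.

#' Per-class Dice similarity coefficient
#'
#' DSC_k = 2|A_k n B_k| / (|A_k| + |B_k|); a class empty in both maps is
#' defined as 1. Symmetric in its arguments.
#'
#' @param a,b integer label maps of identical shape.
#' @param n_classes vocabulary size; defaults to the maximum label seen.
#' @return named numeric vector of per-class DSC values in \[0,1\].
#' @export
dice <- function(a, b, n_classes = NULL) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  a <- as.integer(a); b <- as.integer(b)
  if (is.null(n_classes)) n_classes <- max(a, b)
  na_ <- tabulate(a, n_classes)
  nb <- tabulate(b, n_classes)
  ni <- tabulate(a[a == b], n_classes)
  d <- ifelse(na_ + nb == 0, 1, 2 * ni / (na_ + nb))
  names(d) <- if (n_classes == 9L) class_names9() else paste0("class", seq_len(n_classes))
  d
}

#' Per-boundary mean absolute surface error
#'
#' Mean and standard deviation over all (B-scan, A-scan) samples of
#' |pred - gold| converted to um via the axial scale, per boundary, plus the
#' overall mean of the per-boundary MAEs. Symmetric in its arguments.
#'
#' @param pred,gold complete [surface_set()]s on the same grid.
#' @return list with `per_boundary` data frame (boundary, mae_um, sd_um) and
#'   `overall_mae_um`.
#' @export
boundary_mae <- function(pred, gold) {
  stopifnot(inherits(pred, "surface_set"), inherits(gold, "surface_set"))
  if (!all(dim(pred$values) == dim(gold$values))) stop("grid mismatch")
  ax <- pred$axial_scale
  err <- abs(pred$values - gold$values) * ax
  mae <- apply(err, 3L, mean)
  sdv <- apply(err, 3L, stats::sd)
  if (all(is.na(sdv))) sdv <- rep(0, 8L)  # single-sample grids
  list(per_boundary = data.frame(boundary = boundary_names(), mae_um = mae,
                                 sd_um = ifelse(is.na(sdv), 0, sdv)),
       overall_mae_um = mean(mae))
}

#' Macular thickness and volume parameters in a foveal region
#'
#' Within a circular region of `region_diameter_mm` centered on the fovea
#' (lateral distance from A-scan spacing and B-scan spacing), computes the
#' mean thickness (um) and volume (mm^3) of: mRNFL (ILM to RNFL-GCL), GCIPL
#' (RNFL-GCL to IPL-INL), INL (IPL-INL to INL-OPL), GCC (ILM to IPL-INL) and
#' TM (ILM to BM). Volume = mean thickness x region area.
#'
#' @param surfaces complete ordered [surface_set()].
#' @param lateral_scale um per pixel laterally.
#' @param bscan_spacing um between B-scans.
#' @param fovea c(bscan, ascan), 1-based.
#' @param region_diameter_mm diameter of the analysis circle (default 5).
#' @return data frame with columns `param`, `thickness_um`, `volume_mm3`.
#' @export
thickness_parameters <- function(surfaces, lateral_scale, bscan_spacing, fovea,
                                 region_diameter_mm = 5.0) {
  S <- surfaces$values
  nb <- dim(S)[1]; W <- dim(S)[2]
  fovea <- as.numeric(unlist(fovea))[1:2]
  if (fovea[1] < 1 || fovea[1] > nb || fovea[2] < 1 || fovea[2] > W)
    stop("fovea outside the surface grid")
  dz <- (seq_len(nb) - fovea[1]) * bscan_spacing
  dx <- (seq_len(W) - fovea[2]) * lateral_scale
  dist <- sqrt(outer(dz^2, dx^2, "+"))
  mask <- dist <= region_diameter_mm * 1000 / 2
  if (!any(mask)) stop("analysis region contains no samples")
  ax <- surfaces$axial_scale
  th <- function(k_top, k_bot)
    (matrix(S[, , k_bot], nb, W) - matrix(S[, , k_top], nb, W)) * ax
  maps <- list(mRNFL = th(1, 2), GCIPL = th(2, 3), INL = th(3, 4),
               GCC = th(1, 3), TM = th(1, 8))
  area_mm2 <- pi * (region_diameter_mm / 2)^2
  data.frame(param = names(maps),
             thickness_um = vapply(maps, function(m) mean(m[mask]), numeric(1)),
             volume_mm3 = vapply(maps, function(m)
               mean(m[mask]) / 1000 * area_mm2, numeric(1)),
             row.names = NULL)
}

#' One-way-ANOVA intraclass correlation coefficient
#'
#' ICC(1,1) from the variance components of a one-way ANOVA over a complete
#' subjects x repeats table: (MSB - MSW) / (MSB + (k-1) MSW), with the
#' confidence interval from the F-distribution bounds.
#'
#' @param data numeric matrix, rows = subjects, columns = repeated measures.
#' @param conf_level confidence level for the interval.
#' @return list with `icc`, `lower`, `upper`, `msb`, `msw`.
#' @export
icc_oneway <- function(data, conf_level = 0.95) {
  data <- as.matrix(data)
  n <- nrow(data); k <- ncol(data)
  if (n < 2L) stop("need at least 2 subjects")
  if (k < 2L) stop("need at least 2 repeats per subject")
  if (any(is.na(data))) stop("complete table required")
  grand <- mean(data)
  subj_means <- rowMeans(data)
  ssb <- k * sum((subj_means - grand)^2)
  ssw <- sum((data - subj_means)^2)
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  alpha <- 1 - conf_level
  fobs <- msb / msw
  fl <- fobs / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
  fu <- fobs * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
  list(icc = icc,
       lower = (fl - 1) / (fl + (k - 1)),
       upper = (fu - 1) / (fu + (k - 1)),
       msb = msb, msw = msw)
}
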