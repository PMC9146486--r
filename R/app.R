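# Reproducible end-to-end experiments: the architecture parameter report and
# the scaled-down phantom benchmark (generate -> train cascade -> predict ->
# postprocess -> evaluate), plus the postprocessing corruption-recovery check.

format_param_count <- function(x) {
  if (x < 1e6) paste0(round(x / 1e3), "K")
  else paste0(format(trunc(x / 1e6 * 100) / 100, nsmall = 0), "M")
}

#' Architecture parameter report
#'
#' Builds the two cascade presets, the studied compression variants and the
#' classic reference U-Net, counts trainable parameters (builder count,
#' verified against the analytic formula) and reports the U-Net / RS-Net
#' size ratio. Deterministic; re-runs produce identical output.
#'
#' @param path optional CSV output path.
#' @return data frame with one row per model plus the ratio row, invisibly
#'   written to `path` when given.
#' @export
run_param_report <- function(path = NULL) {
  rows <- list(
    list(label = "RS-Net (preset)", f = 5L, c = 4L, n = 1L, o = 3L),
    list(label = "RS variant", f = 5L, c = 8L, n = 1L, o = 3L),
    list(label = "IS-Net (preset)", f = 5L, c = 16L, n = 2L, o = 9L),
    list(label = "IS variant", f = 3L, c = 8L, n = 2L, o = 9L),
    list(label = "IS variant", f = 3L, c = 32L, n = 2L, o = 9L))
  out <- lapply(rows, function(r) {
    cfg <- net_config(n = r$n, o = r$o, f = r$f, c = r$c)
    model <- build_compressed_unet(cfg)
    cnt <- count_trainable_parameters(model)
    stopifnot(cnt == count_params_analytic(cfg))
    data.frame(model = r$label, f = r$f, c = r$c, n = r$n, o = r$o,
               parameters = cnt, printed = format_param_count(cnt))
  })
  unet <- build_reference_unet(n = 1L, o = 3L)
  cnt_unet <- count_trainable_parameters(unet)
  out[[length(out) + 1L]] <- data.frame(model = "U-Net (reference)", f = 3L,
                                        c = 64L, n = 1L, o = 3L,
                                        parameters = cnt_unet,
                                        printed = format_param_count(cnt_unet))
  df <- do.call(rbind, out)
  ratio <- cnt_unet / df$parameters[1]
  df <- rbind(df, data.frame(model = "U-Net / RS-Net ratio", f = NA, c = NA,
                             n = NA, o = NA, parameters = round(ratio, 1),
                             printed = sprintf("%.0fx", ratio)))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' Benchmark configuration
#'
#' Defaults describe the scaled-down desk benchmark: 128 x 128 phantoms with
#' the pixel scales enlarged fourfold from the 512-px defaults (so the
#' geometry still spans ~6 x 6 mm), 12/2/2 train/val/test volumes of 25
#' B-scans (300/50/50 B-scans), RS at c=4 and IS at c=8, at most 20 epochs
#' with early stopping.
#'
#' @param image_size B-scan size in px.
#' @param rs_c,is_c base channel depths of the two stages.
#' @param n_train_vols,n_val_vols,n_test_vols volume counts.
#' @param bscans_per_vol B-scans per volume.
#' @param max_epochs,patience,batch_size training control.
#' @param dropout_rate dropout after encoder stages 3-4 during training.
#' @param tau_um Laplacian outlier threshold.
#' @param region fraction parameters are inherited from [phantom_params()].
#' @param dsc_threshold,mae_px_threshold pass/fail limits of the report.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `benchmark_config`.
#' @export
benchmark_config <- function(image_size = 128L, rs_c = 4L, is_c = 8L,
                             n_train_vols = 12L, n_val_vols = 2L,
                             n_test_vols = 2L, bscans_per_vol = 25L,
                             max_epochs = 3L, patience = 2L, batch_size = 4L,
                             dropout_rate = 0.25, tau_um = 20,
                             dsc_threshold = 0.85, mae_px_threshold = 2,
                             seed = 1L) {
  structure(as.list(environment()), class = "benchmark_config")
}

# Phantom parameters for the benchmark canvas: scales grow as the canvas
# shrinks so the field of view stays ~6 x 6 mm.
benchmark_phantom_params <- function(cfg, seed, thin_rnfl = FALSE) {
  scale_up <- 512L / cfg$image_size
  phantom_params(image_height = cfg$image_size, image_width = cfg$image_size,
                 axial_scale = 3.87 * scale_up, lateral_scale = 11.7 * scale_up,
                 n_bscans = cfg$bscans_per_vol, bscan_spacing = 240,
                 thin_rnfl = thin_rnfl, seed = seed)
}

benchmark_volumes <- function(cfg, n_vols, tag_offset) {
  lapply(seq_len(n_vols), function(v) {
    p <- benchmark_phantom_params(cfg, seed = derive_seed(cfg$seed, tag_offset + v),
                                  thin_rnfl = v %% 3L == 0L)
    generate_volume(p)
  })
}

volumes_to_rs_data <- function(vols) {
  x <- list(); y <- list()
  for (g in vols) {
    for (i in seq_along(g$volume$bscans)) {
      x[[length(x) + 1L]] <- matrix(as.vector(g$volume$bscans[[i]]), ncol = 1L)
      y[[length(y) + 1L]] <- g$gt$classmap3[[i]]
    }
  }
  list(x = x, y = y)
}

volumes_to_is_data <- function(vols) {
  x <- list(); y <- list()
  for (g in vols) {
    for (i in seq_along(g$volume$bscans)) {
      x[[length(x) + 1L]] <- make_is_input(g$volume$bscans[[i]], g$gt$classmap3[[i]])
      y[[length(y) + 1L]] <- g$gt$classmap9[[i]]
    }
  }
  list(x = x, y = y)
}

#' Corrupt ground-truth class maps for the recovery check
#'
#' Emulates segmentation artifacts: `hole_frac` of the pixels are relabeled
#' to a random other class (salt-type holes/islands) and `spike_frac` of the
#' (B-scan, A-scan, boundary) samples get a local boundary spike of 5-12 px
#' (clamped between the adjacent boundaries to keep the map a valid ordered
#' partition).
#'
#' @param gt ground truth as returned in `generate_volume()$gt`.
#' @param image_height canvas height in px.
#' @param hole_frac,spike_frac corruption rates.
#' @param seed RNG seed.
#' @return list of corrupted 9-class maps.
#' @export
corrupt_classmaps <- function(gt, image_height, hole_frac = 0.01,
                              spike_frac = 0.005, seed = 1L) {
  set.seed(seed)
  S <- gt$surfaces$values
  nb <- dim(S)[1]; W <- dim(S)[2]
  n_spike <- round(spike_frac * nb * W * 8)
  for (s in seq_len(n_spike)) {
    i <- sample.int(nb, 1); j <- sample.int(W, 1); k <- sample.int(8, 1)
    delta <- sample(c(-1, 1), 1) * stats::runif(1, 5, 12)
    lo <- if (k > 1) S[i, j, k - 1] else 1
    hi <- if (k < 8) S[i, j, k + 1] else image_height + 1
    S[i, j, k] <- min(max(S[i, j, k] + delta, lo), hi)
  }
  maps <- lapply(seq_len(nb), function(i)
    classmap_from_surfaces(matrix(S[i, , ], W, 8L), image_height))
  n_hole <- round(hole_frac * image_height * W)
  lapply(maps, function(m) {
    pix <- sample.int(length(m), n_hole)
    m[pix] <- ((m[pix] - 1L + sample.int(8L, n_hole, replace = TRUE)) %% 9L) + 1L
    m
  })
}

#' Scaled-down end-to-end phantom benchmark
#'
#' Generates train/validation/test phantom volumes, trains the RS and IS
#' stages (IS with teacher forcing), runs cascade inference on the test set,
#' postprocesses to surfaces, and reports the mean 9-class Dice, the mean
#' boundary error in px, and the corruption-recovery MAE of the
#' postprocessing chain, with pass/fail flags against the configured
#' thresholds.
#'
#' @param cfg a [benchmark_config()].
#' @return list of class `benchmark_report`.
#' @export
run_phantom_benchmark <- function(cfg = benchmark_config()) {
  stopifnot(inherits(cfg, "benchmark_config"))
  if (cfg$n_train_vols < 1L) stop("config error: no training volumes")
  t0 <- Sys.time()
  train_vols <- benchmark_volumes(cfg, cfg$n_train_vols, 100L)
  val_vols <- benchmark_volumes(cfg, cfg$n_val_vols, 300L)
  test_vols <- benchmark_volumes(cfg, cfg$n_test_vols, 600L)

  rs_cfg <- net_config(h = cfg$image_size, w = cfg$image_size, n = 1L, o = 3L,
                       f = 5L, c = cfg$rs_c, dropout_rate = cfg$dropout_rate)
  is_cfg <- net_config(h = cfg$image_size, w = cfg$image_size, n = 2L, o = 9L,
                       f = 5L, c = cfg$is_c, dropout_rate = cfg$dropout_rate)
  spec <- function(off) train_spec(max_epochs = cfg$max_epochs,
                                   patience = cfg$patience,
                                   batch_size = cfg$batch_size,
                                   seed = derive_seed(cfg$seed, off))
  rs_fit <- train_stage(build_compressed_unet(rs_cfg, seed = derive_seed(cfg$seed, 21L)),
                        list(train = volumes_to_rs_data(train_vols),
                             val = volumes_to_rs_data(val_vols)),
                        spec(22L))
  is_fit <- train_stage(build_compressed_unet(is_cfg, seed = derive_seed(cfg$seed, 31L)),
                        list(train = volumes_to_is_data(train_vols),
                             val = volumes_to_is_data(val_vols)),
                        spec(32L))

  dsc_acc <- matrix(0, 0, 9L)
  mae_px_all <- c()
  mae_by_boundary <- matrix(0, 0, 8L)
  for (g in test_vols) {
    maps <- predict_volume(rs_fit$model, is_fit$model, g$volume)
    cleaned <- extract_clean_surfaces(maps, g$volume$axial_scale,
                                      tau_um = cfg$tau_um)
    for (i in seq_along(maps))
      dsc_acc <- rbind(dsc_acc, dice(cleaned$filled[[i]], g$gt$classmap9[[i]],
                                     n_classes = 9L))
    err_px <- abs(cleaned$surfaces$values - g$gt$surfaces$values)
    mae_px_all <- c(mae_px_all, mean(err_px))
    mae_by_boundary <- rbind(mae_by_boundary, apply(err_px, 3L, mean))
  }
  dsc_per_class <- colMeans(dsc_acc)
  names(dsc_per_class) <- class_names9()
  mean_dsc <- mean(dsc_per_class)
  mae_px <- mean(mae_px_all)

  # postprocessing robustness: recover ground-truth surfaces from corrupted maps
  cor_vol <- test_vols[[1]]
  corrupted <- corrupt_classmaps(cor_vol$gt, cfg$image_size,
                                 seed = derive_seed(cfg$seed, 900L))
  rec <- extract_clean_surfaces(corrupted, cor_vol$volume$axial_scale,
                                tau_um = cfg$tau_um)
  corruption_mae_px <- mean(abs(rec$surfaces$values - cor_vol$gt$surfaces$values))

  structure(list(
    dsc_per_class = dsc_per_class, mean_dsc = mean_dsc,
    mae_px_per_boundary = stats::setNames(colMeans(mae_by_boundary), boundary_names()),
    mean_mae_px = mae_px,
    corruption_mae_px = corruption_mae_px,
    pass = c(dsc = mean_dsc >= cfg$dsc_threshold,
             mae = mae_px <= cfg$mae_px_threshold,
             corruption = corruption_mae_px <= 1),
    rs_epochs = rs_fit$stopped_epoch, is_epochs = is_fit$stopped_epoch,
    rs_history = rs_fit$history, is_history = is_fit$history,
    runtime_min = as.numeric(difftime(Sys.time(), t0, units = "mins"))),
    class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Phantom benchmark\n")
  cat(sprintf("  mean 9-class DSC: %.4f (pass: %s)\n", x$mean_dsc, x$pass["dsc"]))
  cat(sprintf("  mean boundary MAE: %.3f px (pass: %s)\n", x$mean_mae_px, x$pass["mae"]))
  cat(sprintf("  corruption-recovery MAE: %.3f px (pass: %s)\n",
              x$corruption_mae_px, x$pass["corruption"]))
  cat(sprintf("  epochs: RS %d, IS %d; runtime %.1f min\n",
              x$rs_epochs, x$is_epochs, x$runtime_min))
  invisible(x)
}
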