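# Two-stage cascade: the retina network (RS) segments tissue from a B-scan;
# its hard 3-class map joins the image as the second channel of the
# intraretinal network (IS), which produces the 9-class layer map. Training
# minimizes the weighted focal loss with Adam and early-stops on validation
# pixel accuracy. The IS stage is trained with teacher forcing (ground-truth
# retina channel) and evaluated with the predicted RS output.

#' Training specification
#'
#' @param learning_rate Adam learning rate (fixed 0.001 by default).
#' @param max_epochs epoch cap (80 by default, with early stopping).
#' @param patience epochs without validation-accuracy improvement tolerated
#'   before stopping; must be < max_epochs.
#' @param batch_size minibatch size.
#' @param seed seed controlling shuffling, dropout and weight init fan-out.
#' @param loss_type `"weighted_focal"` (per-class frequency weights computed
#'   from the training labels) or `"focal"` (constant alpha).
#' @param alpha,gamma focal-loss modulating factors.
#' @param verbose print per-epoch metrics.
#' @return object of class `train_spec`.
#' @export
train_spec <- function(learning_rate = 0.001, max_epochs = 80L, patience = 10L,
                       batch_size = 8L, seed = 1L,
                       loss_type = c("weighted_focal", "focal"),
                       alpha = 0.25, gamma = 2, verbose = FALSE) {
  stopifnot(max_epochs >= 1L, patience < max_epochs, batch_size >= 1L)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 loss_type = match.arg(loss_type), alpha = alpha,
                 gamma = gamma, verbose = isTRUE(verbose)),
            class = "train_spec")
}

as_label_vector <- function(y) as.integer(y)

# Mean Dice over classes present in either map, for history reporting.
mean_dice_maps <- function(pred, truth, n_classes) {
  mean(dice(pred, truth, n_classes = n_classes), na.rm = TRUE)
}

#' Train one cascade stage
#'
#' @param model an `octl_model` to optimize.
#' @param dataset list with `train` and optional `val`, each holding `x`
#'   (list of (h*w) x n input matrices) and `y` (list of integer label maps).
#'   Without `val`, training accuracy is monitored instead.
#' @param spec a [train_spec()].
#' @return list with `model` (best-validation weights), `history` data frame
#'   (per-epoch loss/accuracy/DSC) and `stopped_epoch`.
#' @export
train_stage <- function(model, dataset, spec = train_spec()) {
  tr <- dataset$train
  if (is.null(tr) || length(tr$x) == 0L) stop("empty training dataset")
  stopifnot(length(tr$x) == length(tr$y))
  o <- model$cfg$o
  w <- if (spec$loss_type == "weighted_focal") {
    as.numeric(class_weights(tr$y, n_classes = o))
  } else rep(spec$alpha, o)
  val <- dataset$val
  n <- length(tr$x)
  state <- adam_init(model$params)
  best <- list(acc = -Inf, params = model$params, epoch = 0L)
  wait <- 0L
  hist <- list()
  for (epoch in seq_len(spec$max_epochs)) {
    set.seed(derive_seed(spec$seed, 7000L + epoch))
    ord <- sample.int(n)
    ep_loss <- 0
    ep_correct <- 0
    ep_pix <- 0
    for (b0 in seq.int(1L, n, by = spec$batch_size)) {
      ids <- ord[b0:min(b0 + spec$batch_size - 1L, n)]
      grads <- NULL
      bloss <- 0
      for (id in ids) {
        y <- as_label_vector(tr$y[[id]])
        fw <- unet_forward(model, tr$x[[id]], train = TRUE)
        lg <- loss_and_grad(fw$probs, y, w, spec$gamma)
        if (!is.finite(lg$loss))
          stop("NaN/Inf loss at epoch ", epoch, "; aborting (check inputs/lr)")
        bloss <- bloss + lg$loss
        gi <- unet_backward(model, fw$cache, lg$dZ)
        grads <- if (is.null(grads)) gi else Map(`+`, grads, gi)
        pred <- max.col(fw$probs, ties.method = "first")
        ep_correct <- ep_correct + sum(pred == y)
        ep_pix <- ep_pix + length(y)
      }
      grads <- lapply(grads, function(gmat) gmat / length(ids))
      upd <- adam_step(model$params, grads, state, lr = spec$learning_rate)
      model$params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + bloss
    }
    ep_loss <- ep_loss / n
    train_acc <- ep_correct / ep_pix
    ev <- if (!is.null(val)) val else tr
    vacc_num <- 0; vacc_den <- 0; vdsc <- numeric(length(ev$x))
    for (i in seq_along(ev$x)) {
      pr <- unet_forward(model, ev$x[[i]], train = FALSE, keep_cache = FALSE)$probs
      pred <- max.col(pr, ties.method = "first")
      y <- as_label_vector(ev$y[[i]])
      vacc_num <- vacc_num + sum(pred == y)
      vacc_den <- vacc_den + length(y)
      vdsc[i] <- mean_dice_maps(pred, y, o)
    }
    val_acc <- vacc_num / vacc_den
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss,
                                train_acc = train_acc, val_acc = val_acc,
                                val_dsc = mean(vdsc))
    if (spec$verbose)
      message(sprintf("epoch %d: loss %.5f train_acc %.4f val_acc %.4f val_dsc %.4f",
                      epoch, ep_loss, train_acc, val_acc, mean(vdsc)))
    if (val_acc > best$acc) {
      best <- list(acc = val_acc, params = model$params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= spec$patience) break
    }
  }
  model$params <- best$params
  list(model = model, history = do.call(rbind, hist),
       stopped_epoch = length(hist), best_epoch = best$epoch)
}

#' Build the two-channel intraretinal-network input
#'
#' Channel 1 is the B-scan in \[0,1\]; channel 2 encodes the retina map as
#' above-ILM -> 0.0, retina -> 0.5, below-BM -> 1.0 so both channels share
#' one range. Ground-truth 3-class maps may be substituted for the RS output
#' (teacher forcing).
#'
#' @param bscan H x W intensity matrix.
#' @param rs_map integer H x W map with labels in 1..3.
#' @return (H*W) x 2 input matrix.
#' @export
make_is_input <- function(bscan, rs_map) {
  if (!all(dim(bscan) == dim(rs_map))) stop("shape mismatch")
  cbind(as.vector(bscan), (as.vector(rs_map) - 1) / 2)
}

#' Run the trained cascade over a preprocessed volume
#'
#' Per B-scan: RS forward pass, hard 3-class map, [make_is_input()], IS
#' forward pass, hard 9-class map. Inference is deterministic (dropout off).
#'
#' @param rs_model,is_model trained `octl_model`s.
#' @param volume an [oct_volume()] at the networks' input size.
#' @return list of integer H x W 9-class maps, one per B-scan.
#' @export
predict_volume <- function(rs_model, is_model, volume) {
  stopifnot(inherits(volume, "oct_volume"))
  h <- rs_model$cfg$h
  w <- rs_model$cfg$w
  if (nrow(volume$bscans[[1]]) != h || ncol(volume$bscans[[1]]) != w)
    stop("volume B-scans do not match the network input size")
  lapply(volume$bscans, function(img) {
    rs_map <- predict_classmap(rs_model, matrix(as.vector(img), ncol = 1L))
    predict_classmap(is_model, make_is_input(img, rs_map))
  })
}
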