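# Focal loss, class-weighted focal loss and class-frequency weights.
#
# Per pixel x with true class t and predicted probability p_t(x) of that
# class, the contribution is -a_t * (1 - p_t)^gamma * log(p_t): the standard
# multi-class focal term, where a_t is the constant alpha for the plain focal
# loss and the per-class frequency weight w_t = 1 - n_f/n_t for the weighted
# form (with gamma = 0 and alpha = 1 this is exactly categorical
# cross-entropy). The printed definition omits the leading minus sign; the
# loss is implemented negated so that it is non-negative and minimized.
# Aggregation: mean over pixels within each class term, then sum over
# classes, so the per-class weights keep their meaning whatever the image
# size. Probabilities are clipped to [eps, 1-eps], eps = 1e-7.

LOSS_EPS <- 1e-7

#' Loss configuration
#'
#' @param alpha constant modulating factor of the plain focal loss
#'   (default 0.25).
#' @param gamma focusing exponent (default 2; 0 with alpha 1 reduces the
#'   focal loss to categorical cross-entropy).
#' @param class_weights optional per-class weights in \[0,1\] switching to the
#'   weighted form.
#' @return object of class `loss_config`.
#' @export
loss_config <- function(alpha = 0.25, gamma = 2, class_weights = NULL) {
  stopifnot(gamma >= 0)
  if (!is.null(class_weights))
    stopifnot(all(class_weights >= 0 & class_weights <= 1))
  structure(list(alpha = alpha, gamma = gamma, class_weights = class_weights),
            class = "loss_config")
}

#' Per-class weights from training-label frequencies
#'
#' For each class k pooled over the whole label stack,
#' w_k = 1 - n_f(k) / n_t with n_f the foreground pixel count of class k and
#' n_t the total pixel count, so abundant classes are down-weighted.
#'
#' @param label_stack list of integer label matrices (or one matrix/array).
#' @param n_classes vocabulary size; defaults to the maximum label seen.
#' @return named numeric vector of weights in \[0,1\].
#' @export
class_weights <- function(label_stack, n_classes = NULL) {
  if (!is.list(label_stack)) label_stack <- list(label_stack)
  if (length(label_stack) == 0L) stop("empty label stack")
  labs <- unlist(lapply(label_stack, as.integer), use.names = FALSE)
  if (length(labs) == 0L) stop("empty label stack")
  if (is.null(n_classes)) n_classes <- max(labs)
  nf <- tabulate(labs, n_classes)
  w <- 1 - nf / length(labs)
  names(w) <- if (n_classes == 9L) class_names9() else paste0("class", seq_len(n_classes))
  w
}

as_prob_matrix <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) x <- matrix(x, ncol = d[3])
  if (min(x) < -1e-6 || max(x) > 1 + 1e-6)
    stop("probabilities outside [0,1] beyond tolerance")
  x
}

focal_core <- function(pred, onehot, weights, gamma) {
  P <- as_prob_matrix(pred)
  G <- as_prob_matrix(onehot)
  stopifnot(identical(dim(P), dim(G)))
  if (length(weights) != ncol(P))
    stop("need one weight per class")
  present <- colSums(G) > 0
  if (any(present & !is.finite(weights)))
    stop("missing weight for a class present in the ground truth")
  Pc <- pmin(pmax(P, LOSS_EPS), 1 - LOSS_EPS)
  # only the true-class probability of each pixel contributes
  term <- ifelse(G >= 0.5, -(1 - Pc)^gamma * log(Pc), 0)
  sum(colMeans(term) * weights)
}

#' Focal loss
#'
#' @param pred_probs per-pixel class probabilities, (N x C) matrix or
#'   (H, W, C) array; rows must sum to 1.
#' @param onehot_gt one-hot ground truth of the same shape.
#' @param cfg a [loss_config()].
#' @return non-negative scalar loss.
#' @export
focal_loss <- function(pred_probs, onehot_gt, cfg = loss_config()) {
  P <- as_prob_matrix(pred_probs)
  if (max(abs(rowSums(P) - 1)) > 1e-4)
    stop("predicted probabilities must sum to 1 per pixel")
  w <- rep(cfg$alpha, ncol(P))
  focal_core(pred_probs, onehot_gt, w, cfg$gamma)
}

#' Class-weighted focal loss
#'
#' The plain focal loss with the constant alpha replaced per class by the
#' frequency weight w_k (see [class_weights()]).
#'
#' @inheritParams focal_loss
#' @param weights per-class weights indexed by class.
#' @param gamma focusing exponent.
#' @return non-negative scalar loss.
#' @export
weighted_focal_loss <- function(pred_probs, onehot_gt, weights, gamma = 2) {
  focal_core(pred_probs, onehot_gt, weights, gamma)
}

# Loss and gradient w.r.t. logits for training. P: (N x C) softmax output;
# y: integer labels (length N); w: per-class weights. Returns the scalar loss
# and dL/dlogits with the 1/N pixel averaging folded in.
loss_and_grad <- function(P, y, w, gamma) {
  N <- nrow(P)
  C <- ncol(P)
  G <- matrix(0, N, C)
  G[cbind(seq_len(N), y)] <- 1
  Pc <- pmin(pmax(P, LOSS_EPS), 1 - LOSS_EPS)
  W <- matrix(w, N, C, byrow = TRUE)
  loss <- sum(colMeans(ifelse(G == 1, -W * (1 - Pc)^gamma * log(Pc), 0)))
  # d(term)/dp at the true-class entries; all other entries contribute 0
  dfg <- if (gamma == 0) -W / Pc
         else W * (gamma * (1 - Pc)^(gamma - 1) * log(Pc) - (1 - Pc)^gamma / Pc)
  dP <- ifelse(G == 1, dfg, 0) / N
  # clipped entries carry no gradient
  dP[P < LOSS_EPS | P > 1 - LOSS_EPS] <- 0
  dZ <- P * (dP - rowSums(dP * P))
  list(loss = loss, dZ = dZ)
}
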