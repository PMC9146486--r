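# Compressed U-Net builders and parameter accounting.
#
# The template: a 4-stage encoder of two f x f same-padded convolutions with
# ReLU per stage, channel depth doubling from c while 2x2 max pooling halves
# the grid; dropout after stages 3 and 4; a decoder of 2x2 stride-2
# transposed convolutions (halving channels), concatenation with the matching
# encoder skip and two more f x f convolutions; a final 1x1 convolution to o
# classes with per-pixel softmax. No batch normalization. The retina stage
# (RS) uses f=5, c=4, n=1, o=3; the intraretinal stage (IS) uses f=5, c=16,
# n=2, o=9. The classic reference U-Net is the same template with 5 stages,
# f=3 and c=64.

#' Network architecture configuration
#'
#' @param h,w input rows and columns in px; must be divisible by
#'   2^(stages-1).
#' @param n input channels (1 for the retina stage, 2 for the intraretinal
#'   stage which also receives the retina map).
#' @param o output classes.
#' @param f convolution kernel size in px.
#' @param c base channel depth of the first stage (doubles per stage).
#' @param dropout_rate dropout fraction applied after stages 3 and 4 during
#'   training.
#' @param stages encoder depth.
#' @param dropout_stages stages followed by dropout.
#' @return object of class `net_config`.
#' @export
net_config <- function(h = 512L, w = 512L, n = 1L, o = 3L, f = 5L, c = 4L,
                       dropout_rate = 0.5, stages = 4L,
                       dropout_stages = c(3L, 4L)) {
  h <- as.integer(h); w <- as.integer(w)
  if (h %% 2L^(stages - 1L) != 0L || w %% 2L^(stages - 1L) != 0L)
    stop("config error: h and w must be divisible by 2^(stages-1)")
  if (f %% 2L != 1L) stop("config error: kernel size f must be odd")
  structure(list(h = h, w = w, n = as.integer(n), o = as.integer(o),
                 f = as.integer(f), c = as.integer(c),
                 dropout_rate = dropout_rate, stages = as.integer(stages),
                 dropout_stages = as.integer(dropout_stages)),
            class = "net_config")
}

#' Preset configurations for the two cascade stages
#'
#' `"rs"` is the retina-segmentation preset (f=5, c=4, n=1, o=3) and `"is"`
#' the intraretinal preset (f=5, c=16, n=2, o=9), both at 512 x 512 by
#' default; pass a smaller `h`/`w` (and optionally `c`) for scaled-down runs.
#'
#' @param which `"rs"` or `"is"`.
#' @param h,w input size.
#' @param c base channel depth override.
#' @return a [net_config()].
#' @export
net_preset <- function(which = c("rs", "is"), h = 512L, w = 512L, c = NULL) {
  which <- match.arg(which)
  if (which == "rs")
    net_config(h = h, w = w, n = 1L, o = 3L, f = 5L, c = if (is.null(c)) 4L else c)
  else
    net_config(h = h, w = w, n = 2L, o = 9L, f = 5L, c = if (is.null(c)) 16L else c)
}

#' Build a compressed U-Net
#'
#' @param cfg a [net_config()].
#' @param seed seed for the He-normal weight initialization.
#' @return object of class `octl_model` holding the configuration and a flat
#'   named list of parameter arrays.
#' @export
build_compressed_unet <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "net_config"))
  set.seed(seed)
  structure(list(cfg = cfg, params = build_unet_params(cfg)),
            class = "octl_model")
}

#' Build the classic reference U-Net
#'
#' Five levels with channels 64..1024 doubling, two 3x3 same-padded
#' convolutions per level, 2x2 max pooling, 2x2 stride-2 transposed-conv
#' upsampling with skip concatenation and a 1x1 output convolution
#' (~31M trainable parameters for n=1, o=3).
#'
#' @param n input channels.
#' @param o output classes.
#' @param h,w input size (needs divisibility by 16).
#' @param seed weight init seed.
#' @return an `octl_model`.
#' @export
build_reference_unet <- function(n = 1L, o = 3L, h = 512L, w = 512L, seed = 1L) {
  cfg <- net_config(h = h, w = w, n = n, o = o, f = 3L, c = 64L,
                    dropout_rate = 0.5, stages = 5L, dropout_stages = c(4L, 5L))
  build_compressed_unet(cfg, seed = seed)
}

#' @export
print.octl_model <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("octl_model: %d-stage U-Net, f=%d c=%d n=%d o=%d, input %dx%d, %s trainable parameters\n",
              cfg$stages, cfg$f, cfg$c, cfg$n, cfg$o, cfg$h, cfg$w,
              format(count_trainable_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters of a built model
#'
#' Sums the elements of every weight and bias array actually allocated;
#' pooling and dropout contribute nothing.
#'
#' @param model an `octl_model`.
#' @return integer-valued count.
#' @export
count_trainable_parameters <- function(model) {
  stopifnot(inherits(model, "octl_model"))
  sum(vapply(model$params, length, numeric(1)))
}

#' Analytic parameter count of the U-Net template
#'
#' Closed-form layer-by-layer accounting (f^2 * c_in * c_out + c_out per
#' convolution, 4 * c_in * c_out + c_out per 2x2 transposed convolution,
#' c * o + o for the output layer), independent of the builder. Must agree
#' with [count_trainable_parameters()] exactly.
#'
#' @param cfg a [net_config()].
#' @return numeric count.
#' @export
count_params_analytic <- function(cfg) {
  stopifnot(inherits(cfg, "net_config"))
  f2 <- cfg$f^2
  total <- 0
  plan <- unet_channel_plan(cfg)
  for (ch in plan$enc)
    total <- total + f2 * ch$cin * ch$cout + ch$cout + f2 * ch$cout^2 + ch$cout
  for (ch in plan$dec)
    total <- total + 4 * ch$cin_up * ch$cout + ch$cout +
      f2 * 2 * ch$cout * ch$cout + ch$cout + f2 * ch$cout^2 + ch$cout
  total + cfg$c * cfg$o + cfg$o
}

#' Per-pixel class probabilities for one input
#'
#' @param model an `octl_model`.
#' @param x input: an H x W image matrix (single-channel models) or an
#'   (H*W) x n matrix.
#' @return (H*W) x o matrix of softmax probabilities.
#' @export
predict_probs <- function(model, x) {
  cfg <- model$cfg
  if (is.matrix(x) && ncol(x) != cfg$n) {
    if (nrow(x) == cfg$h && ncol(x) == cfg$w && cfg$n == 1L) {
      x <- matrix(as.vector(x), ncol = 1L)
    } else stop("input size does not match the model configuration")
  }
  unet_forward(model, x, train = FALSE, keep_cache = FALSE)$probs
}

#' Hard class map for one input
#'
#' @inheritParams predict_probs
#' @return integer H x W matrix of argmax class labels in 1..o.
#' @export
predict_classmap <- function(model, x) {
  p <- predict_probs(model, x)
  matrix(max.col(p, ties.method = "first"), model$cfg$h, model$cfg$w)
}
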