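# Classifier assembly: compact conv backbone (no global average pooling) ->
# optional 1x1 channel reduction -> flatten -> bilinear layer -> attention
# gate -> dense softmax head.

backbone_specs <- list(
  tiny_cnn  = list(channels = c(8L, 16L, 32L), stride = 8L),
  small_cnn = list(channels = c(8L, 16L, 32L, 64L), stride = 16L)
)

#' Classifier configuration
#'
#' Describes the architecture of a bilinear-attention patch classifier. The
#' backbone is a compact stack of 3x3 convolution + ReLU + 2x2 max-pool
#' blocks sized so the full model trains on a CPU in minutes; `tiny_cnn` has
#' three blocks (total stride 8), `small_cnn` four (stride 16). The global
#' average pooling that ends a conventional classification backbone is
#' deliberately absent: the spatial feature map is flattened whole and fed to
#' the bilinear layer so second-order interactions can couple features at
#' different spatial positions.
#'
#' @param n_classes Number of output classes (>= 2).
#' @param backbone `"tiny_cnn"` or `"small_cnn"`.
#' @param input_size Square patch side in pixels; must be divisible by the
#'   backbone stride. Default 224, the standard histopathology patch size.
#' @param reduce_channels Optional positive integer: insert a 1x1 convolution
#'   reducing the final feature map to this many channels before flattening
#'   (keeps the bilinear layer's input dimension small on large inputs).
#' @param bilinear_m Number of bilinear output nodes `m` (the "bilinear
#'   vector" length). Default 16.
#' @param bilinear_k Number of interaction factors `k` per node. Default 8.
#' @param shared_factors If `TRUE`, all bilinear nodes share one factor
#'   matrix `F` (memory-saving variant); default `FALSE` (per-node factors).
#' @param use_bilinear,use_attention Ablation switches. With
#'   `use_bilinear = FALSE` the bilinear layer is replaced by a dense + ReLU
#'   block of the same width; with `use_attention = FALSE` the attention gate
#'   is dropped. Both default `TRUE` (the full model).
#' @param pretrained_source `"none"` or `"checkpoint"` (provenance label;
#'   weights are loaded via [fine_tune()] / [load_checkpoint()]).
#' @return An object of class `tg_model_config`.
#' @export
model_config <- function(n_classes,
                         backbone = c("tiny_cnn", "small_cnn"),
                         input_size = 224L,
                         reduce_channels = NULL,
                         bilinear_m = 16L,
                         bilinear_k = 8L,
                         shared_factors = FALSE,
                         use_bilinear = TRUE,
                         use_attention = TRUE,
                         pretrained_source = c("none", "checkpoint")) {
  backbone <- match.arg(backbone)
  pretrained_source <- match.arg(pretrained_source)
  bs <- backbone_specs[[backbone]]
  if (n_classes < 2L) stop("`n_classes` must be >= 2", call. = FALSE)
  if (input_size %% bs$stride != 0L) {
    stop(sprintf("`input_size` (%d) must be divisible by the %s stride (%d)",
                 input_size, backbone, bs$stride), call. = FALSE)
  }
  if (!is.null(reduce_channels) && reduce_channels < 1L) {
    stop("`reduce_channels` must be a positive integer", call. = FALSE)
  }
  structure(
    list(n_classes = as.integer(n_classes), backbone = backbone,
         input_size = as.integer(input_size),
         reduce_channels = if (is.null(reduce_channels)) NULL else as.integer(reduce_channels),
         bilinear_m = as.integer(bilinear_m), bilinear_k = as.integer(bilinear_k),
         shared_factors = isTRUE(shared_factors),
         use_bilinear = isTRUE(use_bilinear), use_attention = isTRUE(use_attention),
         pretrained_source = pretrained_source),
    class = "tg_model_config")
}

make_conv_layer <- function(name, H, W, cin, cout, k, pad) {
  plan <- conv_plan(H, W, cin, k, pad)
  fan_in <- k * k * cin
  list(type = "conv", name = name, plan = plan,
       params = list(W = init_uniform(c(fan_in, cout), fan_in),
                     b = numeric(cout)))
}

#' Build a bilinear-attention classifier
#'
#' Assembles the network described by a [model_config()] and initializes all
#' parameters with small uniform draws (+/- 1/sqrt(fan-in)) from a
#' Mersenne-Twister stream seeded by `seed`, so construction is bit-for-bit
#' reproducible.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for parameter initialization.
#' @param class_names Optional character vector of length `n_classes`.
#' @return An object of class `tg_model`.
#' @examples
#' cfg <- model_config(n_classes = 3, input_size = 32, backbone = "tiny_cnn",
#'                     bilinear_m = 8, bilinear_k = 2)
#' model <- build_classifier(cfg, seed = 1)
#' p <- predict_patch(model, array(0.5, dim = c(32, 32, 3)))
#' sum(p)  # 1
#' @export
build_classifier <- function(cfg, seed = 0L, class_names = NULL) {
  stopifnot(inherits(cfg, "tg_model_config"))
  if (!is.null(class_names) && length(class_names) != cfg$n_classes) {
    stop("`class_names` must have length n_classes", call. = FALSE)
  }
  bs <- backbone_specs[[cfg$backbone]]
  with_seed_(seed, {
    layers <- list()
    H <- cfg$input_size
    cin <- 3L
    for (i in seq_along(bs$channels)) {
      cout <- bs$channels[i]
      layers[[length(layers) + 1L]] <- make_conv_layer(paste0("conv", i), H, H, cin, cout, 3L, 1L)
      layers[[length(layers) + 1L]] <- list(type = "relu", name = paste0("relu", i))
      layers[[length(layers) + 1L]] <- list(type = "pool", name = paste0("pool", i))
      H <- H %/% 2L
      cin <- cout
    }
    if (!is.null(cfg$reduce_channels)) {
      layers[[length(layers) + 1L]] <-
        make_conv_layer("reduce", H, H, cin, cfg$reduce_channels, 1L, 0L)
      layers[[length(layers) + 1L]] <- list(type = "relu", name = "relu_reduce")
      cin <- cfg$reduce_channels
    }
    layers[[length(layers) + 1L]] <- list(type = "flatten", name = "flatten")
    n_feat <- H * H * cin
    m <- cfg$bilinear_m
    if (cfg$use_bilinear) {
      k <- cfg$bilinear_k
      Fa <- if (cfg$shared_factors) {
        F1 <- init_uniform(c(k, n_feat), n_feat)
        array(rep(F1, m), dim = c(k, n_feat, m))
      } else {
        init_uniform(c(k, n_feat, m), n_feat)
      }
      layers[[length(layers) + 1L]] <- list(
        type = "bilinear", name = "bilinear",
        params = list(b = numeric(m),
                      W = init_uniform(c(m, n_feat), n_feat),
                      F = Fa))
    } else {
      layers[[length(layers) + 1L]] <- list(
        type = "dense", name = "proj",
        params = list(W = init_uniform(c(n_feat, m), n_feat), b = numeric(m)))
      layers[[length(layers) + 1L]] <- list(type = "relu", name = "relu_proj")
    }
    if (cfg$use_attention) {
      # zero-init: softmax(0) is uniform, so the gate starts neutral and
      # learns which features to emphasize instead of suppressing arbitrary
      # ones from the first step
      layers[[length(layers) + 1L]] <- list(
        type = "attention", name = "attention",
        params = list(w = numeric(m)))
    }
    layers[[length(layers) + 1L]] <- list(
      type = "dense", name = "head",
      params = list(W = init_uniform(c(m, cfg$n_classes), m),
                    b = numeric(cfg$n_classes)))
    structure(list(cfg = cfg, layers = layers, class_names = class_names,
                   provenance = "random-init", seed = as.integer(seed)),
              class = "tg_model")
  })
}

#' @export
print.tg_model <- function(x, ...) {
  cfg <- x$cfg
  n_par <- sum(vapply(x$layers, function(l)
    if (is.null(l$params)) 0 else sum(vapply(l$params, length, numeric(1))),
    numeric(1)))
  cat(sprintf("<tg_model> %s, input %dx%d, %d classes\n", cfg$backbone,
              cfg$input_size, cfg$input_size, cfg$n_classes))
  cat(sprintf("  bilinear: %s (m = %d, k = %d%s) | attention: %s\n",
              if (cfg$use_bilinear) "yes" else "no (dense proj)",
              cfg$bilinear_m, cfg$bilinear_k,
              if (cfg$shared_factors) ", shared F" else "",
              if (cfg$use_attention) "yes" else "no"))
  cat(sprintf("  parameters: %s | provenance: %s\n",
              format(n_par, big.mark = ","), x$provenance))
  invisible(x)
}

# stack a list of [H,W,3] images into a [H,W,3,N] batch array
stack_images <- function(imgs) {
  d <- dim(imgs[[1]])
  X <- array(0, dim = c(d, length(imgs)))
  for (i in seq_along(imgs)) X[, , , i] <- imgs[[i]]
  X
}

check_patch <- function(img, input_size) {
  d <- dim(img)
  if (is.null(d) || length(d) != 3L || d[3] != 3L) {
    stop("patch must be an [H, W, 3] numeric array", call. = FALSE)
  }
  if (d[1] != input_size || d[2] != input_size) {
    stop(sprintf("patch is %dx%d but the model expects %dx%d (no silent resize)",
                 d[1], d[2], input_size, input_size), call. = FALSE)
  }
  invisible(img)
}

#' Predict class probabilities for a patch
#'
#' Runs a single patch through the classifier in evaluation mode and returns
#' the softmax probability vector. The input must already match the model's
#' `input_size`; mismatched patches are an error rather than being resized.
#'
#' @param model A fitted or freshly built classifier (or any object with a
#'   `predict_patch` method, e.g. the plug-in oracle used in pipeline tests).
#' @param img `[H, W, 3]` numeric array with values in `[0, 1]`.
#' @param ... Passed on to methods.
#' @return Named numeric probability vector of length `n_classes`, summing
#'   to 1.
#' @export
predict_patch <- function(model, img, ...) UseMethod("predict_patch")

#' @rdname predict_patch
#' @export
predict_patch.tg_model <- function(model, img, ...) {
  check_patch(img, model$cfg$input_size)
  probs <- predict_batch(model, stack_images(list(img)))[1, ]
  if (!is.null(model$class_names)) names(probs) <- model$class_names
  probs
}

# batched eval-mode prediction; X is [H,W,3,N], returns N x n_classes
predict_batch <- function(model, X) {
  fw <- network_forward(model$layers, X)
  softmax_rows(fw$logits)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the parameter arrays, the
#' [model_config()], the class vocabulary and a provenance string (where the
#' weights came from: random init, a training run, or a fine-tuning source).
#'
#' @param model A `tg_model`.
#' @param path File path (conventionally `.rds`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `tg_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "tg_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$cfg) || is.null(obj$layers)) {
    stop("not a tissuegrid checkpoint: ", path, call. = FALSE)
  }
  structure(obj, class = "tg_model")
}
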