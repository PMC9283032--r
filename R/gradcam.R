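# Grad-CAM: class-discriminative localization heatmaps from the gradients of
# a class logit with respect to a spatial convolutional activation.

spatial_layer_indices <- function(model) {
  flat <- which(vapply(model$layers, function(l) l$type == "flatten", logical(1)))
  seq_len(flat - 1L)
}

resolve_cam_layer <- function(model, layer) {
  names <- vapply(model$layers, function(l) l$name %||% "", character(1))
  spat <- spatial_layer_indices(model)
  if (is.null(layer)) {
    # last ReLU of the final conv block (before its pool), standard hook point
    relus <- spat[vapply(model$layers[spat], function(l) l$type == "relu", logical(1))]
    return(relus[length(relus)])
  }
  i <- match(layer, names)
  if (is.na(i)) stop("no layer named `", layer, "`", call. = FALSE)
  if (!(i %in% spat)) {
    stop("layer `", layer, "` has no spatial activations; Grad-CAM needs a ",
         "convolutional-stage layer", call. = FALSE)
  }
  i
}

#' Grad-CAM heatmap for a patch prediction
#'
#' Computes the gradient of the pre-softmax logit of `target_class` with
#' respect to the activations of a spatial layer (by default the ReLU output
#' of the final convolutional block), averages the gradient over space to get
#' one weight per channel, forms the ReLU of the weighted activation sum,
#' min-max normalizes it, and bilinearly upsamples to the input resolution.
#' A raw map that is identically zero stays all zero; otherwise the maximum
#' is exactly 1.
#'
#' @param model A `tg_model`.
#' @param img `[H, W, 3]` patch matching the model's `input_size`.
#' @param target_class 0-based class id to explain.
#' @param layer Optional layer name (e.g. `"relu3"`, `"conv2"`); must be a
#'   spatial (pre-flatten) layer.
#' @return An object of class `tg_heatmap`: `values` (`input_size` square
#'   matrix in `[0, 1]`), `target_class`, `layer`.
#' @export
gradcam <- function(model, img, target_class, layer = NULL) {
  stopifnot(inherits(model, "tg_model"))
  check_patch(img, model$cfg$input_size)
  if (target_class < 0L || target_class >= model$cfg$n_classes) {
    stop("`target_class` out of range", call. = FALSE)
  }
  li <- resolve_cam_layer(model, layer)
  X <- stack_images(list(img))
  fw <- network_forward(model$layers, X, keep = TRUE)
  dlogits <- matrix(0, 1, model$cfg$n_classes)
  dlogits[1, target_class + 1L] <- 1
  bk <- network_backward(model$layers, fw$caches, dlogits, stop_at = li)
  act <- fw$outs[[li]]                        # [h, w, C, 1]
  grad <- bk$dact
  ch_w <- apply(grad, 3, mean)                # spatial mean per channel
  cam <- matrix(0, dim(act)[1], dim(act)[2])
  for (c in seq_along(ch_w)) cam <- cam + ch_w[c] * act[, , c, 1]
  cam[cam < 0] <- 0
  if (max(cam) > 0) cam <- cam / max(cam)
  size <- model$cfg$input_size
  if (!all(dim(cam) == c(size, size))) {
    cam <- EBImage::imageData(
      EBImage::resize(EBImage::Image(cam), w = size, h = size,
                      filter = "bilinear"))
    cam <- clamp01(cam)
    if (max(cam) > 0) cam <- cam / max(cam)
  }
  structure(list(values = cam, target_class = as.integer(target_class),
                 layer = model$layers[[li]]$name),
            class = "tg_heatmap")
}

#' Blend a Grad-CAM heatmap over its patch
#'
#' Maps the heatmap through a blue-cyan-yellow-red ("jet"-style) colour ramp
#' and alpha-blends it over the patch.
#'
#' @param img `[H, W, 3]` patch.
#' @param heatmap A [gradcam()] result.
#' @param alpha Blend weight of the colour map. Default 0.5.
#' @return `[H, W, 3]` RGB array.
#' @export
gradcam_blend <- function(img, heatmap, alpha = 0.5) {
  stopifnot(inherits(heatmap, "tg_heatmap"))
  ramp <- grDevices::colorRamp(c("blue", "cyan", "yellow", "red"))
  cols <- ramp(as.vector(heatmap$values)) / 255
  H <- nrow(heatmap$values); W <- ncol(heatmap$values)
  out <- img
  for (c in 1:3) {
    out[, , c] <- (1 - alpha) * img[, , c] + alpha * matrix(cols[, c], H, W)
  }
  clamp01(out)
}

#' Write a heatmap (and optional blend) to PNG
#'
#' @param heatmap A [gradcam()] result.
#' @param path Output PNG for the grayscale heatmap.
#' @param img Optional patch; when given, a jet blend is written next to
#'   `path` with suffix `_blend.png`.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(heatmap, path, img = NULL) {
  png::writePNG(heatmap$values, path)
  if (!is.null(img)) {
    png::writePNG(gradcam_blend(img, heatmap),
                  sub("\\.png$", "_blend.png", path))
  }
  invisible(path)
}
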