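# Stage-2 segmentation: threshold tissue masking on a downsampled slide,
# overlapping tile enumeration, per-tile classification, probability
# stitching into a label map, and colour overlay rendering.
#
# Conventions: coordinates are 0-based (row, col) with half-open tile
# footprints [r, r + tile) x [c, c + tile); the label-map value 0 is the
# reserved background/unclassified id and model class c maps to label c + 1.

block_downsample <- function(channel, ds) {
  H <- nrow(channel); W <- ncol(channel)
  gr <- rep(seq_len(ceiling(H / ds)), each = ds)[seq_len(H)]
  gc <- rep(seq_len(ceiling(W / ds)), each = ds)[seq_len(W)]
  m <- rowsum(channel, gr, reorder = TRUE)
  m <- t(rowsum(t(m), gc, reorder = TRUE))
  counts <- tabulate(gr) %o% tabulate(gc)
  m / counts
}

#' Compute a binary tissue mask by thresholding a downsampled slide
#'
#' The slide is block-averaged down by an integer factor, a scalar channel is
#' derived (saturation or grayscale), and a threshold separates tissue from
#' the bright background. `"otsu_saturation"` (default) thresholds the HSV
#' saturation channel with Otsu's method — robust for bright, desaturated
#' backgrounds; `"otsu_gray"` applies Otsu to the gray level and keeps the
#' darker side; `"fixed_threshold"` keeps gray values below `threshold`.
#' A constant (blank) slide yields an all-zero mask with a warning.
#'
#' @param slide `[H, W, 3]` numeric array in `[0, 1]`.
#' @param downsample Integer downsampling factor (>= 1); the mask has
#'   dimensions `ceiling(dim / downsample)`. Default 32.
#' @param method One of `"otsu_saturation"`, `"otsu_gray"`,
#'   `"fixed_threshold"`.
#' @param threshold Gray cutoff for `"fixed_threshold"` (tissue where
#'   `gray < threshold`).
#' @return An object of class `tg_tissue_mask`: `mask` (0/1 integer matrix),
#'   `downsample`, `method`, `threshold` (the value actually used).
#' @export
compute_tissue_mask <- function(slide, downsample = 32L,
                                method = c("otsu_saturation", "otsu_gray",
                                           "fixed_threshold"),
                                threshold = NULL) {
  method <- match.arg(method)
  stopifnot(downsample >= 1L, length(dim(slide)) == 3L)
  ds <- as.integer(downsample)
  small <- array(0, dim = c(ceiling(dim(slide)[1] / ds),
                            ceiling(dim(slide)[2] / ds), 3L))
  for (c in 1:3) small[, , c] <- block_downsample(slide[, , c], ds)
  mx <- pmax(small[, , 1], small[, , 2], small[, , 3])
  mn <- pmin(small[, , 1], small[, , 2], small[, , 3])
  gray <- (small[, , 1] + small[, , 2] + small[, , 3]) / 3
  channel <- switch(method,
                    otsu_saturation = (mx - mn) / pmax(mx, 1e-8),
                    otsu_gray = gray,
                    fixed_threshold = gray)
  if (diff(range(channel)) < 1e-6) {
    warning("blank slide: constant intensity, returning an all-zero mask")
    mask <- matrix(0L, nrow(channel), ncol(channel))
    return(structure(list(mask = mask, downsample = ds, method = method,
                          threshold = NA_real_), class = "tg_tissue_mask"))
  }
  thr <- switch(method,
    otsu_saturation = ,
    otsu_gray = EBImage::otsu(EBImage::Image(clamp01(channel)),
                              range = c(0, 1), levels = 256),
    fixed_threshold = {
      if (is.null(threshold)) stop("`threshold` required for fixed_threshold",
                                   call. = FALSE)
      threshold
    })
  mask <- switch(method,
                 otsu_saturation = channel > thr,   # tissue is saturated
                 otsu_gray = ,
                 fixed_threshold = channel < thr)   # tissue is darker
  structure(list(mask = matrix(as.integer(mask), nrow(channel)),
                 downsample = ds, method = method, threshold = as.numeric(thr)),
            class = "tg_tissue_mask")
}

# nearest-neighbour upsampling of the mask to full slide resolution
mask_full_res <- function(mask, slide_dims) {
  ds <- mask$downsample
  mask$mask[ceiling(seq_len(slide_dims[1]) / ds),
            ceiling(seq_len(slide_dims[2]) / ds), drop = FALSE]
}

#' Enumerate sliding-window tiles over the tissue region
#'
#' Tile top-left corners run over `0, stride, 2*stride, ...` in each
#' dimension; windows that would extend past the slide are dropped (no
#' padding). A tile is kept when its footprint's tissue fraction — measured
#' on the nearest-neighbour-upsampled mask — is at least `tissue_frac_min`.
#' Tiles are ordered row-major.
#'
#' @param mask A [compute_tissue_mask()] result.
#' @param slide_dims `c(H, W)` of the full-resolution slide.
#' @param tile_size Window side in pixels. Default 224.
#' @param stride Step between window origins. Default 128.
#' @param tissue_frac_min Minimum tissue fraction to keep a tile.
#'   Default 0.5.
#' @return An object of class `tg_tile_grid` whose `coords` is a tibble with
#'   0-based `row`, `col` and the measured `tissue_frac`.
#' @export
enumerate_tiles <- function(mask, slide_dims, tile_size = 224L, stride = 128L,
                            tissue_frac_min = 0.5) {
  stopifnot(inherits(mask, "tg_tissue_mask"), stride >= 1L)
  H <- slide_dims[1]; W <- slide_dims[2]
  if (tile_size > H || tile_size > W) {
    stop(sprintf("tile_size (%d) exceeds slide dimensions (%d x %d)",
                 tile_size, H, W), call. = FALSE)
  }
  full <- mask_full_res(mask, slide_dims)
  # integral image for O(1) footprint sums
  S <- rbind(0, apply(full, 2, cumsum))
  S <- cbind(0, t(apply(S, 1, cumsum)))
  r0 <- seq(0L, H - tile_size, by = stride)
  c0 <- seq(0L, W - tile_size, by = stride)
  rows <- rep(r0, each = length(c0))
  cols <- rep(c0, times = length(r0))
  ts <- tile_size
  frac <- (S[cbind(rows + ts + 1L, cols + ts + 1L)] -
           S[cbind(rows + 1L, cols + ts + 1L)] -
           S[cbind(rows + ts + 1L, cols + 1L)] +
           S[cbind(rows + 1L, cols + 1L)]) / (ts * ts)
  keep <- frac >= tissue_frac_min
  structure(list(coords = tibble::tibble(row = as.integer(rows[keep]),
                                         col = as.integer(cols[keep]),
                                         tissue_frac = frac[keep]),
                 tile_size = as.integer(tile_size), stride = as.integer(stride),
                 tissue_frac_min = tissue_frac_min,
                 slide_dims = as.integer(slide_dims)),
            class = "tg_tile_grid")
}

#' @export
print.tg_tile_grid <- function(x, ...) {
  cat(sprintf("<tg_tile_grid> %d tiles of %d px, stride %d, over %d x %d slide\n",
              nrow(x$coords), x$tile_size, x$stride,
              x$slide_dims[1], x$slide_dims[2]))
  invisible(x)
}

#' Classify every tile of a grid
#'
#' Runs the classifier over all tiles, batched for `tg_model`s; any other
#' object with a [predict_patch()] method (such as [oracle_classifier()]) is
#' called tile by tile with the tile's coordinates. Row `t` of the result is
#' the probability vector of tile `t`, in `grid$coords` order.
#'
#' @param model A `tg_model` or other `predict_patch`-capable object whose
#'   `input_size` equals the grid's `tile_size`.
#' @param slide `[H, W, 3]` numeric array.
#' @param grid A [enumerate_tiles()] result.
#' @param batch_size Tiles per forward pass for `tg_model`s. Default 32.
#' @return An `n_tiles x n_classes` probability matrix.
#' @export
classify_tiles <- function(model, slide, grid, batch_size = 32L) {
  stopifnot(inherits(grid, "tg_tile_grid"))
  if (model$cfg$input_size != grid$tile_size) {
    stop(sprintf("model input_size (%d) != grid tile_size (%d)",
                 model$cfg$input_size, grid$tile_size), call. = FALSE)
  }
  co <- grid$coords
  n <- nrow(co)
  ts <- grid$tile_size
  probs <- matrix(0, n, model$cfg$n_classes)
  if (n == 0L) return(probs)
  get_tile <- function(t) {
    slide[(co$row[t] + 1L):(co$row[t] + ts),
          (co$col[t] + 1L):(co$col[t] + ts), , drop = FALSE]
  }
  if (inherits(model, "tg_model")) {
    for (start in seq(1L, n, by = batch_size)) {
      idx <- start:min(start + batch_size - 1L, n)
      probs[idx, ] <- predict_batch(model, stack_images(lapply(idx, get_tile)))
    }
  } else {
    for (t in seq_len(n)) {
      probs[t, ] <- predict_patch(model, get_tile(t),
                                  coords = c(co$row[t], co$col[t]))
    }
  }
  probs
}

#' Stitch tile probabilities into a segmentation map
#'
#' Each tile's probability vector is accumulated over its pixel footprint and
#' a per-pixel coverage count is kept. Where tiles overlap (stride < tile
#' size) the accumulated probabilities are averaged by coverage before the
#' argmax, which makes the result independent of tile order and smooths
#' tile-boundary artifacts; with non-overlapping tiles this reduces exactly
#' to the per-tile argmax. Ties break toward the lowest class id. Pixels no
#' tile covers carry the reserved id 0; model class `c` maps to label
#' `c + 1`.
#'
#' @param grid A [enumerate_tiles()] result.
#' @param probs Probability matrix from [classify_tiles()] (rows aligned with
#'   `grid$coords`).
#' @param slide_dims `c(H, W)`; defaults to the grid's.
#' @return An object of class `tg_segmentation`: `label_map` (`H x W`
#'   integer), `prob_field` (`[H, W, n_classes]` accumulated probabilities),
#'   `coverage` (`H x W` integer).
#' @export
stitch_segmentation <- function(grid, probs, slide_dims = grid$slide_dims) {
  stopifnot(inherits(grid, "tg_tile_grid"))
  co <- grid$coords
  if (!is.matrix(probs) || nrow(probs) != nrow(co)) {
    stop("`probs` rows must align with grid$coords", call. = FALSE)
  }
  H <- slide_dims[1]; W <- slide_dims[2]
  K <- ncol(probs)
  ts <- grid$tile_size
  field <- array(0, dim = c(H, W, K))
  coverage <- matrix(0L, H, W)
  for (t in seq_len(nrow(co))) {
    rows <- (co$row[t] + 1L):(co$row[t] + ts)
    cols <- (co$col[t] + 1L):(co$col[t] + ts)
    for (k in seq_len(K)) {
      field[rows, cols, k] <- field[rows, cols, k] + probs[t, k]
    }
    coverage[rows, cols] <- coverage[rows, cols] + 1L
  }
  covered <- coverage > 0L
  flat <- matrix(field, H * W, K)
  lab <- max.col(flat, ties.method = "first")   # lowest id wins ties
  label_map <- matrix(0L, H, W)
  label_map[covered] <- lab[as.vector(covered)]
  structure(list(label_map = label_map, prob_field = field,
                 coverage = coverage),
            class = "tg_segmentation")
}

#' @export
print.tg_segmentation <- function(x, ...) {
  covered <- mean(x$coverage > 0)
  cat(sprintf("<tg_segmentation> %d x %d, %.1f%% covered, %d classes present\n",
              nrow(x$label_map), ncol(x$label_map), 100 * covered,
              length(setdiff(unique(as.vector(x$label_map)), 0L))))
  invisible(x)
}

#' Render a colour overlay of a segmentation map
#'
#' Alpha-blends one palette colour per label over the slide; background /
#' unclassified pixels (label 0) keep the original slide pixel. The returned
#' image carries a `legend` attribute (tibble of label, class name, hex
#' colour) that [write_overlay()] writes as a JSON sidecar.
#'
#' @param slide `[H, W, 3]` numeric array.
#' @param seg A [stitch_segmentation()] result.
#' @param palette `K x 3` matrix of RGB colours in `[0, 1]` for labels
#'   `1..K`, or `NULL` for an evenly spaced hue palette.
#' @param alpha Blend weight in `[0, 1]`: 0 returns the slide, 1 pure colour.
#' @param class_names Optional names for the legend.
#' @return `[H, W, 3]` numeric array with attribute `legend`.
#' @export
render_overlay <- function(slide, seg, palette = NULL, alpha = 0.5,
                           class_names = NULL) {
  stopifnot(inherits(seg, "tg_segmentation"), alpha >= 0, alpha <= 1)
  labs <- sort(setdiff(unique(as.vector(seg$label_map)), 0L))
  K <- max(c(labs, 0L))
  if (is.null(palette)) {
    cols <- grDevices::hcl(h = seq(15, 375, length.out = K + 1)[seq_len(K)],
                           c = 100, l = 60)
    palette <- t(grDevices::col2rgb(cols) / 255)
  }
  if (K > 0 && nrow(palette) < K) {
    stop("palette is missing colours for some labels present in the map",
         call. = FALSE)
  }
  out <- slide
  for (l in labs) {
    sel <- seg$label_map == l
    for (c in 1:3) {
      ch <- out[, , c]
      ch[sel] <- (1 - alpha) * slide[, , c][sel] + alpha * palette[l, c]
      out[, , c] <- ch
    }
  }
  if (is.null(class_names)) class_names <- paste0("class_", labs - 1L)
  legend <- tibble::tibble(
    label = labs,
    class = class_names[seq_along(labs)],
    color = grDevices::rgb(palette[labs, 1], palette[labs, 2], palette[labs, 3]))
  attr(out, "legend") <- legend
  out
}

#' Write segmentation outputs to disk
#'
#' `write_overlay` writes the blended overlay PNG plus a JSON legend sidecar
#' (`<path>.legend.json`). `write_label_map` writes the label map as a
#' grayscale PNG (pixel value = label id) plus the same legend sidecar.
#' `write_tile_predictions` writes the per-tile CSV
#' (row, col, class, per-class probabilities).
#'
#' @param overlay Result of [render_overlay()].
#' @param path Output PNG path.
#' @return The path, invisibly.
#' @export
write_overlay <- function(overlay, path) {
  png::writePNG(clamp01(overlay), path)
  leg <- attr(overlay, "legend")
  if (!is.null(leg)) {
    jsonlite::write_json(leg, paste0(path, ".legend.json"),
                         dataframe = "rows", auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_overlay
#' @param seg A `tg_segmentation`.
#' @param class_names Optional class names for the legend.
#' @export
write_label_map <- function(seg, path, class_names = NULL) {
  K <- max(seg$label_map)
  png::writePNG(seg$label_map / 255, path)
  labs <- sort(setdiff(unique(as.vector(seg$label_map)), 0L))
  if (is.null(class_names)) class_names <- paste0("class_", labs - 1L)
  jsonlite::write_json(
    tibble::tibble(label = labs, class = class_names[seq_along(labs)]),
    paste0(path, ".legend.json"), dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_overlay
#' @param grid A `tg_tile_grid`.
#' @param probs Probability matrix from [classify_tiles()].
#' @export
write_tile_predictions <- function(grid, probs, path, class_names = NULL) {
  if (is.null(class_names)) class_names <- paste0("class_", seq_len(ncol(probs)) - 1L)
  tab <- tile_predictions(grid, probs, class_names)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Per-tile predictions as a tibble
#'
#' @param grid A `tg_tile_grid`.
#' @param probs Probability matrix aligned with `grid$coords`.
#' @param class_names Class vocabulary for naming the probability columns.
#' @return Tibble with `row`, `col`, `class` (argmax name) and one
#'   probability column per class.
#' @export
tile_predictions <- function(grid, probs, class_names = NULL) {
  if (is.null(class_names)) class_names <- paste0("class_", seq_len(ncol(probs)) - 1L)
  pick <- max.col(probs, ties.method = "first")
  out <- tibble::tibble(row = grid$coords$row, col = grid$coords$col,
                        class = class_names[pick])
  pm <- tibble::as_tibble(as.data.frame(probs))
  names(pm) <- paste0("p_", class_names)
  tibble::as_tibble(cbind(out, pm))
}
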