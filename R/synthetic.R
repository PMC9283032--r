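# Synthetic texture patches and mosaic pseudo-slides.
#
# The generator emulates the statistical structure that makes multitissue
# patch classification hard: large within-class appearance spread (every
# patch redraws orientation, frequency, phase, tint and noise from its class
# ranges) and, in the "hard" preset, small between-class gaps (classes whose
# parameter ranges overlap, distinguishable mainly through joint
# orientation-by-frequency statistics). Mosaic slides place textured
# rectangles on a near-white background with an exact ground-truth label
# map, standing in for an H&E slide whose background is bright.

#' Texture class specification
#'
#' @param class_id Integer class id (0-based).
#' @param family One of `"stripes"`, `"blobs"`, `"checker"`, `"smooth_tint"`,
#'   `"noise"`.
#' @param orientation Degrees, `c(lo, hi)` (stripes).
#' @param frequency Cycles per pixel, `c(lo, hi)` (stripes).
#' @param cell Checker cell side in pixels, `c(lo, hi)`.
#' @param radius Blob radius in pixels, `c(lo, hi)`.
#' @param density Blobs per 1000 square pixels, `c(lo, hi)`.
#' @param fg,bg RGB triples in `[0, 1]`: foreground and background tints.
#'   Defaults evoke an H&E palette (dark purple on pink).
#' @param tint_jitter Half-width of the uniform per-draw perturbation applied
#'   to each tint channel.
#' @param noise_sd Standard deviation of the additive Gaussian pixel noise.
#' @param jitter Within-class spread in `[0, 1]`: 0 pins every parameter to
#'   the midpoint of its range (and freezes phase), 1 samples the full range.
#' @return An object of class `tg_texture_spec`.
#' @export
texture_spec <- function(class_id, family = c("stripes", "blobs", "checker",
                                              "smooth_tint", "noise"),
                         orientation = c(0, 180), frequency = c(0.08, 0.2),
                         cell = c(3, 6), radius = c(2, 4), density = c(4, 8),
                         fg = c(0.35, 0.2, 0.5), bg = c(0.9, 0.65, 0.75),
                         tint_jitter = 0.05, noise_sd = 0.03, jitter = 1) {
  family <- match.arg(family)
  if (jitter < 0 || jitter > 1) stop("`jitter` must lie in [0, 1]", call. = FALSE)
  rng2 <- function(r) if (length(r) == 1L) c(r, r) else r[1:2]
  structure(list(class_id = as.integer(class_id), family = family,
                 orientation = rng2(orientation), frequency = rng2(frequency),
                 cell = rng2(cell), radius = rng2(radius), density = rng2(density),
                 fg = fg, bg = bg, tint_jitter = tint_jitter,
                 noise_sd = noise_sd, jitter = jitter),
            class = "tg_texture_spec")
}

draw_in <- function(range, jitter) {
  mid <- mean(range)
  half <- diff(range) / 2
  mid + (stats::runif(1) * 2 - 1) * jitter * half
}

draw_tint <- function(base, tint_jitter, jitter) {
  clamp01(base + (stats::runif(3) * 2 - 1) * tint_jitter * jitter)
}

# render an h x w texture for a spec, using the current RNG stream
render_texture <- function(spec, h, w) {
  j <- spec$jitter
  fg <- draw_tint(spec$fg, spec$tint_jitter, j)
  bg <- draw_tint(spec$bg, spec$tint_jitter, j)
  rowv <- matrix(seq_len(h), nrow = h, ncol = w)
  colv <- matrix(seq_len(w), nrow = h, ncol = w, byrow = TRUE)
  pat <- switch(spec$family,
    stripes = {
      th <- draw_in(spec$orientation, j) * pi / 180
      f <- draw_in(spec$frequency, j)
      phase <- if (j > 0) stats::runif(1, 0, 2 * pi) else 0
      0.5 + 0.5 * sin(2 * pi * f * (colv * cos(th) + rowv * sin(th)) + phase)
    },
    checker = {
      s <- max(1, round(draw_in(spec$cell, j)))
      off_r <- if (j > 0) sample.int(s, 1L) - 1L else 0L
      off_c <- if (j > 0) sample.int(s, 1L) - 1L else 0L
      ((((rowv + off_r) %/% s) + ((colv + off_c) %/% s)) %% 2)
    },
    blobs = {
      dens <- draw_in(spec$density, j)
      n_blob <- max(1L, round(dens * h * w / 1000))
      p <- matrix(0, h, w)
      for (b in seq_len(n_blob)) {
        r0 <- stats::runif(1, 1, h); c0 <- stats::runif(1, 1, w)
        rad <- draw_in(spec$radius, max(j, 1e-9))
        p[(rowv - r0)^2 + (colv - c0)^2 <= rad^2] <- 1
      }
      p
    },
    smooth_tint = {
      gdir <- if (j > 0) stats::runif(1, 0, 2 * pi) else 0
      g <- (colv * cos(gdir) + rowv * sin(gdir))
      0.5 + 0.1 * (g - mean(g)) / max(abs(g - mean(g)), 1)
    },
    noise = matrix(stats::runif(h * w), h, w))
  img <- array(0, dim = c(h, w, 3))
  for (c in 1:3) img[, , c] <- bg[c] + pat * (fg[c] - bg[c])
  if (spec$noise_sd > 0) {
    img <- img + array(stats::rnorm(h * w * 3, 0, spec$noise_sd), dim = dim(img))
  }
  clamp01(img)
}

#' Generate one texture patch
#'
#' Deterministic given the RNG state (or `seed`); with `jitter = 0` repeated
#' calls under the same seed return identical patches, while any positive
#' jitter makes every draw differ (within-class variability).
#'
#' @param spec A [texture_spec()].
#' @param size Square patch side in pixels (>= 16).
#' @param seed Optional integer seed for a self-contained draw.
#' @return An `[size, size, 3]` array in `[0, 1]`.
#' @export
generate_patch <- function(spec, size, seed = NULL) {
  stopifnot(inherits(spec, "tg_texture_spec"))
  if (size < 16L) stop("`size` must be >= 16 pixels", call. = FALSE)
  if (!is.null(seed)) return(with_seed_(seed, render_texture(spec, size, size)))
  render_texture(spec, size, size)
}

#' Preset texture class vocabularies
#'
#' `"easy"` has six classes from visibly different families with disjoint
#' parameter ranges; `"hard"` has six classes dominated by a 2x2
#' orientation-by-frequency grid of stripe classes whose marginal ranges
#' overlap (plus checker and blob classes sharing the same tints and higher
#' noise), so joint second-order statistics carry most of the class signal.
#'
#' @param preset `"easy"` or `"hard"`.
#' @return Named list: `specs` (list of [texture_spec()]),
#'   `class_names` (character).
#' @export
synthetic_presets <- function(preset = c("easy", "hard")) {
  preset <- match.arg(preset)
  if (preset == "easy") {
    # class definitions are closed under the 90-degree-rotation / flip
    # augmentation group: stripe classes differ by frequency, not orientation
    specs <- list(
      texture_spec(0L, "stripes", orientation = c(0, 180), frequency = c(0.05, 0.08)),
      texture_spec(1L, "stripes", orientation = c(0, 180), frequency = c(0.16, 0.22)),
      texture_spec(2L, "checker", cell = c(5, 9)),
      texture_spec(3L, "blobs", radius = c(2, 4), density = c(8, 14),
                   fg = c(0.25, 0.15, 0.45), bg = c(0.92, 0.7, 0.78)),
      texture_spec(4L, "smooth_tint", fg = c(0.85, 0.55, 0.7), bg = c(0.95, 0.75, 0.85),
                   noise_sd = 0.015),
      texture_spec(5L, "noise", noise_sd = 0.1))
    names <- c("stripes_coarse", "stripes_fine", "checker", "blobs", "tint", "speckle")
  } else {
    specs <- list(
      texture_spec(0L, "stripes", orientation = c(0, 40), frequency = c(0.08, 0.14),
                   noise_sd = 0.08),
      texture_spec(1L, "stripes", orientation = c(20, 60), frequency = c(0.08, 0.14),
                   noise_sd = 0.08),
      texture_spec(2L, "stripes", orientation = c(0, 40), frequency = c(0.13, 0.2),
                   noise_sd = 0.08),
      texture_spec(3L, "stripes", orientation = c(20, 60), frequency = c(0.13, 0.2),
                   noise_sd = 0.08),
      texture_spec(4L, "checker", cell = c(4, 8), noise_sd = 0.08),
      texture_spec(5L, "blobs", radius = c(2, 5), density = c(3, 7), noise_sd = 0.08))
    names <- c("str_lo_a", "str_lo_b", "str_hi_a", "str_hi_b", "checker", "blobs")
  }
  list(specs = specs, class_names = names)
}

#' Generate a balanced labelled patch dataset
#'
#' @param specs List of [texture_spec()] (class ids must be `0..K-1`).
#' @param n_per_class Patches per class.
#' @param size Patch side in pixels.
#' @param seed Integer seed; the whole dataset is a pure function of it.
#' @param class_names Optional vocabulary; defaults to `class_<id>`.
#' @return A [patch_dataset()] with exactly `n_per_class` patches per class,
#'   ordered class-major.
#' @export
generate_patch_dataset <- function(specs, n_per_class, size, seed = 0L,
                                   class_names = NULL) {
  stopifnot(n_per_class >= 1L)
  ids <- vapply(specs, function(s) s$class_id, integer(1))
  if (!identical(sort(ids), seq_along(specs) - 1L)) {
    stop("spec class_ids must be 0..K-1 without gaps", call. = FALSE)
  }
  if (is.null(class_names)) class_names <- paste0("class_", ids)
  with_seed_(seed, {
    images <- vector("list", length(specs) * n_per_class)
    labels <- integer(length(images))
    i <- 0L
    for (s in specs[order(ids)]) {
      for (r in seq_len(n_per_class)) {
        i <- i + 1L
        images[[i]] <- generate_patch(s, size)
        labels[i] <- s$class_id
      }
    }
    patch_dataset(images, labels, class_names)
  })
}

# ---- mosaic pseudo-slides ---------------------------------------------------

#' Mosaic slide layout
#'
#' Rectangular, non-overlapping textured regions on a near-white canvas.
#'
#' @param canvas `c(H, W)` canvas size in pixels.
#' @param regions A data frame / tibble with columns `row0`, `col0` (0-based
#'   top-left), `height`, `width`, `class_id`.
#' @param background RGB triple of the background tint (default near-white,
#'   `c(245, 245, 245) / 255`).
#' @param background_noise_sd Gaussian noise added to the background.
#' @return An object of class `tg_mosaic_layout`.
#' @export
mosaic_layout <- function(canvas, regions,
                          background = c(245, 245, 245) / 255,
                          background_noise_sd = 0.008) {
  regions <- tibble::as_tibble(regions)
  need <- c("row0", "col0", "height", "width", "class_id")
  if (!all(need %in% names(regions))) {
    stop("`regions` needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  H <- canvas[1]; W <- canvas[2]
  if (any(regions$row0 < 0 | regions$col0 < 0 |
          regions$row0 + regions$height > H |
          regions$col0 + regions$width > W)) {
    stop("layout error: a region extends beyond the canvas", call. = FALSE)
  }
  n <- nrow(regions)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        a <- regions[i, ]; b <- regions[j, ]
        if (a$row0 < b$row0 + b$height && b$row0 < a$row0 + a$height &&
            a$col0 < b$col0 + b$width && b$col0 < a$col0 + a$width) {
          stop(sprintf("layout error: regions %d and %d overlap", i, j),
               call. = FALSE)
        }
      }
    }
  }
  structure(list(canvas = as.integer(canvas), regions = regions,
                 background = background,
                 background_noise_sd = background_noise_sd),
            class = "tg_mosaic_layout")
}

#' Generate a mosaic pseudo-slide with ground truth
#'
#' Renders each layout region with its class texture and fills the rest of
#' the canvas with a bright near-white background, returning the image
#' together with a pixel-exact label map. Label map convention: `0` is the
#' reserved background id, region pixels carry `class_id + 1`.
#'
#' @param layout A [mosaic_layout()].
#' @param specs List of [texture_spec()] covering every `class_id` used.
#' @param seed Integer seed.
#' @return A list of class `tg_mosaic`: `image` (`[H, W, 3]`),
#'   `label_map` (`H x W` integer matrix), `layout`.
#' @export
generate_mosaic_slide <- function(layout, specs, seed = 0L) {
  stopifnot(inherits(layout, "tg_mosaic_layout"))
  ids <- vapply(specs, function(s) s$class_id, integer(1))
  if (!all(layout$regions$class_id %in% ids)) {
    stop("every region class_id needs a matching texture_spec", call. = FALSE)
  }
  H <- layout$canvas[1]; W <- layout$canvas[2]
  with_seed_(seed, {
    img <- array(rep(layout$background, each = H * W), dim = c(H, W, 3))
    if (layout$background_noise_sd > 0) {
      img <- clamp01(img + array(stats::rnorm(H * W * 3, 0, layout$background_noise_sd),
                                 dim = dim(img)))
    }
    label_map <- matrix(0L, H, W)
    for (i in seq_len(nrow(layout$regions))) {
      rg <- layout$regions[i, ]
      spec <- specs[[match(rg$class_id, ids)]]
      rows <- (rg$row0 + 1L):(rg$row0 + rg$height)
      cols <- (rg$col0 + 1L):(rg$col0 + rg$width)
      img[rows, cols, ] <- render_texture(spec, rg$height, rg$width)
      label_map[rows, cols] <- rg$class_id + 1L
    }
    structure(list(image = img, label_map = label_map, layout = layout),
              class = "tg_mosaic")
  })
}

#' Ground-truth oracle classifier for pipeline tests
#'
#' A plug-in stand-in for a trained model: given a tile's top-left
#' coordinates it returns a one-hot probability vector at the majority
#' ground-truth class inside the tile footprint (uniform over classes if the
#' tile is pure background). Used to exercise the tiling/stitching pipeline
#' independently of any training run.
#'
#' @param label_map Integer matrix from [generate_mosaic_slide()] (0 =
#'   background, classes are `id + 1`).
#' @param n_classes Number of foreground classes.
#' @param input_size Tile size the oracle expects.
#' @return An object of class `tg_oracle` usable wherever a model is.
#' @export
oracle_classifier <- function(label_map, n_classes, input_size = 224L) {
  structure(list(label_map = label_map, n_classes = as.integer(n_classes),
                 cfg = list(input_size = as.integer(input_size), n_classes = as.integer(n_classes))),
            class = "tg_oracle")
}

#' @rdname oracle_classifier
#' @param model,img,coords,... Method arguments: `coords` is the 0-based
#'   `c(row, col)` top-left of the tile in the slide.
#' @export
predict_patch.tg_oracle <- function(model, img, coords = NULL, ...) {
  if (is.null(coords)) stop("the oracle classifier needs tile `coords`", call. = FALSE)
  ts <- dim(img)[1]
  sub <- model$label_map[(coords[1] + 1L):(coords[1] + ts),
                         (coords[2] + 1L):(coords[2] + ts)]
  sub <- sub[sub > 0L]
  p <- rep(0, model$n_classes)
  if (length(sub) == 0L) {
    p[] <- 1 / model$n_classes
  } else {
    tab <- tabulate(sub, nbins = model$n_classes)
    p[which.max(tab)] <- 1
  }
  p
}

#' Two-class blob-localization benchmark
#'
#' Generates a toy task for checking that Grad-CAM heat concentrates on the
#' evidence: class 0 patches are a uniform tint with noise, class 1 patches
#' additionally contain one dark disc at a random position. The returned
#' `boxes` tibble records each patch's disc bounding box (0-based, inclusive;
#' `NA` for class-0 patches) so heat inside vs. outside the box can be
#' compared.
#'
#' @param n_per_class Patches per class.
#' @param size Patch side in pixels.
#' @param seed Integer seed.
#' @param radius Disc radius range in pixels.
#' @return List: `dataset` (a [patch_dataset()], classes
#'   `c("uniform", "blob")`), `boxes` (tibble `row0, col0, row1, col1`).
#' @export
generate_blob_task <- function(n_per_class, size = 32L, seed = 0L,
                               radius = c(4, 6)) {
  with_seed_(seed, {
    n <- 2L * n_per_class
    images <- vector("list", n)
    labels <- integer(n)
    boxes <- matrix(NA_integer_, n, 4)
    bg <- c(0.9, 0.85, 0.88)
    for (i in seq_len(n)) {
      img <- array(rep(bg, each = size * size), dim = c(size, size, 3)) +
        array(stats::rnorm(size * size * 3, 0, 0.03), dim = c(size, size, 3))
      cls <- as.integer(i > n_per_class)
      if (cls == 1L) {
        rad <- stats::runif(1, radius[1], radius[2])
        r0 <- stats::runif(1, rad + 2, size - rad - 1)
        c0 <- stats::runif(1, rad + 2, size - rad - 1)
        rowv <- matrix(seq_len(size), size, size)
        colv <- t(rowv)
        disc <- (rowv - r0)^2 + (colv - c0)^2 <= rad^2
        for (c in 1:3) {
          ch <- img[, , c]
          ch[disc] <- ch[disc] * 0.2
          img[, , c] <- ch
        }
        boxes[i, ] <- c(max(0L, floor(r0 - rad) - 1L), max(0L, floor(c0 - rad) - 1L),
                        min(size - 1L, ceiling(r0 + rad) - 1L),
                        min(size - 1L, ceiling(c0 + rad) - 1L))
      }
      images[[i]] <- clamp01(img)
      labels[i] <- cls
    }
    list(dataset = patch_dataset(images, labels, c("uniform", "blob")),
         boxes = tibble::tibble(row0 = boxes[, 1], col0 = boxes[, 2],
                                row1 = boxes[, 3], col1 = boxes[, 4]))
  })
}
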