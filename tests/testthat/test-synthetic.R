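test_that("patch generation is reproducible and jitter controls variability", {
  spec <- texture_spec(0L, "stripes", jitter = 0)
  a <- generate_patch(spec, 32, seed = 5)
  b <- generate_patch(spec, 32, seed = 5)
  expect_identical(a, b)
  spec_j <- texture_spec(0L, "stripes", jitter = 1)
  c1 <- generate_patch(spec_j, 32, seed = 5)
  c2 <- generate_patch(spec_j, 32, seed = 6)
  expect_gt(mean(abs(c1 - c2)), 0.01)
  expect_true(all(a >= 0 & a <= 1))
  expect_error(generate_patch(spec, 8), "size")
})

test_that("stripe orientation is recoverable from gradients", {
  # 0 vs 90 degree stripes separate on the dominant gradient axis
  h <- texture_spec(0L, "stripes", orientation = c(0, 0), frequency = c(0.1, 0.1),
                    jitter = 0, noise_sd = 0)
  v <- texture_spec(1L, "stripes", orientation = c(90, 90), frequency = c(0.1, 0.1),
                    jitter = 0, noise_sd = 0)
  orient_stat <- function(img) {
    g <- img[, , 1]
    dr <- abs(diff(g))             # row-direction gradient
    dc <- abs(t(diff(t(g))))       # column-direction gradient
    mean(dr) - mean(dc)
  }
  # orientation 0: wave varies along columns; orientation 90: along rows
  s_h <- orient_stat(generate_patch(h, 32, seed = 1))
  s_v <- orient_stat(generate_patch(v, 32, seed = 1))
  expect_true(sign(s_h) != sign(s_v))
})

test_that("smooth tint patches have low per-channel spread", {
  spec <- texture_spec(0L, "smooth_tint", noise_sd = 0.01)
  img <- generate_patch(spec, 32, seed = 9)
  for (c in 1:3) expect_lt(sd(img[, , c]), 0.05)
})

test_that("patch datasets are balanced, reproducible, and class-major", {
  pr <- synthetic_presets("easy")
  ds <- generate_patch_dataset(pr$specs, 5, 16, seed = 4, class_names = pr$class_names)
  expect_length(ds$images, 30)
  expect_equal(as.vector(table(ds$labels)), rep(5L, 6))
  ds2 <- generate_patch_dataset(pr$specs, 5, 16, seed = 4, class_names = pr$class_names)
  expect_identical(ds$images, ds2$images)
  ds3 <- generate_patch_dataset(pr$specs, 5, 16, seed = 5, class_names = pr$class_names)
  expect_false(identical(ds$images, ds3$images))
})

test_that("dataset generation leaves the global RNG untouched", {
  pr <- synthetic_presets("easy")
  set.seed(99)
  before <- .Random.seed
  invisible(generate_patch_dataset(pr$specs, 2, 16, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("mosaic slides have pixel-exact label maps and validated layouts", {
  pr <- synthetic_presets("easy")
  lay <- mosaic_layout(c(128, 128), tibble::tibble(
    row0 = c(8, 72), col0 = c(8, 40), height = c(48, 40), width = c(48, 64),
    class_id = c(0L, 2L)))
  mo <- generate_mosaic_slide(lay, pr$specs, seed = 2)
  area <- 48 * 48 + 40 * 64
  expect_equal(mean(mo$label_map == 0), 1 - area / (128 * 128))
  expect_setequal(unique(as.vector(mo$label_map)), c(0L, 1L, 3L))
  # full-canvas region: constant label map
  lay_full <- mosaic_layout(c(64, 64), tibble::tibble(
    row0 = 0, col0 = 0, height = 64, width = 64, class_id = 1L))
  mo_full <- generate_mosaic_slide(lay_full, pr$specs, seed = 2)
  expect_true(all(mo_full$label_map == 2L))
  expect_error(mosaic_layout(c(64, 64), tibble::tibble(
    row0 = c(0, 10), col0 = c(0, 10), height = c(32, 32), width = c(32, 32),
    class_id = c(0L, 1L))), "overlap")
  expect_error(mosaic_layout(c(64, 64), tibble::tibble(
    row0 = 40, col0 = 0, height = 32, width = 32, class_id = 0L)), "canvas")
})

test_that("the blob task records boxes only for blob patches", {
  task <- generate_blob_task(10, size = 32, seed = 8)
  expect_length(task$dataset$images, 20)
  expect_true(all(is.na(task$boxes$row0[task$dataset$labels == 0])))
  expect_true(all(!is.na(task$boxes$row0[task$dataset$labels == 1])))
  i <- which(task$dataset$labels == 1)[1]
  bx <- task$boxes[i, ]
  img <- task$dataset$images[[i]]
  inside <- img[(bx$row0 + 1):(bx$row1 + 1), (bx$col0 + 1):(bx$col1 + 1), 1]
  expect_lt(mean(inside), mean(img[, , 1]))   # the disc darkens its box
})

test_that("patch datasets round-trip through the directory-per-class layout", {
  ds <- tiny_two_class(n_per = 3, size = 16, seed = 6)
  dir <- withr::local_tempdir()
  write_patch_dataset(ds, dir)
  back <- read_patch_dataset(dir)
  expect_identical(back$class_names, sort(ds$class_names))
  expect_equal(length(back$images), length(ds$images))
  # pixel data survives 8-bit PNG quantization (match first patch of the
  # class that sorts first in the re-read vocabulary)
  i <- which(ds$labels == match(back$class_names[1], ds$class_names) - 1L)[1]
  expect_lt(max(abs(back$images[[1]] - ds$images[[i]])), 1 / 255)
  # manifest CSV path
  man <- file.path(dir, "manifest.csv")
  files <- list.files(dir, pattern = "\\.png$", recursive = TRUE)
  utils::write.csv(
    data.frame(path = files, label = dirname(files)), man, row.names = FALSE)
  via_man <- read_patch_dataset(dir, manifest = man)
  expect_equal(length(via_man$images), length(ds$images))
  expect_identical(via_man$class_names, sort(ds$class_names))
})
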