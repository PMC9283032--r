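test_that("tissue masking recovers mosaic foreground and handles edge cases", {
  pr <- synthetic_presets("easy")
  lay <- mosaic_layout(c(256, 256), tibble::tibble(
    row0 = c(16, 144), col0 = c(16, 96), height = c(96, 96),
    width = c(96, 144), class_id = c(0L, 3L)))
  mo <- generate_mosaic_slide(lay, pr$specs, seed = 3)
  mask <- compute_tissue_mask(mo$image, downsample = 8)   # saturation Otsu
  expect_identical(dim(mask$mask), c(32L, 32L))
  truth <- mo$label_map > 0
  full <- tg_ns$mask_full_res(mask, dim(mo$label_map))
  iou <- sum(full == 1 & truth) / sum(full == 1 | truth)
  expect_gte(iou, 0.95)
  # gray-level Otsu works when the tissue is darker than background;
  # use the two darker texture classes for that variant
  lay_d <- mosaic_layout(c(256, 256), tibble::tibble(
    row0 = c(16, 144), col0 = c(16, 96), height = c(96, 96),
    width = c(96, 144), class_id = c(0L, 2L)))
  mo_d <- generate_mosaic_slide(lay_d, pr$specs, seed = 3)
  mask_g <- compute_tissue_mask(mo_d$image, downsample = 8, method = "otsu_gray")
  full_g <- tg_ns$mask_full_res(mask_g, dim(mo_d$label_map))
  truth_d <- mo_d$label_map > 0
  iou_g <- sum(full_g == 1 & truth_d) / sum(full_g == 1 | truth_d)
  expect_gte(iou_g, 0.95)
  # all-white slide: zero mask with a warning, not an error
  expect_warning(m0 <- compute_tissue_mask(array(1, dim = c(64, 64, 3)), 8),
                 "blank")
  expect_true(all(m0$mask == 0))
  # fixed-threshold symmetry: inverting the image inverts the mask
  set.seed(2)
  img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  m1 <- compute_tissue_mask(img, 1, "fixed_threshold", threshold = 0.5)
  m2 <- compute_tissue_mask(1 - img, 1, "fixed_threshold", threshold = 0.5)
  expect_identical(m1$mask == 1, m2$mask == 0)
})

test_that("tile enumeration matches the closed form and brute force", {
  g <- enumerate_tiles(full_tissue_mask(c(480, 480)), c(480, 480),
                       tile_size = 224, stride = 128)
  expect_equal(nrow(g$coords), 9)
  expect_setequal(unique(g$coords$row), c(0L, 128L, 256L))
  expect_setequal(unique(g$coords$col), c(0L, 128L, 256L))
  # single-tile slide
  g1 <- enumerate_tiles(full_tissue_mask(c(224, 224)), c(224, 224), 224, 64)
  expect_equal(as.data.frame(g1$coords[, 1:2]),
               data.frame(row = 0L, col = 0L))
  # all-background mask keeps nothing
  m0 <- full_tissue_mask(c(300, 300))
  m0$mask[] <- 0L
  expect_equal(nrow(enumerate_tiles(m0, c(300, 300), 224, 128)$coords), 0)
  # randomized dims against brute-force enumeration
  set.seed(61)
  for (i in 1:10) {
    H <- sample(60:200, 1); W <- sample(60:200, 1)
    tile <- sample(c(32, 48, 64), 1)
    stride <- sample(c(16, 32, 48), 1)
    mask <- full_tissue_mask(c(H, W), downsample = 8L)
    mask$mask[] <- rbinom(length(mask$mask), 1, 0.7)
    g <- enumerate_tiles(mask, c(H, W), tile, stride, 0.5)
    bf <- bruteforce_tiles(tg_ns$mask_full_res(mask, c(H, W)), tile, stride, 0.5)
    expect_equal(nrow(g$coords), if (is.null(bf)) 0L else nrow(bf))
    if (!is.null(bf)) {
      expect_equal(cbind(g$coords$row, g$coords$col), unname(bf))
    }
    # closed-form count under a full mask
    gf <- enumerate_tiles(full_tissue_mask(c(H, W)), c(H, W), tile, stride, 0.5)
    expect_equal(nrow(gf$coords),
                 (floor((H - tile) / stride) + 1) * (floor((W - tile) / stride) + 1))
  }
  expect_error(enumerate_tiles(full_tissue_mask(c(100, 100)), c(100, 100), 224, 128),
               "tile_size")
})

test_that("tile classification is batch-invariant and rows sum to one", {
  model <- tiny_model(n_classes = 2, size = 16, seed = 31)
  set.seed(31)
  slide <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  grid <- enumerate_tiles(full_tissue_mask(c(64, 64), 8L), c(64, 64), 16, 16)
  p1 <- classify_tiles(model, slide, grid, batch_size = 1)
  p32 <- classify_tiles(model, slide, grid, batch_size = 32)
  expect_equal(rowSums(p32), rep(1, nrow(grid$coords)), tolerance = 1e-6)
  expect_equal(p1, p32, tolerance = 1e-5)
  # consistency with predict_patch on one tile
  tile1 <- slide[1:16, 1:16, , drop = FALSE]
  expect_equal(p32[1, ], unname(predict_patch(model, tile1)), tolerance = 1e-9)
  expect_error(classify_tiles(model, slide,
                              enumerate_tiles(full_tissue_mask(c(64, 64), 8L),
                                              c(64, 64), 32, 32)),
               "input_size")
})

test_that("stitching averages overlaps, conserves probability, honours ties", {
  # one full-cover tile: constant map
  grid1 <- enumerate_tiles(full_tissue_mask(c(32, 32), 8L), c(32, 32), 32, 32)
  seg1 <- stitch_segmentation(grid1, matrix(c(0, 1, 0), 1, 3))
  expect_true(all(seg1$label_map == 2L))
  # hand-computed two-tile overlap: probs average to [0.4, 0.6] -> class 2
  grid2 <- structure(list(coords = tibble::tibble(row = c(0L, 0L), col = c(0L, 16L),
                                                  tissue_frac = c(1, 1)),
                          tile_size = 32L, stride = 16L, tissue_frac_min = 0,
                          slide_dims = c(32L, 48L)),
                     class = "tg_tile_grid")
  probs <- rbind(c(0.6, 0.4), c(0.2, 0.8))
  seg2 <- stitch_segmentation(grid2, probs)
  overlap <- seg2$prob_field[1, 17, ] / seg2$coverage[1, 17]
  expect_equal(overlap, c(0.4, 0.6))
  expect_equal(seg2$label_map[1, 17], 2L)
  expect_equal(seg2$label_map[1, 1], 1L)    # left-only region
  expect_equal(seg2$label_map[1, 48], 2L)   # right-only region
  # probability conservation at covered pixels (brute-force accumulation)
  field_bf <- array(0, dim = c(32, 48, 2))
  cov_bf <- matrix(0, 32, 48)
  for (t in 1:2) {
    rr <- (grid2$coords$row[t] + 1):(grid2$coords$row[t] + 32)
    cc <- (grid2$coords$col[t] + 1):(grid2$coords$col[t] + 32)
    for (k in 1:2) field_bf[rr, cc, k] <- field_bf[rr, cc, k] + probs[t, k]
    cov_bf[rr, cc] <- cov_bf[rr, cc] + 1
  }
  expect_equal(seg2$prob_field, field_bf)
  norm <- seg2$prob_field / array(pmax(seg2$coverage, 1), dim = dim(seg2$prob_field))
  sums <- apply(norm, c(1, 2), sum)
  expect_true(all(abs(sums[seg2$coverage > 0] - 1) < 1e-6))
  # ties break to the lowest class id
  seg_tie <- stitch_segmentation(grid1, matrix(c(0.5, 0.5, 0), 1, 3))
  expect_true(all(seg_tie$label_map == 1L))
  expect_error(stitch_segmentation(grid2, probs[1, , drop = FALSE]), "align")
})

test_that("non-overlapping stitching equals the per-tile argmax", {
  model <- tiny_model(n_classes = 3, size = 16, seed = 33)
  set.seed(33)
  slide <- array(runif(48 * 48 * 3), dim = c(48, 48, 3))
  grid <- enumerate_tiles(full_tissue_mask(c(48, 48), 8L), c(48, 48), 16, 16)
  probs <- classify_tiles(model, slide, grid)
  seg <- stitch_segmentation(grid, probs)
  for (t in seq_len(nrow(grid$coords))) {
    lab <- seg$label_map[grid$coords$row[t] + 1, grid$coords$col[t] + 1]
    expect_equal(lab, which.max(probs[t, ]))
  }
})

test_that("overlay blending is exact per pixel and writes a legend", {
  grid <- enumerate_tiles(full_tissue_mask(c(32, 32), 8L), c(32, 32), 16, 16)
  probs <- matrix(rep(c(1, 0), each = 2), 4, 2)[, c(1, 2)]
  probs <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1))
  seg <- stitch_segmentation(grid, probs)
  set.seed(3)
  slide <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  pal <- rbind(c(1, 0, 0), c(0, 0, 1))
  ov0 <- render_overlay(slide, seg, pal, alpha = 0)
  expect_equal(ov0, slide, ignore_attr = TRUE)
  ov1 <- render_overlay(slide, seg, pal, alpha = 1)
  expect_equal(unique(as.vector(ov1[1:16, 1:16, 1])), 1)
  a <- 0.3
  ov <- render_overlay(slide, seg, pal, alpha = a)
  lab <- seg$label_map[5, 5]
  expect_equal(ov[5, 5, 2], (1 - a) * slide[5, 5, 2] + a * pal[lab, 2])
  expect_s3_class(attr(ov, "legend"), "tbl_df")
  tmp <- withr::local_tempfile(fileext = ".png")
  write_overlay(ov, tmp)
  expect_true(file.exists(tmp))
  expect_true(file.exists(paste0(tmp, ".legend.json")))
  expect_error(render_overlay(slide, seg, pal[1, , drop = FALSE], 0.5), "palette")
})
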