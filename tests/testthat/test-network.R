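test_that("a built classifier outputs a probability vector and is deterministic", {
  model <- build_classifier(model_config(n_classes = 3, input_size = 32,
                                         bilinear_m = 16, bilinear_k = 4),
                            seed = 21)
  img <- generate_patch(texture_spec(0L, "checker"), 32, seed = 1)
  p1 <- predict_patch(model, img)
  expect_length(p1, 3)
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  expect_identical(p1, predict_patch(model, img))
  expect_error(predict_patch(model, generate_patch(texture_spec(0L), 16, seed = 1)),
               "resize")
  # same seed -> bit-identical parameters; different seed -> different
  m_same <- build_classifier(model_config(n_classes = 3, input_size = 32,
                                          bilinear_m = 16, bilinear_k = 4),
                             seed = 21)
  expect_identical(model$layers, m_same$layers)
  m_diff <- build_classifier(model_config(n_classes = 3, input_size = 32,
                                          bilinear_m = 16, bilinear_k = 4),
                             seed = 22)
  expect_false(identical(model$layers, m_diff$layers))
})

test_that("untrained models predict near-uniform probabilities on average", {
  img <- generate_patch(texture_spec(0L, "noise"), 16, seed = 3)
  probs <- vapply(1:60, function(s) {
    predict_patch(tiny_model(n_classes = 4, seed = s), img)
  }, numeric(4))
  expect_lt(max(abs(rowMeans(probs) - 0.25)), 0.1)
})

test_that("config validation rejects incompatible shapes", {
  expect_error(model_config(n_classes = 3, input_size = 30), "divisible")
  expect_error(model_config(n_classes = 1), "n_classes")
  expect_error(train_config(lr = 0), "lr")
  expect_error(train_config(plateau_factor = 1.2), "plateau_factor")
})

test_that("augmentation preserves labels, dimensions and the off-switch", {
  img <- generate_patch(texture_spec(0L, "stripes"), 16, seed = 2)
  off <- augment_flags(rotate90s = FALSE, hflip = FALSE, color_normalize = FALSE)
  expect_identical(augment_patch(img, off), img)
  rot <- tg_ns$rot90_image
  expect_equal(rot(rot(rot(rot(img, 1), 1), 1), 1), img)
  expect_equal(rot(img, 4), img)
  aug <- augment_patch(img, augment_flags(), seed = 5)
  expect_identical(dim(aug), dim(img))
  norm <- augment_patch(img, augment_flags(rotate90s = FALSE, hflip = FALSE,
                                           color_normalize = TRUE))
  for (c in 1:3) {
    expect_equal(mean(norm[, , c]), 0, tolerance = 1e-8)
    expect_equal(sd(norm[, , c]), 1, tolerance = 1e-8)
  }
})

test_that("training reduces the loss on a separable two-class problem", {
  ds <- tiny_two_class(n_per = 16, size = 16, seed = 3)
  sp <- split_dataset(ds, 0.75, seed = 3)
  fit <- train_classifier(tiny_model(seed = 4), sp$train, sp$val,
                          train_config(epochs = 10, batch_size = 8, seed = 4))
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_s3_class(h, "tbl_df")
  expect_named(h, c("epoch", "train_loss", "val_loss", "val_acc", "lr"))
  # broom accessors
  expect_identical(tidy(fit), h)
  g <- glance(fit)
  expect_equal(g$epochs, 10L)
})

test_that("training histories are identical under identical seeds", {
  ds <- tiny_two_class(n_per = 10, size = 16, seed = 5)
  sp <- split_dataset(ds, 0.8, seed = 5)
  cfg <- train_config(epochs = 3, batch_size = 8, seed = 9)
  f1 <- train_classifier(tiny_model(seed = 6), sp$train, sp$val, cfg)
  f2 <- train_classifier(tiny_model(seed = 6), sp$train, sp$val, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$layers, f2$model$layers)
})

test_that("the plateau rule only ever multiplies the LR by the factor", {
  ds <- tiny_two_class(n_per = 6, size = 16, seed = 7)
  sp <- split_dataset(ds, 0.7, seed = 7)
  cfg <- train_config(epochs = 8, batch_size = 8, seed = 7,
                      plateau_patience = 2L, plateau_factor = 0.1)
  fit <- train_classifier(tiny_model(seed = 8), sp$train, sp$val, cfg)
  lrs <- fit$history$lr
  expect_true(all(diff(lrs) <= 0))
  steps <- lrs[-1] / lrs[-length(lrs)]
  expect_true(all(abs(steps - 1) < 1e-12 | abs(steps - 0.1) < 1e-12))
})

test_that("fine-tuning replaces only the head and is identity at 0 epochs", {
  ds <- tiny_two_class(n_per = 10, size = 16, seed = 11)
  model <- tiny_model(seed = 12)
  model$class_names <- ds$class_names
  # same vocabulary, zero epochs: predictions unchanged
  ft0 <- fine_tune(model, ds, train_config(epochs = 0L, seed = 1))
  img <- ds$images[[1]]
  expect_equal(predict_patch(ft0$model, img),
               predict_patch(model, img), tolerance = 1e-12,
               ignore_attr = TRUE)
  # new vocabulary: only the head layer changes shape
  specs3 <- list(texture_spec(0L, "stripes"), texture_spec(1L, "checker"),
                 texture_spec(2L, "blobs"))
  ds3 <- generate_patch_dataset(specs3, 6, 16, seed = 13,
                                class_names = c("a", "b", "c"))
  ft3 <- fine_tune(model, ds3, train_config(epochs = 0L, seed = 1))
  n_l <- length(model$layers)
  expect_equal(dim(ft3$model$layers[[n_l]]$params$W), c(8, 3))
  for (i in seq_len(n_l - 1L)) {
    expect_identical(ft3$model$layers[[i]], model$layers[[i]])
  }
  # architecture mismatch is a checkpoint error
  ds32 <- generate_patch_dataset(specs3, 2, 32, seed = 1,
                                 class_names = c("a", "b", "c"))
  expect_error(fine_tune(model, ds32, train_config(epochs = 0L)), "checkpoint")
})

test_that("checkpoints round-trip through disk", {
  model <- tiny_model(seed = 15)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(back$layers, model$layers)
  expect_identical(back$cfg, model$cfg)
  img <- generate_patch(texture_spec(0L, "checker"), 16, seed = 1)
  expect_identical(predict_patch(back, img), predict_patch(model, img))
})
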