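# Training: cross-entropy + Adam with a plateau learning-rate schedule, and
# the label-preserving augmentations used for histology patches (90-degree
# rotations, horizontal flips, per-channel colour standardization).

#' Training configuration
#'
#' Defaults follow the standard recipe for patch classifiers of this kind:
#' batch size 32, Adam at learning rate 3e-4 with first-moment coefficient
#' 0.9 and weight decay 1e-4, 80 epochs, and the learning rate multiplied by
#' 0.1 whenever the epoch-mean training loss has not reached a new minimum
#' (tolerance 1e-4) for 30 consecutive epochs.
#'
#' @param batch_size Minibatch size. Default 32.
#' @param epochs Number of passes over the training set. Default 80.
#' @param lr Initial Adam learning rate. Default 3e-4.
#' @param weight_decay L2 penalty coefficient added to gradients. Default 1e-4.
#' @param beta1 Adam first-moment coefficient ("momentum"). Default 0.9.
#' @param beta2 Adam second-moment coefficient. Default 0.999.
#' @param plateau_patience Epochs without a new training-loss minimum before
#'   the learning rate is dropped. Default 30.
#' @param plateau_factor Multiplier applied at each drop, in (0, 1).
#'   Default 0.1.
#' @param seed Integer seed governing shuffling and augmentation draws.
#' @param augment An [augment_flags()] list.
#' @return An object of class `tg_train_config`.
#' @export
train_config <- function(batch_size = 32L, epochs = 80L, lr = 3e-4,
                         weight_decay = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         plateau_patience = 30L, plateau_factor = 0.1,
                         seed = 0L, augment = augment_flags()) {
  if (lr <= 0) stop("`lr` must be positive", call. = FALSE)
  if (plateau_factor <= 0 || plateau_factor >= 1) {
    stop("`plateau_factor` must lie in (0, 1)", call. = FALSE)
  }
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr,
                 weight_decay = weight_decay, beta1 = beta1, beta2 = beta2,
                 plateau_patience = as.integer(plateau_patience),
                 plateau_factor = plateau_factor, seed = as.integer(seed),
                 augment = augment),
            class = "tg_train_config")
}

#' Augmentation flags
#'
#' @param rotate90s Random rotation by a multiple of 90 degrees (restricting
#'   to right angles avoids interpolation artifacts and padding).
#' @param hflip Horizontal flip with probability 0.5.
#' @param color_normalize Per-channel standardization of the patch to
#'   mean `norm_mean` and standard deviation `norm_sd` (defaults 0 and 1),
#'   using the patch's own channel statistics.
#' @param norm_mean,norm_sd Targets for `color_normalize`.
#' @return A named list of flags.
#' @export
augment_flags <- function(rotate90s = TRUE, hflip = TRUE,
                          color_normalize = FALSE,
                          norm_mean = 0, norm_sd = 1) {
  list(rotate90s = isTRUE(rotate90s), hflip = isTRUE(hflip),
       color_normalize = isTRUE(color_normalize),
       norm_mean = norm_mean, norm_sd = norm_sd)
}

rot90_image <- function(img, k) {
  k <- k %% 4L
  if (k == 0L) return(img)
  for (i in seq_len(k)) {
    d <- dim(img)
    out <- array(0, dim = c(d[2], d[1], d[3]))
    for (c in 1:d[3]) out[, , c] <- t(img[d[1]:1, , c])
    img <- out
  }
  img
}

#' Augment one patch
#'
#' Applies, in order: a uniformly drawn rotation by a multiple of 90 degrees,
#' a horizontal flip with probability 0.5, and per-channel standardization.
#' All transforms preserve the label and the image dimensions. With all flags
#' off the patch is returned unchanged. Random draws come from the current
#' RNG stream (or from `seed` if supplied), so augmentation is reproducible
#' under a seeded training loop.
#'
#' @param img `[H, W, 3]` numeric array.
#' @param flags An [augment_flags()] list.
#' @param seed Optional integer seed for a self-contained draw.
#' @return The augmented `[H, W, 3]` array.
#' @export
augment_patch <- function(img, flags = augment_flags(), seed = NULL) {
  if (!is.null(seed)) return(with_seed_(seed, augment_patch(img, flags)))
  if (flags$rotate90s) img <- rot90_image(img, sample.int(4L, 1L) - 1L)
  if (flags$hflip && stats::runif(1) < 0.5) img <- img[, dim(img)[2]:1, , drop = FALSE]
  if (flags$color_normalize) {
    for (c in 1:dim(img)[3]) {
      ch <- img[, , c]
      s <- stats::sd(ch)
      img[, , c] <- (ch - mean(ch)) / (if (s > 0) s else 1) * flags$norm_sd + flags$norm_mean
    }
  }
  img
}

#' Train a classifier
#'
#' Minimizes softmax cross-entropy with Adam. Each epoch shuffles the
#' training set, applies the configured augmentations independently to every
#' patch, and records the epoch-mean training loss, validation loss,
#' validation accuracy and current learning rate. The learning rate is
#' multiplied by `plateau_factor` whenever the training loss has not improved
#' its running minimum by more than 1e-4 for `plateau_patience` consecutive
#' epochs. All randomness (shuffling, augmentation) derives from `cfg$seed`,
#' so two runs with the same inputs produce identical histories.
#'
#' @param model A `tg_model` from [build_classifier()].
#' @param train,val [patch_dataset()]s; validation labels must be covered by
#'   the training vocabulary.
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return A list of class `tg_fit`: `model` (trained), `history` (a tibble
#'   with one row per epoch), `cfg`.
#' @export
train_classifier <- function(model, train, val, cfg, verbose = FALSE) {
  stopifnot(inherits(model, "tg_model"), inherits(cfg, "tg_train_config"),
            inherits(train, "tg_patch_dataset"), inherits(val, "tg_patch_dataset"))
  if (length(train$images) == 0L || length(val$images) == 0L) {
    stop("train and val datasets must be non-empty", call. = FALSE)
  }
  d <- dim(train$images[[1]])
  if (d[1] != model$cfg$input_size) {
    stop(sprintf("dataset patches are %dx%d but the model expects %dx%d",
                 d[1], d[2], model$cfg$input_size, model$cfg$input_size),
         call. = FALSE)
  }
  if (is.null(model$class_names)) model$class_names <- train$class_names

  layers <- model$layers
  state <- adam_init(layers)
  n <- length(train$images)
  y <- train$labels + 1L
  Xval <- stack_images(val$images)
  yval <- val$labels + 1L

  history <- vector("list", cfg$epochs)
  lr <- cfg$lr
  best_loss <- Inf
  stall <- 0L
  t_step <- 0L

  with_seed_(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        imgs <- lapply(train$images[idx], augment_patch, flags = cfg$augment)
        X <- stack_images(imgs)
        fw <- network_forward(layers, X)
        ce <- softmax_ce(fw$logits, y[idx])
        if (!is.finite(ce$loss)) {
          stop(sprintf("training aborted: non-finite loss at epoch %d (lr = %g)",
                       epoch, lr), call. = FALSE)
        }
        losses <- c(losses, ce$loss)
        bk <- network_backward(layers, fw$caches, ce$dlogits)
        t_step <- t_step + 1L
        upd <- adam_step(layers, bk$grads, state, lr, cfg$beta1, cfg$beta2,
                         1e-8, cfg$weight_decay, t_step)
        layers <- upd$layers
        state <- upd$state
      }
      train_loss <- mean(losses)

      vfw <- network_forward(layers, Xval)
      vce <- softmax_ce(vfw$logits, yval)
      val_acc <- mean(max.col(vce$probs, ties.method = "first") == yval)

      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = train_loss, val_loss = vce$loss,
        val_acc = val_acc, lr = lr)
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f  lr %g",
                        epoch, train_loss, vce$loss, val_acc, lr))
      }

      # plateau rule: drop LR if no new loss minimum for `patience` epochs
      if (train_loss < best_loss - 1e-4) {
        best_loss <- train_loss
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$plateau_patience) {
          lr <- lr * cfg$plateau_factor
          stall <- 0L
        }
      }
    }
  })

  model$layers <- layers
  model$provenance <- sprintf("trained (%d epochs, seed %d)", cfg$epochs, cfg$seed)
  structure(list(model = model, history = do.call(rbind, history), cfg = cfg),
            class = "tg_fit")
}

#' @export
print.tg_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<tg_fit> %d epochs | final train loss %.4f | val acc %.3f\n",
              nrow(h), h$train_loss[nrow(h)], h$val_acc[nrow(h)]))
  invisible(x)
}

#' Fine-tune a pretrained checkpoint on a new dataset
#'
#' Implements head-replacement transfer learning: all backbone, bilinear and
#' attention weights are retained from the checkpoint; the final dense head
#' is re-initialized for the new class vocabulary whenever it differs in
#' size (when the vocabulary size matches, the head is kept, so fine-tuning
#' for 0 epochs is an identity). Training then proceeds as in
#' [train_classifier()] on a stratified 80/20 split of `new_dataset`.
#'
#' @param checkpoint A `tg_model` or a path readable by [load_checkpoint()].
#' @param new_dataset A [patch_dataset()] for the target domain.
#' @param cfg A [train_config()]; `cfg$epochs = 0` returns the (possibly
#'   head-replaced) model untrained.
#' @param split_seed Seed for the train/val split. Default `cfg$seed`.
#' @return A `tg_fit` (with an empty history when `epochs = 0`); the model's
#'   provenance records the pretraining source.
#' @export
fine_tune <- function(checkpoint, new_dataset, cfg, split_seed = NULL) {
  model <- if (inherits(checkpoint, "tg_model")) checkpoint else load_checkpoint(checkpoint)
  stopifnot(inherits(new_dataset, "tg_patch_dataset"))
  d <- dim(new_dataset$images[[1]])
  if (d[1] != model$cfg$input_size) {
    stop("checkpoint error: dataset patch size does not match the checkpoint architecture",
         call. = FALSE)
  }
  n_new <- length(new_dataset$class_names)
  head_i <- length(model$layers)
  pre <- model$provenance
  if (n_new != model$cfg$n_classes) {
    m <- model$cfg$bilinear_m
    model$cfg$n_classes <- as.integer(n_new)
    model$layers[[head_i]]$params <- with_seed_(cfg$seed, list(
      W = init_uniform(c(m, n_new), m), b = numeric(n_new)))
  }
  model$class_names <- new_dataset$class_names
  model$cfg$pretrained_source <- "checkpoint"
  if (cfg$epochs == 0L) {
    model$provenance <- sprintf("fine-tuned from [%s] (0 epochs)", pre)
    return(structure(list(model = model, history = NULL, cfg = cfg),
                     class = "tg_fit"))
  }
  sp <- split_dataset(new_dataset, 0.8,
                      seed = if (is.null(split_seed)) cfg$seed else split_seed)
  fit <- train_classifier(model, sp$train, sp$val, cfg)
  fit$model$provenance <- sprintf("fine-tuned from [%s] (%d epochs, seed %d)",
                                  pre, cfg$epochs, cfg$seed)
  fit
}
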