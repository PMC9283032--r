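# broom-style accessors for fitted objects and evaluations.

#' Tidy a training run
#'
#' @param x A `tg_fit` from [train_classifier()] or [fine_tune()].
#' @param ... Unused.
#' @return The per-epoch history tibble (`epoch`, `train_loss`, `val_loss`,
#'   `val_acc`, `lr`).
#' @export
tidy.tg_fit <- function(x, ...) {
  if (is.null(x$history)) return(tibble::tibble())
  tibble::as_tibble(x$history)
}

#' @rdname tidy.tg_fit
#' @return For `glance`: a one-row tibble with the final epoch's losses and
#'   accuracy, the number of epochs, and the number of LR drops.
#' @export
glance.tg_fit <- function(x, ...) {
  h <- x$history
  if (is.null(h)) {
    return(tibble::tibble(epochs = 0L, train_loss = NA_real_,
                          val_loss = NA_real_, val_acc = NA_real_,
                          lr_drops = 0L))
  }
  tibble::tibble(epochs = nrow(h),
                 train_loss = h$train_loss[nrow(h)],
                 val_loss = h$val_loss[nrow(h)],
                 val_acc = h$val_acc[nrow(h)],
                 lr_drops = length(unique(h$lr)) - 1L)
}

#' Tidy an evaluation
#'
#' @param x A `tg_eval` from [evaluate_model()].
#' @param ... Unused.
#' @return `tidy`: the per-class metrics tibble. `glance`: the one-row macro
#'   summary with overall accuracy.
#' @export
tidy.tg_eval <- function(x, ...) x$per_class

#' @rdname tidy.tg_eval
#' @export
glance.tg_eval <- function(x, ...) {
  tibble::add_column(x$summary, accuracy = x$accuracy, .before = 1)
}
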