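# Confusion-matrix metrics: per-class precision/recall/F1 and the macro
# summary whose "average F1" is the harmonic mean of macro-precision and
# macro-recall (the convention under which published average rows are
# internally consistent; the plain mean of per-class F1s is also reported).

#' Confusion matrix from label vectors
#'
#' @param y_true,y_pred Integer class ids, 0-based, equal length.
#' @param n_classes Number of classes.
#' @return An `n_classes x n_classes` integer matrix of class
#'   `tg_confusion`; rows are true classes, columns predicted.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` lengths differ", call. = FALSE)
  }
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (any(y_true < 0L | y_true >= n_classes) ||
      any(y_pred < 0L | y_pred >= n_classes)) {
    stop("labels out of range [0, n_classes)", call. = FALSE)
  }
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true)) {
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  structure(cm, class = c("tg_confusion", "matrix", "array"))
}

#' Per-class precision, recall and F1
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2PR / (P + R)`. A class with zero support (no true examples) or
#' zero predictions has the corresponding quantity undefined; it is reported
#' as 0 and flagged in the `flagged` column.
#'
#' @param cm A [confusion_matrix()].
#' @return A tibble with columns `class` (0-based id), `precision`,
#'   `recall`, `f1`, `support`, `flagged`.
#' @export
per_class_prf <- function(cm) {
  stopifnot(inherits(cm, "tg_confusion") || (is.matrix(cm) && nrow(cm) == ncol(cm)))
  K <- nrow(cm)
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  tibble::tibble(class = seq_len(K) - 1L,
                 precision = as.numeric(precision),
                 recall = as.numeric(recall),
                 f1 = as.numeric(f1),
                 support = as.integer(support),
                 flagged = support == 0 | predicted == 0)
}

#' Macro-averaged summary metrics
#'
#' Average precision and recall are unweighted means over classes. The
#' reported `average_f1` is the harmonic mean of those two macro averages —
#' the identity `2*AP*AR/(AP+AR)` — rather than the mean of per-class F1s,
#' which is also returned as `mean_f1`.
#'
#' @param per_class A [per_class_prf()] tibble (or a `tg_confusion`, which
#'   is converted first).
#' @return One-row tibble: `average_precision`, `average_recall`,
#'   `average_f1`, `mean_f1`.
#' @export
macro_summary <- function(per_class) {
  if (inherits(per_class, "tg_confusion")) per_class <- per_class_prf(per_class)
  stopifnot(nrow(per_class) >= 1L)
  ap <- mean(per_class$precision)
  ar <- mean(per_class$recall)
  af1 <- if (ap + ar > 0) 2 * ap * ar / (ap + ar) else 0
  tibble::tibble(average_precision = ap, average_recall = ar,
                 average_f1 = af1, mean_f1 = mean(per_class$f1))
}

#' Evaluate a classifier on a labelled dataset
#'
#' @param model A `tg_model` (or other `predict_patch`-capable object).
#' @param ds A [patch_dataset()].
#' @param batch_size Patches per forward pass. Default 64.
#' @return An object of class `tg_eval`: `confusion`, `per_class` (tibble),
#'   `summary` (one-row tibble), `accuracy`.
#' @export
evaluate_model <- function(model, ds, batch_size = 64L) {
  stopifnot(inherits(ds, "tg_patch_dataset"))
  n <- length(ds$images)
  K <- length(ds$class_names)
  pred <- integer(n)
  if (inherits(model, "tg_model")) {
    for (start in seq(1L, n, by = batch_size)) {
      idx <- start:min(start + batch_size - 1L, n)
      P <- predict_batch(model, stack_images(ds$images[idx]))
      pred[idx] <- max.col(P, ties.method = "first") - 1L
    }
  } else {
    for (i in seq_len(n)) {
      pred[i] <- which.max(predict_patch(model, ds$images[[i]])) - 1L
    }
  }
  cm <- confusion_matrix(ds$labels, pred, K)
  pc <- per_class_prf(cm)
  pc$class_name <- ds$class_names[pc$class + 1L]
  structure(list(confusion = cm, per_class = pc, summary = macro_summary(pc),
                 accuracy = mean(pred == ds$labels)),
            class = "tg_eval")
}

#' @export
print.tg_eval <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<tg_eval> accuracy %.4f | macro P %.4f R %.4f | average F1 %.4f\n",
              x$accuracy, s$average_precision, s$average_recall, s$average_f1))
  invisible(x)
}

#' Write a metrics report
#'
#' Writes the per-class table and macro summary as CSV (values rounded to 4
#' decimals, the conventional reporting precision) and, optionally, a
#' machine-readable JSON with full precision.
#'
#' @param eval A [evaluate_model()] result.
#' @param csv_path Output CSV path.
#' @param json_path Optional JSON path.
#' @return `csv_path`, invisibly.
#' @export
write_metrics_report <- function(eval, csv_path, json_path = NULL) {
  stopifnot(inherits(eval, "tg_eval"))
  pc <- eval$per_class
  num <- vapply(pc, is.numeric, logical(1)) & names(pc) != "class"
  pc[num] <- lapply(pc[num], round, 4)
  utils::write.csv(pc, csv_path, row.names = FALSE)
  sm <- eval$summary
  sm[] <- lapply(sm, round, 4)
  utils::write.csv(sm, sub("\\.csv$", "_summary.csv", csv_path),
                   row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(per_class = eval$per_class, summary = eval$summary,
           accuracy = eval$accuracy),
      json_path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
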