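# ggplot2 views of the result objects.

#' Plot a training history
#'
#' Train/validation loss curves (left axis) over epochs; learning-rate drops
#' appear as dotted vertical lines.
#'
#' @param object A `tg_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tg_fit <- function(object, ...) {
  h <- object$history
  df <- rbind(
    data.frame(epoch = h$epoch, loss = h$train_loss, set = "train"),
    data.frame(epoch = h$epoch, loss = h$val_loss, set = "validation"))
  drops <- h$epoch[c(FALSE, diff(h$lr) < 0)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                        colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss", colour = NULL) +
    ggplot2::theme_minimal()
  if (length(drops)) {
    p <- p + ggplot2::geom_vline(xintercept = drops, linetype = "dotted")
  }
  p
}

#' Plot a Grad-CAM heatmap
#'
#' @param object A `tg_heatmap`.
#' @param ... Unused.
#' @return A ggplot raster of the normalized heat values.
#' @export
autoplot.tg_heatmap <- function(object, ...) {
  v <- object$values
  df <- data.frame(row = rep(seq_len(nrow(v)), ncol(v)),
                   col = rep(seq_len(ncol(v)), each = nrow(v)),
                   heat = as.vector(v))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$heat)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradientn(colours = c("blue", "cyan", "yellow", "red"),
                                  limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "heat",
                  title = sprintf("Grad-CAM (class %d, layer %s)",
                                  object$target_class, object$layer)) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param object A `tg_eval`.
#' @param ... Unused.
#' @return A ggplot tile map of counts (rows true, columns predicted).
#' @export
autoplot.tg_eval <- function(object, ...) {
  cm <- unclass(object$confusion)
  K <- nrow(cm)
  nm <- object$per_class$class_name %||% as.character(seq_len(K) - 1L)
  df <- data.frame(true = factor(rep(nm, K), levels = rev(nm)),
                   pred = factor(rep(nm, each = K), levels = nm),
                   n = as.vector(cm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true", fill = "count") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
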