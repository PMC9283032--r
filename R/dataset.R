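# Labelled patch datasets: in-memory container plus the two on-disk layouts
# common for patch classification corpora (directory-per-class PNGs, or a
# manifest CSV of path,label).

#' Labelled patch dataset
#'
#' @param images List of `[H, W, 3]` numeric arrays with values in `[0, 1]`,
#'   all the same size.
#' @param labels Integer class ids, 0-based, in `[0, n_classes)`.
#' @param class_names Ordered character vocabulary; class id `i` is
#'   `class_names[i + 1]`.
#' @return An object of class `tg_patch_dataset`.
#' @export
patch_dataset <- function(images, labels, class_names) {
  if (length(images) == 0L) stop("dataset is empty", call. = FALSE)
  if (length(images) != length(labels)) {
    stop("`images` and `labels` lengths differ", call. = FALSE)
  }
  labels <- as.integer(labels)
  n_classes <- length(class_names)
  if (any(labels < 0L | labels >= n_classes)) {
    stop("labels must lie in [0, n_classes)", call. = FALSE)
  }
  d <- dim(images[[1]])
  ok <- vapply(images, function(im) identical(dim(im), d), logical(1))
  if (!all(ok)) stop("all images must share the same dimensions", call. = FALSE)
  structure(list(images = images, labels = labels,
                 class_names = as.character(class_names)),
            class = "tg_patch_dataset")
}

#' @export
print.tg_patch_dataset <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("<tg_patch_dataset> %d patches (%dx%d), %d classes: %s\n",
              length(x$images), d[1], d[2], length(x$class_names),
              paste(x$class_names, collapse = ", ")))
  print(table(factor(x$labels, levels = seq_along(x$class_names) - 1L,
                     labels = x$class_names)))
  invisible(x)
}

#' @export
length.tg_patch_dataset <- function(x) length(x$images)

dataset_subset <- function(ds, idx) {
  patch_dataset(ds$images[idx], ds$labels[idx], ds$class_names)
}

#' Stratified train/validation split
#'
#' Splits a patch dataset per class with a seeded shuffle, so every class
#' keeps (approximately) the requested training proportion.
#'
#' @param ds A [patch_dataset()].
#' @param prop_train Training proportion in (0, 1); default 0.8.
#' @param seed Integer seed for the shuffle.
#' @return A list with elements `train` and `val`.
#' @export
split_dataset <- function(ds, prop_train = 0.8, seed = 0L) {
  stopifnot(inherits(ds, "tg_patch_dataset"), prop_train > 0, prop_train < 1)
  with_seed_(seed, {
    tr <- integer(0)
    for (cl in sort(unique(ds$labels))) {
      idx <- which(ds$labels == cl)
      idx <- sample(idx)
      n_tr <- max(1L, floor(length(idx) * prop_train))
      tr <- c(tr, idx[seq_len(n_tr)])
    }
    tr <- sort(tr)
    list(train = dataset_subset(ds, tr),
         val = dataset_subset(ds, setdiff(seq_along(ds$labels), tr)))
  })
}

#' Write / read a patch dataset in the directory-per-class layout
#'
#' `write_patch_dataset` creates one subdirectory per class name containing
#' numbered PNG patches. `read_patch_dataset` reads that layout back (class
#' order = sorted subdirectory names unless `class_names` is given), or, when
#' `manifest` is supplied, reads a CSV with columns `path,label` instead.
#'
#' @param ds A [patch_dataset()].
#' @param dir Target / source directory.
#' @param class_names Optional explicit class ordering when reading.
#' @param manifest Optional path to a `path,label` CSV manifest (paths
#'   relative to `dir` or absolute).
#' @return `write_patch_dataset` returns `dir` invisibly;
#'   `read_patch_dataset` returns a [patch_dataset()].
#' @export
write_patch_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "tg_patch_dataset"))
  for (i in seq_along(ds$class_names)) {
    sub <- file.path(dir, ds$class_names[i])
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    idx <- which(ds$labels == i - 1L)
    for (j in seq_along(idx)) {
      png::writePNG(clamp01(ds$images[[idx[j]]]),
                    file.path(sub, sprintf("patch_%05d.png", j)))
    }
  }
  invisible(dir)
}

#' @rdname write_patch_dataset
#' @export
read_patch_dataset <- function(dir, class_names = NULL, manifest = NULL) {
  if (!is.null(manifest)) {
    tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    if (!all(c("path", "label") %in% names(tab))) {
      stop("manifest must have columns `path` and `label`", call. = FALSE)
    }
    paths <- ifelse(file.exists(tab$path), tab$path, file.path(dir, tab$path))
    if (is.null(class_names)) class_names <- sort(unique(as.character(tab$label)))
    labels <- match(as.character(tab$label), class_names) - 1L
    if (anyNA(labels)) stop("manifest labels not covered by class_names", call. = FALSE)
    images <- lapply(paths, read_rgb)
    return(patch_dataset(images, labels, class_names))
  }
  subs <- list.dirs(dir, recursive = FALSE, full.names = FALSE)
  if (is.null(class_names)) class_names <- sort(subs)
  images <- list(); labels <- integer(0)
  for (i in seq_along(class_names)) {
    files <- sort(list.files(file.path(dir, class_names[i]),
                             pattern = "\\.png$", full.names = TRUE))
    images <- c(images, lapply(files, read_rgb))
    labels <- c(labels, rep(i - 1L, length(files)))
  }
  patch_dataset(images, labels, class_names)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# read any PNG as an [H, W, 3] array in [0, 1]
read_rgb <- function(path) {
  im <- png::readPNG(path)
  if (length(dim(im)) == 2L) im <- array(rep(im, 3L), dim = c(dim(im), 3L))
  if (dim(im)[3] > 3L) im <- im[, , 1:3, drop = FALSE]
  im
}
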