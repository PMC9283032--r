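# Shared fixtures and numeric utilities for the suite.

tg_ns <- asNamespace("tissuegrid")

# central finite-difference gradient of f at x (vectorized over entries)
numeric_gradient <- function(f, x, eps = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rel_err <- function(a, b) abs(a - b) / pmax(1e-8, abs(a) + abs(b))

# random bilinear node for property tests (uses current RNG)
random_node <- function(n, k) {
  bilinear_node(bias = runif(1, -1, 1),
                linear_weight = runif(n, -1, 1),
                factor_matrix = matrix(runif(k * n, -1, 1), k, n))
}

# a small full-tissue mask object without running the mask op
full_tissue_mask <- function(slide_dims, downsample = 32L) {
  structure(list(mask = matrix(1L, ceiling(slide_dims[1] / downsample),
                               ceiling(slide_dims[2] / downsample)),
                 downsample = as.integer(downsample), method = "otsu_gray",
                 threshold = 0.5),
            class = "tg_tissue_mask")
}

# brute-force tile enumeration oracle: every stride-aligned window fully
# inside the slide whose tissue fraction passes the cutoff
bruteforce_tiles <- function(mask_full, tile, stride, frac_min) {
  H <- nrow(mask_full); W <- ncol(mask_full)
  out <- NULL
  for (r in seq(0L, H - tile, by = stride)) {
    for (c in seq(0L, W - tile, by = stride)) {
      fr <- mean(mask_full[(r + 1):(r + tile), (c + 1):(c + tile)])
      if (fr >= frac_min) out <- rbind(out, c(r, c))
    }
  }
  out
}

# tiny 2-class texture dataset that a tiny_cnn separates quickly
tiny_two_class <- function(n_per = 20, size = 16, seed = 3) {
  specs <- list(
    texture_spec(0L, "stripes", orientation = c(0, 180), frequency = c(0.05, 0.08)),
    texture_spec(1L, "checker", cell = c(2, 3)))
  generate_patch_dataset(specs, n_per, size, seed = seed,
                         class_names = c("coarse", "checker"))
}

tiny_model <- function(n_classes = 2, size = 16, seed = 1, ...) {
  build_classifier(model_config(n_classes = n_classes, input_size = size,
                                bilinear_m = 8, bilinear_k = 2, ...),
                   seed = seed)
}
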