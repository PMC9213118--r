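# Dataset reading (ISIC-style images/ + masks/ layout), preprocessing
# (resize + per-channel normalization) and paired augmentation. Images flow
# as (H, W, C) arrays in [0, 1], row-major, origin top-left.

.FIXED_STATS <- list(mean = c(0.485, 0.456, 0.406),
                     sd = c(0.229, 0.224, 0.225))

read_image <- function(path) {
  if (!file.exists(path)) stop("unreadable image: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
  } else {
    a <- as.array(EBImage::readImage(path))
    a <- if (length(dim(a)) == 2L) t(a) else aperm(a, c(2, 1, 3))
  }
  if (length(dim(a)) == 3L && dim(a)[3] == 4L) a <- a[, , 1:3]
  a
}

read_mask <- function(path) {
  a <- read_image(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  array((a >= 0.5) * 1, c(dim(a), 1L))
}

# EBImage::resize addresses dim1 through `w`; wrap so callers think in (H, W).
resize_array <- function(a, h, w, nearest = FALSE) {
  out <- EBImage::resize(a, w = h, h = w,
                         filter = if (nearest) "none" else "bilinear")
  as.array(out)
}

#' Load an ISIC-style dataset directory and split it
#'
#' Expects `root/images` with JPEG/PNG images and `root/masks` with PNG masks
#' pairable by file stem (an `_segmentation` suffix on the mask stem is
#' tolerated). Pairs are shuffled deterministically under `seed` and split by
#' `fractions`; the default fractions reproduce the canonical
#' 1814/260/520 division of 2594 images.
#'
#' @param root Dataset root directory.
#' @param fractions Train/val/test fractions, summing to 1.
#' @param seed Shuffle seed.
#' @return A list of class `dataset_split` with data.frames `train`, `val`,
#'   `test` (columns `stem`, `image`, `mask`) and the `fractions` used.
#' @export
load_isic_dataset <- function(root,
                              fractions = c(1814, 260, 520) / 2594,
                              seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-6 || length(fractions) != 3L)
    stop("fractions must be three values summing to 1")
  df <- .list_pairs(root, seed)
  n <- nrow(df)
  n1 <- round(fractions[1] * n)
  n2 <- round(fractions[2] * n)
  n3 <- n - n1 - n2
  if (min(n1, n2, n3) < 0) stop("fractions produce a negative split size")
  structure(list(train = df[seq_len(n1), ],
                 val = df[n1 + seq_len(n2), ],
                 test = df[n1 + n2 + seq_len(n3), ],
                 fractions = fractions),
            class = "dataset_split")
}

# List image/mask pairs under root and shuffle them deterministically.
.list_pairs <- function(root, seed) {
  img_dir <- file.path(root, "images")
  msk_dir <- file.path(root, "masks")
  imgs <- list.files(img_dir, pattern = "\\.(png|jpg|jpeg)$",
                     ignore.case = TRUE)
  if (length(imgs) == 0) stop("empty dataset directory: ", img_dir)
  stems <- sub("\\.(png|jpg|jpeg)$", "", imgs, ignore.case = TRUE)
  masks <- character(length(imgs))
  for (i in seq_along(stems)) {
    cand <- file.path(msk_dir, paste0(stems[i],
                                      c(".png", "_segmentation.png")))
    hit <- cand[file.exists(cand)]
    if (length(hit) == 0)
      stop("missing mask for image stem '", stems[i], "'")
    masks[i] <- hit[1]
  }
  ord <- withr::with_seed(seed, sample.int(length(imgs)))
  df <- data.frame(stem = stems, image = file.path(img_dir, imgs),
                   mask = masks, stringsAsFactors = FALSE)[ord, ]
  rownames(df) <- NULL
  df
}

#' Rotating k-fold cross-validation splits
#'
#' Shuffles the pairs under `root` once (deterministically in `seed`),
#' assigns them to `k` folds round-robin, and returns one `dataset_split`
#' per fold with that fold as validation set and the remainder as training
#' set (test set empty). A driver for cross-validated training; the default
#' pipeline uses a single fixed split.
#'
#' @param root Dataset root in `images/` + `masks/` layout.
#' @param k Number of folds (>= 2).
#' @param seed Shuffle seed.
#' @return A list of `k` `dataset_split` objects.
#' @export
kfold_splits <- function(root, k = 5L, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  df <- .list_pairs(root, seed)
  if (nrow(df) < k) stop("fewer pairs than folds")
  fold <- rep_len(seq_len(k), nrow(df))
  lapply(seq_len(k), function(f) {
    structure(list(train = df[fold != f, ],
                   val = df[fold == f, ],
                   test = df[0, ],
                   fractions = c((k - 1) / k, 1 / k, 0)),
              class = "dataset_split")
  })
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train %d / val %d / test %d\n",
              nrow(x$train), nrow(x$val), nrow(x$test)))
  invisible(x)
}

#' Per-channel mean and standard deviation of the training images
#'
#' @param split A `dataset_split`.
#' @return A list with numeric length-3 `mean` and `sd`.
#' @export
dataset_stats <- function(split) {
  s <- numeric(3); ss <- numeric(3); npx <- 0
  for (p in split$train$image) {
    a <- read_image(p)
    if (length(dim(a)) != 3L || dim(a)[3] != 3L)
      stop("non-RGB image: ", p)
    m <- matrix(a, ncol = 3)
    s <- s + colSums(m)
    ss <- ss + colSums(m * m)
    npx <- npx + nrow(m)
  }
  mu <- s / npx
  list(mean = mu, sd = sqrt(pmax(ss / npx - mu^2, 1e-12)))
}

#' Resize and normalize an image/mask pair
#'
#' Resizes the image bilinearly and the mask with nearest-neighbor (so it
#' stays binary) to `size`, then standardizes the image per channel by the
#' supplied statistics. By default fixed ImageNet-style constants are used;
#' pass the output of [dataset_stats()] to normalize by the training split.
#'
#' @param image Path or `(H, W, 3)` array in \[0, 1\].
#' @param mask Optional path, `(H, W)` or `(H, W, 1)` binary array.
#' @param size Target `c(H, W)` (default 224 x 224).
#' @param stats List with per-channel `mean` and `sd`.
#' @return List with `image` (`size` x 3 normalized array) and `mask`
#'   (`size` x 1 binary array, or `NULL`).
#' @export
preprocess_pair <- function(image, mask = NULL, size = c(224L, 224L),
                            stats = NULL) {
  stats <- stats %||% .FIXED_STATS
  if (is.character(image)) image <- read_image(image)
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("non-RGB image: expected an (H, W, 3) array")
  img <- resize_array(image, size[1], size[2])
  for (c in 1:3)
    img[, , c] <- (img[, , c] - stats$mean[c]) / stats$sd[c]
  out_mask <- NULL
  if (!is.null(mask)) {
    if (is.character(mask)) mask <- read_mask(mask)
    if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
    m <- resize_array(mask[, , 1], size[1], size[2], nearest = TRUE)
    out_mask <- array(m, c(size[1], size[2], 1L))
  }
  list(image = img, mask = out_mask)
}

#' Paired geometric and photometric augmentation
#'
#' Applies one random rotation and center crop identically to image and mask
#' (bilinear resampling for the image, nearest-neighbor for the mask), then
#' photometric jitter (brightness, contrast, saturation, hue) to the image
#' only. With `rotation_range = 0`, `crop_scale = c(1, 1)` and `jitter = 0`
#' the pair is returned unchanged. Deterministic under `seed`.
#'
#' @param image `(H, W, 3)` array in \[0, 1\] (pre-normalization).
#' @param mask `(H, W, 1)` binary array.
#' @param seed Optional seed for reproducible draws.
#' @param rotation_range Max absolute rotation in degrees (default 30).
#' @param crop_scale Range of the center-crop side fraction (default
#'   0.8 to 1).
#' @param jitter Photometric jitter amplitude (default 0.2).
#' @return List with augmented `image` and `mask` at the input size.
#' @export
augment_pair <- function(image, mask, seed = NULL, rotation_range = 30,
                         crop_scale = c(0.8, 1), jitter = 0.2) {
  if (!identical(dim(image)[1:2], dim(mask)[1:2]))
    stop("shape error: image and mask spatial dims differ")
  run <- function() .augment_impl(image, mask, rotation_range, crop_scale,
                                  jitter)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

.augment_impl <- function(image, mask, rotation_range, crop_scale, jitter) {
  h <- dim(image)[1]; w <- dim(image)[2]
  angle <- stats::runif(1, -rotation_range, rotation_range)
  if (angle != 0) {
    image <- as.array(EBImage::rotate(image, angle, filter = "bilinear",
                                      output.dim = c(h, w), bg.col = 0))
    mask <- array(as.array(EBImage::rotate(mask[, , 1], angle,
                                           filter = "none",
                                           output.dim = c(h, w),
                                           bg.col = 0)), c(h, w, 1L))
  }
  s <- stats::runif(1, crop_scale[1], crop_scale[2])
  if (s < 1) {
    ch <- max(2L, round(h * s)); cw <- max(2L, round(w * s))
    r0 <- (h - ch) %/% 2L; c0 <- (w - cw) %/% 2L
    image <- image[r0 + seq_len(ch), c0 + seq_len(cw), , drop = FALSE]
    mask <- mask[r0 + seq_len(ch), c0 + seq_len(cw), , drop = FALSE]
    image <- resize_array(image, h, w)
    mask <- array(resize_array(mask[, , 1], h, w, nearest = TRUE),
                  c(h, w, 1L))
  }
  if (jitter > 0) {
    image <- image + stats::runif(1, -jitter, jitter) * 0.5      # brightness
    m <- mean(image)
    image <- (image - m) * (1 + stats::runif(1, -jitter, jitter)) + m
    gray <- array(rep(apply(image, c(1, 2), mean), 3), dim(image))
    image <- gray + (image - gray) * (1 + stats::runif(1, -jitter, jitter))
    image <- pmin(pmax(image, 0), 1)
    hsv <- grDevices::rgb2hsv(t(matrix(image, ncol = 3)), maxColorValue = 1)
    hsv[1, ] <- (hsv[1, ] + stats::runif(1, -jitter, jitter) * 0.25) %% 1
    cols <- grDevices::hsv(hsv[1, ], hsv[2, ], hsv[3, ])
    image <- array(t(grDevices::col2rgb(cols)) / 255, dim(image))
  }
  list(image = pmin(pmax(image, 0), 1), mask = mask)
}

#' Materialize a split as in-memory tensors
#'
#' Reads, preprocesses and stacks every pair of a [load_isic_dataset()] (or
#' [generate_dataset()]) split into `(H, W, C, N)` arrays ready for training.
#'
#' @param split A `dataset_split`.
#' @param size Target spatial size `c(H, W)`.
#' @param stats Normalization statistics; `NULL` (default) computes them
#'   from the training images via [dataset_stats()].
#' @return A list with `train`, `val`, `test` (each a `seg_dataset` holding
#'   `images` and `masks` arrays) and the `stats` used.
#' @export
load_split <- function(split, size = c(224L, 224L), stats = NULL) {
  stats <- stats %||% dataset_stats(split)
  mat <- function(df) {
    n <- nrow(df)
    if (n == 0) return(NULL)
    imgs <- array(0, c(size[1], size[2], 3L, n))
    msks <- array(0, c(size[1], size[2], 1L, n))
    for (i in seq_len(n)) {
      pp <- preprocess_pair(df$image[i], df$mask[i], size = size,
                            stats = stats)
      imgs[, , , i] <- pp$image
      msks[, , , i] <- pp$mask
    }
    structure(list(images = imgs, masks = msks), class = "seg_dataset")
  }
  list(train = mat(split$train), val = mat(split$val), test = mat(split$test),
       stats = stats)
}
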