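# Dataset splitting, preprocessing and paired augmentation.

make_pair_dir <- function(n, dir, mask_suffix = "_segmentation") {
  dir.create(file.path(dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n)) {
    stem <- sprintf("im%04d", i)
    file.create(file.path(dir, "images", paste0(stem, ".png")))
    file.create(file.path(dir, "masks",
                          paste0(stem, mask_suffix, ".png")))
  }
  dir
}

test_that("the canonical 2594-image split reproduces 1814/260/520", {
  d <- make_pair_dir(2594, file.path(tempdir(), "isic_full"))
  sp <- load_isic_dataset(d)
  expect_identical(nrow(sp$train), 1814L)
  expect_identical(nrow(sp$val), 260L)
  expect_identical(nrow(sp$test), 520L)
  unlink(d, recursive = TRUE)
})

test_that("splits are proportional, disjoint and seed-deterministic", {
  d <- make_pair_dir(10, file.path(tempdir(), "isic_small"))
  sp <- load_isic_dataset(d, fractions = c(0.8, 0.1, 0.1), seed = 5)
  expect_identical(c(nrow(sp$train), nrow(sp$val), nrow(sp$test)),
                   c(8L, 1L, 1L))
  all_stems <- c(sp$train$stem, sp$val$stem, sp$test$stem)
  expect_identical(sort(all_stems), sort(unique(all_stems)))
  sp2 <- load_isic_dataset(d, fractions = c(0.8, 0.1, 0.1), seed = 5)
  expect_identical(sp$train$stem, sp2$train$stem)
  sp3 <- load_isic_dataset(d, fractions = c(0.8, 0.1, 0.1), seed = 6)
  expect_false(identical(sp$train$stem, sp3$train$stem))
  unlink(d, recursive = TRUE)
})

test_that("k-fold splits partition the pairs into disjoint rotating folds", {
  d <- make_pair_dir(11, file.path(tempdir(), "isic_kf"))
  folds <- kfold_splits(d, k = 3, seed = 2)
  expect_length(folds, 3)
  val_stems <- unlist(lapply(folds, function(f) f$val$stem))
  expect_identical(sort(val_stems), sort(paste0("im", sprintf("%04d", 1:11))))
  for (f in folds) {
    expect_identical(length(intersect(f$train$stem, f$val$stem)), 0L)
    expect_identical(nrow(f$train) + nrow(f$val), 11L)
    expect_identical(nrow(f$test), 0L)
  }
  expect_error(kfold_splits(d, k = 20), "fewer pairs")
  unlink(d, recursive = TRUE)
})

test_that("missing masks and empty directories fail loudly", {
  d <- file.path(tempdir(), "isic_broken")
  make_pair_dir(3, d)
  file.remove(file.path(d, "masks", "im0002_segmentation.png"))
  expect_error(load_isic_dataset(d), "im0002")
  expect_error(load_isic_dataset(tempfile()), "empty")
  unlink(d, recursive = TRUE)
})

test_that("preprocessing resizes to 224 and standardizes channels", {
  img <- withr::with_seed(1, array(stats::runif(720 * 540 * 3),
                                   c(720, 540, 3)))
  pp <- preprocess_pair(img)
  expect_identical(dim(pp$image), c(224L, 224L, 3L))
  # constant image equal to the normalization mean maps to all-zero
  stats <- list(mean = c(0.3, 0.5, 0.7), sd = c(1, 1, 1))
  flat <- array(rep(c(0.3, 0.5, 0.7), each = 50 * 40), c(50, 40, 3))
  pp2 <- preprocess_pair(flat, size = c(32, 32), stats = stats)
  expect_lt(max(abs(pp2$image)), 1e-9)
  expect_error(preprocess_pair(array(0.5, c(10, 10))), "RGB")
})

test_that("mask values survive resizing exactly binary", {
  m <- rand_mask(50, 40, 0.3, seed = 2)
  img <- array(0.5, c(50, 40, 3))
  pp <- preprocess_pair(img, m, size = c(224, 224))
  expect_identical(dim(pp$mask), c(224L, 224L, 1L))
  expect_true(all(pp$mask %in% c(0, 1)))
  pp2 <- preprocess_pair(img, m, size = c(17, 13))
  expect_true(all(pp2$mask %in% c(0, 1)))
})

test_that("augmentation with neutral parameters is the identity", {
  img <- withr::with_seed(3, array(stats::runif(30 * 30 * 3), c(30, 30, 3)))
  m <- rand_mask(30, 30, 0.3, seed = 4)
  out <- augment_pair(img, m, seed = 1, rotation_range = 0,
                      crop_scale = c(1, 1), jitter = 0)
  expect_equal(out$image, img, tolerance = 1e-12)
  expect_identical(out$mask, m)
})

test_that("augmentation is seed-deterministic and keeps masks binary", {
  img <- withr::with_seed(5, array(stats::runif(40 * 40 * 3), c(40, 40, 3)))
  m <- rand_mask(40, 40, 0.3, seed = 6)
  a <- augment_pair(img, m, seed = 9)
  b <- augment_pair(img, m, seed = 9)
  expect_identical(a, b)
  expect_true(all(a$mask %in% c(0, 1)))
  expect_identical(dim(a$image), dim(img))
  cc <- augment_pair(img, m, seed = 10)
  expect_false(identical(a$image, cc$image))
})

test_that("geometric transforms move image and mask together", {
  # marked blob: bright square in the image at the mask's foreground; after
  # rotation + crop the two must land at the same place (centroids agree)
  img <- array(0, c(41, 41, 3))
  m <- array(0, c(41, 41, 1))
  img[10:14, 26:30, ] <- 1
  m[10:14, 26:30, 1] <- 1
  out <- augment_pair(img, m, seed = 3, rotation_range = 30,
                      crop_scale = c(0.9, 0.9), jitter = 0)
  expect_gt(sum(out$mask), 0)
  centroid <- function(w) {
    idx <- which(w > 0, arr.ind = TRUE)
    colSums(idx * w[w > 0]) / sum(w)
  }
  expect_lt(max(abs(centroid(out$mask[, , 1]) -
                      centroid(out$image[, , 1]))), 1)
})

test_that("materialized splits stack normalized tensors with exact masks", {
  ds <- tiny_dataset(8, size = 16, seed = 41)
  expect_identical(dim(ds$train$images), c(16L, 16L, 3L, 6L))
  expect_identical(dim(ds$train$masks), c(16L, 16L, 1L, 6L))
  expect_true(all(ds$train$masks %in% c(0, 1)))
  expect_length(ds$stats$mean, 3)
  # normalization by training statistics centers the stack near zero
  expect_lt(abs(mean(ds$train$images)), 0.5)
})
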