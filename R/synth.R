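# Seeded synthetic dermoscopy generator. Lesions are darker elliptical blobs
# whose boundary radius is modulated by low-frequency angular noise; three
# morphologies are emulated: small high-contrast targets, prominent
# large-area targets, and irregular-edge targets (same area band as mid-size
# lesions but much stronger boundary modulation). Optional thin dark arcs
# imitate hair artifacts. The paired mask is the exact binary indicator of
# the lesion region (the image may blend softly at the boundary; the mask
# does not).

.CATEGORY_DEFAULTS <- list(
  small          = list(area = c(0.005, 0.05), amp = 0.08),
  prominent      = list(area = c(0.15, 0.45),  amp = 0.08),
  irregular_edge = list(area = c(0.05, 0.25),  amp = 0.35))

#' Specification of one synthetic lesion image
#'
#' @param category `"small"`, `"prominent"` or `"irregular_edge"`.
#' @param image_size `c(H, W)` in pixels.
#' @param area_fraction_range Admissible lesion area as a fraction of the
#'   image; defaults per category: small (0.005, 0.05), prominent
#'   (0.15, 0.45), irregular_edge (0.05, 0.25).
#' @param boundary_noise_amplitude Amplitude of the angular radius
#'   modulation; default 0.08 (0.35 for irregular_edge).
#' @param hair_artifact_probability Probability of overlaying hair-line arcs.
#' @param color_jitter Amplitude of the random skin/lesion color offsets.
#' @param seed Integer seed; the same spec yields bit-identical output.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(category = c("small", "prominent",
                                        "irregular_edge"),
                           image_size = c(224L, 224L),
                           area_fraction_range = NULL,
                           boundary_noise_amplitude = NULL,
                           hair_artifact_probability = 0.3,
                           color_jitter = 0.1,
                           seed = 1L) {
  category <- match.arg(category)
  def <- .CATEGORY_DEFAULTS[[category]]
  area <- area_fraction_range %||% def$area
  amp <- boundary_noise_amplitude %||% def$amp
  if (any(area <= 0) || any(area >= 1) || area[1] >= area[2])
    stop("area_fraction_range must be an increasing pair within (0, 1)")
  # largest lesion that still fits: radius 0.45 * min(H, W)
  max_frac <- pi * (0.45 * min(image_size))^2 / prod(image_size)
  if (area[1] > max_frac)
    stop("infeasible area range for image size: lower bound ", area[1],
         " exceeds the largest lesion that fits (", round(max_frac, 3), ")")
  structure(list(category = category,
                 image_size = as.integer(image_size),
                 area_fraction_range = area,
                 boundary_noise_amplitude = amp,
                 hair_artifact_probability = hair_artifact_probability,
                 color_jitter = color_jitter,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate one synthetic dermoscopy image with its exact mask
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `image` (H x W x 3, values in \[0, 1\]), `mask`
#'   (H x W x 1 binary), and `area_fraction` (measured lesion fraction,
#'   guaranteed inside the spec's range).
#' @export
generate_synthetic_lesion <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, .synth_lesion_impl(spec))
}

.synth_lesion_impl <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  rng <- spec$area_fraction_range
  target <- rng[1] + diff(rng) * stats::runif(1, 0.3, 0.7)
  cy <- H * stats::runif(1, 0.40, 0.60)
  cx <- W * stats::runif(1, 0.40, 0.60)
  ecc <- stats::runif(1, 0.55, 0.95)           # axis ratio b/a
  phi <- stats::runif(1, 0, pi)
  # angular radius modulation rho(theta) = 1 + sum_k a_k cos + b_k sin
  ks <- 2:6
  ak <- stats::rnorm(length(ks), sd = spec$boundary_noise_amplitude / ks * 2)
  bk <- stats::rnorm(length(ks), sd = spec$boundary_noise_amplitude / ks * 2)
  pow2 <- sum(ak^2 + bk^2) / 2                 # E[(rho - 1)^2]
  yy <- matrix(seq_len(H) - cy, H, W)
  xx <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)
  u1 <- cos(phi) * xx + sin(phi) * yy
  u2 <- -sin(phi) * xx + cos(phi) * yy
  theta <- atan2(u2, u1)
  rho <- 1
  for (j in seq_along(ks))
    rho <- rho + ak[j] * cos(ks[j] * theta) + bk[j] * sin(ks[j] * theta)
  rho <- pmax(rho, 0.25)
  ab <- target * H * W / (pi * (1 + pow2))     # product of semi-axes
  a <- sqrt(ab / ecc); b <- sqrt(ab * ecc)
  frac <- NA
  for (it in 1:6) {
    re <- sqrt((u1 / a)^2 + (u2 / b)^2)
    inside <- re <= rho
    frac <- mean(inside)
    if (frac >= rng[1] && frac <= rng[2]) break
    adj <- sqrt(target / max(frac, 1 / (H * W)))
    a <- a * adj; b <- b * adj
  }
  if (frac < rng[1] || frac > rng[2])
    stop("infeasible area range for image size: could not place a lesion ",
         "with area fraction in [", rng[1], ", ", rng[2], "]")
  jit <- spec$color_jitter
  skin <- pmin(pmax(c(0.82, 0.62, 0.54) + stats::runif(3, -jit, jit), 0), 1)
  les <- pmin(pmax(c(0.42, 0.26, 0.20) + stats::runif(3, -jit, jit), 0), 1)
  # soft blend near the boundary for realism; the mask stays exact
  alpha <- pmin(pmax((1.04 - re / rho) / 0.08, 0), 1)
  img <- array(0, c(H, W, 3))
  for (c in 1:3)
    img[, , c] <- skin[c] * (1 - alpha) + les[c] * alpha
  img <- img + array(stats::rnorm(H * W * 3, sd = 0.02), c(H, W, 3))
  if (stats::runif(1) < spec$hair_artifact_probability)
    img <- .draw_hairs(img, sample(1:3, 1))
  img <- pmin(pmax(img, 0), 1)
  mask <- array(as.numeric(inside), c(H, W, 1))
  list(image = img, mask = mask, area_fraction = frac)
}

# Thin dark quadratic-Bezier arcs across the frame.
.draw_hairs <- function(img, n_hairs) {
  H <- dim(img)[1]; W <- dim(img)[2]
  hair <- c(0.10, 0.08, 0.06)
  for (h in seq_len(n_hairs)) {
    p0 <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
    p2 <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
    p1 <- (p0 + p2) / 2 + stats::rnorm(2, sd = min(H, W) / 4)
    t <- seq(0, 1, length.out = 4L * max(H, W))
    py <- (1 - t)^2 * p0[1] + 2 * t * (1 - t) * p1[1] + t^2 * p2[1]
    px <- (1 - t)^2 * p0[2] + 2 * t * (1 - t) * p1[2] + t^2 * p2[2]
    iy <- round(py); ix <- round(px)
    keep <- iy >= 1 & iy <= H & ix >= 1 & ix <= W
    iy <- iy[keep]; ix <- ix[keep]
    for (c in 1:3) {
      ch <- img[, , c]
      ch[cbind(iy, ix)] <- 0.35 * ch[cbind(iy, ix)] + 0.65 * hair[c]
      img[, , c] <- ch
    }
  }
  img
}

#' Generate a synthetic dataset on disk in ISIC-like layout
#'
#' Writes `n` image/mask PNG pairs under `dir/images` and `dir/masks`
#' (masks carry the `_segmentation` suffix), a `manifest.csv` recording
#' filename, category, measured area fraction and per-image seed, and
#' returns a train/val/test split of the pairs. Regenerating with the same
#' arguments reproduces the files bit for bit.
#'
#' @param n Number of images (>= 3).
#' @param dir Output directory (created if needed).
#' @param category_mix Named non-negative weights over the three categories;
#'   converted to deterministic counts.
#' @param image_size `c(H, W)` of the generated images.
#' @param seed Master seed; image `i` uses `seed * 10000 + i`.
#' @param fractions Train/val/test fractions (sum to 1).
#' @param hair_artifact_probability,color_jitter Passed to
#'   [synthetic_spec()].
#' @return A `dataset_split` (see [load_isic_dataset()]).
#' @export
generate_dataset <- function(n, dir,
                             category_mix = c(small = 1, prominent = 1,
                                              irregular_edge = 1),
                             image_size = c(224L, 224L), seed = 1L,
                             fractions = c(0.7, 0.15, 0.15),
                             hair_artifact_probability = 0.3,
                             color_jitter = 0.1) {
  if (n < 3) stop("n must be >= 3")
  cats <- names(.CATEGORY_DEFAULTS)
  mix <- category_mix[cats]
  mix[is.na(mix)] <- 0
  if (sum(mix) <= 0) stop("category_mix must have positive total weight")
  counts <- floor(mix / sum(mix) * n)
  while (sum(counts) < n)
    counts[which.max(mix / sum(mix) * n - counts)] <-
      counts[which.max(mix / sum(mix) * n - counts)] + 1
  assignment <- rep(cats, counts)
  img_dir <- file.path(dir, "images")
  msk_dir <- file.path(dir, "masks")
  ok <- dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(msk_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir) || !dir.exists(msk_dir))
    stop("cannot create output directory: ", dir)
  manifest <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- synthetic_spec(assignment[i], image_size = image_size,
                         hair_artifact_probability =
                           hair_artifact_probability,
                         color_jitter = color_jitter,
                         seed = seed * 10000L + i)
    out <- generate_synthetic_lesion(sp)
    stem <- sprintf("synth_%04d", i)
    png::writePNG(out$image, file.path(img_dir, paste0(stem, ".png")))
    png::writePNG(out$mask[, , 1],
                  file.path(msk_dir, paste0(stem, "_segmentation.png")))
    manifest[[i]] <- data.frame(filename = paste0(stem, ".png"),
                                category = assignment[i],
                                area_fraction = out$area_fraction,
                                seed = sp$seed)
  }
  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  load_isic_dataset(dir, fractions = fractions, seed = seed)
}
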