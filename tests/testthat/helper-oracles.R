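# Independent oracles and small fixtures shared across tests.
# The oracles are deliberately written as explicit loops / elementwise
# arithmetic, independent of the package's im2col and tape machinery.

# Direct sliding-window convolution with "same" padding and tap spacing
# `dil` (explicit loops over kernel taps).
oracle_conv <- function(x, w, b, dil = 1L) {
  d <- dim(x)
  kh <- dim(w)[1]; kw <- dim(w)[2]; cout <- dim(w)[4]
  ph <- ((kh - 1) * dil) / 2; pw <- ((kw - 1) * dil) / 2
  y <- array(0, c(d[1], d[2], cout))
  for (oc in seq_len(cout)) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    acc <- b[oc]
    for (c in seq_len(d[3])) for (ki in seq_len(kh)) for (kj in seq_len(kw)) {
      ii <- i + (ki - 1) * dil - ph
      jj <- j + (kj - 1) * dil - pw
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2])
        acc <- acc + x[ii, jj, c] * w[ki, kj, c, oc]
    }
    y[i, j, oc] <- acc
  }
  y
}

sigmoid_ <- function(z) 1 / (1 + exp(-z))

# Hand-rolled concurrent squeeze-excitation: channel branch (GAP ->
# bottleneck -> expand -> sigmoid gate) plus spatial branch (1x1 conv ->
# sigmoid gate), combined by addition.
oracle_scse <- function(f, w) {
  d <- dim(f)
  C <- d[3]
  z <- vapply(seq_len(C), function(c) mean(f[, , c]), 0)
  w1 <- w[["scse.cse.fc1.w"]]; b1 <- w[["scse.cse.fc1.b"]]
  w2 <- w[["scse.cse.fc2.w"]]; b2 <- w[["scse.cse.fc2.b"]]
  cr <- dim(w1)[4]
  h <- pmax(as.vector(t(matrix(w1[1, 1, , ], C, cr)) %*% z + b1), 0)
  gate_c <- sigmoid_(as.vector(t(matrix(w2[1, 1, , ], cr, C)) %*% h + b2))
  cse <- f
  for (c in seq_len(C)) cse[, , c] <- f[, , c] * gate_c[c]
  ws <- w[["scse.sse.w"]]; bs <- w[["scse.sse.b"]]
  smap <- matrix(bs, d[1], d[2])
  for (c in seq_len(C)) smap <- smap + f[, , c] * ws[1, 1, c, 1]
  gate_s <- sigmoid_(smap)
  sse <- f
  for (c in seq_len(C)) sse[, , c] <- f[, , c] * gate_s
  cse + sse
}

# Inference-mode batch norm with fresh running statistics (mean 0, var 1).
oracle_bn_fresh <- function(y, gamma, beta, eps = 1e-5) {
  d <- dim(y)
  out <- y
  for (c in seq_len(d[3]))
    out[, , c] <- y[, , c] / sqrt(1 + eps) * gamma[c] + beta[c]
  out
}

tiny_config <- function(dropout_rate = 0, ...) {
  model_config(rates = c(1L, 2L, 3L, 4L, 5L), branch_channels = 4L,
               dropout_rate = dropout_rate, ...)
}

rand_image <- function(h = 8, w = 8, c = 3, seed = 1) {
  withr::with_seed(seed, array(stats::rnorm(h * w * c), c(h, w, c)))
}

rand_mask <- function(h = 8, w = 8, p = 0.4, seed = 1) {
  withr::with_seed(seed, array(stats::rbinom(h * w, 1, p), c(h, w, 1)))
}

# Tiny in-memory seg_dataset built from the synthetic generator.
tiny_dataset <- function(n, size = 32L, seed = 1L, dir = NULL) {
  dir <- dir %||% file.path(tempdir(), paste0("ds_", seed, "_", n, "_", size))
  if (!file.exists(file.path(dir, "manifest.csv")))
    generate_dataset(n, dir, image_size = c(size, size), seed = seed,
                     fractions = c(0.75, 0.25, 0))
  split <- load_isic_dataset(dir, fractions = c(0.75, 0.25, 0), seed = seed)
  load_split(split, size = c(size, size))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
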