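# The segmentation network: multiscale dilated-fusion encoder (MSF), scSE
# attention, asymmetric skip-connection bridge (ASCS), calibrating decoder
# with deep-supervision heads. All blocks preserve the spatial dims: there is
# no pooling or upsampling anywhere, which is what makes the channel
# concatenations and the pixel-wise calibration product shape-consistent.

IN_CHANNELS <- 3L

.kaiming <- function(dims) {
  fan_in <- prod(dims[-length(dims)])
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

.conv_par <- function(params, name, kh, kw, cin, cout) {
  params[[paste0(name, ".w")]] <- .kaiming(c(kh, kw, cin, cout))
  params[[paste0(name, ".b")]] <- numeric(cout)
  params
}

.bn_par <- function(params, name, c) {
  params[[paste0(name, ".gamma")]] <- rep(1, c)
  params[[paste0(name, ".beta")]] <- numeric(c)
  params
}

.scse_par <- function(params, name, c, reduction) {
  cr <- max(1L, c %/% reduction)
  params <- .conv_par(params, paste0(name, ".cse.fc1"), 1, 1, c, cr)
  params <- .conv_par(params, paste0(name, ".cse.fc2"), 1, 1, cr, c)
  params <- .conv_par(params, paste0(name, ".sse"), 1, 1, c, 1)
  params
}

#' Instantiate a model with freshly initialized weights
#'
#' Builds the full parameter set for a given [model_config()]: five encoder
#' branches (dilated convolution + 3x3 filtering convolution + batch norm),
#' optional scSE blocks per branch and/or on the fused map, the three
#' asymmetric bridge paths (3x3, 1x3, 3x1), the decoder's compression and
#' output convolutions, and the three auxiliary presegmentation heads.
#' Convolution weights use Kaiming fan-in initialization; biases and batch
#' norm shifts start at zero; initialization is deterministic in
#' `config$seed`.
#'
#' @param config A [model_config()].
#' @return An object of class `msfa_model` (an environment holding `config`,
#'   the named parameter list `params`, and batch-norm running statistics).
#' @export
msfa_model <- function(config = model_config()) {
  stopifnot(inherits(config, "msfa_config"))
  model <- new.env(parent = emptyenv())
  model$config <- config
  model$bn_state <- new.env(parent = emptyenv())
  G <- config$branch_channels
  Gb <- config$bridge_channels
  Q <- config$decoder_compress_channels
  p <- list()
  withr::with_seed(config$seed, {
    for (i in 1:5) {
      k <- if (config$rates[i] == 1L) 1L else 3L
      p <- .conv_par(p, sprintf("msf.b%d.dil", i), k, k, IN_CHANNELS, G)
      p <- .conv_par(p, sprintf("msf.b%d.filt", i), 3, 3, G, G)
      p <- .bn_par(p, sprintf("msf.b%d.bn", i), G)
      if (config$scse_placement %in% c("I", "I_and_II"))
        p <- .scse_par(p, sprintf("msf.scse1.b%d", i), G,
                       config$scse_reduction)
    }
    if (config$scse_placement %in% c("II", "I_and_II"))
      p <- .scse_par(p, "msf.scse2", 5L * G, config$scse_reduction)
    for (pp in c("k3x3", "k1x3", "k3x1")) {
      kh <- if (pp == "k1x3") 1L else 3L
      kw <- if (pp == "k3x1") 1L else 3L
      p <- .conv_par(p, paste0("ascs.", pp), kh, kw, IN_CHANNELS, Gb)
      p <- .bn_par(p, paste0("ascs.", pp, ".bn"), Gb)
    }
    p <- .conv_par(p, "dec.compress", 1, 1, 5L * G, Q)
    p <- .bn_par(p, "dec.compress.bn", Q)
    p <- .conv_par(p, "dec.out", 1, 1, Gb + 2L * Q, 1)
    p <- .bn_par(p, "dec.out.bn", 1)
    p <- .conv_par(p, "aux.bridge", 1, 1, Gb, 1)
    p <- .conv_par(p, "aux.compressed", 1, 1, Q, 1)
    p <- .conv_par(p, "aux.calibrated", 1, 1, Q, 1)
  })
  model$params <- p
  class(model) <- "msfa_model"
  model
}

#' @export
print.msfa_model <- function(x, ...) {
  cat("<msfa_model> ", count_parameters(x), " trainable parameters\n",
      sep = "")
  print(x$config)
  invisible(x)
}

# Deep copy (environments are reference objects).
clone_model <- function(model) {
  m <- new.env(parent = emptyenv())
  m$config <- model$config
  m$params <- model$params
  m$bn_state <- new.env(parent = emptyenv())
  for (k in ls(model$bn_state)) m$bn_state[[k]] <- model$bn_state[[k]]
  class(m) <- "msfa_model"
  m
}

# ---- input plumbing --------------------------------------------------------

as_batch <- function(x, channels = NULL) {
  if (is.null(dim(x))) stop("expected an array input")
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 4L)
    stop("expected an (H, W, C) or (H, W, C, N) array")
  if (!is.null(channels) && dim(x)[3] != channels)
    stop("expected ", channels, " channels, got ", dim(x)[3])
  if (any(!is.finite(x))) stop("input contains non-finite values")
  x
}

.restore <- function(a, was_3d) if (was_3d) array(a, dim(a)[1:3]) else a

# ---- tape-level blocks -----------------------------------------------------

.tp <- function(tape, model, grads, name) {
  if (grads) t_param(tape, model$params[[name]], name)
  else t_const(tape, model$params[[name]])
}

.conv_t <- function(tape, model, grads, x_t, name, dil = 1L) {
  t_conv2d(tape, x_t, .tp(tape, model, grads, paste0(name, ".w")),
           .tp(tape, model, grads, paste0(name, ".b")), dil = dil)
}

.bn_t <- function(tape, model, grads, x_t, name, training) {
  t_batchnorm(tape, x_t,
              .tp(tape, model, grads, paste0(name, ".gamma")),
              .tp(tape, model, grads, paste0(name, ".beta")),
              model$bn_state, name, training)
}

.scse_t <- function(tape, model, grads, f_t, name) {
  z <- t_gap(tape, f_t)
  z <- t_relu(tape, .conv_t(tape, model, grads, z, paste0(name, ".cse.fc1")))
  cg <- t_sigmoid(tape, .conv_t(tape, model, grads, z,
                                paste0(name, ".cse.fc2")))
  cse <- t_scale_channels(tape, f_t, cg)
  sg <- t_sigmoid(tape, .conv_t(tape, model, grads, f_t,
                                paste0(name, ".sse")))
  sse <- t_scale_spatial(tape, f_t, sg)
  t_add(tape, cse, sse)
}

.branch_t <- function(tape, model, grads, x_t, i, training) {
  rate <- model$config$rates[i]
  y <- .conv_t(tape, model, grads, x_t, sprintf("msf.b%d.dil", i), dil = rate)
  y <- .conv_t(tape, model, grads, y, sprintf("msf.b%d.filt", i))
  y <- .bn_t(tape, model, grads, y, sprintf("msf.b%d.bn", i), training)
  t_relu(tape, y)
}

.msf_t <- function(tape, model, grads, x_t, training) {
  pl <- model$config$scse_placement
  branches <- lapply(1:5, function(i) {
    f <- .branch_t(tape, model, grads, x_t, i, training)
    if (pl %in% c("I", "I_and_II"))
      f <- .scse_t(tape, model, grads, f, sprintf("msf.scse1.b%d", i))
    f
  })
  y <- t_concat(tape, branches)
  if (pl %in% c("II", "I_and_II"))
    y <- .scse_t(tape, model, grads, y, "msf.scse2")
  y
}

.ascs_t <- function(tape, model, grads, x_t, training) {
  path <- function(name) {
    y <- .conv_t(tape, model, grads, x_t, paste0("ascs.", name))
    t_relu(tape, .bn_t(tape, model, grads, y, paste0("ascs.", name, ".bn"),
                       training))
  }
  y33 <- path("k3x3")
  y13 <- path("k1x3")
  y31 <- path("k3x1")
  fused <- switch(model$config$fusion_rule,
    literal_product = t_hadamard(tape, t_hadamard(tape, y13, y33),
                                 t_hadamard(tape, y31, y33)),
    sum_product = t_hadamard(tape, t_add(tape, y13, y33),
                             t_add(tape, y31, y33)),
    stop("invalid config: unknown fusion_rule"))
  t_dropout(tape, fused, model$config$dropout_rate, training)
}

.decoder_t <- function(tape, model, grads, enc_t, bridge_t, training) {
  de <- dim(enc_t$value); db <- dim(bridge_t$value)
  if (any(de[c(1, 2)] != db[c(1, 2)]))
    stop("shape error: encoder map is ", de[1], "x", de[2],
         " but bridge map is ", db[1], "x", db[2])
  comp <- .conv_t(tape, model, grads, enc_t, "dec.compress")
  comp <- t_relu(tape, .bn_t(tape, model, grads, comp, "dec.compress.bn",
                             training))
  calib <- t_hadamard(tape, comp, bridge_t)
  fused <- t_concat(tape, list(bridge_t, comp, calib))
  out <- .conv_t(tape, model, grads, fused, "dec.out")
  out <- .bn_t(tape, model, grads, out, "dec.out.bn", training)
  pred <- t_sigmoid(tape, out)
  aux <- list(
    bridge = t_sigmoid(tape, .conv_t(tape, model, grads, bridge_t,
                                     "aux.bridge")),
    compressed = t_sigmoid(tape, .conv_t(tape, model, grads, comp,
                                         "aux.compressed")),
    calibrated = t_sigmoid(tape, .conv_t(tape, model, grads, calib,
                                         "aux.calibrated")))
  list(bridge = bridge_t, compressed = comp, calibrated = calib,
       fused = fused, prediction = pred, aux = aux)
}

.msfa_t <- function(tape, model, grads, x_t, training) {
  enc <- .msf_t(tape, model, grads, x_t, training)
  bridge <- .ascs_t(tape, model, grads, x_t, training)
  .decoder_t(tape, model, grads, enc, bridge, training)
}

# ---- public block surface --------------------------------------------------

#' One encoder branch: dilated convolution, 3x3 filtering, batch norm, ReLU
#'
#' Branch `i` applies its dilated convolution (1x1 kernel when the rate is 1,
#' otherwise a 3x3 kernel with taps spaced `rate` pixels apart and "same"
#' padding equal to the rate), then a 3x3 conventional convolution that
#' filters the spatial information, then batch normalization and ReLU.
#' Spatial dims are preserved.
#'
#' @param x An `(H, W, 3)` or `(H, W, 3, N)` array.
#' @param model An [msfa_model()].
#' @param branch Branch index in 1..5.
#' @param training Use batch statistics (`TRUE`) or running statistics.
#' @return A feature map with `branch_channels` channels.
#' @export
dilated_branch <- function(x, model, branch = 1L, training = FALSE) {
  was_3d <- length(dim(x)) == 3L
  x <- as_batch(x, IN_CHANNELS)
  tape <- new_tape()
  out <- .branch_t(tape, model, FALSE, t_const(tape, x), branch, training)
  .restore(out$value, was_3d)
}

#' Standalone scSE attention weights
#'
#' @param channels Number of input channels.
#' @param reduction Bottleneck reduction ratio of the channel branch.
#' @param seed Seed for Kaiming initialization.
#' @return A named list of arrays usable with [scse_attention()].
#' @export
scse_init <- function(channels, reduction = 2L, seed = 1L) {
  if (channels < reduction)
    stop("invalid config: channels (", channels, ") < reduction (",
         reduction, ")")
  p <- list()
  withr::with_seed(seed, p <- .scse_par(p, "scse", channels, reduction))
  p
}

#' Concurrent spatial and channel squeeze-excitation attention
#'
#' The channel branch global-average-pools the map, passes it through a
#' bottleneck (reduction ratio `r`) with ReLU, expands back and gates every
#' channel with a sigmoid. The spatial branch projects the map to one channel
#' with a 1x1 convolution and gates every pixel with a sigmoid. The two gated
#' maps are combined by element-wise addition, so the output is bounded by
#' twice the input magnitude and has the input's shape.
#'
#' @param f An `(H, W, C)` or `(H, W, C, N)` feature map.
#' @param weights A list from [scse_init()] (or a model's scSE parameters
#'   renamed to the `scse.*` keys).
#' @return A gated feature map of the same shape as `f`.
#' @export
scse_attention <- function(f, weights) {
  was_3d <- length(dim(f)) == 3L
  f <- as_batch(f)
  if (dim(f)[3] != dim(weights[["scse.cse.fc1.w"]])[3])
    stop("shape error: map has ", dim(f)[3], " channels but weights expect ",
         dim(weights[["scse.cse.fc1.w"]])[3])
  shim <- new.env(parent = emptyenv())
  shim$params <- weights
  tape <- new_tape()
  out <- .scse_t(tape, shim, FALSE, t_const(tape, f), "scse")
  .restore(out$value, was_3d)
}

#' Multiscale fusion encoder forward pass
#'
#' Runs the five dilated branches in parallel, applies scSE attention per
#' branch and/or after channel concatenation according to
#' `config$scse_placement`, and returns the fused map with
#' `5 * branch_channels` channels at the input's spatial dims.
#'
#' @inheritParams dilated_branch
#' @return The fused encoder feature map.
#' @export
msf_forward <- function(x, model, training = FALSE) {
  was_3d <- length(dim(x)) == 3L
  x <- as_batch(x, IN_CHANNELS)
  tape <- new_tape()
  out <- .msf_t(tape, model, FALSE, t_const(tape, x), training)
  .restore(out$value, was_3d)
}

#' Asymmetric skip-connection bridge forward pass
#'
#' Three parallel convolution + batch norm + ReLU paths with 3x3, 1x3 and 3x1
#' kernels (all "same"-padded) are fused according to `config$fusion_rule`
#' (Hadamard products of the path outputs, or of their pairwise sums), then
#' dropout is applied during training. Spatial dims are preserved; output has
#' `bridge_channels` channels.
#'
#' @inheritParams dilated_branch
#' @return The bridge feature map.
#' @export
ascs_forward <- function(x, model, training = FALSE) {
  was_3d <- length(dim(x)) == 3L
  x <- as_batch(x, IN_CHANNELS)
  tape <- new_tape()
  out <- .ascs_t(tape, model, FALSE, t_const(tape, x), training)
  .restore(out$value, was_3d)
}

#' Batch normalization followed by ReLU
#'
#' Standardizes each channel by `(value - channel_mean) / channel_std`,
#' applies the learned affine transform `scale * xhat + shift`, then clamps
#' at zero. In training mode the mean and (biased) standard deviation are
#' computed from the batch itself; otherwise the supplied per-channel
#' statistics are used. An epsilon keeps zero-variance channels finite.
#'
#' @param y An `(H, W, C)` or `(H, W, C, N)` feature map.
#' @param bn List with `channel_mean`, `channel_std`, `scale`, `shift`
#'   (per-channel numerics).
#' @param training Compute statistics from the batch instead of `bn`.
#' @param eps Stabilizing epsilon added to the variance.
#' @return The normalized, rectified map, same shape as `y`.
#' @export
batchnorm_relu <- function(y, bn, training = FALSE, eps = 1e-5) {
  was_3d <- length(dim(y)) == 3L
  y <- as_batch(y)
  d <- dim(y)
  if (length(bn$scale) != d[3])
    stop("shape error: bn parameters have ", length(bn$scale),
         " channels, map has ", d[3])
  xp <- matrix(aperm(y, c(1, 2, 4, 3)), ncol = d[3])
  if (training) {
    mu <- colMeans(xp)
    xc <- sweep(xp, 2, mu)
    sd_ <- sqrt(colMeans(xc * xc) + eps)
  } else {
    mu <- bn$channel_mean
    sd_ <- sqrt(bn$channel_std^2 + eps)
    xc <- sweep(xp, 2, mu)
  }
  xhat <- sweep(xc, 2, sd_, "/")
  out <- sweep(sweep(xhat, 2, bn$scale, "*"), 2, bn$shift, "+")
  out <- pmax(out, 0)
  out <- aperm(array(out, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  .restore(out, was_3d)
}

#' Calibrating decoder forward pass
#'
#' Compresses the encoder map with a 1x1 convolution + batch norm + ReLU to
#' `decoder_compress_channels` channels, calibrates it by a pixel-wise
#' Hadamard product with the bridge map, concatenates bridge, compressed and
#' calibrated maps on the channel axis, and produces the final
#' single-channel sigmoid probability map via a 1x1 convolution + batch norm.
#'
#' @param encoded Encoder output (`5 * branch_channels` channels).
#' @param bridge Bridge output (`bridge_channels` channels).
#' @param model An [msfa_model()].
#' @param training Batch vs running statistics for batch norm.
#' @return A list of class `msfa_features`; see [msfa_forward()].
#' @export
decoder_forward <- function(encoded, bridge, model, training = FALSE) {
  was_3d <- length(dim(encoded)) == 3L
  encoded <- as_batch(encoded)
  bridge <- as_batch(bridge)
  tape <- new_tape()
  out <- .decoder_t(tape, model, FALSE, t_const(tape, encoded),
                    t_const(tape, bridge), training)
  .features_values(out, was_3d)
}

.features_values <- function(out, was_3d) {
  structure(list(
    bridge = .restore(out$bridge$value, was_3d),
    compressed = .restore(out$compressed$value, was_3d),
    calibrated = .restore(out$calibrated$value, was_3d),
    fused = .restore(out$fused$value, was_3d),
    prediction = .restore(out$prediction$value, was_3d),
    aux = lapply(out$aux, function(a) .restore(a$value, was_3d))),
    class = "msfa_features")
}

#' Full network forward pass
#'
#' Composes the multiscale fusion encoder, the asymmetric bridge and the
#' calibrating decoder. In inference mode (the default) dropout is disabled
#' and batch norm uses running statistics, so the pass is deterministic.
#'
#' @inheritParams dilated_branch
#' @return An `msfa_features` list with elements `bridge`, `compressed`,
#'   `calibrated`, `fused`, `prediction` (values strictly in (0,1), one
#'   channel, input spatial dims) and `aux` (the three auxiliary
#'   presegmentation probability maps).
#' @export
msfa_forward <- function(x, model, training = FALSE) {
  was_3d <- length(dim(x)) == 3L
  x <- as_batch(x, IN_CHANNELS)
  tape <- new_tape()
  out <- .msfa_t(tape, model, FALSE, t_const(tape, x), training)
  .features_values(out, was_3d)
}

#' @export
print.msfa_features <- function(x, ...) {
  cat("<msfa_features>\n")
  for (nm in c("bridge", "compressed", "calibrated", "fused", "prediction"))
    cat(sprintf("  %-11s %s\n", nm, paste(dim(x[[nm]]), collapse = "x")))
  invisible(x)
}

# ---- parameter accounting --------------------------------------------------

#' Count trainable parameters
#'
#' @param model An [msfa_model()] (or a bare named parameter list).
#' @param by_block Return a per-block breakdown instead of the total.
#' @return Integer total, or a data.frame with columns `block` and `params`.
#' @export
count_parameters <- function(model, by_block = FALSE) {
  params <- if (inherits(model, "msfa_model")) model$params else model
  n <- vapply(params, length, 0L)
  if (!by_block) return(sum(n))
  block <- sub("\\..*$", "", names(params))
  agg <- tapply(n, block, sum)
  data.frame(block = names(agg), params = as.integer(agg),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Static multiply-accumulate estimate for one forward pass at the given
# spatial size: each convolution contributes H*W*kh*kw*cin*cout, except the
# scSE channel-bottleneck convolutions which act on the 1x1 pooled vector.
model_macs <- function(model, input_size = c(224L, 224L)) {
  hw <- prod(as.numeric(input_size))
  total <- 0
  for (nm in names(model$params)) {
    if (!grepl("\\.w$", nm)) next
    d <- dim(model$params[[nm]])
    sp <- if (grepl("\\.cse\\.", nm)) 1 else hw
    total <- total + sp * prod(as.numeric(d))
  }
  total
}

# ---- checkpoints -----------------------------------------------------------

#' Save a model checkpoint
#'
#' Writes the parameters, batch-norm running statistics, configuration and
#' (optionally) preprocessing statistics to `path` (RDS), plus a JSON sidecar
#' `<path>.json` carrying the full configuration so the checkpoint is
#' self-describing.
#'
#' @param model An [msfa_model()].
#' @param path Destination file.
#' @param stats Optional preprocessing statistics (list with `mean`, `sd`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, stats = NULL) {
  bn <- mget(ls(model$bn_state), envir = model$bn_state)
  saveRDS(list(config = unclass(model$config), params = model$params,
               bn_state = bn, stats = stats), path)
  jsonlite::write_json(c(unclass(model$config), list(stats = stats)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#'
#' @param path Checkpoint file.
#' @return A list with elements `model` and `stats`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  cfg <- do.call(model_config, obj$config[setdiff(names(obj$config),
                                                  "kernel_set")])
  model <- msfa_model(cfg)
  model$params <- obj$params
  for (k in names(obj$bn_state)) model$bn_state[[k]] <- obj$bn_state[[k]]
  list(model = model, stats = obj$stats)
}
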