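# Minimal reverse-mode automatic differentiation over dense 4-D arrays.
#
# Tensors flow as H x W x C x N arrays (rows, cols, channels, batch). Each op
# appends a node (an environment holding value / grad / backward closure) to a
# tape; backward() replays the tape in reverse creation order, which is a
# valid topological order because every node's parents precede it.
#
# This is deliberately small: exactly the ops the network needs, nothing more.

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 128L)
  tp$n <- 0L
  tp
}

.node <- function(tape, value, backward = NULL, name = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  nd$name <- name
  n <- tape$n + 1L
  if (n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

.accum <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

#' @noRd
backward_pass <- function(tape, loss_node) {
  loss_node$grad <- 1
  for (k in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[k]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

# Collect parameter gradients (leaf nodes carrying names) into a named list.
collect_grads <- function(tape) {
  out <- list()
  for (k in seq_len(tape$n)) {
    nd <- tape$nodes[[k]]
    if (!is.null(nd$name) && !is.null(nd$grad))
      out[[nd$name]] <- if (is.null(out[[nd$name]])) nd$grad else
        out[[nd$name]] + nd$grad
  }
  out
}

t_const <- function(tape, value) .node(tape, value)

t_param <- function(tape, value, name) .node(tape, value, name = name)

# x: (H,W,Cin,N); w: (kh,kw,Cin,Cout); b: length Cout. "Same" padding,
# dilation = dil (taps spaced dil pixels; dil = 1 is ordinary convolution).
t_conv2d <- function(tape, x, w, b, dil = 1L) {
  dx <- dim(x$value)
  dw <- dim(w$value)
  if (dx[3] != dw[3])
    stop("conv2d: input has ", dx[3], " channels but kernel expects ", dw[3])
  kh <- dw[1]; kw <- dw[2]; cout <- dw[4]
  wmat <- matrix(w$value, nrow = kh * kw * dw[3], ncol = cout)
  val <- conv2d_fwd_batch_cpp(x$value, wmat, b$value, kh, kw, dil, dil)
  nd <- .node(tape, val)
  nd$backward <- function(g) {
    if (is.null(dim(g))) dim(g) <- dim(nd$value)
    r <- conv2d_bwd_batch_cpp(x$value, g, wmat, kh, kw, dil, dil)
    .accum(x, r$gx)
    .accum(w, array(r$gw, dw))
    .accum(b, as.numeric(r$gb))
  }
  nd
}

t_relu <- function(tape, x) {
  v <- pmax(x$value, 0)
  nd <- .node(tape, v)
  nd$backward <- function(g) .accum(x, g * (x$value > 0))
  nd
}

t_sigmoid <- function(tape, x) {
  v <- 1 / (1 + exp(-x$value))
  nd <- .node(tape, v)
  nd$backward <- function(g) .accum(x, g * v * (1 - v))
  nd
}

t_add <- function(tape, x, y) {
  nd <- .node(tape, x$value + y$value)
  nd$backward <- function(g) { .accum(x, g); .accum(y, g) }
  nd
}

t_hadamard <- function(tape, x, y) {
  nd <- .node(tape, x$value * y$value)
  nd$backward <- function(g) { .accum(x, g * y$value); .accum(y, g * x$value) }
  nd
}

# Channel gate: f (H,W,C,N) scaled by gate (1,1,C,N).
t_scale_channels <- function(tape, f, gate) {
  d <- dim(f$value)
  hw <- d[1] * d[2]
  gexp <- array(rep(as.vector(gate$value), each = hw), d)
  nd <- .node(tape, f$value * gexp)
  nd$backward <- function(g) {
    .accum(f, g * gexp)
    gg <- colSums(matrix(g * f$value, nrow = hw))       # per (c, n)
    .accum(gate, array(gg, c(1, 1, d[3], d[4])))
  }
  nd
}

# Spatial gate: f (H,W,C,N) scaled by gate (H,W,1,N).
t_scale_spatial <- function(tape, f, gate) {
  d <- dim(f$value)
  hw <- d[1] * d[2]
  # expand (H,W,1,N) across channels: per sample, repeat the H*W block C times
  gexp <- array(0, d)
  gv <- gate$value
  for (n in seq_len(d[4]))
    gexp[, , , n] <- gv[, , 1, n]                       # recycles over C
  nd <- .node(tape, f$value * gexp)
  nd$backward <- function(g) {
    .accum(f, g * gexp)
    gf <- g * f$value
    gg <- array(0, c(d[1], d[2], 1, d[4]))
    for (n in seq_len(d[4]))
      gg[, , 1, n] <- rowSums(matrix(gf[, , , n], nrow = hw))
    .accum(gate, gg)
  }
  nd
}

# Global average pool to (1,1,C,N).
t_gap <- function(tape, f) {
  d <- dim(f$value)
  hw <- d[1] * d[2]
  v <- colMeans(matrix(f$value, nrow = hw))             # per (c, n)
  nd <- .node(tape, array(v, c(1, 1, d[3], d[4])))
  nd$backward <- function(g) {
    .accum(f, array(rep(as.vector(g) / hw, each = hw), d))
  }
  nd
}

t_concat <- function(tape, parts) {
  dims <- lapply(parts, function(p) dim(p$value))
  cc <- vapply(dims, `[`, 0, 3)
  d0 <- dims[[1]]
  val <- array(0, c(d0[1], d0[2], sum(cc), d0[4]))
  at <- 0L
  for (i in seq_along(parts)) {
    val[, , at + seq_len(cc[i]), ] <- parts[[i]]$value
    at <- at + cc[i]
  }
  nd <- .node(tape, val)
  nd$backward <- function(g) {
    at <- 0L
    for (i in seq_along(parts)) {
      .accum(parts[[i]], array(g[, , at + seq_len(cc[i]), , drop = FALSE],
                               dims[[i]]))
      at <- at + cc[i]
    }
  }
  nd
}

# Batch normalization over (H,W,N) per channel; ReLU is applied separately.
# Training mode normalizes with batch statistics (biased variance) and updates
# the running statistics held in `state[[key]]`; inference mode uses the
# running statistics. Epsilon stabilizes zero-variance channels.
t_batchnorm <- function(tape, x, gamma, beta, state, key, training,
                        momentum = 0.1, eps = 1e-5) {
  d <- dim(x$value)
  C <- d[3]; N <- d[4]
  hw <- d[1] * d[2]
  m <- hw * N
  # columns of xm are (channel, sample) pairs, channel fastest
  xm <- matrix(x$value, nrow = hw, ncol = C * N)
  per_ch <- function(v) rowMeans(matrix(v, C, N))       # (c,n) means -> c
  if (training) {
    mu <- per_ch(colMeans(xm))
    xc <- sweep(xm, 2, rep(mu, N))
    va <- per_ch(colMeans(xc * xc))
    st <- state[[key]]
    if (is.null(st)) st <- list(mean = numeric(C), var = rep(1, C))
    state[[key]] <- list(mean = (1 - momentum) * st$mean + momentum * mu,
                         var  = (1 - momentum) * st$var + momentum * va)
  } else {
    st <- state[[key]]
    if (is.null(st)) st <- list(mean = numeric(C), var = rep(1, C))
    mu <- st$mean
    va <- st$var
    xc <- sweep(xm, 2, rep(mu, N))
  }
  sd_ <- sqrt(va + eps)
  xhat <- sweep(xc, 2, rep(sd_, N), "/")
  ym <- sweep(sweep(xhat, 2, rep(gamma$value, N), "*"), 2,
              rep(beta$value, N), "+")
  nd <- .node(tape, array(ym, d))
  nd$backward <- function(g) {
    gm <- matrix(g, nrow = hw, ncol = C * N)
    per_ch_sum <- function(v) rowSums(matrix(v, C, N))
    .accum(gamma, per_ch_sum(colSums(gm * xhat)))
    .accum(beta, per_ch_sum(colSums(gm)))
    gxh <- sweep(gm, 2, rep(gamma$value, N), "*")
    if (training) {
      # d/dx of batch standardization (biased variance)
      s1 <- per_ch_sum(colSums(gxh))
      s2 <- per_ch_sum(colSums(gxh * xhat))
      gx <- sweep(gxh, 2, rep(s1 / m, N)) -
        sweep(xhat, 2, rep(s2 / m, N), "*")
      gx <- sweep(gx, 2, rep(sd_, N), "/")
    } else {
      gx <- sweep(gxh, 2, rep(sd_, N), "/")
    }
    .accum(x, array(gx, d))
  }
  nd
}

# Inverted dropout; identity at inference. Uses the session RNG (seeded by the
# training loop) so runs are reproducible.
t_dropout <- function(tape, x, rate, training) {
  if (!training || rate <= 0) return(x)
  d <- dim(x$value)
  keep <- array(stats::rbinom(prod(d), 1L, 1 - rate), d) / (1 - rate)
  nd <- .node(tape, x$value * keep)
  nd$backward <- function(g) .accum(x, g * keep)
  nd
}

# Mean binary cross-entropy between a probability map and a {0,1} label map.
# Probabilities are clamped away from 0/1 for numeric safety; the gradient is
# taken through the clamped value.
t_bce <- function(tape, pred, label, eps = 1e-7) {
  y <- label$value
  p <- pmin(pmax(pred$value, eps), 1 - eps)
  n <- length(p)
  nd <- .node(tape, -mean(y * log(p) + (1 - y) * log(1 - p)))
  nd$backward <- function(g) {
    .accum(pred, array(g * (p - y) / (p * (1 - p)) / n, dim(pred$value)))
  }
  nd
}

# Weighted sum of scalar nodes (loss assembly).
t_wsum <- function(tape, nodes, coefs) {
  nd <- .node(tape, sum(vapply(nodes, function(x) x$value, 0) * coefs))
  nd$backward <- function(g) {
    for (i in seq_along(nodes)) .accum(nodes[[i]], g * coefs[i])
  }
  nd
}
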