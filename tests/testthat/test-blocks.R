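# Architectural blocks: encoder branches, scSE attention, asymmetric bridge,
# batch norm + ReLU, decoder, and the composed forward pass.

test_that("config validation rejects malformed architectures", {
  expect_error(model_config(rates = c(1, 3, 6)), "5 dilation rates")
  expect_error(model_config(rates = c(2, 3, 6, 12, 18)), "must be 1")
  expect_error(model_config(rates = c(1, 3, 3, 12, 18)), "increasing")
  expect_error(model_config(rates = c(1, 3, 6, 12, 18),
                            decoder_compress_channels = 5),
               "bridge_channels")
  expect_error(model_config(branch_channels = 1, scse_reduction = 4),
               "scse_reduction")
  expect_error(tiny_config(dropout_rate = 1.2), "dropout_rate")
})

test_that("encoder branch preserves spatial dims and emits G channels", {
  model <- msfa_model(tiny_config(seed = 2))
  x <- rand_image(10, 12)
  for (i in c(1, 3, 5)) {
    y <- dilated_branch(x, model, branch = i)
    expect_identical(dim(y), c(10L, 12L, 4L))
    expect_true(all(y >= 0))          # post-ReLU
  }
})

test_that("zero input flows to zero through branch and bridge", {
  model <- msfa_model(tiny_config(seed = 2))
  x <- array(0, c(8, 8, 3))
  expect_equal(max(abs(dilated_branch(x, model, 2))), 0)
  expect_equal(max(abs(ascs_forward(x, model))), 0)
  m2 <- msfa_model(tiny_config(seed = 2, fusion_rule = "sum_product"))
  expect_equal(max(abs(ascs_forward(x, m2))), 0)
})

test_that("scSE matches the loop-written squeeze-excitation oracle", {
  w <- scse_init(channels = 4, reduction = 2, seed = 5)
  f <- rand_image(4, 4, 4, seed = 6)
  got <- scse_attention(f, w)
  expect_lt(max(abs(got - oracle_scse(f, w))), 1e-6)
})

test_that("scSE gates bound the output and annihilate zero input", {
  w <- scse_init(channels = 3, reduction = 2, seed = 7)
  f0 <- array(0, c(5, 5, 3))
  expect_equal(max(abs(scse_attention(f0, w))), 0)
  f <- rand_image(5, 5, 3, seed = 8)
  out <- scse_attention(f, w)
  expect_true(all(abs(out) <= 2 * abs(f) + 1e-12))
  expect_error(scse_init(channels = 1, reduction = 4), "reduction")
})

test_that("encoder concatenates five gated branches on channels", {
  model <- msfa_model(tiny_config(seed = 3, scse_placement = "none"))
  x <- rand_image(9, 9)
  y <- msf_forward(x, model)
  expect_identical(dim(y), c(9L, 9L, 20L))
  # placement "none": fused map is exactly the stacked branch outputs
  for (i in 1:5)
    expect_equal(y[, , (i - 1) * 4 + 1:4],
                 dilated_branch(x, model, i), tolerance = 1e-12)
})

test_that("asymmetric bridge matches a step-by-step oracle on both rules", {
  for (rule in c("literal_product", "sum_product")) {
    model <- msfa_model(tiny_config(seed = 4, fusion_rule = rule))
    x <- rand_image(8, 8, 3, seed = 9)
    p <- model$params
    path <- function(nm) {
      y <- oracle_conv(x, p[[paste0("ascs.", nm, ".w")]],
                       p[[paste0("ascs.", nm, ".b")]], 1)
      pmax(oracle_bn_fresh(y, p[[paste0("ascs.", nm, ".bn.gamma")]],
                           p[[paste0("ascs.", nm, ".bn.beta")]]), 0)
    }
    y33 <- path("k3x3"); y13 <- path("k1x3"); y31 <- path("k3x1")
    want <- if (rule == "literal_product") (y13 * y33) * (y31 * y33)
            else (y13 + y33) * (y31 + y33)
    expect_lt(max(abs(ascs_forward(x, model) - want)), 1e-5, label = rule)
  }
})

test_that("asymmetric kernel pair carries 2/3 the weights of a square kernel",
{
  model <- msfa_model(tiny_config(seed = 1))
  n13 <- length(model$params[["ascs.k1x3.w"]])
  n31 <- length(model$params[["ascs.k3x1.w"]])
  n33 <- length(model$params[["ascs.k3x3.w"]])
  expect_identical(n13 + n31, as.integer(2 / 3 * n33))
})

test_that("batch norm + ReLU standardizes and clamps as specified", {
  y <- rand_image(4, 4, 2, seed = 11)
  bn_id <- list(channel_mean = c(0, 0), channel_std = c(1, 1),
                scale = c(1, 1), shift = c(0, 0))
  expect_equal(batchnorm_relu(y, bn_id, eps = 0), pmax(y, 0),
               tolerance = 1e-12)
  expect_true(all(batchnorm_relu(rand_image(3, 3, 2, seed = 12),
                                 bn_id) >= 0))
  # batch statistics: values {1,2,3} standardize to mean 0, unit variance
  v <- array(rep(c(1, 2, 3), each = 1), c(1, 3, 1))
  bn1 <- list(channel_mean = 0, channel_std = 1, scale = 1, shift = 0)
  got <- batchnorm_relu(v, bn1, training = TRUE, eps = 0)
  want <- pmax((c(1, 2, 3) - 2) / sqrt(2 / 3), 0)  # biased sd of {1,2,3}
  expect_equal(as.vector(got), want, tolerance = 1e-9)
  expect_error(batchnorm_relu(y, bn1), "channels")
})

test_that("decoder calibrates, concatenates and predicts per the contract", {
  model <- msfa_model(tiny_config(seed = 6))
  x <- rand_image(6, 6, 3, seed = 13)
  enc <- msf_forward(x, model)
  bridge <- ascs_forward(x, model)
  out <- decoder_forward(enc, bridge, model)
  expect_identical(dim(out$prediction), c(6L, 6L, 1L))
  expect_true(all(out$prediction > 0 & out$prediction < 1))
  expect_identical(dim(out$fused)[3], 9L)
  expect_equal(out$calibrated, out$compressed * bridge, tolerance = 1e-12)
  # bridge identically 1: calibration is the identity
  ones <- array(1, dim(bridge))
  out1 <- decoder_forward(enc, ones, model)
  expect_equal(out1$calibrated, out1$compressed, tolerance = 1e-12)
  expect_error(decoder_forward(enc, ascs_forward(rand_image(4, 4), model),
                               model), "shape")
})

test_that("decoder matches an explicit oracle of its four stages", {
  model <- msfa_model(tiny_config(seed = 7))
  p <- model$params
  enc <- rand_image(4, 4, 20, seed = 14)
  bridge <- abs(rand_image(4, 4, 3, seed = 15))
  comp <- pmax(oracle_bn_fresh(
    oracle_conv(enc, p[["dec.compress.w"]], p[["dec.compress.b"]], 1),
    p[["dec.compress.bn.gamma"]], p[["dec.compress.bn.beta"]]), 0)
  calib <- comp * bridge
  fused <- array(c(bridge, comp, calib), c(4, 4, 9))
  logit <- oracle_bn_fresh(
    oracle_conv(fused, p[["dec.out.w"]], p[["dec.out.b"]], 1),
    p[["dec.out.bn.gamma"]], p[["dec.out.bn.beta"]])
  want <- sigmoid_(logit)
  got <- decoder_forward(enc, bridge, model)
  expect_lt(max(abs(got$prediction - want)), 1e-5)
  expect_lt(max(abs(got$compressed - comp)), 1e-5)
})

test_that("full forward pass is shape-correct, bounded and deterministic", {
  model <- msfa_model(tiny_config(seed = 8))
  x <- rand_image(16, 16, 3, seed = 16)
  out <- msfa_forward(x, model)
  expect_identical(dim(out$prediction), c(16L, 16L, 1L))
  expect_true(all(out$prediction > 0 & out$prediction < 1))
  for (a in out$aux) expect_true(all(a > 0 & a < 1))
  out2 <- msfa_forward(x, model)
  expect_identical(out$prediction, out2$prediction)   # bit-identical
  # batch of two preserves order and matches single passes
  xb <- array(c(x, 2 * x), c(16, 16, 3, 2))
  ob <- msfa_forward(xb, model)
  expect_equal(ob$prediction[, , , 1, drop = TRUE],
               out$prediction[, , 1], tolerance = 1e-12)
})

test_that("every block preserves spatial dimensions", {
  model <- msfa_model(tiny_config(seed = 9))
  x <- rand_image(7, 11)
  expect_identical(dim(msf_forward(x, model))[1:2], c(7L, 11L))
  expect_identical(dim(ascs_forward(x, model))[1:2], c(7L, 11L))
  expect_identical(dim(msfa_forward(x, model)$prediction)[1:2], c(7L, 11L))
})

test_that("parameter counting is exact on closed-form cases", {
  # one 3x3 conv, 1 -> 1 channels, no bias: 9 weights
  expect_identical(count_parameters(list(w = array(0, c(3, 3, 1, 1)))), 9L)
  # the 1x3 + 3x1 pair at 1 -> 1 channels: 6 weights
  expect_identical(count_parameters(list(a = array(0, c(1, 3, 1, 1)),
                                         b = array(0, c(3, 1, 1, 1)))), 6L)
  model <- msfa_model(tiny_config(seed = 1))
  bb <- count_parameters(model, by_block = TRUE)
  expect_identical(sum(bb$params), count_parameters(model))
  expect_true(all(c("msf", "ascs", "dec", "aux") %in% bb$block))
})
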