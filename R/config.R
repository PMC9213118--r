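#' Architecture configuration
#'
#' Collects every architectural hyperparameter of the segmentation network:
#' the five dilation rates of the multiscale fusion (MSF) encoder, the encoder
#' branch width, the asymmetric-bridge (ASCS) width, where the scSE attention
#' blocks sit, how the bridge's three paths are fused, and the decoder
#' compression width.
#'
#' @param rates Integer vector of five dilation rates `r_1..r_5`, strictly
#'   increasing with `rates[1] == 1`. Rate 1 uses a 1x1 kernel; the others use
#'   3x3 kernels with taps spaced `rate` pixels apart.
#' @param branch_channels Channels `G` produced by each encoder branch
#'   (default 128).
#' @param bridge_channels Channels `G` of the ASCS bridge (default 3).
#' @param scse_placement Where scSE attention is applied: `"I"` (on each
#'   branch before concatenation), `"II"` (on the fused map), `"I_and_II"`
#'   (both, default) or `"none"`.
#' @param fusion_rule How the bridge's three path outputs are fused:
#'   `"literal_product"` (default) fuses by
#'   `(Y1x3 * Y3x3) * (Y3x1 * Y3x3)` (Hadamard products);
#'   `"sum_product"` by `(Y1x3 + Y3x3) * (Y3x1 + Y3x3)`.
#' @param dropout_rate Dropout fraction applied after bridge fusion during
#'   training (default 0.1).
#' @param scse_reduction Channel-bottleneck reduction ratio of the scSE
#'   channel branch (default 2).
#' @param decoder_compress_channels Channels of the decoder's compressed map;
#'   must equal `bridge_channels` so the pixel-wise calibration product is
#'   shape-valid (default 3).
#' @param seed Integer seed for weight initialization.
#' @return A validated list of class `msfa_config`.
#' @export
model_config <- function(rates = c(1L, 3L, 6L, 12L, 18L),
                         branch_channels = 128L,
                         bridge_channels = 3L,
                         scse_placement = c("I_and_II", "I", "II", "none"),
                         fusion_rule = c("literal_product", "sum_product"),
                         dropout_rate = 0.1,
                         scse_reduction = 2L,
                         decoder_compress_channels = bridge_channels,
                         seed = 1L) {
  scse_placement <- match.arg(scse_placement)
  fusion_rule <- match.arg(fusion_rule)
  rates <- as.integer(rates)
  if (length(rates) != 5L)
    stop("invalid config: exactly 5 dilation rates are required, got ",
         length(rates))
  if (any(rates < 1L))
    stop("invalid config: dilation rates must be >= 1")
  if (rates[1] != 1L)
    stop("invalid config: the first dilation rate must be 1 (1x1 branch)")
  if (any(diff(rates) <= 0))
    stop("invalid config: dilation rates must be strictly increasing")
  if (branch_channels < 1L)
    stop("invalid config: branch_channels must be >= 1")
  if (bridge_channels < 1L)
    stop("invalid config: bridge_channels must be >= 1")
  if (decoder_compress_channels != bridge_channels)
    stop("invalid config: decoder_compress_channels (",
         decoder_compress_channels, ") must equal bridge_channels (",
         bridge_channels, ") for the pixel-wise calibration product")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("invalid config: dropout_rate must lie in [0, 1)")
  if (scse_reduction < 1L)
    stop("invalid config: scse_reduction must be >= 1")
  if (scse_placement %in% c("I", "I_and_II") &&
      branch_channels < scse_reduction)
    stop("invalid config: branch_channels (", branch_channels,
         ") < scse_reduction (", scse_reduction, ")")
  structure(list(rates = rates,
                 branch_channels = as.integer(branch_channels),
                 kernel_set = c(1L, 3L),
                 bridge_channels = as.integer(bridge_channels),
                 scse_placement = scse_placement,
                 fusion_rule = fusion_rule,
                 dropout_rate = dropout_rate,
                 scse_reduction = as.integer(scse_reduction),
                 decoder_compress_channels =
                   as.integer(decoder_compress_channels),
                 seed = as.integer(seed)),
            class = "msfa_config")
}

#' @export
print.msfa_config <- function(x, ...) {
  cat("<msfa_config>\n")
  cat("  rates:            ", paste(x$rates, collapse = ", "), "\n")
  cat("  branch channels:  ", x$branch_channels, "\n")
  cat("  bridge channels:  ", x$bridge_channels, "\n")
  cat("  scSE placement:   ", x$scse_placement,
      " (reduction ", x$scse_reduction, ")\n", sep = "")
  cat("  fusion rule:      ", x$fusion_rule, "\n")
  cat("  dropout rate:     ", x$dropout_rate, "\n")
  cat("  seed:             ", x$seed, "\n")
  invisible(x)
}

#' Loss coefficients of the deep-supervision objective
#'
#' The composite training loss adds the main prediction's cross-entropy to
#' three auxiliary cross-entropies computed from presegmentation heads on the
#' bridge, compressed and calibrated feature maps, weighted by `mu`, `nu` and
#' `xi`. The coefficients must each lie in `[0, 1]` and sum to one.
#'
#' @param mu,nu,xi Weights of the bridge, compressed and calibrated auxiliary
#'   heads. Default is the uniform `1/3` each.
#' @return A list of class `loss_weights`.
#' @export
loss_weights <- function(mu = 1 / 3, nu = 1 / 3, xi = 1 / 3) {
  w <- c(mu, nu, xi)
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
    stop("invalid loss weights: mu, nu, xi must lie in [0, 1]")
  if (abs(sum(w) - 1) > 1e-9)
    stop("invalid loss weights: mu + nu + xi must equal 1 (got ",
         format(sum(w), digits = 12), ")")
  structure(list(mu = mu, nu = nu, xi = xi), class = "loss_weights")
}
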