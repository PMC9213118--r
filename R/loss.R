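#' Mean binary cross-entropy
#'
#' Computes `-mean(y * log(p) + (1 - y) * log(1 - p))` over all pixels, with
#' probabilities clamped to `[eps, 1 - eps]` for numeric safety.
#'
#' @param pred Probability array with values in (0, 1).
#' @param label Binary array of the same shape.
#' @param eps Clamp width (default `1e-7`).
#' @return A non-negative scalar.
#' @export
binary_cross_entropy <- function(pred, label, eps = 1e-7) {
  if (!identical(dim(pred), dim(label)) &&
      length(pred) != length(label))
    stop("shape error: prediction and label differ in shape")
  p <- pmin(pmax(pred, eps), 1 - eps)
  -mean(label * log(p) + (1 - label) * log(1 - p))
}

#' Composite deep-supervision loss
#'
#' The training objective adds the main prediction's cross-entropy to three
#' auxiliary cross-entropies computed from single-channel presegmentation
#' heads on the bridge, compressed and calibrated maps:
#' `BCE(pred) + mu * BCE(head_bridge) + nu * BCE(head_compressed) +
#' xi * BCE(head_calibrated)`, with `mu + nu + xi = 1`.
#'
#' @param features An `msfa_features` list from [msfa_forward()], or any list
#'   with a `prediction` element.
#' @param label Binary mask array matching the prediction's spatial dims.
#' @param w A [loss_weights()] object.
#' @param aux Optional list of the three auxiliary probability maps (named
#'   `bridge`, `compressed`, `calibrated`); defaults to `features$aux`.
#' @return A non-negative scalar.
#' @export
composite_loss <- function(features, label, w = loss_weights(), aux = NULL) {
  if (!inherits(w, "loss_weights"))
    w <- do.call(loss_weights, as.list(w))
  if (is.null(aux)) aux <- features$aux
  label <- as_batch(label)
  pred <- as_batch(features$prediction)
  binary_cross_entropy(pred, label) +
    w$mu * binary_cross_entropy(as_batch(aux$bridge), label) +
    w$nu * binary_cross_entropy(as_batch(aux$compressed), label) +
    w$xi * binary_cross_entropy(as_batch(aux$calibrated), label)
}
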