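# Adam optimizer and the training loop. One Adam step per minibatch; the
# learning rate is re-read from the annealing schedule at each epoch.

adam_init <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  st$v <- st$m
  st$t <- 0L
  st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(model, grads, opt, lr) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g * g
    step <- lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
    model$params[[nm]] <- model$params[[nm]] - step
  }
  invisible(NULL)
}

# One forward/backward pass on a batch; returns loss and parameter grads.
.train_batch <- function(model, x, y, w) {
  tape <- new_tape()
  out <- .msfa_t(tape, model, TRUE, t_const(tape, x), training = TRUE)
  lab <- t_const(tape, y)
  losses <- list(t_bce(tape, out$prediction, lab),
                 t_bce(tape, out$aux$bridge, lab),
                 t_bce(tape, out$aux$compressed, lab),
                 t_bce(tape, out$aux$calibrated, lab))
  total <- t_wsum(tape, losses, c(1, w$mu, w$nu, w$xi))
  backward_pass(tape, total)
  list(loss = total$value, grads = collect_grads(tape))
}

#' Train a segmentation model
#'
#' Minibatch training with Adam under the two-stage annealing schedule.
#' Each epoch shuffles the training set, optimizes the composite
#' deep-supervision loss, then evaluates loss and micro-averaged Dice/IoU on
#' the validation set in inference mode. The model with the best validation
#' Dice is kept. All randomness (shuffling, dropout) derives from `seed`,
#' so a repeated run reproduces the history exactly.
#'
#' @param model An [msfa_model()]; updated in place.
#' @param train_set,val_set `seg_dataset` objects (see [load_split()]).
#' @param epochs Number of training epochs.
#' @param batch_size Images per Adam step (default 8).
#' @param lr Initial learning rate (default `1e-4`).
#' @param weights [loss_weights()] of the auxiliary heads.
#' @param seed Integer seed controlling shuffling and dropout.
#' @param total_epochs Planned schedule length `s` for the annealer
#'   (defaults to `epochs`).
#' @param lr_floor Learning-rate floor (default `1e-6`).
#' @param threshold Binarization threshold for validation metrics.
#' @param verbose Print one line per epoch.
#' @return A list of class `msfa_fit`: `model` (final), `best` (best
#'   validation-Dice snapshot), `history` (data.frame with epoch, lr,
#'   train_loss, val_loss, val_dice, val_iou), `best_epoch`.
#' @export
train_model <- function(model, train_set, val_set, epochs = 150L,
                        batch_size = 8L, lr = 1e-4,
                        weights = loss_weights(), seed = 1L,
                        total_epochs = epochs, lr_floor = 1e-6,
                        threshold = 0.5, verbose = FALSE) {
  n <- dim(train_set$images)[4]
  nv <- dim(val_set$images)[4]
  if (is.null(n) || n == 0 || is.null(nv) || nv == 0)
    stop("empty dataset")
  if (!inherits(weights, "loss_weights"))
    weights <- do.call(loss_weights, as.list(weights))
  sched <- lraa_init(lr = lr, total_epochs = total_epochs,
                     lr_floor = lr_floor)
  opt <- adam_init(model$params)
  history <- vector("list", epochs)
  best <- NULL
  best_dice <- -Inf
  best_epoch <- NA_integer_
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      bl <- 0
      nb <- 0L
      for (i0 in seq(1, n, by = batch_size)) {
        idx <- ord[i0:min(i0 + batch_size - 1, n)]
        r <- .train_batch(model,
                          train_set$images[, , , idx, drop = FALSE],
                          train_set$masks[, , , idx, drop = FALSE],
                          weights)
        adam_step(model, r$grads, opt, sched$lr)
        bl <- bl + r$loss
        nb <- nb + 1L
      }
      train_loss <- bl / nb
      val <- .validate(model, val_set, weights, threshold, batch_size)
      history[[ep]] <- data.frame(epoch = ep, lr = sched$lr,
                                  train_loss = train_loss,
                                  val_loss = val$loss,
                                  val_dice = val$dice, val_iou = val$iou)
      if (verbose)
        message(sprintf(
          "epoch %3d  lr %.2e  train %.4f  val %.4f  dice %.4f  iou %.4f",
          ep, sched$lr, train_loss, val$loss, val$dice, val$iou))
      if (val$dice > best_dice) {
        best_dice <- val$dice
        best <- clone_model(model)
        best_epoch <- ep
      }
      sched <- lraa_step(sched, train_loss)
    }
  })
  structure(list(model = model, best = best,
                 history = do.call(rbind, history),
                 best_epoch = best_epoch),
            class = "msfa_fit")
}

.validate <- function(model, val_set, weights, threshold, batch_size) {
  nv <- dim(val_set$images)[4]
  counts <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  loss <- 0
  nb <- 0L
  for (i0 in seq(1, nv, by = batch_size)) {
    idx <- i0:min(i0 + batch_size - 1, nv)
    x <- val_set$images[, , , idx, drop = FALSE]
    y <- val_set$masks[, , , idx, drop = FALSE]
    fx <- msfa_forward(x, model, training = FALSE)
    loss <- loss + composite_loss(fx, y, weights)
    nb <- nb + 1L
    counts <- counts + confusion_counts((fx$prediction >= threshold) * 1, y)
  }
  list(loss = loss / nb,
       dice = unname(dice(counts["tp"], counts["fp"], counts["fn"])),
       iou = unname(iou(counts["tp"], counts["fp"], counts["fn"])))
}

#' @export
print.msfa_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<msfa_fit> %d epochs; best val Dice %.4f at epoch %d; final lr %.2e\n",
    nrow(h), max(h$val_dice), x$best_epoch, h$lr[nrow(h)]))
  invisible(x)
}

#' Predict a lesion mask for one image
#'
#' @param model An [msfa_model()].
#' @param image An `(H, W, 3)` normalized array (see [preprocess_pair()]).
#' @param threshold Binarization threshold.
#' @return A list with `prob` (H x W probability matrix) and `mask`
#'   (H x W binary matrix).
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  fx <- msfa_forward(image, model, training = FALSE)
  prob <- fx$prediction[, , 1]
  list(prob = prob, mask = (prob >= threshold) * 1)
}
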