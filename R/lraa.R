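#' Initialize the two-stage annealing learning-rate schedule
#'
#' The schedule (used on top of Adam) keeps the learning rate constant for
#' the first half of training. From the attenuation epoch `tau = s %/% 2`
#' onwards it compares the loss of adjacent epochs: whenever an epoch fails
#' to improve on the previous one, the rate is halved, never dropping below
#' `lr_floor`. The rate is therefore non-increasing throughout training.
#'
#' @param lr Initial learning rate (default `1e-4`).
#' @param total_epochs Planned number of training epochs `s` (default 150).
#' @param lr_floor Lower bound on the learning rate (default `1e-6`).
#' @return A list of class `lraa_state` with fields `lr`, `total_epochs`,
#'   `decay_start`, `epoch`, `prev_loss`, `lr_floor`.
#' @export
lraa_init <- function(lr = 1e-4, total_epochs = 150L, lr_floor = 1e-6) {
  stopifnot(lr > 0, total_epochs >= 1, lr_floor > 0, lr >= lr_floor)
  structure(list(lr = lr, total_epochs = as.integer(total_epochs),
                 decay_start = as.integer(total_epochs) %/% 2L,
                 epoch = 0L, prev_loss = NULL, lr_floor = lr_floor),
            class = "lraa_state")
}

#' Advance the annealing schedule by one epoch
#'
#' @param state An `lraa_state` from [lraa_init()].
#' @param epoch_loss The (finite) training loss of the epoch just completed.
#' @return The updated state; `state$lr` is the rate to use for the next
#'   epoch.
#' @export
lraa_step <- function(state, epoch_loss) {
  stopifnot(inherits(state, "lraa_state"))
  if (!is.finite(epoch_loss)) stop("epoch_loss must be finite")
  if (state$epoch >= state$decay_start && !is.null(state$prev_loss) &&
      epoch_loss >= state$prev_loss)
    state$lr <- max(state$lr / 2, state$lr_floor)
  state$prev_loss <- epoch_loss
  state$epoch <- state$epoch + 1L
  state
}

#' @export
print.lraa_state <- function(x, ...) {
  cat(sprintf(
    "<lraa_state> epoch %d/%d  lr %.3g  (decay from epoch %d, floor %.0e)\n",
    x$epoch, x$total_epochs, x$lr, x$decay_start, x$lr_floor))
  invisible(x)
}
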