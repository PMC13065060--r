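# Adam optimizer and the plateau/early-stopping monitors of the training
# protocol. The monitors are standalone objects so the protocol logic can be
# exercised against synthetic monitor sequences without running training.

adam_init <- function() {
  e <- new.env(parent = emptyenv())
  e$t <- 0L
  e
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(net$layers)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    for (f in intersect(names(g), param_fields)) {
      gr <- g[[f]]
      if (weight_decay > 0) gr <- gr + weight_decay * net$layers[[nm]][[f]]
      km <- paste0(nm, ".", f, ".m"); kv <- paste0(nm, ".", f, ".v")
      m <- if (is.null(state[[km]])) gr * 0 else state[[km]]
      v <- if (is.null(state[[kv]])) gr * 0 else state[[kv]]
      m <- beta1 * m + (1 - beta1) * gr
      v <- beta2 * v + (1 - beta2) * gr * gr
      state[[km]] <- m; state[[kv]] <- v
      net$layers[[nm]][[f]] <- net$layers[[nm]][[f]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  net
}

#' Plateau learning-rate scheduler
#'
#' Halves the learning rate (`factor` 0.5) after `patience` epochs without an
#' improvement of more than `min_delta` in the monitored quantity
#' (maximized). Mirrors reduce-on-plateau semantics: the rate drops on the
#' first epoch whose bad-epoch count exceeds `patience`, then the count
#' resets.
#'
#' @param lr0 initial learning rate
#' @param factor multiplicative decay factor
#' @param patience epochs without improvement before decaying
#' @param min_delta minimum improvement to reset the counter
#' @return object with `$step(monitor)` returning the rate to use next, and
#'   `$lr()` for the current rate
#' @export
plateau_scheduler <- function(lr0, factor = 0.5, patience = 5L,
                              min_delta = 1e-3) {
  best <- -Inf; bad <- 0L; lr <- lr0
  list(
    step = function(monitor) {
      if (monitor > best + min_delta) {
        best <<- monitor; bad <<- 0L
      } else {
        bad <<- bad + 1L
        if (bad > patience) { lr <<- lr * factor; bad <<- 0L }
      }
      lr
    },
    lr = function() lr)
}

#' Early stopping on a maximized monitor
#'
#' Signals a stop after `patience` consecutive epochs without an improvement
#' of more than `min_delta` over the best value seen.
#'
#' @param patience epochs to wait
#' @param min_delta minimum improvement
#' @return object with `$step(monitor)` returning `TRUE` when the epoch
#'   improved the best value, `$should_stop()`, and `$best()`
#' @export
early_stopping <- function(patience = 12L, min_delta = 1e-3) {
  best <- -Inf; bad <- 0L
  list(
    step = function(monitor) {
      if (monitor > best + min_delta) {
        best <<- monitor; bad <<- 0L
        TRUE
      } else {
        bad <<- bad + 1L
        FALSE
      }
    },
    should_stop = function() bad >= patience,
    best = function() best)
}

#' Training protocol settings
#'
#' The unified protocol shared by every variant: Adam (no weight decay),
#' plateau halving of the learning rate (factor 0.5, patience 5), early
#' stopping (patience 12, minimum improvement 1e-3), both monitored on
#' validation macro Dice (maximized), capped at 200 epochs.
#'
#' @param lr Adam learning rate
#' @param weight_decay L2 penalty (0 by default: plain Adam)
#' @param sched_factor,sched_patience plateau scheduler settings
#' @param es_patience,min_delta early-stopping settings
#' @param max_epochs epoch cap
#' @param batch_size slices per optimization step
#' @param augment an [augment_params()] for training batches
#' @return a `train_protocol` list
#' @export
train_protocol <- function(lr = 1e-4, weight_decay = 0, sched_factor = 0.5,
                           sched_patience = 5L, es_patience = 12L,
                           min_delta = 1e-3, max_epochs = 200L,
                           batch_size = 4L, augment = augment_params()) {
  if (min_delta <= 0) stopf("min_delta must be > 0")
  structure(list(lr = lr, weight_decay = weight_decay,
                 sched_factor = sched_factor,
                 sched_patience = as.integer(sched_patience),
                 es_patience = as.integer(es_patience), min_delta = min_delta,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), augment = augment),
            class = "train_protocol")
}
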