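#' Optimizer specification
#'
#' The three optimizers used for head training: Adam, Adagrad and SGD
#' (with momentum).
#'
#' @param kind `"adam"`, `"adagrad"` or `"sgd"`.
#' @param learningRate positive base learning rate.
#' @param momentum SGD momentum in [0, 1); ignored otherwise.
#' @return an object of class `OptimizerSpec`.
#' @export
optimizerSpec <- function(kind = c("adam", "adagrad", "sgd"),
                          learningRate = 1e-3, momentum = 0.9) {
  if (length(kind) == 1L && !kind %in% c("adam", "adagrad", "sgd")) {
    stop("unknown optimizer '", kind,
         "'; valid options are: adam, adagrad, sgd", call. = FALSE)
  }
  kind <- match.arg(kind)
  assertScalarNumber(learningRate, "learningRate", 1e-12)
  assertScalarNumber(momentum, "momentum", 0, 1 - 1e-9)
  structure(list(kind = kind, learningRate = learningRate,
                 momentum = momentum),
            class = "OptimizerSpec")
}

optimizerInit <- function(spec, n) {
  switch(spec$kind,
         adam = list(m = numeric(n), v = numeric(n), t = 0L),
         adagrad = list(G = numeric(n)),
         sgd = list(buf = numeric(n)))
}

# One optimizer step on a flat parameter vector; returns updated params
# and state. `lr` is the scheduled learning rate for the current epoch.
optimizerStep <- function(spec, state, params, grad, lr) {
  eps <- 1e-8
  if (spec$kind == "adam") {
    state$t <- state$t + 1L
    state$m <- 0.9 * state$m + 0.1 * grad
    state$v <- 0.999 * state$v + 0.001 * grad^2
    mhat <- state$m / (1 - 0.9^state$t)
    vhat <- state$v / (1 - 0.999^state$t)
    params <- params - lr * mhat / (sqrt(vhat) + eps)
  } else if (spec$kind == "adagrad") {
    state$G <- state$G + grad^2
    params <- params - lr * grad / (sqrt(state$G) + eps)
  } else {
    state$buf <- spec$momentum * state$buf + grad
    params <- params - lr * state$buf
  }
  list(params = params, state = state)
}

#' Learning-rate schedule
#'
#' Step decay: the learning rate is multiplied by `factor` at each
#' milestone epoch (so from epoch `milestones[i]` onward the rate has been
#' reduced `i` times).
#'
#' @param factor multiplicative decay in (0, 1), default 0.1.
#' @param milestones strictly increasing epoch indices (default c(40, 70)).
#' @return an object of class `LrScheduleSpec`.
#' @export
lrScheduleSpec <- function(factor = 0.1, milestones = c(40L, 70L)) {
  assertScalarNumber(factor, "factor", 1e-12, 1 - 1e-12)
  stopifnot(all(diff(milestones) > 0) || length(milestones) <= 1L)
  structure(list(factor = factor, milestones = as.integer(milestones)),
            class = "LrScheduleSpec")
}

#' Scheduled learning rate at an epoch
#' @param sched a [lrScheduleSpec()].
#' @param baseLr base learning rate.
#' @param epoch epoch index (1-based).
#' @return the decayed learning rate.
#' @export
scheduledLr <- function(sched, baseLr, epoch) {
  baseLr * sched$factor^sum(sched$milestones <= epoch)
}

#' Early-stopping specification
#'
#' Training halts when the monitored validation loss has not improved for
#' `patience` epochs; the best-epoch weights are restored.
#'
#' @param patience positive integer (default 15).
#' @param restoreBest logical; restore the best weights on stop.
#' @return an object of class `EarlyStopSpec`.
#' @export
earlyStopSpec <- function(patience = 15L, restoreBest = TRUE) {
  assertCount(patience, "patience")
  structure(list(patience = as.integer(patience),
                 restoreBest = isTRUE(restoreBest)),
            class = "EarlyStopSpec")
}

# Early-stopping tracker: feed one monitored loss per epoch (plus an
# arbitrary snapshot of the weights); `update` returns TRUE when training
# should halt, and `best` recovers the minimum-loss epoch and snapshot.
earlyStopTracker <- function(spec) {
  env <- new.env(parent = emptyenv())
  env$best <- Inf; env$bestEpoch <- 0L; env$snapshot <- NULL
  env$wait <- 0L; env$epoch <- 0L
  list(
    update = function(loss, snapshot = NULL) {
      env$epoch <- env$epoch + 1L
      if (loss < env$best - 1e-12) {
        env$best <- loss
        env$bestEpoch <- env$epoch
        env$snapshot <- snapshot
        env$wait <- 0L
        FALSE
      } else {
        env$wait <- env$wait + 1L
        env$wait >= spec$patience
      }
    },
    best = function() list(loss = env$best, epoch = env$bestEpoch,
                           snapshot = env$snapshot)
  )
}
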