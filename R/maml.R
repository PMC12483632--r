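# Model-agnostic meta-learning. The inner loop adapts the head parameters
# on an episode's support set by plain gradient descent; the outer loop
# differentiates the query loss at the adapted parameters with respect to
# the meta-parameters. The full (second-order) meta-gradient is
#
#   d L_q(theta_T) / d theta_0 = [ prod_t (I - alpha H_s(theta_t)) ] g_q
#
# accumulated in reverse as v <- v - alpha * H_s(theta_t) v, where each
# Hessian-vector product is evaluated by central differencing of the
# analytic support gradient (Pearlmutter-style R-operator, numerically).

#' MAML configuration
#'
#' @param innerLr inner-loop (task adaptation) learning rate, default 0.01.
#' @param innerSteps number of inner gradient steps, default 1.
#' @param metaOptimizer an [optimizerSpec()] for the outer loop (default
#'   Adam at 1e-4).
#' @param firstOrder logical; drop the second-order term (FOMAML).
#' @param shotTask a [shotTaskConfig()] with query size (default preset
#'   `maml-low`).
#' @return an object of class `MamlConfig`.
#' @export
mamlConfig <- function(innerLr = 0.01, innerSteps = 1L,
                       metaOptimizer = optimizerSpec("adam", 1e-4),
                       firstOrder = FALSE,
                       shotTask = shotTaskPreset("maml-low")) {
  assertScalarNumber(innerLr, "innerLr", 0)
  assertCount(innerSteps, "innerSteps", min = 0L)
  stopifnot(inherits(metaOptimizer, "OptimizerSpec"),
            inherits(shotTask, "ShotTaskConfig"))
  structure(list(innerLr = innerLr, innerSteps = as.integer(innerSteps),
                 metaOptimizer = metaOptimizer,
                 firstOrder = isTRUE(firstOrder), shotTask = shotTask),
            class = "MamlConfig")
}

#' Inner-loop task adaptation
#'
#' Performs `innerSteps` gradient-descent updates of step size `innerLr`
#' on the support loss, starting from `params`. The update is purely
#' functional: the input vector is never modified.
#'
#' @param params numeric parameter vector.
#' @param lossGrad function of a parameter vector returning
#'   `list(loss, grad)` for the support set.
#' @param innerLr step size.
#' @param innerSteps number of steps.
#' @return adapted parameter vector, with the support-loss trajectory in
#'   attribute `lossTrace`.
#' @export
innerAdapt <- function(params, lossGrad, innerLr, innerSteps = 1L) {
  trace <- numeric(innerSteps)
  p <- params
  for (s in seq_len(innerSteps)) {
    lg <- lossGrad(p)
    if (!is.finite(lg$loss)) {
      stop("non-finite support loss during inner adaptation (step ", s, ")",
           call. = FALSE)
    }
    trace[s] <- lg$loss
    p <- p - innerLr * lg$grad
  }
  attr(p, "lossTrace") <- trace
  p
}

# Hessian-vector product of the support loss by central differences of its
# analytic gradient.
hvp <- function(lossGrad, p, v, eps = NULL) {
  vmax <- max(abs(v))
  if (vmax == 0) return(v)
  eps <- eps %||% (1e-5 * (1 + max(abs(p))) / vmax)
  (lossGrad(p + eps * v)$grad - lossGrad(p - eps * v)$grad) / (2 * eps)
}

#' Meta-gradient over a batch of episodes
#'
#' For each episode, adapts `params` on the support loss via
#' [innerAdapt()], evaluates the query gradient at the adapted parameters,
#' and back-propagates it through the inner trajectory (unless
#' `firstOrder`). Returns the mean query loss and its gradient with
#' respect to the meta-parameters.
#'
#' @param params meta-parameter vector.
#' @param episodes list of episode objects (opaque; passed through to the
#'   loss closures).
#' @param supportLossGrad,queryLossGrad functions `(params, episode)`
#'   returning `list(loss, grad)`.
#' @param innerLr,innerSteps inner-loop hyperparameters.
#' @param firstOrder logical; skip the curvature term.
#' @return list with `grad` (mean meta-gradient) and `loss` (mean query
#'   loss at adapted parameters).
#' @export
metaGradient <- function(params, episodes, supportLossGrad, queryLossGrad,
                         innerLr, innerSteps = 1L, firstOrder = FALSE) {
  acc <- numeric(length(params))
  lossSum <- 0
  for (e in seq_along(episodes)) {
    ep <- episodes[[e]]
    sg <- function(p) supportLossGrad(p, ep)
    thetas <- vector("list", innerSteps + 1L)
    thetas[[1L]] <- params
    p <- params
    for (s in seq_len(innerSteps)) {
      lg <- sg(p)
      if (!is.finite(lg$loss)) {
        stop("non-finite support loss in episode ", e, call. = FALSE)
      }
      p <- p - innerLr * lg$grad
      thetas[[s + 1L]] <- p
    }
    qg <- queryLossGrad(p, ep)
    if (!is.finite(qg$loss)) {
      stop("non-finite query loss in episode ", e, call. = FALSE)
    }
    v <- qg$grad
    if (!firstOrder && innerSteps > 0L && innerLr > 0) {
      for (s in rev(seq_len(innerSteps))) {
        v <- v - innerLr * hvp(sg, thetas[[s]], v)
      }
    }
    acc <- acc + v
    lossSum <- lossSum + qg$loss
  }
  list(grad = acc / length(episodes), loss = lossSum / length(episodes))
}

#' One outer-loop meta-update
#'
#' Computes the meta-gradient of the mean query loss over a batch of
#' episodes and applies one step of the meta-optimizer.
#'
#' @param params meta-parameter vector.
#' @param episodes list of episodes.
#' @param config a [mamlConfig()].
#' @param supportLossGrad,queryLossGrad loss closures as in
#'   [metaGradient()].
#' @param optState meta-optimizer state (from [optimizerInit]); created on
#'   first use when `NULL`.
#' @param lr scheduled meta learning rate (defaults to the spec's base
#'   rate).
#' @return list with updated `params`, `optState`, the mean query
#'   `metaLoss` and the `metaGrad` vector.
#' @export
metaStep <- function(params, episodes, config, supportLossGrad,
                     queryLossGrad, optState = NULL, lr = NULL) {
  stopifnot(inherits(config, "MamlConfig"))
  mg <- metaGradient(params, episodes, supportLossGrad, queryLossGrad,
                     config$innerLr, config$innerSteps, config$firstOrder)
  optState <- optState %||% optimizerInit(config$metaOptimizer, length(params))
  lr <- lr %||% config$metaOptimizer$learningRate
  st <- optimizerStep(config$metaOptimizer, optState, params, mg$grad, lr)
  list(params = st$params, optState = st$state, metaLoss = mg$loss,
       metaGrad = mg$grad)
}

#' Train a classifier under the MAML regime
#'
#' Each epoch samples `nTasks` support/query episodes from the training
#' bank and processes them in meta-batches through [metaStep()]; only the
#' head parameters are meta-learned, the backbone stays frozen, and batch
#' normalization uses current-batch statistics inside all loops (the
#' transductive convention). Validation is episodic: adapt on a sampled
#' validation support set, then score its query set; early stopping
#' monitors that loss.
#'
#' @param model an untrained [MarkClassifier-class].
#' @param trainBank,valBank [ImageBank-class] splits.
#' @param config a [mamlConfig()].
#' @param earlyStop an [earlyStopSpec()].
#' @param lrSchedule a [lrScheduleSpec()] applied to the meta rate.
#' @param geomAug,hsvAug augmentation configs (training episodes only).
#' @param augment logical.
#' @param maxEpochs maximum epochs.
#' @param metaBatch episodes per meta-update (default 4).
#' @param valEpisodes validation episodes per epoch (default 4).
#' @param seed integer seed.
#' @param verbose print one line per epoch.
#' @return list with the trained `model` and `history` data.frame.
#' @export
trainMAML <- function(model, trainBank, valBank, config = mamlConfig(),
                      earlyStop = earlyStopSpec(),
                      lrSchedule = lrScheduleSpec(),
                      geomAug = geometricAugConfig(),
                      hsvAug = hsvAugConfig(),
                      augment = TRUE, maxEpochs = 100L, metaBatch = 4L,
                      valEpisodes = 4L, seed = 1, verbose = FALSE) {
  stopifnot(is(model, "MarkClassifier"), is(trainBank, "ImageBank"),
            is(valBank, "ImageBank"), inherits(config, "MamlConfig"))
  if (length(trainBank) == 0L) stop("empty training bank", call. = FALSE)
  withr::with_seed(deriveSeed(seed, "train-maml"), {
    getImages <- makeImageCache()
    params <- nnParamVec(model@headParams)
    optState <- optimizerInit(config$metaOptimizer, length(params))
    template <- model@headParams
    net <- model@head$net
    net$state <- model@headState
    lossGradOn <- function(p, prep) {
      lg <- nnLossGrad(net, nnVecToParams(template, p), prep$feats,
                       prep$labels, ctx = list(train = FALSE, bnMode = "batch"))
      list(loss = lg$loss, grad = lg$grads)
    }
    supportLossGrad <- function(p, ep) lossGradOn(p, ep$supPrep)
    queryLossGrad <- function(p, ep) lossGradOn(p, ep$qryPrep)
    prepEpisode <- function(bank, doAug) {
      ep <- sampleEpisode(bank, config$shotTask)
      list(supPrep = batchFeatures(model, getImages, ep$support, doAug,
                                   geomAug, hsvAug),
           qryPrep = batchFeatures(model, getImages, ep$query, doAug,
                                   geomAug, hsvAug))
    }
    history <- list()
    stopper <- earlyStopTracker(earlyStop)
    for (epoch in seq_len(maxEpochs)) {
      lr <- scheduledLr(lrSchedule, config$metaOptimizer$learningRate, epoch)
      nTasks <- config$shotTask$nTasks
      losses <- numeric(0)
      done <- 0L
      while (done < nTasks) {
        m <- min(metaBatch, nTasks - done)
        episodes <- lapply(seq_len(m), function(i) prepEpisode(trainBank, augment))
        st <- metaStep(params, episodes, config, supportLossGrad,
                       queryLossGrad, optState, lr)
        params <- st$params
        optState <- st$optState
        losses <- c(losses, st$metaLoss)
        done <- done + m
      }
      # episodic validation: adapt on support, score query
      vl <- va <- numeric(valEpisodes)
      for (vRun in seq_len(valEpisodes)) {
        vep <- prepEpisode(valBank, FALSE)
        adapted <- innerAdapt(params, function(p) supportLossGrad(p, vep),
                              config$innerLr, config$innerSteps)
        ev <- headEvalLoss(model, nnVecToParams(template, adapted),
                           model@headState, vep$qryPrep$feats,
                           vep$qryPrep$labels, "batch")
        vl[vRun] <- ev$loss
        va[vRun] <- ev$acc
      }
      history[[epoch]] <- data.frame(epoch = epoch,
                                     trainLoss = mean(losses),
                                     trainAcc = NA_real_,
                                     valLoss = mean(vl), valAcc = mean(va),
                                     lr = lr)
      if (verbose) {
        message(sprintf("epoch %3d | meta loss %.4f | val %.4f acc %.3f | lr %g",
                        epoch, mean(losses), mean(vl), mean(va), lr))
      }
      if (stopper$update(mean(vl), params)) break
    }
    best <- stopper$best()
    if (earlyStop$restoreBest && best$epoch > 0L) params <- best$snapshot
    model@headParams <- nnVecToParams(template, params)
    # calibrate batch-norm running statistics on the (unaugmented)
    # training set so that small-batch and single-image evaluation --
    # where batch statistics are unavailable -- is well defined
    calib <- batchFeatures(model, getImages, bankRecords(trainBank),
                           FALSE, NULL, NULL)
    fw <- nnForward(net, model@headParams, calib$feats,
                    ctx = list(train = FALSE, bnMode = "batch",
                               captureBn = TRUE))
    model@headState <- fw$state
    model@info$regime <- "maml"
    model@info$bnEval <- "batch"
    model@info$innerLr <- config$innerLr
    model@info$innerSteps <- config$innerSteps
    hist <- do.call(rbind, history)
    attr(hist, "bestEpoch") <- best$epoch
    list(model = model, history = hist)
  })
}
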