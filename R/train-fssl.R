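# Supervised few-shot training (FSSL): ordinary supervised transfer
# learning over class-balanced n-way k-shot mini-batches drawn from a
# frozen backbone's feature space.

# In-memory image cache keyed by mark_id: decoded RGB arrays.
makeImageCache <- function() {
  env <- new.env(parent = emptyenv())
  function(rec) {
    out <- vector("list", nrow(rec))
    for (i in seq_len(nrow(rec))) {
      id <- rec$mark_id[i]
      if (is.null(env[[id]])) env[[id]] <- loadImage(rec$path[i])
      out[[i]] <- env[[id]]
    }
    out
  }
}

# Augment (optionally), preprocess and extract frozen features for a
# record batch. Labels are 1-based indices into taxonLevels().
batchFeatures <- function(model, getImages, rec, augment, geomAug, hsvAug) {
  imgs <- getImages(rec)
  if (augment) {
    imgs <- lapply(imgs, function(im) {
      im <- augmentGeometric(im, geomAug)
      augmentHSV(im, hsvAug)
    })
  }
  x <- preprocessBatch(model, imgs)
  list(feats = backboneForward(model@backbone, x),
       labels = as.integer(taxonFactor(rec$taxon)))
}

# Evaluation-mode loss/accuracy of a head over precomputed features.
headEvalLoss <- function(model, params, state, feats, labels, bnMode) {
  net <- model@head$net
  net$state <- state
  out <- nnForward(net, params, feats,
                   ctx = list(train = FALSE, bnMode = bnMode))$out
  ce <- softmaxCrossEntropy(out, labels)
  list(loss = ce$loss, acc = mean(max.col(ce$probs) == labels),
       probs = ce$probs)
}

#' Train a classifier under the supervised few-shot regime
#'
#' Each epoch consumes `nTasks` class-balanced k-shot batches (online
#' geometric + HSV augmentation on training images only), minimising
#' cross-entropy over the head while the backbone stays frozen. Validation
#' loss is monitored for early stopping with best-weight restoration, and
#' the learning rate follows the step-decay schedule.
#'
#' @param model an untrained [MarkClassifier-class].
#' @param trainBank,valBank [ImageBank-class] splits.
#' @param shotTask a [shotTaskConfig()] (default preset `fssl-low`).
#' @param optimizer an [optimizerSpec()].
#' @param earlyStop an [earlyStopSpec()].
#' @param lrSchedule a [lrScheduleSpec()].
#' @param geomAug,hsvAug augmentation configs.
#' @param augment logical; apply augmentation to training batches.
#' @param maxEpochs maximum number of epochs (default 100).
#' @param seed integer seed driving sampling, dropout and augmentation.
#' @param verbose print one line per epoch.
#' @return list with the trained `model` and a `history` data.frame
#'   (epoch, trainLoss, trainAcc, valLoss, valAcc, lr) carrying the best
#'   epoch index as attribute `bestEpoch`.
#' @export
trainFSSL <- function(model, trainBank, valBank,
                      shotTask = shotTaskPreset("fssl-low"),
                      optimizer = optimizerSpec("adam", 1e-3),
                      earlyStop = earlyStopSpec(),
                      lrSchedule = lrScheduleSpec(),
                      geomAug = geometricAugConfig(),
                      hsvAug = hsvAugConfig(),
                      augment = TRUE, maxEpochs = 100L, seed = 1,
                      verbose = FALSE) {
  stopifnot(is(model, "MarkClassifier"), is(trainBank, "ImageBank"),
            is(valBank, "ImageBank"))
  if (length(trainBank) == 0L) stop("empty training bank", call. = FALSE)
  withr::with_seed(deriveSeed(seed, "train-fssl"), {
    getImages <- makeImageCache()
    net <- model@head$net
    params <- nnParamVec(model@headParams)
    state <- model@headState
    optState <- optimizerInit(optimizer, length(params))
    valPrep <- batchFeatures(model, getImages, bankRecords(valBank),
                             augment = FALSE, geomAug, hsvAug)
    history <- list()
    stopper <- earlyStopTracker(earlyStop)
    for (epoch in seq_len(maxEpochs)) {
      lr <- scheduledLr(lrSchedule, optimizer$learningRate, epoch)
      batches <- sampleFewShotEpoch(trainBank, shotTask)
      tl <- ta <- numeric(length(batches))
      for (b in seq_along(batches)) {
        bf <- batchFeatures(model, getImages, batches[[b]], augment,
                            geomAug, hsvAug)
        net$state <- state
        lg <- nnLossGrad(net, nnVecToParams(model@headParams, params),
                         bf$feats, bf$labels,
                         ctx = list(train = TRUE, bnMode = "running"))
        state <- lg$state
        st <- optimizerStep(optimizer, optState, params, lg$grads, lr)
        params <- st$params
        optState <- st$state
        tl[b] <- lg$loss
        ta[b] <- mean(max.col(lg$probs) == bf$labels)
      }
      ev <- headEvalLoss(model, nnVecToParams(model@headParams, params),
                         state, valPrep$feats, valPrep$labels, "running")
      history[[epoch]] <- data.frame(epoch = epoch, trainLoss = mean(tl),
                                     trainAcc = mean(ta), valLoss = ev$loss,
                                     valAcc = ev$acc, lr = lr)
      if (verbose) {
        message(sprintf("epoch %3d | loss %.4f acc %.3f | val %.4f acc %.3f | lr %g",
                        epoch, mean(tl), mean(ta), ev$loss, ev$acc, lr))
      }
      if (stopper$update(ev$loss, list(params = params, state = state))) break
    }
    best <- stopper$best()
    if (earlyStop$restoreBest && best$epoch > 0L) {
      params <- best$snapshot$params
      state <- best$snapshot$state
    }
    model@headParams <- nnVecToParams(model@headParams, params)
    model@headState <- state
    model@info$regime <- "fssl"
    model@info$bnEval <- "running"
    hist <- do.call(rbind, history)
    attr(hist, "bestEpoch") <- best$epoch
    list(model = model, history = hist)
  })
}

#' Evaluate a classifier on a bank
#'
#' Scores every record of `bank`, optionally after a task-specific
#' inner-loop adaptation on a support set (the deployment mode of the
#' meta-learned models). Returns the confusion matrix and the full
#' per-class precision/recall/F1 report.
#'
#' @param model a [MarkClassifier-class].
#' @param bank an [ImageBank-class] to score.
#' @param adaptBank optional [ImageBank-class]; when supplied together with
#'   `shotTask`, a support set is sampled from it and the head is adapted
#'   by `innerSteps` gradient steps of size `innerLr` before scoring.
#' @param shotTask [shotTaskConfig()] used to sample the adaptation support.
#' @param innerLr,innerSteps adaptation hyperparameters (defaults from the
#'   model's training record when available).
#' @param seed integer seed for support sampling.
#' @return list with `report` ([ClassificationReport-class]), `confusion`,
#'   `accuracy`, `loss` and the probability matrix `probs`.
#' @export
evaluateModel <- function(model, bank, adaptBank = NULL, shotTask = NULL,
                          innerLr = NULL, innerSteps = NULL, seed = 1) {
  stopifnot(is(model, "MarkClassifier"), is(bank, "ImageBank"))
  getImages <- makeImageCache()
  prep <- batchFeatures(model, getImages, bankRecords(bank), FALSE,
                        NULL, NULL)
  params <- nnParamVec(model@headParams)
  if (!is.null(adaptBank)) {
    shotTask <- shotTask %||% shotTaskPreset("maml-low")
    innerLr <- innerLr %||% model@info$innerLr %||% 0.01
    innerSteps <- innerSteps %||% model@info$innerSteps %||% 1L
    ep <- sampleEpisode(adaptBank, shotTask,
                        seed = deriveSeed(seed, "eval-adapt"))
    sup <- batchFeatures(model, getImages, ep$support, FALSE, NULL, NULL)
    lossGrad <- function(p) {
      lg <- nnLossGrad(model@head$net,
                       nnVecToParams(model@headParams, p),
                       sup$feats, sup$labels,
                       ctx = list(train = FALSE, bnMode = "batch"))
      list(loss = lg$loss, grad = lg$grads)
    }
    params <- innerAdapt(params, lossGrad, innerLr, innerSteps)
  }
  ev <- headEvalLoss(model, nnVecToParams(model@headParams, params),
                     model@headState, prep$feats, prep$labels,
                     model@info$bnEval)
  predIdx <- max.col(ev$probs)
  truth <- taxonLevels()[prep$labels]
  pred <- taxonLevels()[predIdx]
  cm <- confusionMatrix(truth, pred)
  list(report = classificationReport(cm), confusion = cm,
       accuracy = mean(predIdx == prep$labels), loss = ev$loss,
       probs = ev$probs)
}
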