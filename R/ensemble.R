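# Accuracy-weighted soft-voting ensembles per regime, and the dual-method
# reliability verdict for archaeological marks.

#' Compute accuracy-proportional ensemble weights
#'
#' Member weights proportional to each model's held-out test accuracy:
#' `w_i = acc_i / sum(acc)`. Scale-invariant (percentages and fractions
#' give the same weights) and order-preserving.
#'
#' @param accuracies positive numeric vector.
#' @return numeric weights summing to 1.
#' @export
computeWeights <- function(accuracies) {
  if (length(accuracies) == 0L) stop("no accuracies supplied", call. = FALSE)
  if (!is.numeric(accuracies) || any(!is.finite(accuracies)) ||
      any(accuracies <= 0)) {
    stop("accuracies must be positive finite numbers", call. = FALSE)
  }
  accuracies / sum(accuracies)
}

#' A member model of a weighted ensemble
#'
#' @param modelId short identifier (e.g. the backbone name).
#' @param regime `"fssl"` or `"maml"`.
#' @param testAccuracy held-out test accuracy in (0, 1] (or percent; only
#'   proportions matter for the weights).
#' @param predictor function mapping one RGB image to a probability vector
#'   over [taxonLevels()].
#' @return an object of class `MemberModel`.
#' @export
memberModel <- function(modelId, regime = c("fssl", "maml"), testAccuracy,
                        predictor) {
  regime <- match.arg(regime)
  assertScalarNumber(testAccuracy, "testAccuracy", 1e-12)
  stopifnot(is.function(predictor))
  structure(list(modelId = as.character(modelId), regime = regime,
                 testAccuracy = testAccuracy, predictor = predictor),
            class = "MemberModel")
}

#' Wrap a trained classifier as an ensemble member
#'
#' @param model a [MarkClassifier-class].
#' @param modelId identifier; defaults to the backbone name.
#' @param regime member regime; defaults to the model's training regime.
#' @param testAccuracy held-out test accuracy recorded for the weight.
#' @return a [memberModel()].
#' @export
asMemberModel <- function(model, testAccuracy, modelId = NULL,
                          regime = NULL) {
  stopifnot(is(model, "MarkClassifier"))
  memberModel(modelId %||% model@backbone$name,
              regime %||% model@info$regime, testAccuracy,
              predictor = function(img) drop(predictProbs(model, img)))
}

#' WeightedEnsemble: accuracy-weighted soft voting
#'
#' @slot members list of [memberModel()] objects (one regime).
#' @slot weights numeric; accuracy-proportional, summing to 1.
#' @slot regime character.
#' @aliases WeightedEnsemble
#' @export
setClass("WeightedEnsemble",
         representation(members = "list", weights = "numeric",
                        regime = "character"))

setValidity("WeightedEnsemble", function(object) {
  if (length(object@members) < 1L) return("at least one member required")
  if (abs(sum(object@weights) - 1) > 1e-9) return("weights must sum to 1")
  if (any(object@weights < 0)) return("weights must be nonnegative")
  regimes <- vapply(object@members, `[[`, "", "regime")
  if (length(unique(regimes)) != 1L) return("members must share one regime")
  TRUE
})

#' Build a weighted ensemble from member models
#'
#' @param members list of [memberModel()] objects of one regime.
#' @return a [WeightedEnsemble-class] with weights from [computeWeights()].
#' @export
weightedEnsemble <- function(members) {
  if (inherits(members, "MemberModel")) members <- list(members)
  acc <- vapply(members, `[[`, 0, "testAccuracy")
  new("WeightedEnsemble", members = members,
      weights = unname(computeWeights(acc)),
      regime = members[[1L]]$regime)
}

setMethod("show", "WeightedEnsemble", function(object) {
  cat(sprintf("WeightedEnsemble (%s) with %d member(s):\n", object@regime,
              length(object@members)))
  for (i in seq_along(object@members)) {
    cat(sprintf("  %-16s acc %.4g  weight %.4f\n",
                object@members[[i]]$modelId,
                object@members[[i]]$testAccuracy, object@weights[i]))
  }
})

#' Ensemble prediction for one image
#'
#' Weighted soft vote: the accuracy-weighted sum of member probability
#' vectors (each member applies its own preprocessing), renormalized to
#' sum to 1.
#'
#' @param ensemble a [WeightedEnsemble-class].
#' @param img RGB array.
#' @return named probability vector over [taxonLevels()].
#' @export
ensemblePredict <- function(ensemble, img) {
  stopifnot(is(ensemble, "WeightedEnsemble"))
  out <- numeric(4L)
  for (i in seq_along(ensemble@members)) {
    mem <- ensemble@members[[i]]
    p <- tryCatch(mem$predictor(img), error = function(e) {
      stop("member '", mem$modelId, "' failed to predict: ",
           conditionMessage(e), call. = FALSE)
    })
    if (length(p) != 4L || any(p < -1e-9) || abs(sum(p) - 1) > 1e-6) {
      stop("member '", mem$modelId, "' returned an invalid probability vector",
           call. = FALSE)
    }
    out <- out + ensemble@weights[i] * p
  }
  setNames(out / sum(out), taxonLevels())
}

#' ReliabilityVerdict: the dual-method agreement rule
#'
#' A mark's attribution is `reliable` only when the FSSL and MAML
#' ensembles select the same taxon and both do so with probability
#' strictly greater than the threshold (0.70); otherwise
#' `caution` ("interpretation with caution"). The best taxon (the FSSL
#' ensemble argmax) is reported either way.
#'
#' @slot bestTaxon character.
#' @slot fsslProb,mamlProb numeric argmax probabilities.
#' @slot status `"reliable"` or `"caution"`.
#' @aliases ReliabilityVerdict
#' @export
setClass("ReliabilityVerdict",
         representation(bestTaxon = "character", fsslProb = "numeric",
                        mamlProb = "numeric", status = "character"))

setMethod("show", "ReliabilityVerdict", function(object) {
  cat(sprintf("%s (%s: FSSL %.2f, MAML %.2f)\n", object@bestTaxon,
              object@status, object@fsslProb, object@mamlProb))
})

assertProbVector <- function(p, name) {
  if (length(p) != 4L || any(!is.finite(p)) || any(p < -1e-9) ||
      abs(sum(p) - 1) > 1e-6) {
    stop("'", name, "' must be 4 nonnegative probabilities summing to 1",
         call. = FALSE)
  }
  invisible(p)
}

#' Dual-ensemble reliability verdict for one mark
#'
#' @param fsslProbs,mamlProbs probability vectors over [taxonLevels()]
#'   from the two regime ensembles.
#' @param threshold probability threshold (default 0.70, strict).
#' @return a [ReliabilityVerdict-class].
#' @export
dualVerdict <- function(fsslProbs, mamlProbs, threshold = 0.70) {
  assertProbVector(fsslProbs, "fsslProbs")
  assertProbVector(mamlProbs, "mamlProbs")
  fi <- which.max(fsslProbs)
  mi <- which.max(mamlProbs)
  agree <- fi == mi
  status <- if (agree && fsslProbs[fi] > threshold &&
                mamlProbs[mi] > threshold) "reliable" else "caution"
  new("ReliabilityVerdict", bestTaxon = taxonLevels()[fi],
      fsslProb = unname(fsslProbs[fi]), mamlProb = unname(mamlProbs[mi]),
      status = status)
}

#' Classify a set of marks through both regime ensembles
#'
#' Runs every mark image through the FSSL and MAML ensembles, derives the
#' dual verdict, and returns a long table (one row per mark and regime)
#' matching the published layout: probabilities in taxon column order,
#' the argmax taxon, and the verdict. Unreadable images yield an error row
#' and processing continues.
#'
#' @param marks named list of RGB arrays, or a character vector of image
#'   paths (names taken as mark ids; basenames otherwise).
#' @param fsslEnsemble,mamlEnsemble [WeightedEnsemble-class] objects.
#' @param threshold verdict threshold.
#' @return data.frame with columns `mark_id`, `regime`, the four taxa,
#'   `argmax`, `verdict`, `error`.
#' @export
classifyMarks <- function(marks, fsslEnsemble, mamlEnsemble,
                          threshold = 0.70) {
  ids <- names(marks)
  if (is.character(marks)) {
    if (is.null(ids)) ids <- tools::file_path_sans_ext(basename(marks))
    marks <- as.list(marks)
    names(marks) <- ids
  } else if (is.null(ids)) {
    ids <- sprintf("mark_%02d", seq_along(marks))
    names(marks) <- ids
  }
  emptyCols <- c("mark_id", "regime", taxonLevels(), "argmax", "verdict",
                 "error")
  if (length(marks) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(emptyCols)),
                                  emptyCols))
    return(out)
  }
  rows <- list()
  for (id in ids) {
    res <- tryCatch({
      img <- marks[[id]]
      if (is.character(img)) img <- loadImage(img)
      pf <- ensemblePredict(fsslEnsemble, img)
      pm <- ensemblePredict(mamlEnsemble, img)
      v <- dualVerdict(pf, pm, threshold)
      list(pf = pf, pm = pm, v = v, err = NA_character_)
    }, error = function(e) list(pf = rep(NA_real_, 4), pm = rep(NA_real_, 4),
                                v = NULL, err = conditionMessage(e)))
    mk <- function(regime, p) {
      df <- data.frame(mark_id = id, regime = regime, stringsAsFactors = FALSE)
      for (k in seq_along(taxonLevels())) df[[taxonLevels()[k]]] <- unname(p[k])
      df$argmax <- if (is.null(res$v)) NA_character_ else
        taxonLevels()[which.max(p)]
      df$verdict <- if (is.null(res$v)) NA_character_ else res$v@status
      df$error <- res$err
      df
    }
    rows[[paste0(id, ".fssl")]] <- mk("fssl", res$pf)
    rows[[paste0(id, ".maml")]] <- mk("maml", res$pm)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a mark-classification table as TSV
#' @param table result of [classifyMarks()].
#' @param file output path.
#' @export
writeMarksTable <- function(table, file) {
  utils::write.table(table, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
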