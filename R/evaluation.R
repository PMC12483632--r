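#' ConfusionMatrix: counts of true vs predicted taxa
#'
#' 4x4 nonnegative integer counts; rows are the true taxon, columns the
#' predicted taxon, both in [taxonLevels()] order.
#'
#' @slot counts integer matrix.
#' @aliases ConfusionMatrix
#' @export
setClass("ConfusionMatrix", representation(counts = "matrix"))

setValidity("ConfusionMatrix", function(object) {
  m <- object@counts
  if (!all(dim(m) == c(4L, 4L))) return("counts must be 4x4")
  if (!identical(rownames(m), taxonLevels()) ||
      !identical(colnames(m), taxonLevels())) {
    return("axes must be labelled with taxonLevels() in order")
  }
  if (any(m < 0) || any(m != round(m))) return("counts must be nonnegative integers")
  TRUE
})

#' Build a confusion matrix from label vectors
#'
#' @param truth,predicted equal-length character vectors of taxon labels.
#' @return a [ConfusionMatrix-class].
#' @export
confusionMatrix <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  m <- table(taxonFactor(truth), taxonFactor(predicted))
  m <- matrix(as.integer(m), 4L, 4L,
              dimnames = list(taxonLevels(), taxonLevels()))
  new("ConfusionMatrix", counts = m)
}

#' @describeIn ConfusionMatrix-class the raw count matrix
#' @param x a `ConfusionMatrix`.
#' @export
confusionCounts <- function(x) x@counts

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (rows = true, cols = predicted)\n")
  print(object@counts)
})

#' ClassificationReport: per-class and aggregate metrics
#'
#' Per-class precision, recall, F1 and support, plus accuracy,
#' macro-averages (unweighted class means) and weighted averages
#' (support-weighted means). All values are stored unrounded; rounding to
#' two decimals happens only at rendering.
#'
#' @slot perClass data.frame with columns taxon, precision, recall, f1,
#'   support.
#' @slot accuracy numeric.
#' @slot macro,weighted named numeric (precision, recall, f1).
#' @slot totalSupport integer.
#' @aliases ClassificationReport
#' @export
setClass("ClassificationReport",
         representation(perClass = "data.frame", accuracy = "numeric",
                        macro = "numeric", weighted = "numeric",
                        totalSupport = "integer"))

setMethod("show", "ClassificationReport", function(object) {
  cat(renderReport(object, "text"), sep = "\n")
})

# F1 with the zero-denominator convention (0 when precision + recall = 0).
f1Score <- function(p, r) ifelse(p + r > 0, 2 * p * r / (p + r), 0)

buildReport <- function(taxa, precision, recall, f1, support, accuracy) {
  w <- support / sum(support)
  new("ClassificationReport",
      perClass = data.frame(taxon = taxa, precision = precision,
                            recall = recall, f1 = f1, support = support,
                            stringsAsFactors = FALSE),
      accuracy = accuracy,
      macro = c(precision = mean(precision), recall = mean(recall),
                f1 = mean(f1)),
      weighted = c(precision = sum(w * precision), recall = sum(w * recall),
                   f1 = sum(w * f1)),
      totalSupport = as.integer(sum(support)))
}

#' Classification report from a confusion matrix
#'
#' Per-class precision and recall use the zero-division convention
#' (metric = 0 when its denominator is 0); accuracy is
#' trace(counts) / total, identically the support-weighted mean recall.
#'
#' @param x a [ConfusionMatrix-class].
#' @return a [ClassificationReport-class].
#' @export
classificationReport <- function(x) {
  stopifnot(is(x, "ConfusionMatrix"))
  m <- x@counts
  total <- sum(m)
  if (total == 0L) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(m)
  support <- rowSums(m)
  predPos <- colSums(m)
  precision <- ifelse(predPos > 0, tp / predPos, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  buildReport(taxonLevels(), unname(precision), unname(recall),
              unname(f1Score(precision, recall)), unname(support),
              accuracy = sum(tp) / total)
}

#' Classification report from printed per-class metrics
#'
#' Reconstructs the full report from per-class precision, recall and
#' support (as printed in published metric tables): F1 from the
#' precision/recall harmonic mean, accuracy from the identity
#' accuracy = support-weighted mean recall, and macro/weighted rows from
#' the (unrounded) per-class values.
#'
#' @param precision,recall numeric vectors in [taxonLevels()] order.
#' @param support integer vector of per-class test counts.
#' @return a [ClassificationReport-class].
#' @export
reportFromMetrics <- function(precision, recall, support) {
  stopifnot(length(precision) == 4L, length(recall) == 4L,
            length(support) == 4L, all(support > 0),
            all(precision >= 0 & precision <= 1),
            all(recall >= 0 & recall <= 1))
  buildReport(taxonLevels(), precision, recall, f1Score(precision, recall),
              support, accuracy = sum(support * recall) / sum(support))
}

#' Render a classification report
#'
#' Mirrors the published table layout: one row per class, then `accuracy`,
#' `macro-average` and `weighted average` rows. Numbers are rendered at
#' two decimals (half-up, trailing zeros preserved).
#'
#' @param report a [ClassificationReport-class].
#' @param format `"text"`, `"tsv"` or `"json"`.
#' @return character vector of lines (`text`, `tsv`) or a JSON string.
#' @export
renderReport <- function(report, format = c("text", "tsv", "json")) {
  stopifnot(is(report, "ClassificationReport"))
  format <- match.arg(format)
  fmt <- function(x) sprintf("%.2f", roundHalfUp(x, 2))
  pc <- report@perClass
  if (format == "json") {
    return(jsonlite::toJSON(list(
      per_class = pc,
      accuracy = report@accuracy,
      macro = as.list(report@macro),
      weighted = as.list(report@weighted),
      total_support = report@totalSupport), auto_unbox = TRUE, digits = NA))
  }
  rows <- list(c("", "precision", "recall", "F1 score", "support"))
  for (i in seq_len(nrow(pc))) {
    rows[[length(rows) + 1L]] <- c(pc$taxon[i], fmt(pc$precision[i]),
                                   fmt(pc$recall[i]), fmt(pc$f1[i]),
                                   as.character(pc$support[i]))
  }
  rows[[length(rows) + 1L]] <- c("accuracy", "", "", fmt(report@accuracy),
                                 as.character(report@totalSupport))
  rows[[length(rows) + 1L]] <- c("macro-average", fmt(report@macro["precision"]),
                                 fmt(report@macro["recall"]),
                                 fmt(report@macro["f1"]),
                                 as.character(report@totalSupport))
  rows[[length(rows) + 1L]] <- c("weighted average",
                                 fmt(report@weighted["precision"]),
                                 fmt(report@weighted["recall"]),
                                 fmt(report@weighted["f1"]),
                                 as.character(report@totalSupport))
  if (format == "tsv") {
    return(vapply(rows, paste, "", collapse = "\t"))
  }
  widths <- apply(matrix(unlist(rows), ncol = 5L, byrow = TRUE), 2,
                  function(cl) max(nchar(cl)))
  vapply(rows, function(r) {
    paste(mapply(formatC, r, width = widths,
                 flag = c("-", rep("", 4))), collapse = "  ")
  }, "")
}

#' Write a confusion matrix to CSV
#' @param x a [ConfusionMatrix-class].
#' @param file output path.
#' @export
writeConfusion <- function(x, file) {
  write.csv(x@counts, file)
  invisible(file)
}
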