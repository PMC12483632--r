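#' Build a feature-extraction backbone
#'
#' The classification heads sit on the last convolutional feature map of a
#' frozen, pre-trained backbone. Five named architectures (resnet50,
#' resnet152, densenet201, xception, efficientnetv2l) are recognised but
#' require their pre-trained weights, which are not shipped; requesting one
#' raises an error suggesting the stand-in. The `standin` backbone is a
#' small fixed random convolutional stack (three conv/ReLU/max-pool stages,
#' channels 16/32/64, about 24k parameters) usable on CPU: it is frozen at
#' construction and deterministic given its seed.
#'
#' @param name backbone name.
#' @param inputSide input side in pixels (stand-in only; default 64).
#' @param seed integer seed fixing the stand-in weights.
#' @return an object of class `carniBackbone` with the feature-map shape in
#'   `$featureShape`.
#' @export
buildBackbone <- function(name = "standin", inputSide = NULL, seed = 1) {
  name <- match.arg(name, names(.backboneTable))
  if (name != "standin") {
    stop("pre-trained weights for backbone '", name, "' are not available ",
         "in this installation; use the 'standin' backbone", call. = FALSE)
  }
  spec <- backboneInputSpec(name, side = inputSide)
  side <- spec$side
  if (side %% 8L != 0L) stop("stand-in input side must be divisible by 8")
  # pooling precedes the (monotone) ReLU so the activation runs on the
  # quarter-size map; the composition is identical
  layers <- list(nnConv("c1", 16L), nnPool("p1"), nnRelu("r1"),
                 nnConv("c2", 32L), nnPool("p2"), nnRelu("r2"),
                 nnConv("c3", 64L), nnPool("p3"), nnRelu("r3"))
  net <- nnBuild(layers, c(side, side, 3L), seed = deriveSeed(seed, "backbone"))
  structure(list(name = name, inputSpec = spec, net = net,
                 params = net$params, featureShape = net$outShape,
                 frozen = TRUE),
            class = "carniBackbone")
}

# Forward a preprocessed (side, side, 3, n) tensor through a frozen
# backbone; deterministic (no dropout, no batch-norm in the stand-in).
backboneForward <- function(backbone, x) {
  nnForward(backbone$net, backbone$params, x,
            ctx = list(train = FALSE, bnMode = "running"))$out
}

#' Squeeze-and-excitation channel recalibration
#'
#' Gates each channel of a feature map by a sigmoid weight computed from
#' its globally pooled statistics: `out = x * sigmoid(W2 relu(W1 gap(x)))`.
#' Gate weights can be supplied explicitly; otherwise they are drawn from
#' the standard initialisation under `seed`.
#'
#' @param features (h, w, c) or (h, w, c, n) feature array.
#' @param reduction positive integer bottleneck ratio (bottleneck width is
#'   `max(1, c / reduction)`).
#' @param params optional list with `W1`, `b1`, `W2`, `b2`.
#' @param seed seed for random gate weights when `params` is `NULL`.
#' @return recalibrated array of the same shape, with the gate matrix in
#'   attribute `gates`.
#' @export
seRecalibrate <- function(features, reduction = 16, params = NULL, seed = 1) {
  d <- dim(features)
  squeeze <- length(d) == 3L
  # user-facing layout is (h, w, c[, n]); the engine uses (h, w, n, c)
  x <- if (squeeze) {
    aperm(array(features, c(d, 1L)), c(1, 2, 4, 3))
  } else {
    aperm(features, c(1, 2, 4, 3))
  }
  cc <- dim(x)[4]
  cr <- max(1L, cc %/% as.integer(reduction))
  if (is.null(params)) {
    params <- withr::with_seed(as.integer(seed), list(
      W1 = heMatrix(cc, cr), b1 = numeric(cr),
      W2 = heMatrix(cr, cc), b2 = numeric(cc)))
  }
  fw <- seForward(x, params$W1, params$b1, params$W2, params$b2)
  out <- aperm(fw$y, c(1, 2, 4, 3))
  if (squeeze) {
    dim(out) <- d
  }
  attr(out, "gates") <- fw$g
  out
}

#' Build a classification head
#'
#' Two variants over a backbone feature map:
#' \describe{
#'   \item{complex}{two residual blocks of depthwise-separable convolutions
#'     (kernel 3, stride 1, same padding) with squeeze-and-excitation
#'     attention, then global average pooling, a 512-unit ReLU dense layer,
#'     dropout, batch normalization and a softmax output over the four
#'     taxa. The residual shortcut is the identity when channel counts
#'     match, a 1x1 convolution otherwise.}
#'   \item{baseline}{a single standard convolutional layer with 512
#'     filters, global average pooling, a 512-unit dense layer, dropout
#'     plus batch normalization, and the softmax output.}
#' }
#'
#' @param featureShape integer c(h, w, c) of the backbone feature map.
#' @param variant `"complex"` or `"baseline"`.
#' @param nClasses number of output classes (4).
#' @param dropout dropout probability (default 0.5, from the tested range
#'   0.3-0.8).
#' @param seReduction squeeze-and-excitation bottleneck ratio (default 16).
#' @param denseWidth width of the dense layer (512).
#' @param seed integer seed for weight initialisation.
#' @return an object of class `carniHead` wrapping the network.
#' @export
buildHead <- function(featureShape, variant = c("complex", "baseline"),
                      nClasses = 4L, dropout = 0.5, seReduction = 16L,
                      denseWidth = 512L, seed = 1) {
  variant <- match.arg(variant)
  assertScalarNumber(dropout, "dropout", 0, 1)
  layers <- if (variant == "complex") {
    list(nnResSepSE("res1", seReduction = seReduction),
         nnResSepSE("res2", seReduction = seReduction),
         nnGap("gap"),
         nnDense("fc", denseWidth), nnRelu("fcRelu"),
         nnDropout("drop", dropout),
         nnBatchNorm("bn"),
         nnDense("out", nClasses))
  } else {
    list(nnConv("conv", 512L, kernel = 3L), nnRelu("convRelu"),
         nnGap("gap"),
         nnDense("fc", denseWidth),
         nnDropout("drop", dropout),
         nnBatchNorm("bn"),
         nnDense("out", nClasses))
  }
  net <- nnBuild(layers, as.integer(featureShape),
                 seed = deriveSeed(seed, paste0("head:", variant)))
  structure(list(variant = variant, nClasses = as.integer(nClasses),
                 dropout = dropout, seReduction = as.integer(seReduction),
                 denseWidth = as.integer(denseWidth), net = net),
            class = "carniHead")
}

#' Layer inventory of a head
#'
#' Compact descriptors of the head's structural layers (activations
#' excluded), for inspection and structural tests.
#'
#' @param head a `carniHead`.
#' @return character vector of layer descriptors.
#' @export
headLayerInventory <- function(head) {
  out <- character()
  for (ly in head$net$layers) {
    out <- c(out, switch(ly$type,
      resSepSE = sprintf("resblock(dw-sep conv k3 s1 same + SE, %d ch)", ly$filters),
      conv = sprintf("conv(%d filters, k%d)", ly$filters, ly$kernel),
      gap = "gap",
      dense = sprintf("dense(%d)", ly$units),
      dropout = sprintf("dropout(%.2f)", ly$p),
      bn = "batch-norm",
      NULL))
  }
  # the final dense feeds the softmax
  out[length(out)] <- sub("^dense\\((\\d+)\\)$", "softmax(\\1)", out[length(out)])
  out
}

#' Total trainable parameter count
#' @param x a `carniHead`, `carniBackbone` or `MarkClassifier`.
#' @return integer number of scalar parameters.
#' @export
nParameters <- function(x) {
  if (is(x, "MarkClassifier")) {
    return(nParameters(x@head) + length(nnParamVec(x@backbone$params)))
  }
  length(nnParamVec(x$net$params))
}

#' MarkClassifier: a backbone plus classification head
#'
#' The deployable classifier object: a frozen feature-extraction backbone,
#' a trainable head, the head's batch-norm state, and a manifest (class
#' ordering, input contract, training regime) used to refuse mismatched
#' evaluation.
#'
#' @slot backbone `carniBackbone` list object.
#' @slot head `carniHead` list object.
#' @slot headParams named list of head parameter arrays.
#' @slot headState batch-norm running statistics.
#' @slot classLevels character; class order of the output axis.
#' @slot info list; regime, bnEval mode, adaptation defaults, history.
#' @aliases MarkClassifier
#' @export
setClass("MarkClassifier",
         representation(backbone = "list", head = "list",
                        headParams = "list", headState = "list",
                        classLevels = "character", info = "list"))

setValidity("MarkClassifier", function(object) {
  if (!identical(object@classLevels, taxonLevels())) {
    return("classLevels must equal taxonLevels()")
  }
  TRUE
})

#' Construct an untrained classifier
#'
#' @param backbone backbone name (see [buildBackbone()]) or a prebuilt
#'   `carniBackbone`.
#' @param headVariant `"complex"` or `"baseline"`.
#' @param inputSide stand-in input side in pixels.
#' @param dropout,seReduction,denseWidth head hyperparameters.
#' @param seed integer seed for all weight initialisation.
#' @return a [MarkClassifier-class].
#' @export
buildClassifier <- function(backbone = "standin", headVariant = "complex",
                            inputSide = 64L, dropout = 0.5,
                            seReduction = 16L, denseWidth = 512L, seed = 1) {
  bb <- if (inherits(backbone, "carniBackbone")) backbone else
    buildBackbone(backbone, inputSide = inputSide, seed = seed)
  head <- buildHead(bb$featureShape, headVariant, dropout = dropout,
                    seReduction = seReduction, denseWidth = denseWidth,
                    seed = seed)
  new("MarkClassifier", backbone = unclass(bb), head = unclass(head),
      headParams = head$net$params, headState = head$net$state,
      classLevels = taxonLevels(),
      info = list(regime = "untrained", bnEval = "running",
                  innerLr = NULL, innerSteps = NULL))
}

setMethod("show", "MarkClassifier", function(object) {
  cat(sprintf("MarkClassifier: %s backbone (%s px, %s norm) + %s head (%d params), regime: %s\n",
              object@backbone$name, object@backbone$inputSpec$side,
              object@backbone$inputSpec$normalization,
              object@head$variant,
              length(nnParamVec(object@headParams)),
              object@info$regime))
})

# Preprocess a list of raw RGB images into the model's input tensor.
preprocessBatch <- function(model, imgs) {
  spec <- model@backbone$inputSpec
  stackImages(lapply(imgs, resizeNormalize, spec = spec))
}

# Head forward in evaluation mode; returns class probabilities (n x 4).
headProbs <- function(model, feats, params = NULL, bnMode = NULL) {
  params <- params %||% model@headParams
  bnMode <- bnMode %||% model@info$bnEval
  net <- model@head$net
  net$state <- model@headState
  out <- nnForward(net, params, feats,
                   ctx = list(train = FALSE, bnMode = bnMode))$out
  probs <- softmaxRows(out)
  colnames(probs) <- model@classLevels
  probs
}

#' Class probabilities for images
#'
#' Runs preprocessing, the frozen backbone and the head in evaluation mode
#' (dropout disabled; batch normalization in the model's evaluation mode).
#' Deterministic: repeated calls on the same input are identical.
#'
#' @param model a [MarkClassifier-class].
#' @param images a single RGB array, a list of RGB arrays, or an
#'   [ImageBank-class] whose images are loaded from disk.
#' @return matrix (n x 4) of probabilities, columns in [taxonLevels()]
#'   order; each row sums to 1.
#' @export
predictProbs <- function(model, images) {
  stopifnot(is(model, "MarkClassifier"))
  if (is(images, "ImageBank")) {
    images <- lapply(bankRecords(images)$path, loadImage)
  }
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  x <- preprocessBatch(model, images)
  feats <- backboneForward(model@backbone, x)
  headProbs(model, feats)
}
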