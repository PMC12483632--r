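# Backbone-specific input contracts: target side length and the named
# per-channel normalization each feature extractor expects.

.backboneTable <- list(
  resnet50        = list(side = 224L, normalization = "caffe"),
  resnet152       = list(side = 224L, normalization = "caffe"),
  densenet201     = list(side = 224L, normalization = "torch"),
  xception        = list(side = 299L, normalization = "tf"),
  efficientnetv2l = list(side = 299L, normalization = "tf"),
  standin         = list(side = 64L, normalization = "unit")
)

#' Backbone input specification
#'
#' Resolves the input side length and normalization contract for a named
#' backbone: 224 px for the ResNet and DenseNet family, 299 px for
#' Xception and EfficientNetV2L, and a configurable side (default 64) with
#' unit scaling for the stand-in backbone.
#'
#' Normalization contracts (applied after scaling pixels to [0, 1]):
#' `unit` = identity; `tf` = scale to [-1, 1]; `torch` = subtract the
#' ImageNet channel means and divide by the channel standard deviations;
#' `caffe` = scale to 0-255 and subtract the ImageNet channel means.
#'
#' @param backboneName one of resnet50, resnet152, densenet201, xception,
#'   efficientnetv2l, standin.
#' @param side optional override of the input side (stand-in only).
#' @return an object of class `BackboneInputSpec`.
#' @export
backboneInputSpec <- function(backboneName = "standin", side = NULL) {
  backboneName <- match.arg(backboneName, names(.backboneTable))
  entry <- .backboneTable[[backboneName]]
  if (!is.null(side)) {
    if (backboneName != "standin" && !side %in% c(224L, 299L)) {
      stop("side must be 224 or 299 for named backbones", call. = FALSE)
    }
    entry$side <- assertCount(side, "side", 8L)
  }
  structure(list(backboneName = backboneName, side = entry$side,
                 normalization = entry$normalization),
            class = "BackboneInputSpec")
}

applyNormalization <- function(x, contract) {
  switch(contract,
         unit = x,
         tf = 2 * x - 1,
         torch = {
           mean <- c(0.485, 0.456, 0.406); sd <- c(0.229, 0.224, 0.225)
           for (ch in 1:3) x[, , ch] <- (x[, , ch] - mean[ch]) / sd[ch]
           x
         },
         caffe = {
           mean <- c(123.68, 116.779, 103.939)
           for (ch in 1:3) x[, , ch] <- x[, , ch] * 255 - mean[ch]
           x
         },
         stop("unknown normalization contract: ", contract))
}

#' Resize and normalize an image for a backbone
#'
#' Bilinearly resizes a decoded RGB image to the backbone's square input
#' side and applies its per-channel normalization contract.
#'
#' @param img RGB array (h x w x 3) in [0, 1].
#' @param spec a [backboneInputSpec()].
#' @return side x side x 3 input tensor.
#' @export
resizeNormalize <- function(img, spec = backboneInputSpec()) {
  assertImage(img)
  stopifnot(inherits(spec, "BackboneInputSpec"))
  out <- if (all(dim(img)[1:2] == spec$side)) img else
    resizeBilinear(img, spec$side, spec$side)
  applyNormalization(out, spec$normalization)
}

# Stack a list of side x side x 3 images into the engine's (h, w, n,
# channel) tensor layout.
stackImages <- function(imgs) {
  d <- dim(imgs[[1]])
  x <- array(unlist(imgs, use.names = FALSE), c(d[1], d[2], d[3], length(imgs)))
  aperm(x, c(1, 2, 4, 3))
}
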