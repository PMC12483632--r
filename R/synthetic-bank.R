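# Synthetic tooth-mark image bank.
#
# The generator does not attempt biologically realistic micro-morphology;
# it reproduces the statistical structure the classifiers assume: four
# classes with controllable per-class counts, variable native image sizes,
# and class-specific shape/texture/tint signatures whose distinctness is
# governed by a single separability dial.

#' Construct a class signature
#'
#' A signature parameterizes how marks of one taxon are rendered: ellipse
#' elongation, boundary roughness, interior depth shading, hue tint on the
#' 0-180 scale, and ridge texture frequency.
#'
#' @param taxon one of [taxonLevels()].
#' @param ellipseAspect positive real; ratio of major to minor axis.
#' @param edgeRoughness nonnegative real; relative boundary noise amplitude.
#' @param interiorDepth real in [0, 1]; centre-to-edge intensity gradient.
#' @param hueTint hue in degrees, [0, 180).
#' @param textureFreq nonnegative real; ridge cycles across the mark.
#' @return an object of class `ClassSignature`.
#' @export
classSignature <- function(taxon, ellipseAspect, edgeRoughness,
                           interiorDepth, hueTint, textureFreq) {
  assertTaxa(taxon)
  assertScalarNumber(ellipseAspect, "ellipseAspect", 1e-6)
  assertScalarNumber(edgeRoughness, "edgeRoughness", 0)
  assertScalarNumber(interiorDepth, "interiorDepth", 0, 1)
  assertScalarNumber(hueTint, "hueTint", 0, 180 - 1e-9)
  assertScalarNumber(textureFreq, "textureFreq", 0)
  structure(list(taxon = taxon, ellipseAspect = ellipseAspect,
                 edgeRoughness = edgeRoughness, interiorDepth = interiorDepth,
                 hueTint = hueTint, textureFreq = textureFreq),
            class = "ClassSignature")
}

# Fixed distinct endpoint signatures (separability = 1) and the shared base
# signature (separability = 0). One scalar interpolates linearly between
# them, so task difficulty is controlled by a single dial.
.baseSig <- c(ellipseAspect = 1.8, edgeRoughness = 0.06, interiorDepth = 0.45,
              hueTint = 35, textureFreq = 4)
.distinctSigs <- list(
  crocodile = c(1.1, 0.18, 0.75, 10, 2),
  hyena     = c(2.6, 0.10, 0.55, 55, 6),
  leopard   = c(1.7, 0.03, 0.25, 95, 10),
  lion      = c(3.4, 0.22, 0.65, 140, 1)
)

#' Class signatures at a given separability
#'
#' Interpolates each taxon's signature linearly between a shared base
#' signature (`separability = 0`: all four classes identical) and four
#' fixed distinct signatures (`separability = 1`: maximally distinct).
#'
#' @param separability real in [0, 1].
#' @return named list of four [classSignature()] objects in taxon order.
#' @export
classSignatures <- function(separability = 1) {
  assertScalarNumber(separability, "separability", 0, 1)
  out <- lapply(taxonLevels(), function(tx) {
    v <- .baseSig + separability * (setNames(.distinctSigs[[tx]], names(.baseSig)) - .baseSig)
    classSignature(tx, v["ellipseAspect"], v["edgeRoughness"],
                   v["interiorDepth"], v["hueTint"], v["textureFreq"])
  })
  setNames(out, taxonLevels())
}

# Continuous HSV -> RGB (no 8-bit rounding); hue on 0-180, s in [0,1],
# v in [0,1].
hsvToRgbFloat <- function(h, s, v) {
  H <- (h * 2) %% 360
  c <- v * s
  x <- c * (1 - abs((H / 60) %% 2 - 1))
  m <- v - c
  sector <- floor(H / 60)
  rgb1 <- switch(as.character(sector),
                 "0" = c(c, x, 0), "1" = c(x, c, 0), "2" = c(0, c, x),
                 "3" = c(0, x, c), "4" = c(x, 0, c), c(c, 0, x))
  rgb1 + m
}

# Low-frequency stationary background texture: a coarse Gaussian grid
# bilinearly upsampled to full resolution (Perlin-like bone surface).
lowFreqNoise <- function(h, w, cells = 6L, amplitude = 1) {
  g <- array(rnorm(cells * cells), c(cells, cells, 3))
  g[, , 2] <- g[, , 1]; g[, , 3] <- g[, , 1]
  resizeBilinear(g, h, w)[, , 1] * amplitude
}

#' Render one synthetic tooth-mark image
#'
#' Draws a single elliptical mark-like region whose geometry, texture and
#' tint follow the class signature, over a bone-like low-frequency
#' background, plus white pixel noise. Output is quantized to 8-bit so PNG
#' round-trips are bit-exact. Deterministic given `seed`; with `seed = NULL`
#' the current RNG stream is consumed.
#'
#' @param sig a [classSignature()].
#' @param size integer c(height, width) in pixels.
#' @param noiseSd nonnegative real; white-noise standard deviation on the
#'   [0, 1] intensity scale.
#' @param seed optional integer seed.
#' @return RGB array (h x w x 3) in [0, 1].
#' @export
generateMarkImage <- function(sig, size, noiseSd = 0.02, seed = NULL) {
  stopifnot(inherits(sig, "ClassSignature"))
  if (length(size) == 1L) size <- c(size, size)
  if (any(size < 1) || any(size != round(size))) {
    stop("'size' must be positive integers", call. = FALSE)
  }
  assertScalarNumber(noiseSd, "noiseSd", 0)
  render <- function() {
    h <- as.integer(size[1]); w <- as.integer(size[2])
    yy <- matrix(seq(-1, 1, length.out = h), h, w)
    xx <- matrix(seq(-1, 1, length.out = w), h, w, byrow = TRUE)
    # bone-like background
    bg <- lowFreqNoise(h, w, cells = 6L, amplitude = 0.06)
    bone <- c(0.82, 0.72, 0.58)
    img <- array(0, c(h, w, 3))
    for (ch in 1:3) img[, , ch] <- bone[ch] + bg
    # mark geometry
    cy <- runif(1, -0.1, 0.1); cx <- runif(1, -0.1, 0.1)
    phi <- runif(1, 0, pi)
    a <- 0.38 * sqrt(sig$ellipseAspect)
    b <- 0.38 / sqrt(sig$ellipseAspect)
    u <- cos(phi) * (xx - cx) + sin(phi) * (yy - cy)
    v <- -sin(phi) * (xx - cx) + cos(phi) * (yy - cy)
    r <- sqrt((u / a)^2 + (v / b)^2)
    theta <- atan2(v / b, u / a)
    ph <- runif(3, 0, 2 * pi)
    rough <- 1 + sig$edgeRoughness *
      (sin(3 * theta + ph[1]) + 0.6 * sin(5 * theta + ph[2]) +
         0.4 * sin(7 * theta + ph[3]))
    rough <- pmax(rough, 0.2)
    rd <- r / rough
    alpha <- clamp((1 - rd) / 0.05, 0, 1) # soft edge
    # interior shading: darker centre by interiorDepth, ridge texture along u
    val <- 0.75 * (1 - sig$interiorDepth * (1 - pmin(rd, 1)))
    if (sig$textureFreq > 0) {
      val <- val + 0.07 * sin(2 * pi * sig$textureFreq * u)
    }
    val <- clamp(val, 0, 1)
    tint <- hsvToRgbFloat(sig$hueTint, 0.45, 1)
    for (ch in 1:3) {
      img[, , ch] <- img[, , ch] * (1 - alpha) + (val * tint[ch]) * alpha
    }
    if (noiseSd > 0) {
      img <- img + array(rnorm(h * w * 3, sd = noiseSd), c(h, w, 3))
    }
    roundHalfUp(clamp(img, 0, 1) * 255, 0) / 255
  }
  if (is.null(seed)) render() else withr::with_seed(as.integer(seed), render())
}

#' Synthetic bank configuration
#'
#' Defaults reproduce the reference bank structure: per-class counts
#' 264/544/364/124 (crocodile, hyena, leopard, lion; 1296 marks in total),
#' variable native sizes, fully distinct class signatures.
#'
#' @param perClassCounts named integer vector over the four taxa.
#' @param sizeRange integer c(min, max) native side length in pixels
#'   (heights and widths drawn independently and uniformly).
#' @param separability real in [0, 1]; see [classSignatures()].
#' @param noiseSd white-noise standard deviation.
#' @param seed integer seed controlling the whole bank.
#' @return an object of class `BankConfig`.
#' @export
bankConfig <- function(perClassCounts = c(crocodile = 124, hyena = 364,
                                          leopard = 544, lion = 264),
                       sizeRange = c(96, 192), separability = 1,
                       noiseSd = 0.02, seed = 1) {
  stopifnot(length(sizeRange) == 2L, sizeRange[1] >= 32,
            sizeRange[2] >= sizeRange[1])
  assertScalarNumber(separability, "separability", 0, 1)
  assertScalarNumber(noiseSd, "noiseSd", 0)
  if (is.null(names(perClassCounts))) {
    stopifnot(length(perClassCounts) == 4L)
    names(perClassCounts) <- taxonLevels()
  }
  assertTaxa(names(perClassCounts))
  stopifnot(setequal(names(perClassCounts), taxonLevels()),
            all(perClassCounts >= 1), all(perClassCounts == round(perClassCounts)))
  structure(list(perClassCounts = perClassCounts[taxonLevels()],
                 sizeRange = as.integer(sizeRange),
                 separability = separability, noiseSd = noiseSd,
                 seed = as.integer(seed)),
            class = "BankConfig")
}

#' Generate a synthetic image bank on disk
#'
#' Writes one PNG per mark under `<dir>/<taxon>/<mark_id>.png` plus a
#' `manifest.csv` (`mark_id,taxon,path,height,width`), and returns the bank.
#' Regeneration under the same configuration is bit-identical.
#'
#' @param config a [bankConfig()].
#' @param dir output directory (created if missing).
#' @return an [ImageBank-class] of the generated records.
#' @export
generateBank <- function(config = bankConfig(), dir) {
  stopifnot(inherits(config, "BankConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  sigs <- classSignatures(config$separability)
  rows <- list()
  for (tx in taxonLevels()) {
    n <- config$perClassCounts[[tx]]
    txDir <- file.path(dir, tx)
    dir.create(txDir, showWarnings = FALSE)
    lo <- config$sizeRange[1]
    span <- config$sizeRange[2] - lo + 1L
    sizes <- withr::with_seed(deriveSeed(config$seed, paste0(tx, ":sizes")), {
      cbind(lo + sample.int(span, n, replace = TRUE) - 1L,
            lo + sample.int(span, n, replace = TRUE) - 1L)
    })
    for (i in seq_len(n)) {
      markId <- sprintf("%s_%04d", tx, i)
      img <- generateMarkImage(sigs[[tx]], sizes[i, ], config$noiseSd,
                               seed = deriveSeed(config$seed, markId))
      path <- file.path(txDir, paste0(markId, ".png"))
      png::writePNG(img, path)
      rows[[markId]] <- data.frame(mark_id = markId, taxon = tx,
                                   path = path, height = sizes[i, 1],
                                   width = sizes[i, 2],
                                   stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  manifest <- records
  manifest$path <- file.path(manifest$taxon, paste0(manifest$mark_id, ".png"))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  ImageBank(records = records, root = dir)
}
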