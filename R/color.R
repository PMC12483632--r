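# RGB <-> HSV conversion on the convention used throughout the package:
# 8-bit RGB channels, hue on a circular 0-180 degree scale (half-degrees),
# saturation in [0, 1], value in [0, 255]. Conversions are vectorized over
# pixels; grDevices::rgb2hsv is deliberately NOT used here so that the unit
# tests can hold it up as an independent oracle.

#' Convert 8-bit RGB values to HSV (hue 0-180)
#'
#' @param r,g,b numeric vectors of 8-bit channel values (0-255).
#' @return list with components `h` (degrees in [0, 180)), `s` in [0, 1] and
#'   `v` in [0, 255].
#' @export
rgbToHsv180 <- function(r, g, b) {
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  d <- mx - mn
  h <- numeric(length(r))
  nz <- d > 0
  ir <- nz & (mx == r)
  ig <- nz & (mx == g) & !ir
  ib <- nz & (mx == b) & !ir & !ig
  h[ir] <- 60 * (((g[ir] - b[ir]) / d[ir]) %% 6)
  h[ig] <- 60 * ((b[ig] - r[ig]) / d[ig] + 2)
  h[ib] <- 60 * ((r[ib] - g[ib]) / d[ib] + 4)
  s <- ifelse(mx > 0, d / mx, 0)
  list(h = h / 2, s = s, v = mx)
}

#' Convert HSV (hue 0-180) back to 8-bit RGB
#'
#' Inverse of [rgbToHsv180()]; output channels are rounded half-up to
#' integers in 0-255.
#'
#' @param h hue in degrees on the 0-180 circular scale.
#' @param s saturation in [0, 1].
#' @param v value in [0, 255].
#' @return list with integer-valued components `r`, `g`, `b`.
#' @export
hsvToRgb180 <- function(h, s, v) {
  H <- (h * 2) %% 360
  c <- v * s
  x <- c * (1 - abs((H / 60) %% 2 - 1))
  m <- v - c
  sector <- pmin(floor(H / 60), 5)
  n <- length(H)
  r1 <- g1 <- b1 <- numeric(n)
  idx <- function(k) sector == k
  r1[idx(0)] <- c[idx(0)]; g1[idx(0)] <- x[idx(0)]
  r1[idx(1)] <- x[idx(1)]; g1[idx(1)] <- c[idx(1)]
  g1[idx(2)] <- c[idx(2)]; b1[idx(2)] <- x[idx(2)]
  g1[idx(3)] <- x[idx(3)]; b1[idx(3)] <- c[idx(3)]
  r1[idx(4)] <- x[idx(4)]; b1[idx(4)] <- c[idx(4)]
  r1[idx(5)] <- c[idx(5)]; b1[idx(5)] <- x[idx(5)]
  list(r = clamp(roundHalfUp(r1 + m, 0), 0, 255),
       g = clamp(roundHalfUp(g1 + m, 0), 0, 255),
       b = clamp(roundHalfUp(b1 + m, 0), 0, 255))
}

#' HSV augmentation configuration
#'
#' Colour augmentation protocol: each augmented image has exactly one HSV
#' attribute modified, chosen uniformly among hue, saturation and value.
#' A hue modification adds a uniform shift in `hueShiftRange` degrees on the
#' 0-180 circular hue scale (wrapping); saturation and value modifications
#' scale their channel by a uniform factor in the corresponding range, with
#' clamping to the valid channel range.
#'
#' @param hueShiftRange length-2 numeric, degrees on the 0-180 scale.
#' @param satScaleRange,valScaleRange length-2 numeric scale-factor ranges.
#' @param mode `"random"` (default: pick one attribute uniformly) or one of
#'   `"hue"`, `"sat"`, `"val"` to force the attribute (useful for tests).
#' @return an object of class `HsvAugConfig`.
#' @export
hsvAugConfig <- function(hueShiftRange = c(-10, 10),
                         satScaleRange = c(0.8, 1.2),
                         valScaleRange = c(0.8, 1.2),
                         mode = "random") {
  stopifnot(length(hueShiftRange) == 2L, length(satScaleRange) == 2L,
            length(valScaleRange) == 2L)
  mode <- match.arg(mode, c("random", "hue", "sat", "val"))
  structure(list(hueShiftRange = sort(hueShiftRange),
                 satScaleRange = sort(satScaleRange),
                 valScaleRange = sort(valScaleRange),
                 mode = mode),
            class = "HsvAugConfig")
}

#' Apply one random HSV modification to an image
#'
#' Converts the image RGB -> HSV (hue on 0-180), modifies exactly one
#' attribute drawn according to `config`, and converts back to RGB. Hue
#' wraps circularly; saturation and value are clamped to their valid
#' ranges. Gray pixels (saturation 0) are bit-invariant under hue shifts.
#'
#' @param img RGB array (h x w x 3) with values in [0, 1] (8-bit quantized).
#' @param config an [hsvAugConfig()] object.
#' @return augmented image in [0, 1], with attributes `hsvMode` and
#'   `hsvAmount` recording the modification drawn.
#' @export
augmentHSV <- function(img, config = hsvAugConfig()) {
  assertImage(img)
  x <- round(img * 255) # inputs are 8-bit quantized already
  hsv <- rgbToHsv180(x[, , 1], x[, , 2], x[, , 3])
  mode <- config$mode
  if (mode == "random") {
    mode <- c("hue", "sat", "val")[sample.int(3L, 1L)]
  }
  if (mode == "hue") {
    amount <- runif(1, config$hueShiftRange[1], config$hueShiftRange[2])
    hsv$h <- (hsv$h + amount) %% 180
  } else if (mode == "sat") {
    amount <- runif(1, config$satScaleRange[1], config$satScaleRange[2])
    hsv$s <- clamp(hsv$s * amount, 0, 1)
  } else {
    amount <- runif(1, config$valScaleRange[1], config$valScaleRange[2])
    hsv$v <- clamp(hsv$v * amount, 0, 255)
  }
  rgb <- hsvToRgb180(hsv$h, hsv$s, hsv$v)
  out <- img
  out[, , 1] <- rgb$r / 255
  out[, , 2] <- rgb$g / 255
  out[, , 3] <- rgb$b / 255
  attr(out, "hsvMode") <- mode
  attr(out, "hsvAmount") <- amount
  out
}
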