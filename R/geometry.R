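# Bilinear sampling with nearest-edge fill. All geometric operations in the
# package (resizing and geometric augmentation) funnel through
# bilinearSample(), so the interpolation and border policy are defined in
# exactly one place.

# Sample img (h x w x 3, [0,1]) at fractional row/col coordinate matrices
# ys, xs (same dims as output). Coordinates are clamped to the image, which
# implements the nearest-edge fill policy for regions mapped outside.
bilinearSample <- function(img, ys, xs) {
  h <- dim(img)[1]; w <- dim(img)[2]
  ys <- clamp(ys, 1, h)
  xs <- clamp(xs, 1, w)
  y0 <- pmin(floor(ys), max(h - 1, 1))
  x0 <- pmin(floor(xs), max(w - 1, 1))
  y1 <- pmin(y0 + 1, h)
  x1 <- pmin(x0 + 1, w)
  wy <- ys - y0
  wx <- xs - x0
  out <- array(0, dim = c(dim(ys), 3L))
  for (ch in 1:3) {
    plane <- img[, , ch]
    v00 <- plane[cbind(c(y0), c(x0))]
    v01 <- plane[cbind(c(y0), c(x1))]
    v10 <- plane[cbind(c(y1), c(x0))]
    v11 <- plane[cbind(c(y1), c(x1))]
    v <- (1 - wy) * ((1 - wx) * v00 + wx * v01) +
      wy * ((1 - wx) * v10 + wx * v11)
    out[, , ch] <- v
  }
  out
}

#' Resize an RGB image by bilinear interpolation
#'
#' Uses the align-corners convention, so resizing an image to its own size
#' is the exact identity.
#'
#' @param img RGB array (h x w x 3).
#' @param height,width target size in pixels.
#' @return resized RGB array.
#' @export
resizeBilinear <- function(img, height, width = height) {
  assertImage(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  rows <- if (height == 1L) rep((h + 1) / 2, 1) else
    1 + (seq_len(height) - 1) * (h - 1) / (height - 1)
  cols <- if (width == 1L) rep((w + 1) / 2, 1) else
    1 + (seq_len(width) - 1) * (w - 1) / (width - 1)
  ys <- matrix(rows, nrow = height, ncol = width)
  xs <- matrix(cols, nrow = height, ncol = width, byrow = TRUE)
  bilinearSample(img, ys, xs)
}

#' Apply a fixed geometric transform to an image
#'
#' Composes (in this order) an optional horizontal flip, a rotation about
#' the image centre, and a translation, then resamples bilinearly with
#' nearest-edge fill. Output shape equals input shape. With all parameters
#' at zero the transform is the exact identity.
#'
#' @param img RGB array (h x w x 3).
#' @param angle rotation in degrees (counter-clockwise).
#' @param dx,dy translation in pixels along width and height.
#' @param flip logical; mirror horizontally first.
#' @return transformed RGB array with the same dimensions.
#' @export
applyGeometric <- function(img, angle = 0, dx = 0, dy = 0, flip = FALSE) {
  assertImage(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- angle * pi / 180
  # Inverse mapping: undo translation, rotation, then flip.
  yo <- matrix(seq_len(h), nrow = h, ncol = w)
  xo <- matrix(seq_len(w), nrow = h, ncol = w, byrow = TRUE)
  yr <- yo - cy - dy
  xr <- xo - cx - dx
  xs <- cos(th) * xr + sin(th) * yr
  ys <- -sin(th) * xr + cos(th) * yr
  xs <- xs + cx
  ys <- ys + cy
  if (flip) xs <- (w + 1) - xs
  bilinearSample(img, ys, xs)
}

#' Geometric augmentation configuration
#'
#' Random rotation, width/height shifts and horizontal flipping. Defaults
#' follow the training protocol: rotation uniform in +/-20 degrees, shifts
#' uniform in +/-0.2 of the image side on each axis independently, and a
#' fair-coin horizontal flip. Exposed borders are filled nearest-edge.
#'
#' @param rotationDeg maximum absolute rotation in degrees.
#' @param shiftFrac maximum absolute shift as a fraction of the image side.
#' @param hflip logical; enable random horizontal flips.
#' @return an object of class `GeometricAugConfig`.
#' @export
geometricAugConfig <- function(rotationDeg = 20, shiftFrac = 0.2,
                               hflip = TRUE) {
  assertScalarNumber(rotationDeg, "rotationDeg", 0, 180)
  assertScalarNumber(shiftFrac, "shiftFrac", 0, 1)
  structure(list(rotationDeg = rotationDeg, shiftFrac = shiftFrac,
                 hflip = isTRUE(hflip)),
            class = "GeometricAugConfig")
}

#' Apply one random geometric augmentation to an image
#'
#' Draws a rotation angle, independent width/height shifts and a flip
#' decision from `config` and applies them via [applyGeometric()].
#'
#' @param img RGB array (h x w x 3).
#' @param config a [geometricAugConfig()] object.
#' @return augmented image, same shape, with attribute `geomDraw` recording
#'   the sampled transform.
#' @export
augmentGeometric <- function(img, config = geometricAugConfig()) {
  assertImage(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  angle <- runif(1, -config$rotationDeg, config$rotationDeg)
  dx <- runif(1, -config$shiftFrac, config$shiftFrac) * w
  dy <- runif(1, -config$shiftFrac, config$shiftFrac) * h
  flip <- config$hflip && (runif(1) < 0.5)
  out <- applyGeometric(img, angle = angle, dx = dx, dy = dy, flip = flip)
  attr(out, "geomDraw") <- list(angle = angle, dx = dx, dy = dy, flip = flip)
  out
}
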