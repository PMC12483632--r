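#' @import methods
#' @importFrom stats rnorm runif setNames
#' @importFrom utils read.csv write.csv modifyList
NULL

# Clamp numeric values into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Round half-up at a fixed number of decimals
#'
#' Decimal rounding with the half-up convention used when rendering report
#' tables (0.835 -> 0.84). A small relative guard absorbs binary floating
#' point representation of decimal inputs, so values that are exact decimal
#' halves round up even when stored as 0.83499...9.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to `digits` decimals.
#' @export
roundHalfUp <- function(x, digits = 2) {
  scale <- 10^digits
  guard <- 1e-9 * pmax(1, abs(x))
  sign(x) * floor(abs(x) * scale + 0.5 + guard * scale) / scale
}

# Deterministic derivation of a child seed from (seed, key). Keeps the
# result in [1, 2^31 - 2] so it is always a valid R integer seed. The
# derivation is a small multiplicative hash over the key string; documented
# so that partial re-runs are reproducible from the global seed alone.
deriveSeed <- function(seed, key) {
  m <- 2147483647 # 2^31 - 1 (prime)
  h <- as.numeric(seed %% m)
  codes <- utf8ToInt(as.character(key))
  for (k in codes) {
    h <- (h * 31 + k) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Tiny FNV-1a style hash of a character scalar, hex-rendered; used to name
# run directories from their configuration.
hashString <- function(s) {
  h <- 2166136261
  for (k in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), k)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# Shared input checks -------------------------------------------------------

assertScalarNumber <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("'%s' must be a finite number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}

assertCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

assertImage <- function(img, name = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop(sprintf("'%s' must be an h x w x 3 RGB array", name), call. = FALSE)
  }
  invisible(img)
}
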