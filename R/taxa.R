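#' Carnivore taxon labels
#'
#' The four carnivore agents distinguished by the classifiers, in the fixed
#' alphabetical order used for every vector and matrix axis in the package:
#' crocodile, hyena, leopard, lion.
#'
#' @return character vector of the four taxon names.
#' @examples
#' taxonLevels()
#' @export
taxonLevels <- function() c("crocodile", "hyena", "leopard", "lion")

# Validate a vector of taxon names against the fixed label set.
assertTaxa <- function(x, name = "taxon") {
  bad <- setdiff(unique(as.character(x)), taxonLevels())
  if (length(bad) > 0L) {
    stop(sprintf("unknown %s label(s): %s (valid: %s)", name,
                 paste(bad, collapse = ", "),
                 paste(taxonLevels(), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# Taxon names as a factor in canonical order.
taxonFactor <- function(x) {
  assertTaxa(x)
  factor(as.character(x), levels = taxonLevels())
}
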