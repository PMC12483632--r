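# Shared fixtures: tiny synthetic banks generated in the session temp dir,
# cached across test files, plus a fake in-memory bank (no image files) for
# split arithmetic at the reference sample sizes.

.bankCache <- new.env(parent = emptyenv())

# A small on-disk bank: `n` marks per class at a fixed side length.
tinyBank <- function(n = 8L, side = 32L, separability = 1, seed = 99L,
                     noiseSd = 0.02) {
  key <- paste("bank", n, side, separability, seed, noiseSd, sep = "-")
  if (is.null(.bankCache[[key]])) {
    dir <- file.path(tempdir(), paste0("carni-", key))
    cfg <- bankConfig(perClassCounts = setNames(rep(as.integer(n), 4),
                                                taxonLevels()),
                      sizeRange = c(side, side),
                      separability = separability,
                      noiseSd = noiseSd, seed = seed)
    .bankCache[[key]] <- generateBank(cfg, dir)
  }
  .bankCache[[key]]
}

# A records-only bank with the reference per-class counts (no files);
# sufficient for split arithmetic.
fakeBank <- function(counts = c(crocodile = 124, hyena = 364,
                                leopard = 544, lion = 264)) {
  rec <- do.call(rbind, lapply(names(counts), function(tx) {
    data.frame(mark_id = sprintf("%s_%04d", tx, seq_len(counts[[tx]])),
               taxon = tx, path = paste0(tx, ".png"),
               height = 64L, width = 64L, stringsAsFactors = FALSE)
  }))
  new("ImageBank", records = rec, root = NA_character_)
}

# A deterministic flat test image with an off-center bright pixel.
onehotImage <- function(h = 20L, w = 20L, at = c(5L, 7L)) {
  img <- array(0, c(h, w, 3))
  img[at[1], at[2], ] <- 1
  img
}
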