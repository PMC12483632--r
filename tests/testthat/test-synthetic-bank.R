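test_that("mark rendering is deterministic and signature-driven", {
  sig <- classSignatures(1)$leopard
  a <- generateMarkImage(sig, c(48, 48), noiseSd = 0.02, seed = 5)
  b <- generateMarkImage(sig, c(48, 48), noiseSd = 0.02, seed = 5)
  expect_identical(a, b)
  c <- generateMarkImage(sig, c(48, 48), noiseSd = 0.02, seed = 6)
  expect_false(identical(a, c))
  expect_equal(dim(a), c(48, 48, 3))
  expect_true(all(a >= 0 & a <= 1))
  expect_error(generateMarkImage(sig, c(0, 10)), "size")
})

test_that("degenerate signature renders a constant-colour mark interior", {
  sig <- classSignature("lion", ellipseAspect = 1, edgeRoughness = 0,
                        interiorDepth = 0, hueTint = 40, textureFreq = 0)
  img <- generateMarkImage(sig, c(64, 64), noiseSd = 0, seed = 1)
  # the mark spans the image centre; a small central window is interior
  mid <- 29:35
  for (ch in 1:3) {
    expect_equal(stats::sd(img[mid, mid, ch]), 0)
  }
})

test_that("signature interpolation collapses at separability zero", {
  s0 <- classSignatures(0)
  s1 <- classSignatures(1)
  for (tx in taxonLevels()[-1]) {
    expect_equal(unlist(s0[[tx]][-1]), unlist(s0$crocodile[-1]))
  }
  expect_false(identical(unlist(s1$leopard[-1]), unlist(s1$lion[-1])))
  # halfway signatures lie between the endpoints
  sh <- classSignatures(0.5)
  expect_equal(sh$lion$hueTint, (s0$lion$hueTint + s1$lion$hueTint) / 2)
})

test_that("generateBank writes exact per-class counts and a manifest", {
  counts <- c(crocodile = 2L, hyena = 4L, leopard = 3L, lion = 5L)
  dir <- file.path(tempdir(), "carni-countbank")
  unlink(dir, recursive = TRUE)
  bank <- generateBank(bankConfig(perClassCounts = counts,
                                  sizeRange = c(32, 40), seed = 3), dir)
  expect_equal(length(bank), sum(counts))
  expect_equal(taxaCounts(bank), counts[taxonLevels()])
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), sum(counts))
  expect_equal(sort(names(man)),
               sort(c("mark_id", "taxon", "path", "height", "width")))
  # native sizes drawn within the configured range
  expect_true(all(man$height >= 32 & man$height <= 40))
  expect_true(all(man$width >= 32 & man$width <= 40))
  # one subdirectory per taxon, one file per record
  expect_setequal(list.dirs(dir, full.names = FALSE, recursive = FALSE),
                  taxonLevels())
  expect_equal(length(list.files(file.path(dir, "lion"))), 5L)
})

test_that("one mark per taxon yields a four-row bank", {
  dir <- file.path(tempdir(), "carni-minbank")
  unlink(dir, recursive = TRUE)
  bank <- generateBank(bankConfig(perClassCounts = setNames(rep(1L, 4),
                                                            taxonLevels()),
                                  sizeRange = c(32, 32), seed = 1), dir)
  expect_equal(length(bank), 4L)
  expect_equal(unname(taxaCounts(bank)), rep(1L, 4))
})

test_that("bank regeneration under one seed is bit-identical", {
  d1 <- file.path(tempdir(), "carni-regen1")
  d2 <- file.path(tempdir(), "carni-regen2")
  unlink(c(d1, d2), recursive = TRUE)
  cfg <- bankConfig(perClassCounts = setNames(rep(2L, 4), taxonLevels()),
                    sizeRange = c(32, 36), seed = 17)
  b1 <- generateBank(cfg, d1)
  b2 <- generateBank(cfg, d2)
  r1 <- bankRecords(b1); r2 <- bankRecords(b2)
  expect_identical(r1[c("mark_id", "taxon", "height", "width")],
                   r2[c("mark_id", "taxon", "height", "width")])
  for (i in seq_len(nrow(r1))) {
    expect_identical(readBin(r1$path[i], "raw", 1e6),
                     readBin(r2$path[i], "raw", 1e6))
  }
})

test_that("separability dial controls nearest-centroid learnability", {
  # independent of the neural pipeline: class centroids on down-sampled
  # pixels must separate a separability-1 bank and fail on a
  # separability-0 bank
  runCentroid <- function(sep) {
    bank <- tinyBank(n = 30L, side = 48L, separability = sep, seed = 51L)
    sp <- stratifiedSplit(bank, splitSpec(c(0.7, 0.15, 0.15), seed = 5))
    down <- function(p) as.vector(resizeBilinear(loadImage(p), 12, 12))
    tr <- bankRecords(sp$train)
    te <- bankRecords(sp$test)
    Xtr <- t(vapply(tr$path, down, numeric(12 * 12 * 3)))
    Xte <- t(vapply(te$path, down, numeric(12 * 12 * 3)))
    cent <- sapply(taxonLevels(),
                   function(tx) colMeans(Xtr[tr$taxon == tx, , drop = FALSE]))
    pred <- taxonLevels()[apply(Xte, 1,
                                function(v) which.min(colSums((cent - v)^2)))]
    mean(pred == te$taxon)
  }
  expect_gte(runCentroid(1), 0.9)
  accNull <- runCentroid(0)
  n <- 20 # test records at 30/class under 70/15/15
  expect_lt(abs(accNull - 0.25), 3 * sqrt(0.25 * 0.75 / n) + 1e-9)
})
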