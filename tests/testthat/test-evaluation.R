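randomLabels <- function(n) sample(taxonLevels(), n, replace = TRUE)

test_that("confusion matrices count true/predicted pairs", {
  truth <- c("crocodile", "hyena", "leopard", "lion")
  cmPerfect <- confusionMatrix(truth, truth)
  expect_equal(confusionCounts(cmPerfect), diag(1L, 4),
               ignore_attr = TRUE)
  allLion <- confusionMatrix(truth, rep("lion", 4))
  counts <- confusionCounts(allLion)
  expect_equal(unname(colSums(counts)), c(0L, 0L, 0L, 4L))
  withr::with_seed(1, {
    t2 <- randomLabels(60); p2 <- randomLabels(60)
  })
  perm <- withr::with_seed(2, sample(60))
  expect_identical(confusionCounts(confusionMatrix(t2, p2)),
                   confusionCounts(confusionMatrix(t2[perm], p2[perm])))
  expect_error(confusionMatrix(c("lion", "wolf"), c("lion", "lion")), "wolf")
  expect_error(confusionMatrix(t2, p2[-1]), "equal length")
})

test_that("reports agree with a direct-count oracle on random label sets", {
  withr::with_seed(33, {
    for (rep in 1:200) {
      n <- sample(10:80, 1)
      truth <- randomLabels(n)
      pred <- randomLabels(n)
      r <- classificationReport(confusionMatrix(truth, pred))
      for (k in seq_along(taxonLevels())) {
        tx <- taxonLevels()[k]
        tp <- sum(truth == tx & pred == tx)
        predPos <- sum(pred == tx)
        sup <- sum(truth == tx)
        expect_equal(r@perClass$precision[k],
                     if (predPos > 0) tp / predPos else 0)
        expect_equal(r@perClass$recall[k], if (sup > 0) tp / sup else 0)
        expect_equal(r@perClass$support[k], sup)
      }
      expect_equal(r@accuracy, mean(truth == pred))
    }
  })
})

test_that("accuracy equals support-weighted recall and macro F1 is bounded", {
  withr::with_seed(34, {
    for (rep in 1:100) {
      m <- matrix(rpois(16, 5), 4, 4,
                  dimnames = list(taxonLevels(), taxonLevels()))
      if (sum(m) == 0) next
      cm <- new("ConfusionMatrix", counts = m)
      r <- classificationReport(cm)
      expect_equal(r@accuracy, unname(r@weighted["recall"]), tolerance = 1e-12)
      expect_gte(r@macro[["f1"]], min(r@perClass$f1) - 1e-12)
      expect_lte(r@macro[["f1"]], max(r@perClass$f1) + 1e-12)
    }
  })
})

test_that("zero-division conventions keep degenerate reports valid", {
  truth <- c("crocodile", "crocodile", "hyena", "leopard", "lion")
  pred <- rep("hyena", 5) # crocodile never predicted
  r <- classificationReport(confusionMatrix(truth, pred))
  expect_equal(r@perClass$precision[1], 0)
  expect_equal(r@perClass$recall[1], 0)
  expect_equal(r@perClass$f1[1], 0)
  expect_true(is.finite(r@accuracy))
  expect_error(classificationReport(
    new("ConfusionMatrix",
        counts = matrix(0L, 4, 4,
                        dimnames = list(taxonLevels(), taxonLevels())))),
    "empty")
})

test_that("metric-table reconstruction reproduces published-style rows", {
  # per-class precision/recall/support as printed for the supervised
  # ResNet50 run
  r <- reportFromMetrics(precision = c(0.85, 0.72, 0.94, 0.77),
                         recall = c(0.52, 0.91, 0.82, 0.87),
                         support = c(21, 54, 82, 38))
  expect_equal(roundHalfUp(r@perClass$f1[1], 2), 0.65)
  expect_equal(roundHalfUp(r@macro[["precision"]], 2), 0.82)
  expect_equal(roundHalfUp(r@weighted[["f1"]], 2), 0.82)
  expect_equal(roundHalfUp(r@accuracy, 2), 0.82)
  expect_equal(r@totalSupport, 195L)
})

test_that("rendered tables mirror the published layout and round-trip", {
  r <- reportFromMetrics(precision = c(0.85, 0.72, 0.94, 0.77),
                         recall = c(0.52, 0.91, 0.82, 0.87),
                         support = c(21, 54, 82, 38))
  txt <- renderReport(r, "text")
  expect_length(txt, 8L) # header + 4 classes + accuracy + macro + weighted
  expect_match(txt[6], "^accuracy")
  expect_match(txt[7], "^macro-average\\s+0\\.82")
  tsv <- renderReport(r, "tsv")
  f <- tempfile(fileext = ".tsv")
  writeLines(tsv, f)
  back <- read.delim(f, check.names = FALSE)
  expect_equal(nrow(back), 7L)
  expect_equal(back$precision[1:4],
               as.numeric(sprintf("%.2f", r@perClass$precision)))
  expect_equal(back$`F1 score`[5], roundHalfUp(r@accuracy, 2))
  js <- jsonlite::fromJSON(renderReport(r, "json"))
  expect_setequal(names(js), c("per_class", "accuracy", "macro", "weighted",
                               "total_support"))
  expect_equal(js$accuracy, r@accuracy)
  expect_error(renderReport(r, "xml"), "arg")
})

test_that("half-up rendering handles exact decimal midpoints", {
  expect_equal(roundHalfUp(0.835, 2), 0.84)
  expect_equal(roundHalfUp(0.825, 2), 0.83)
  expect_equal(roundHalfUp(-0.835, 2), -0.84)
  expect_equal(roundHalfUp(2.5, 0), 3)
  expect_equal(roundHalfUp(0.8349, 2), 0.83)
})
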