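# Fake deterministic member predictors: probability mass concentrated on a
# fixed taxon, independent of the image content.
fixedMember <- function(id, regime, acc, onehot) {
  memberModel(id, regime, acc, predictor = function(img) onehot)
}
oneHot <- function(k) {
  p <- numeric(4); p[k] <- 1
  setNames(p, taxonLevels())
}

test_that("accuracy-proportional weights are normalized and scale-invariant", {
  expect_equal(computeWeights(c(3, 3, 3)), rep(1 / 3, 3))
  expect_equal(computeWeights(5), 1)
  # published supervised-regime test accuracies across the five backbones
  accs <- c(82, 83.59, 81.54, 81.03, 82.56)
  w <- computeWeights(accs)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(w[2], 83.59 / 410.72, tolerance = 1e-9)
  expect_equal(computeWeights(accs / 100), w)
  expect_equal(order(w), order(accs))
  expect_error(computeWeights(numeric(0)), "no accuracies")
  expect_error(computeWeights(c(0.5, 0)), "positive")
})

test_that("ensemble prediction is an accuracy-weighted convex soft vote", {
  img <- array(0.5, c(8, 8, 3))
  e5050 <- weightedEnsemble(list(fixedMember("a", "fssl", 0.8, oneHot(1)),
                                 fixedMember("b", "fssl", 0.8, oneHot(2))))
  expect_equal(unname(ensemblePredict(e5050, img)), c(0.5, 0.5, 0, 0))
  e7525 <- weightedEnsemble(list(fixedMember("a", "fssl", 0.75, oneHot(1)),
                                 fixedMember("b", "fssl", 0.25, oneHot(2))))
  expect_equal(unname(ensemblePredict(e7525, img)), c(0.75, 0.25, 0, 0))
  same <- weightedEnsemble(list(fixedMember("a", "fssl", 0.9, oneHot(3)),
                                fixedMember("b", "fssl", 0.4, oneHot(3))))
  expect_equal(unname(ensemblePredict(same, img)), oneHot(3),
               ignore_attr = TRUE)
  # convexity: each coordinate within the member range
  withr::with_seed(12, {
    for (i in 1:20) {
      ms <- lapply(1:3, function(j) {
        p <- runif(4); p <- p / sum(p)
        memberModel(paste0("m", j), "maml", runif(1, 0.5, 0.9),
                    predictor = function(img) p)
      })
      ens <- weightedEnsemble(ms)
      out <- ensemblePredict(ens, img)
      probs <- vapply(ms, function(m) m$predictor(img), numeric(4))
      expect_true(all(out >= apply(probs, 1, min) - 1e-9))
      expect_true(all(out <= apply(probs, 1, max) + 1e-9))
      expect_equal(sum(out), 1, tolerance = 1e-9)
    }
  })
  bad <- weightedEnsemble(list(
    memberModel("broken", "fssl", 0.8,
                predictor = function(img) stop("boom"))))
  expect_error(ensemblePredict(bad, img), "broken")
})

test_that("mixed-regime ensembles are rejected", {
  expect_error(weightedEnsemble(list(fixedMember("a", "fssl", 0.8, oneHot(1)),
                                     fixedMember("b", "maml", 0.8, oneHot(1)))),
               "one regime")
})

test_that("the dual verdict applies the agreement and threshold rule", {
  leo <- function(p) {
    v <- c((1 - p) / 3, (1 - p) / 3, p, (1 - p) / 3)
    setNames(v, taxonLevels())
  }
  # strong agreement on leopard from both regimes
  v1 <- dualVerdict(leo(1.00), leo(0.99))
  expect_equal(v1@status, "reliable")
  expect_equal(v1@bestTaxon, "leopard")
  # agreement but weak probabilities (0.44 / 0.53) stays cautious
  v2 <- dualVerdict(leo(0.44), leo(0.53))
  expect_equal(v2@status, "caution")
  expect_equal(v2@bestTaxon, "leopard")
  expect_equal(v2@fsslProb, 0.44)
  # disagreement at high confidence is never reliable
  hye <- setNames(c(0.05, 0.9, 0.03, 0.02), taxonLevels())
  v3 <- dualVerdict(leo(0.9), hye)
  expect_equal(v3@status, "caution")
  # strictly-greater threshold semantics
  v4 <- dualVerdict(leo(0.7), leo(0.9))
  expect_equal(v4@status, "caution")
  expect_error(dualVerdict(c(0.5, 0.5), leo(0.9)), "probabilities")
})

test_that("raising the threshold never promotes caution to reliable", {
  withr::with_seed(13, {
    for (i in 1:100) {
      pf <- runif(4); pf <- pf / sum(pf)
      pm <- runif(4); pm <- pm / sum(pm)
      lo <- dualVerdict(pf, pm, threshold = 0.4)@status
      hi <- dualVerdict(pf, pm, threshold = 0.8)@status
      expect_false(lo == "caution" && hi == "reliable")
    }
  })
})

test_that("mark classification tabulates both regimes and survives bad rows", {
  fssl <- weightedEnsemble(list(fixedMember("a", "fssl", 0.8, oneHot(3))))
  maml <- weightedEnsemble(list(fixedMember("b", "maml", 0.8, oneHot(3))))
  marks <- list(m1 = array(0.2, c(8, 8, 3)), m2 = array(0.7, c(8, 8, 3)))
  tab <- classifyMarks(marks, fssl, maml)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$regime, rep(c("fssl", "maml"), 2))
  expect_equal(tab$argmax, rep("leopard", 4))
  expect_equal(tab$verdict, rep("reliable", 4))
  expect_identical(tab, classifyMarks(marks, fssl, maml))
  # empty input: empty table, no error
  empty <- classifyMarks(list(), fssl, maml)
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("mark_id", "regime", taxonLevels(), "argmax",
                    "verdict") %in% names(empty)))
  # unreadable path: error recorded per row, processing continues
  mixed <- classifyMarks(c(bad = file.path(tempdir(), "nope.png")),
                         fssl, maml)
  expect_equal(nrow(mixed), 2L)
  expect_true(all(!is.na(mixed$error)))
  f <- tempfile(fileext = ".tsv")
  writeMarksTable(tab, f)
  expect_equal(nrow(read.delim(f)), 4L)
})
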