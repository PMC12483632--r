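test_that("stand-in backbone meets its shape and freezing contract", {
  bb <- buildBackbone("standin", inputSide = 64, seed = 3)
  expect_equal(bb$featureShape, c(8L, 8L, 64L))
  x <- array(runif(64 * 64 * 2 * 3), c(64, 64, 2, 3))
  f1 <- carniMark:::backboneForward(bb, x)
  f2 <- carniMark:::backboneForward(bb, x)
  expect_identical(f1, f2)
  expect_equal(dim(f1), c(8L, 8L, 2L, 64L))
  # same seed rebuild -> identical weights (frozen, reproducible)
  bb2 <- buildBackbone("standin", inputSide = 64, seed = 3)
  expect_identical(bb$params, bb2$params)
  expect_error(buildBackbone("resnet50"), "standin")
  small <- buildBackbone("standin", inputSide = 32, seed = 1)
  expect_equal(small$featureShape, c(4L, 4L, 64L))
})

test_that("squeeze-and-excitation gates behave as multiplicative attention", {
  f <- array(rnorm(6 * 6 * 8), c(6, 6, 8))
  out <- seRecalibrate(f, reduction = 4, seed = 2)
  g <- attr(out, "gates")
  expect_true(all(g > 0 & g < 1))
  expect_equal(dim(out), dim(f))
  # zero input stays zero under any gating
  zf <- array(0, c(4, 4, 8))
  expect_equal(max(abs(seRecalibrate(zf, seed = 5))), 0)
  # saturated gates (huge W2 bias) make the block the identity
  cc <- 8L; cr <- 2L
  p <- list(W1 = matrix(0.1, cc, cr), b1 = numeric(cr),
            W2 = matrix(0, cr, cc), b2 = rep(50, cc))
  out2 <- seRecalibrate(f, reduction = 4, params = p)
  expect_equal(unclass(out2), f, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("head layer inventories match the two architecture variants", {
  cx <- buildHead(c(8L, 8L, 16L), "complex", seed = 1)
  inv <- headLayerInventory(cx)
  expect_equal(inv, c("resblock(dw-sep conv k3 s1 same + SE, 16 ch)",
                      "resblock(dw-sep conv k3 s1 same + SE, 16 ch)",
                      "gap", "dense(512)", "dropout(0.50)", "batch-norm",
                      "softmax(4)"))
  bl <- buildHead(c(8L, 8L, 16L), "baseline", seed = 1)
  expect_equal(headLayerInventory(bl),
               c("conv(512 filters, k3)", "gap", "dense(512)",
                 "dropout(0.50)", "batch-norm", "softmax(4)"))
  expect_error(buildHead(c(8L, 8L, 16L), "fancy"), "arg")
})

test_that("depthwise-separable blocks use fewer parameters than standard conv", {
  cc <- 16L
  cx <- buildHead(c(8L, 8L, cc), "complex", seed = 1)
  p <- cx$net$params
  sepParams <- length(p$res1.sep1.dw) + length(p$res1.sep1.pw) +
    length(p$res1.sep1.b)
  standardParams <- 3 * 3 * cc * cc + cc
  expect_lt(sepParams, standardParams)
})

test_that("residual shortcut is the identity path when the transform is zeroed", {
  cc <- 6L
  head <- buildHead(c(5L, 5L, cc), "complex", dropout = 0, seed = 4)
  params <- head$net$params
  # kill the second separable conv: transform branch output becomes zero
  params$res1.sep2.pw[] <- 0
  params$res1.sep2.b[] <- 0
  x <- array(rnorm(5 * 5 * 3 * cc), c(5, 5, 3, cc))
  ly <- head$net$layers[[1]]
  out <- carniMark:::resSepSEForward(ly, params, x)$y
  expect_equal(out, carniMark:::relu(x))
})

test_that("forward passes produce valid, repeatable probability vectors", {
  model <- buildClassifier("standin", "complex", inputSide = 32, seed = 6)
  imgs <- lapply(1:3, function(i) array(runif(32 * 32 * 3), c(32, 32, 3)))
  p1 <- predictProbs(model, imgs)
  p2 <- predictProbs(model, imgs)
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(3L, 4L))
  expect_equal(colnames(p1), taxonLevels())
  expect_equal(unname(rowSums(p1)), rep(1, 3), tolerance = 1e-6)
  expect_true(all(p1 >= 0))
})

test_that("untrained heads are near-uniform on average over initialisations", {
  feats <- withr::with_seed(9, array(rnorm(4 * 4 * 1 * 8), c(4, 4, 1, 8)))
  probs <- vapply(1:100, function(i) {
    head <- buildHead(c(4L, 4L, 8L), "complex", dropout = 0, seed = i)
    out <- carniMark:::nnForward(head$net, head$net$params, feats,
                                 list(train = FALSE, bnMode = "running"))$out
    drop(carniMark:::softmaxRows(out))
  }, numeric(4))
  expect_lt(max(abs(rowMeans(probs) - 0.25)), 0.06)
})

test_that("head gradients match central finite differences", {
  for (variant in c("complex", "baseline")) {
    head <- buildHead(c(4L, 4L, 6L), variant, dropout = 0, seed = 11)
    net <- head$net
    x <- withr::with_seed(3, array(rnorm(4 * 4 * 5 * 6), c(4, 4, 5, 6)))
    labels <- c(1L, 2L, 3L, 4L, 1L)
    ctx <- list(train = TRUE, bnMode = "batch")
    v <- carniMark:::nnParamVec(net$params)
    lg <- carniMark:::nnLossGrad(net, net$params, x, labels, ctx)
    idx <- withr::with_seed(4, sample(length(v), 50))
    num <- vapply(idx, function(i) {
      e <- numeric(length(v)); e[i] <- 1e-5
      f <- function(vv) {
        p <- carniMark:::nnVecToParams(net$params, vv)
        out <- carniMark:::nnForward(net, p, x, ctx)$out
        carniMark:::softmaxCrossEntropy(out, labels)$loss
      }
      (f(v + e) - f(v - e)) / 2e-5
    }, 0)
    expect_lt(max(abs(num - lg$grads[idx]) / (1e-6 + abs(num))), 1e-4)
  }
})

test_that("classifier manifest records the class ordering and input contract", {
  model <- buildClassifier("standin", "baseline", inputSide = 32, seed = 2)
  expect_equal(model@classLevels, taxonLevels())
  expect_equal(model@backbone$inputSpec$side, 32L)
  expect_equal(model@backbone$inputSpec$normalization, "unit")
  expect_gt(nParameters(model), 0)
  expect_output(show(model), "baseline head")
})
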