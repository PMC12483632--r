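# Meta-learning correctness on analytic toy models, plus loop contracts on
# a tiny bank.

# Quadratic support loss with known minimiser.
quadLossGrad <- function(wstar) {
  function(p) list(loss = 0.5 * sum((p - wstar)^2), grad = p - wstar)
}

# Two-parameter logistic-regression loss closures for one fixed data set.
logisticLossGrad <- function(x, y) {
  function(p, ep = NULL) {
    mu <- stats::plogis(p[1] + p[2] * x)
    list(loss = -mean(y * log(mu) + (1 - y) * log(1 - mu)),
         grad = c(mean(mu - y), mean((mu - y) * x)))
  }
}

test_that("inner adaptation matches closed-form gradient descent", {
  wstar <- c(0.5, 0.25)
  lg <- quadLossGrad(wstar)
  w0 <- c(2, -1)
  a1 <- innerAdapt(w0, lg, innerLr = 0.2, innerSteps = 1L)
  expect_equal(as.vector(a1), w0 + 0.2 * (wstar - w0), tolerance = 1e-10)
  a2 <- innerAdapt(w0, lg, innerLr = 0.2, innerSteps = 2L)
  expect_equal(as.vector(a2), wstar + (1 - 0.2)^2 * (w0 - wstar),
               tolerance = 1e-10)
  # zero learning rate leaves the parameters untouched
  a0 <- innerAdapt(w0, lg, innerLr = 0, innerSteps = 3L)
  expect_equal(as.vector(a0), w0)
  # purely functional: the input vector is not modified
  expect_identical(w0, c(2, -1))
  expect_equal(attr(a2, "lossTrace"),
               c(lg(w0)$loss, lg(a1)$loss), tolerance = 1e-12)
  expect_error(innerAdapt(w0, function(p) list(loss = NaN, grad = p), 0.1),
               "non-finite")
})

test_that("meta-gradient matches finite differences of the composed loss", {
  set.seed(5)
  xs <- rnorm(20); ys <- rbinom(20, 1, stats::plogis(1.5 * xs - 0.5))
  xq <- rnorm(10); yq <- rbinom(10, 1, stats::plogis(1.5 * xq - 0.5))
  sg <- logisticLossGrad(xs, ys)
  qg <- logisticLossGrad(xq, yq)
  p0 <- c(0.3, -0.2)
  innerLr <- 0.1
  for (steps in c(1L, 3L)) {
    mg <- metaGradient(p0, list("ep"), sg, qg, innerLr, steps)
    composed <- function(p) {
      for (s in seq_len(steps)) p <- p - innerLr * sg(p)$grad
      qg(p)$loss
    }
    fd <- vapply(1:2, function(i) {
      e <- c(0, 0); e[i] <- 1e-6
      (composed(p0 + e) - composed(p0 - e)) / 2e-6
    }, 0)
    expect_lt(max(abs(mg$grad - fd) / abs(fd)), 1e-4)
  }
})

test_that("first- and second-order meta-gradients agree as innerLr -> 0", {
  set.seed(6)
  xs <- rnorm(15); ys <- rbinom(15, 1, stats::plogis(xs))
  xq <- rnorm(8); yq <- rbinom(8, 1, stats::plogis(xq))
  sg <- logisticLossGrad(xs, ys)
  qg <- logisticLossGrad(xq, yq)
  p0 <- c(0.4, 0.1)
  fo <- metaGradient(p0, list(1), sg, qg, 1e-6, 1L, firstOrder = TRUE)
  so <- metaGradient(p0, list(1), sg, qg, 1e-6, 1L, firstOrder = FALSE)
  expect_lt(max(abs(fo$grad - so$grad) / abs(so$grad)), 1e-3)
  # zero inner steps with firstOrder reduces to the plain query gradient
  none <- metaGradient(p0, list(1), sg, qg, 0.1, 0L, firstOrder = TRUE)
  expect_equal(none$grad, qg(p0)$grad)
  expect_equal(none$loss, qg(p0)$loss)
})

test_that("meta-steps are deterministic and average across episodes", {
  set.seed(7)
  eps <- lapply(1:3, function(i) {
    x <- rnorm(12); y <- rbinom(12, 1, stats::plogis(x))
    list(sg = logisticLossGrad(x[1:8], y[1:8]),
         qg = logisticLossGrad(x[9:12], y[9:12]))
  })
  sg <- function(p, ep) ep$sg(p)
  qg <- function(p, ep) ep$qg(p)
  cfg <- mamlConfig(innerLr = 0.05, innerSteps = 1L,
                    metaOptimizer = optimizerSpec("adam", 1e-2))
  p0 <- c(0.1, 0.2)
  s1 <- metaStep(p0, eps, cfg, sg, qg)
  s2 <- metaStep(p0, eps, cfg, sg, qg)
  expect_identical(s1$params, s2$params)
  expect_identical(s1$metaLoss, s2$metaLoss)
  # the meta gradient is the mean of per-episode meta gradients
  per <- sapply(eps, function(ep) {
    metaGradient(p0, list(ep), sg, qg, 0.05, 1L)$grad
  })
  expect_equal(s1$metaGrad, rowMeans(per), tolerance = 1e-9)
})

test_that("meta-training adapts a head and leaves the backbone frozen", {
  bank <- tinyBank(n = 14L, side = 32L, seed = 63L)
  sp <- stratifiedSplit(bank, splitSpec(seed = 2))
  model <- buildClassifier("standin", "complex", inputSide = 32, seed = 3)
  cfg <- mamlConfig(innerLr = 0.01, innerSteps = 1L,
                    metaOptimizer = optimizerSpec("adam", 1e-3),
                    shotTask = shotTaskConfig(2L, 4L, qQuery = 2L))
  run <- function() trainMAML(model, sp$train, sp$val, config = cfg,
                              maxEpochs = 3L, metaBatch = 2L,
                              valEpisodes = 2L, seed = 4)
  fit <- run()
  expect_equal(nrow(fit$history), 3L)
  expect_true(all(is.finite(fit$history$valLoss)))
  fit2 <- run()
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$model@backbone$params, model@backbone$params)
  expect_equal(fit$model@info$regime, "maml")
  expect_equal(fit$model@info$innerLr, 0.01)
})
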