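# Minimal neural-network engine.
#
# Tensors are dense double arrays laid out (h, w, batch, channels) -- with
# the channel dimension last, an im2col patch matrix whose rows run over
# (pixel, sample) is a plain reshape, so convolutions reduce to BLAS
# matrix products without any array permutation. Vector activations are
# (batch x features) matrices. Every layer implements init / forward /
# backward by hand. Parameters live in a flat named list of arrays so that
# gradient-based procedures -- in particular the functional inner-loop
# updates of meta-learning -- can treat a whole network as a single
# numeric vector.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

addBias <- function(Y, b) {
  # frozen zero biases (e.g. the stand-in backbone) skip the broadcast add
  if (!any(b != 0)) return(Y)
  Y + rep(b, each = nrow(Y))
}

# ---- conv primitives ------------------------------------------------------

padSame <- function(x, p) {
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  xp[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  xp
}

# im2col for stride-1 'same' convolution: rows ordered (h, w, batch),
# columns ordered (kernel offset major, input channel minor).
im2col <- function(x, k) {
  d <- dim(x)
  if (k == 1L) {
    return(matrix(x, ncol = d[4]))
  }
  .cppIm2col(x, d[1], d[2], d[3], d[4], k)
}

# Scatter-add of im2col gradient back to the input tensor.
col2im <- function(dM, k, dimIn) {
  if (k == 1L) {
    return(array(dM, dimIn))
  }
  .cppCol2im(dM, dimIn[1], dimIn[2], dimIn[3], dimIn[4], k)
}

convForward <- function(x, W, b, k) {
  d <- dim(x)
  M <- im2col(x, k)
  Y <- addBias(M %*% W, b)
  list(y = array(Y, c(d[1], d[2], d[3], ncol(W))), M = M, dimIn = d)
}

convBackward <- function(dy, cache, W, k) {
  cout <- dim(dy)[4]
  dY <- matrix(dy, ncol = cout)
  dW <- crossprod(cache$M, dY)
  db <- colSums(dY)
  dM <- tcrossprod(dY, W)
  dx <- col2im(dM, k, cache$dimIn)
  list(dx = dx, dW = dW, db = db)
}

# Depthwise 3x3 'same' convolution, evaluated as a dense matrix product
# with a structurally masked (block-diagonal per channel) weight matrix
# built from the (9 x channels) kernel; the masked zeros cost BLAS flops
# but avoid R-level slab loops, which dominate otherwise. Wd is
# offset-major to match im2col column ordering.
dwExpand <- function(Wd) {
  cin <- ncol(Wd)
  Wfull <- matrix(0, 9L * cin, cin)
  idx <- cbind(rep(0:8 * cin, each = cin) + seq_len(cin),
               rep(seq_len(cin), 9L))
  Wfull[idx] <- as.vector(t(Wd))
  Wfull
}

dwCollapse <- function(dWfull) {
  cin <- ncol(dWfull)
  idx <- cbind(rep(0:8 * cin, each = cin) + seq_len(cin),
               rep(seq_len(cin), 9L))
  matrix(dWfull[idx], 9L, cin, byrow = TRUE)
}

# ---- separable conv block pieces -----------------------------------------

# Global average pooling: (h, w, n, c) array or (hwn x c) matrix with known
# spatial size -> (n x c) matrix.
gapMat <- function(x, hw = NULL, n = NULL) {
  if (is.matrix(x)) {
    cm <- colMeans(matrix(as.vector(x), nrow = hw))
    return(matrix(cm, nrow = n))
  }
  d <- dim(x)
  matrix(colMeans(matrix(x, nrow = d[1] * d[2])), nrow = d[3])
}

# Broadcast a (batch x channels) matrix over the spatial dims of shape d
# (h, w, n, c layout).
broadcastChan <- function(m, d) {
  array(rep(as.vector(m), each = d[1] * d[2]), d)
}

maxPool2 <- function(x) {
  d <- dim(x)
  .cppMaxPool2(x, d[1], d[2], d[3], d[4])
}

# ---- parameter initialisation --------------------------------------------

heMatrix <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

# ---- layer constructors ---------------------------------------------------

nnConv <- function(name, filters, kernel = 3L) {
  list(type = "conv", name = name, filters = as.integer(filters),
       kernel = as.integer(kernel))
}
nnPool <- function(name) list(type = "pool", name = name)
nnRelu <- function(name) list(type = "relu", name = name)
nnGap <- function(name) list(type = "gap", name = name)
nnDense <- function(name, units) {
  list(type = "dense", name = name, units = as.integer(units))
}
nnDropout <- function(name, p = 0.5) list(type = "dropout", name = name, p = p)
nnBatchNorm <- function(name) list(type = "bn", name = name)
nnResSepSE <- function(name, filters = NULL, seReduction = 16L) {
  list(type = "resSepSE", name = name, filters = filters,
       seReduction = as.integer(seReduction))
}

# ---- build ----------------------------------------------------------------

# Assemble a network: initialises all parameters (He-normal weights, zero
# biases, unit batch-norm scale) and records output shapes layer by layer.
nnBuild <- function(layers, inShape, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    params <- list()
    state <- list()
    shape <- inShape # either c(h, w, c) or a feature count
    for (i in seq_along(layers)) {
      ly <- layers[[i]]
      nm <- ly$name
      if (ly$type == "conv") {
        cin <- shape[3]
        params[[paste0(nm, ".W")]] <- heMatrix(ly$kernel^2 * cin, ly$filters)
        params[[paste0(nm, ".b")]] <- numeric(ly$filters)
        shape <- c(shape[1], shape[2], ly$filters)
      } else if (ly$type == "pool") {
        shape <- c(shape[1] %/% 2L, shape[2] %/% 2L, shape[3])
      } else if (ly$type == "gap") {
        shape <- shape[3]
      } else if (ly$type == "dense") {
        params[[paste0(nm, ".W")]] <- heMatrix(shape[1], ly$units)
        params[[paste0(nm, ".b")]] <- numeric(ly$units)
        shape <- ly$units
      } else if (ly$type == "bn") {
        params[[paste0(nm, ".gamma")]] <- rep(1, shape[1])
        params[[paste0(nm, ".beta")]] <- numeric(shape[1])
        state[[nm]] <- list(mean = numeric(shape[1]), var = rep(1, shape[1]))
      } else if (ly$type == "resSepSE") {
        cin <- shape[3]
        cout <- if (is.null(ly$filters)) cin else as.integer(ly$filters)
        layers[[i]]$filters <- cout
        cr <- max(1L, cout %/% ly$seReduction)
        params[[paste0(nm, ".sep1.dw")]] <- matrix(rnorm(9 * cin, sd = sqrt(2 / 9)), 9, cin)
        params[[paste0(nm, ".sep1.pw")]] <- heMatrix(cin, cout)
        params[[paste0(nm, ".sep1.b")]] <- numeric(cout)
        params[[paste0(nm, ".sep2.dw")]] <- matrix(rnorm(9 * cout, sd = sqrt(2 / 9)), 9, cout)
        params[[paste0(nm, ".sep2.pw")]] <- heMatrix(cout, cout)
        params[[paste0(nm, ".sep2.b")]] <- numeric(cout)
        params[[paste0(nm, ".se.W1")]] <- heMatrix(cout, cr)
        params[[paste0(nm, ".se.b1")]] <- numeric(cr)
        params[[paste0(nm, ".se.W2")]] <- heMatrix(cr, cout)
        params[[paste0(nm, ".se.b2")]] <- numeric(cout)
        if (cin != cout) {
          params[[paste0(nm, ".proj.W")]] <- heMatrix(cin, cout)
          params[[paste0(nm, ".proj.b")]] <- numeric(cout)
        }
        shape <- c(shape[1], shape[2], cout)
      } else if (ly$type %in% c("relu", "dropout")) {
        # shape unchanged
      } else {
        stop("unknown layer type: ", ly$type)
      }
    }
    list(layers = layers, inShape = inShape, outShape = shape,
         params = params, state = state)
  })
}

nnParamVec <- function(params) unlist(params, use.names = FALSE)

nnVecToParams <- function(template, vec) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    len <- length(template[[nm]])
    v <- vec[pos + seq_len(len)]
    dim(v) <- dim(template[[nm]])
    out[[nm]] <- v
    pos <- pos + len
  }
  stopifnot(pos == length(vec))
  out
}

# ---- SE block -------------------------------------------------------------

seForward <- function(x, W1, b1, W2, b2) {
  d <- dim(x)
  s <- gapMat(x)
  z <- addBias(s %*% W1, b1)
  zr <- relu(z)
  g <- sigmoid(addBias(zr %*% W2, b2))
  y <- x * broadcastChan(g, d)
  list(y = y, s = s, z = z, zr = zr, g = g, x = x)
}

seBackward <- function(dy, cache, W1, W2) {
  d <- dim(cache$x)
  hw <- d[1] * d[2]
  dxDirect <- dy * broadcastChan(cache$g, d)
  dg <- matrix(colSums(matrix(dy * cache$x, nrow = hw)), nrow = d[3])
  da <- dg * cache$g * (1 - cache$g)
  dW2 <- crossprod(cache$zr, da)
  db2 <- colSums(da)
  dz <- tcrossprod(da, W2) * (cache$z > 0)
  dW1 <- crossprod(cache$s, dz)
  db1 <- colSums(dz)
  ds <- tcrossprod(dz, W1)
  dx <- dxDirect + broadcastChan(ds, d) / hw
  list(dx = dx, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

# ---- residual separable-SE block -----------------------------------------

# One separable convolution evaluated in matrix form: shared im2col, the
# depthwise kernel as a masked dense product, then the pointwise 1x1
# convolution as a plain matrix product.
sepConvForward <- function(x, Wd, Wp, b) {
  d <- dim(x)
  M <- im2col(x, 3L)
  Ydw <- M %*% dwExpand(Wd)
  Y <- addBias(Ydw %*% Wp, b)
  list(y = array(Y, c(d[1], d[2], d[3], ncol(Wp))), M = M, Ydw = Ydw,
       dimIn = d)
}

sepConvBackward <- function(dy, cache, Wd, Wp) {
  dY <- matrix(dy, ncol = dim(dy)[4])
  dWp <- crossprod(cache$Ydw, dY)
  db <- colSums(dY)
  dYdw <- tcrossprod(dY, Wp)
  dWd <- dwCollapse(crossprod(cache$M, dYdw))
  dM <- tcrossprod(dYdw, dwExpand(Wd))
  dx <- col2im(dM, 3L, cache$dimIn)
  list(dx = dx, dWd = dWd, dWp = dWp, db = db)
}

resSepSEForward <- function(ly, params, x) {
  nm <- ly$name
  p <- function(s) params[[paste0(nm, ".", s)]]
  sep1 <- sepConvForward(x, p("sep1.dw"), p("sep1.pw"), p("sep1.b"))
  r1 <- relu(sep1$y)
  sep2 <- sepConvForward(r1, p("sep2.dw"), p("sep2.pw"), p("sep2.b"))
  se <- seForward(sep2$y, p("se.W1"), p("se.b1"), p("se.W2"), p("se.b2"))
  if (!is.null(p("proj.W"))) {
    proj <- convForward(x, p("proj.W"), p("proj.b"), 1L)
    shortcut <- proj$y
  } else {
    proj <- NULL
    shortcut <- x
  }
  pre <- se$y + shortcut
  list(y = relu(pre), cache = list(sep1 = sep1, sep2 = sep2, se = se,
                                   proj = proj, pre = pre))
}

resSepSEBackward <- function(ly, params, cache, dy) {
  nm <- ly$name
  p <- function(s) params[[paste0(nm, ".", s)]]
  grads <- list()
  dpre <- dy * (cache$pre > 0)
  seb <- seBackward(dpre, cache$se, p("se.W1"), p("se.W2"))
  grads[[paste0(nm, ".se.W1")]] <- seb$dW1
  grads[[paste0(nm, ".se.b1")]] <- seb$db1
  grads[[paste0(nm, ".se.W2")]] <- seb$dW2
  grads[[paste0(nm, ".se.b2")]] <- seb$db2
  sb2 <- sepConvBackward(seb$dx, cache$sep2, p("sep2.dw"), p("sep2.pw"))
  grads[[paste0(nm, ".sep2.dw")]] <- sb2$dWd
  grads[[paste0(nm, ".sep2.pw")]] <- sb2$dWp
  grads[[paste0(nm, ".sep2.b")]] <- sb2$db
  dr1 <- sb2$dx * (cache$sep1$y > 0)
  sb1 <- sepConvBackward(dr1, cache$sep1, p("sep1.dw"), p("sep1.pw"))
  grads[[paste0(nm, ".sep1.dw")]] <- sb1$dWd
  grads[[paste0(nm, ".sep1.pw")]] <- sb1$dWp
  grads[[paste0(nm, ".sep1.b")]] <- sb1$db
  dx <- sb1$dx
  if (!is.null(p("proj.W"))) {
    cbp <- convBackward(dpre, cache$proj, p("proj.W"), 1L)
    grads[[paste0(nm, ".proj.W")]] <- cbp$dW
    grads[[paste0(nm, ".proj.b")]] <- cbp$db
    dx <- dx + cbp$dx
  } else {
    dx <- dx + dpre
  }
  list(dx = dx, grads = grads)
}

# ---- full network forward / backward -------------------------------------

# ctx: list(train = logical, bnMode = "running" | "batch").
# In "running" mode batch statistics are used during training and running
# statistics are updated (classical supervised training); in "batch" mode
# batch statistics are always used and running statistics never updated
# (the transductive convention used inside meta-learning loops).
nnForward <- function(net, params, x, ctx = list(train = FALSE, bnMode = "running")) {
  caches <- vector("list", length(net$layers))
  state <- net$state
  bnEps <- 1e-5
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    nm <- ly$name
    if (ly$type == "conv") {
      cf <- convForward(x, params[[paste0(nm, ".W")]],
                        params[[paste0(nm, ".b")]], ly$kernel)
      caches[[i]] <- cf
      x <- cf$y
    } else if (ly$type == "pool") {
      caches[[i]] <- NULL
      x <- maxPool2(x)
    } else if (ly$type == "relu") {
      caches[[i]] <- list(mask = x > 0)
      x <- relu(x)
    } else if (ly$type == "gap") {
      caches[[i]] <- list(dimIn = dim(x))
      x <- gapMat(x)
    } else if (ly$type == "dense") {
      caches[[i]] <- list(x = x)
      x <- addBias(x %*% params[[paste0(nm, ".W")]],
                   params[[paste0(nm, ".b")]])
    } else if (ly$type == "dropout") {
      if (isTRUE(ctx$train) && ly$p > 0) {
        mask <- (runif(length(x)) >= ly$p) / (1 - ly$p)
        dim(mask) <- dim(x)
        caches[[i]] <- list(mask = mask)
        x <- x * mask
      } else {
        caches[[i]] <- list(mask = NULL)
      }
    } else if (ly$type == "bn") {
      gamma <- params[[paste0(nm, ".gamma")]]
      beta <- params[[paste0(nm, ".beta")]]
      n <- nrow(x)
      useBatch <- isTRUE(ctx$train) || identical(ctx$bnMode, "batch")
      if (useBatch && n > 1L) {
        mu <- colMeans(x)
        va <- colMeans(x^2) - mu^2
        if (isTRUE(ctx$train) && identical(ctx$bnMode, "running")) {
          state[[nm]]$mean <- 0.9 * state[[nm]]$mean + 0.1 * mu
          state[[nm]]$var <- 0.9 * state[[nm]]$var + 0.1 * va
        }
        if (isTRUE(ctx$captureBn)) {
          # write the exact batch statistics into the running slots
          # (post-training calibration pass)
          state[[nm]]$mean <- mu
          state[[nm]]$var <- va
        }
      } else {
        mu <- state[[nm]]$mean
        va <- state[[nm]]$var
      }
      invstd <- 1 / sqrt(va + bnEps)
      xhat <- (x - rep(mu, each = n)) * rep(invstd, each = n)
      caches[[i]] <- list(xhat = xhat, invstd = invstd, batch = useBatch && n > 1L)
      x <- addBias(xhat * rep(gamma, each = n), beta)
    } else if (ly$type == "resSepSE") {
      rf <- resSepSEForward(ly, params, x)
      caches[[i]] <- rf$cache
      x <- rf$y
    }
  }
  list(out = x, caches = caches, state = state)
}

nnBackward <- function(net, params, caches, dOut) {
  grads <- list()
  dx <- dOut
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    nm <- ly$name
    if (ly$type == "conv") {
      cb <- convBackward(dx, caches[[i]], params[[paste0(nm, ".W")]], ly$kernel)
      grads[[paste0(nm, ".W")]] <- cb$dW
      grads[[paste0(nm, ".b")]] <- cb$db
      dx <- cb$dx
    } else if (ly$type == "pool") {
      stop("backward through max-pooling is not needed (frozen backbones only)")
    } else if (ly$type == "relu") {
      dx <- dx * caches[[i]]$mask
    } else if (ly$type == "gap") {
      d <- caches[[i]]$dimIn
      dx <- broadcastChan(dx, d) / (d[1] * d[2])
    } else if (ly$type == "dense") {
      W <- params[[paste0(nm, ".W")]]
      grads[[paste0(nm, ".W")]] <- crossprod(caches[[i]]$x, dx)
      grads[[paste0(nm, ".b")]] <- colSums(dx)
      dx <- tcrossprod(dx, W)
    } else if (ly$type == "dropout") {
      if (!is.null(caches[[i]]$mask)) dx <- dx * caches[[i]]$mask
    } else if (ly$type == "bn") {
      gamma <- params[[paste0(nm, ".gamma")]]
      cc <- caches[[i]]
      n <- nrow(dx)
      grads[[paste0(nm, ".gamma")]] <- colSums(dx * cc$xhat)
      grads[[paste0(nm, ".beta")]] <- colSums(dx)
      dxhat <- dx * rep(gamma, each = n)
      if (cc$batch) {
        t1 <- colSums(dxhat)
        t2 <- colSums(dxhat * cc$xhat)
        dx <- (dxhat - rep(t1 / n, each = n) -
                 cc$xhat * rep(t2 / n, each = n)) * rep(cc$invstd, each = n)
      } else {
        dx <- dxhat * rep(cc$invstd, each = n)
      }
    } else if (ly$type == "resSepSE") {
      rb <- resSepSEBackward(ly, params, caches[[i]], dx)
      grads <- c(grads, rb$grads)
      dx <- rb$dx
    }
  }
  list(dx = dx, grads = grads)
}

softmaxRows <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

# Cross-entropy loss and gradient for integer class labels (1-based).
softmaxCrossEntropy <- function(logits, labels) {
  n <- nrow(logits)
  probs <- softmaxRows(logits)
  idx <- cbind(seq_len(n), labels)
  loss <- -mean(log(pmax(probs[idx], 1e-12)))
  dlogits <- probs
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n, probs = probs)
}

# Loss, flat gradient and probabilities for one labelled batch.
nnLossGrad <- function(net, params, x, labels, ctx) {
  fw <- nnForward(net, params, x, ctx)
  ce <- softmaxCrossEntropy(fw$out, labels)
  bw <- nnBackward(net, params, fw$caches, ce$dlogits)
  g <- params
  for (nm in names(g)) {
    g[[nm]] <- if (is.null(bw$grads[[nm]])) 0 * g[[nm]] else bw$grads[[nm]]
  }
  list(loss = ce$loss, grads = nnParamVec(g), probs = ce$probs,
       state = fw$state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
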