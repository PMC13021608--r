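## The Brain Age Network: a VGG-style 3D backbone with residual units and
## stride-2 convolutional downsampling, ROI-Align pooling over the
## non-lesion bounding box, and a linear regression head. Convolutions are
## evaluated by im2col gathers + BLAS matrix products; gradients are
## computed by hand (the operator set is small: 3x3x3 convolution, ReLU,
## residual add, ROI-Align, linear head).

.convGeomCache <- new.env(parent = emptyenv())

# geometry of a padded 3x3x3 convolution: gather indices into the padded
# volume for each output voxel x kernel offset, plus interior indices
.convGeom <- function(dims, stride) {
  key <- paste(c(dims, stride), collapse = "x")
  if (!is.null(.convGeomCache[[key]])) return(.convGeomCache[[key]])
  dp <- dims + 2L
  dOut <- as.integer(floor((dims - 1) / stride) + 1)
  nOut <- prod(dOut)
  oi <- seq_len(nOut) - 1L
  ox <- (oi %% dOut[1]) * stride
  oy <- ((oi %/% dOut[1]) %% dOut[2]) * stride
  oz <- (oi %/% (dOut[1] * dOut[2])) * stride
  idx <- matrix(0L, nOut, 27L)
  k <- 0L
  for (kz in 0:2) for (ky in 0:2) for (kx in 0:2) {
    k <- k + 1L
    idx[, k] <- 1L + (ox + kx) + dp[1] * ((oy + ky) + dp[2] * (oz + kz))
  }
  ii <- seq_len(prod(dims)) - 1L
  ix <- ii %% dims[1]; iy <- (ii %/% dims[1]) %% dims[2]
  iz <- ii %/% (dims[1] * dims[2])
  interior <- 1L + (ix + 1L) + dp[1] * ((iy + 1L) + dp[2] * (iz + 1L))
  geom <- list(dims = dims, dp = dp, dOut = dOut, nOut = nOut,
               npad = prod(dp), idx = idx, interior = interior,
               stride = stride)
  .convGeomCache[[key]] <- geom
  geom
}

# full gather index for a given channel count, cached alongside the geometry
.convGather <- function(geom, Cin) {
  key <- paste0(paste(c(geom$dims, geom$stride), collapse = "x"), "c", Cin)
  if (is.null(.convGeomCache[[key]])) {
    .convGeomCache[[key]] <- rep(as.vector(geom$idx), times = Cin) +
      rep((seq_len(Cin) - 1L) * geom$npad, each = geom$nOut * 27L)
  }
  .convGeomCache[[key]]
}

# x: [nvox, Cin] matrix; returns y [nOut, Cout] plus cache for backward
.convForward <- function(x, dims, W, b, stride) {
  Cin <- ncol(x)
  geom <- .convGeom(dims, stride)
  Xp <- matrix(0, geom$npad, Cin)
  Xp[geom$interior, ] <- x
  cols <- Xp[.convGather(geom, Cin)]
  dim(cols) <- c(geom$nOut, 27L * Cin)
  y <- cols %*% W
  y <- y + matrix(b, geom$nOut, length(b), byrow = TRUE)
  list(y = y, cols = cols, geom = geom, Cin = Cin)
}

# needInput = FALSE skips the (expensive) scatter back to the layer input;
# used for the stem, whose input is the image itself
.convBackward <- function(dY, cache, W, needInput = TRUE) {
  geom <- cache$geom
  Cin <- cache$Cin
  dW <- crossprod(cache$cols, dY)
  db <- colSums(dY)
  if (!needInput) return(list(dX = NULL, dW = dW, db = db))
  dcols <- tcrossprod(dY, W)
  dXp <- matrix(0, geom$npad, Cin)
  chOff <- (seq_len(Cin) - 1L) * 27L
  for (k in 1:27) {
    dXp[geom$idx[, k], ] <- dXp[geom$idx[, k], ] +
      dcols[, chOff + k, drop = FALSE]
  }
  list(dX = dXp[geom$interior, , drop = FALSE], dW = dW, db = db)
}

.heInit <- function(fanIn, fanOut) {
  matrix(rnorm(fanIn * fanOut, 0, sqrt(2 / fanIn)), fanIn, fanOut)
}

#' Build an untrained Brain Age Network
#'
#' Assembles the layer parameters for `length(convChannels)` stages of 3x3x3
#' convolutions with residual short-circuit connections; a full-resolution
#' stem convolution is followed by stages that each open with a stride-2
#' convolution (the only downsampling in the network) before their residual
#' units. The head ROI-Align-pools the final feature
#' map over the subject's non-lesion bounding box and regresses a single
#' scalar age.
#'
#' @param config a [BanConfig].
#' @param inputShape integer length-3 voxel dimensions the network accepts.
#' @return an untrained [BrainAgeNetwork].
#' @export
buildBan <- function(config, inputShape = c(32L, 32L, 32L)) {
  stopifnot(is(config, "BanConfig"))
  validObject(config)
  inputShape <- as.integer(inputShape)
  ch <- config@convChannels
  nDown <- length(ch)
  minShape <- 2L^nDown
  if (any(inputShape < minShape))
    stop(sprintf(
      "input shape %s too small for %d downsampling stages; minimum admissible shape is %dx%dx%d",
      paste(inputShape, collapse = "x"), nDown, minShape, minShape, minShape))

  set.seed(config@seed)
  params <- list(stem = list(W = .heInit(27L, ch[1]), b = numeric(ch[1])))
  stages <- vector("list", length(ch))
  for (s in seq_along(ch)) {
    st <- list()
    cin <- if (s == 1L) ch[1] else ch[s - 1]
    st$down <- list(W = .heInit(27L * cin, ch[s]), b = numeric(ch[s]))
    st$units <- lapply(seq_len(config@blocksPerStage), function(u) {
      list(conv1 = list(W = .heInit(27L * ch[s], ch[s]), b = numeric(ch[s])),
           conv2 = list(W = .heInit(27L * ch[s], ch[s]), b = numeric(ch[s])))
    })
    stages[[s]] <- st
  }
  params$stages <- stages
  nFc <- prod(config@roiOutputGrid) * ch[length(ch)]
  params$fc <- list(W = rnorm(nFc, 0, 0.01 / sqrt(nFc)), b = 0)
  new("BrainAgeNetwork", params = params, config = config,
      inputShape = inputShape, trained = FALSE)
}

#' Number of learnable parameters of a network
#'
#' @param model a [BrainAgeNetwork].
#' @return integer parameter count (a pure function of the configuration).
#' @export
numParameters <- function(model) {
  stopifnot(is(model, "BrainAgeNetwork"))
  cnt <- 0L
  rec <- function(x) {
    if (is.list(x)) lapply(x, rec)
    else cnt <<- cnt + length(x)
    invisible(NULL)
  }
  rec(model@params)
  cnt
}

# forward pass on one preprocessed sample (3D array + ROI box in input
# coordinates); returns prediction and, optionally, all caches for backward
.banForward <- function(params, config, inputShape, x, roiBoxInput,
                        withCache = FALSE) {
  ch <- config@convChannels
  fm <- matrix(as.vector(x), prod(inputShape), 1L)
  dims <- inputShape
  caches <- list()

  cf <- .convForward(fm, dims, params$stem$W, params$stem$b, 1L)
  a <- pmax(cf$y, 0)
  if (withCache) caches$stem <- list(conv = cf, mask = cf$y > 0)
  fm <- a

  for (s in seq_along(ch)) {
    st <- params$stages[[s]]
    sc <- list()
    cf <- .convForward(fm, dims, st$down$W, st$down$b, 2L)
    dims <- cf$geom$dOut
    a <- pmax(cf$y, 0)
    if (withCache) sc$down <- list(conv = cf, mask = cf$y > 0)
    fm <- a
    sc$units <- vector("list", length(st$units))
    for (u in seq_along(st$units)) {
      un <- st$units[[u]]
      c1 <- .convForward(fm, dims, un$conv1$W, un$conv1$b, 1L)
      a1 <- pmax(c1$y, 0)
      c2 <- .convForward(a1, dims, un$conv2$W, un$conv2$b, 1L)
      pre <- c2$y + fm                      # short-circuit connection
      out <- pmax(pre, 0)
      if (withCache)
        sc$units[[u]] <- list(c1 = c1, m1 = c1$y > 0, c2 = c2,
                              mOut = pre > 0)
      fm <- out
    }
    if (withCache) caches$stages[[s]] <- sc
  }

  strideTot <- 2L^length(ch)
  boxFeat <- (roiBoxInput + 0.5) / strideTot - 0.5
  P <- .roiAlignMatrix(dims, boxFeat, config@roiOutputGrid,
                       config@samplesPerCell)
  pooled <- as.matrix(P %*% fm)
  flat <- as.vector(pooled)
  pred <- sum(flat * params$fc$W) + params$fc$b

  if (!withCache) return(list(pred = pred))
  caches$P <- P
  caches$flat <- flat
  caches$dimsFinal <- dims
  caches$nchFinal <- ncol(fm)
  list(pred = pred, caches = caches)
}

# backward pass; dPred is the scalar loss gradient wrt the prediction.
# Returns gradients with the same structure as params.
.banBackward <- function(params, config, caches, dPred) {
  ch <- config@convChannels
  g <- list()
  g$fc <- list(W = caches$flat * dPred, b = dPred)
  dPooled <- matrix(params$fc$W * dPred, ncol = caches$nchFinal)
  dFm <- as.matrix(Matrix::crossprod(caches$P, dPooled))

  g$stages <- vector("list", length(ch))
  for (s in rev(seq_along(ch))) {
    sc <- caches$stages[[s]]
    gs <- list(units = vector("list", length(sc$units)))
    for (u in rev(seq_along(sc$units))) {
      cu <- sc$units[[u]]
      dPre <- dFm * cu$mOut
      bw2 <- .convBackward(dPre, cu$c2, params$stages[[s]]$units[[u]]$conv2$W)
      dA1 <- bw2$dX * cu$m1
      bw1 <- .convBackward(dA1, cu$c1, params$stages[[s]]$units[[u]]$conv1$W)
      gs$units[[u]] <- list(conv1 = list(W = bw1$dW, b = bw1$db),
                            conv2 = list(W = bw2$dW, b = bw2$db))
      dFm <- bw1$dX + dPre                  # shortcut gradient
    }
    dDown <- dFm * sc$down$mask
    bwd <- .convBackward(dDown, sc$down$conv, params$stages[[s]]$down$W)
    gs$down <- list(W = bwd$dW, b = bwd$db)
    dFm <- bwd$dX
    g$stages[[s]] <- gs
  }
  dStem <- dFm * caches$stem$mask
  bws <- .convBackward(dStem, caches$stem$conv, params$stem$W,
                       needInput = FALSE)
  g$stem <- list(W = bws$dW, b = bws$db)
  g
}

## ---- structured-parameter arithmetic (Adam) --------------------------------

.leafMap2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    nmA <- names(a)
    for (i in seq_along(a)) {
      if (is.null(a[[i]])) next
      bi <- if (!is.null(nmA) && nzchar(nmA[i]) && !is.null(names(b)))
        b[[nmA[i]]] else b[[i]]
      out[[i]] <- .leafMap2(a[[i]], bi, f)
    }
    out
  } else f(a, b)
}

.leafZero <- function(a) {
  if (is.list(a)) lapply(a, function(e) if (is.null(e)) NULL else .leafZero(e))
  else a * 0
}

.adamInit <- function(params) {
  list(m = .leafZero(params), v = .leafZero(params), t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1, beta2,
                      weightDecay, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .leafMap2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- .leafMap2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- .leafMap2(state$m, state$v, function(m, v)
    (m / c1) / (sqrt(v / c2) + eps))
  params <- .leafMap2(params, upd, function(p, u)
    p - lr * (u + weightDecay * p))
  list(params = params, state = state)
}
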