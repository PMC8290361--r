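# The convolutional pair classifier. Inputs are flattened 3-channel
# D x K pair tensors in channel-major order: entry (c, h, w) sits at
# column (c-1)*H*W + (h-1)*W + w. Convolutions are evaluated as matrix
# products via precomputed im2col gather indices; max-pooling uses
# ceil-mode non-overlapping windows so the 5 x 5 spatial grid survives
# two conv+pool blocks. Everything is deterministic given the seed.

#' CNN architecture specification
#'
#' Three named presets over the 3 x D x K pair tensor:
#' \describe{
#'   \item{A (default)}{conv(16, 3x3, same, tanh) -> maxpool(2x2,
#'     stride 2, ceil) -> conv(32, 3x3, same, tanh) -> maxpool(2x2) ->
#'     dense(64, tanh) -> dense(1, sigmoid). Two conv+pool blocks.}
#'   \item{B}{a shallower variant with a single conv+pool block.}
#'   \item{C}{as A but with enlarged 5x5 kernels.}
#' }
#' Hidden activations are tanh; the output layer is one sigmoid unit,
#' so scores always lie in (0, 1).
#'
#' @param preset `"A"`, `"B"` or `"C"`.
#' @param inputDim integer(3): channels, height, width.
#' @return an architecture list consumed by [buildCnn()].
#' @export
cnnArchitecture <- function(preset = c("A", "B", "C"),
                            inputDim = c(3L, 5L, 5L)) {
  preset <- match.arg(preset)
  inputDim <- as.integer(inputDim)
  stopifnot(length(inputDim) == 3L, all(inputDim >= 1L))
  kern <- if (preset == "C") c(5L, 5L) else c(3L, 3L)
  blocks <- list(
    list(type = "conv", filters = 16L, kernel = kern,
         activation = "tanh"),
    list(type = "pool", size = c(2L, 2L), stride = c(2L, 2L)))
  if (preset != "B") {
    blocks <- c(blocks, list(
      list(type = "conv", filters = 32L, kernel = kern,
           activation = "tanh"),
      list(type = "pool", size = c(2L, 2L), stride = c(2L, 2L))))
  }
  layers <- c(blocks, list(
    list(type = "dense", units = 64L, activation = "tanh"),
    list(type = "dense", units = 1L, activation = "sigmoid")))
  list(preset = preset, inputDim = inputDim, layers = layers)
}

# im2col gather indices for a same-padded convolution; dummy index
# points at an appended zero column
.convIndices <- function(C, H, W, KH, KW) {
  padH <- (KH - 1L) %/% 2L
  padW <- (KW - 1L) %/% 2L
  HW <- H * W
  CKK <- C * KH * KW
  dummy <- C * HW + 1L
  colIdx <- integer(HW * CKK)
  e <- 0L
  for (h in seq_len(H)) for (w in seq_len(W)) {
    for (c in seq_len(C)) for (kh in seq_len(KH)) for (kw in seq_len(KW)) {
      e <- e + 1L
      ih <- h + kh - 1L - padH
      iw <- w + kw - 1L - padW
      colIdx[e] <- if (ih >= 1L && ih <= H && iw >= 1L && iw <= W)
        (c - 1L) * HW + (ih - 1L) * W + iw else dummy
    }
  }
  keep <- which(colIdx != dummy)
  Tmat <- Matrix::sparseMatrix(i = keep, j = colIdx[keep], x = 1,
                               dims = c(HW * CKK, C * HW))
  list(colIdx = colIdx, Tmat = Tmat)
}

# per-window input positions for ceil-mode max pooling (NA-padded)
.poolIndices <- function(C, H, W, sh, sw, th, tw) {
  oH <- as.integer(ceiling(H / th))
  oW <- as.integer(ceiling(W / tw))
  if (oH < 1L || oW < 1L)
    stop("pooling reduces a spatial dimension below 1", call. = FALSE)
  HW <- H * W
  oHW <- oH * oW
  maxWin <- sh * sw
  spIdx <- matrix(NA_integer_, nrow = oHW, ncol = maxWin)
  for (oh in seq_len(oH)) for (ow in seq_len(oW)) {
    q <- (oh - 1L) * oW + ow
    hs <- ((oh - 1L) * th + 1L):min(H, (oh - 1L) * th + sh)
    ws <- ((ow - 1L) * tw + 1L):min(W, (ow - 1L) * tw + sw)
    cells <- as.vector(outer(ws, (hs - 1L) * W, "+"))
    spIdx[q, seq_along(cells)] <- cells
  }
  dummy <- C * HW + 1L
  colmMat <- matrix(dummy, nrow = C * oHW, ncol = maxWin)
  for (m in seq_len(maxWin)) {
    v <- spIdx[, m]
    full <- as.vector(outer(v, (seq_len(C) - 1L) * HW, "+"))
    full[is.na(full)] <- dummy
    colmMat[, m] <- full
  }
  list(colmMat = colmMat, oH = oH, oW = oW, maxWin = maxWin)
}

.glorot <- function(nr, nc, fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# run fn with a private, restored RNG stream
.withSeed <- function(seed, fn) {
  hasSeed <- exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE)
  old <- if (hasSeed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Build (initialize) the CNN pair scorer
#'
#' Compiles the architecture into layer states with precomputed
#' convolution gather/scatter indices and Glorot-uniform initial
#' weights. Initialization is fully deterministic given `seed`: two
#' builds with the same seed have identical weights.
#'
#' @param arch architecture from [cnnArchitecture()].
#' @param seed integer RNG seed for weight initialization.
#' @return an untrained [CnnModel-class].
#' @export
buildCnn <- function(arch = cnnArchitecture(), seed = 1L) {
  seed <- as.integer(seed)
  dims <- arch$inputDim
  C <- dims[1]; H <- dims[2]; W <- dims[3]
  layers <- .withSeed(seed, function() {
    out <- vector("list", length(arch$layers))
    for (i in seq_along(arch$layers)) {
      sp <- arch$layers[[i]]
      if (sp$type == "conv") {
        KH <- sp$kernel[1]; KW <- sp$kernel[2]; Fo <- sp$filters
        idx <- .convIndices(C, H, W, KH, KW)
        CKK <- C * KH * KW
        out[[i]] <- list(
          type = "conv", activation = sp$activation,
          W = .glorot(CKK, Fo, CKK, Fo * KH * KW), b = numeric(Fo),
          colIdx = idx$colIdx, Tmat = idx$Tmat,
          C = C, HW = H * W, filters = Fo, CKK = CKK)
        C <- Fo
      } else if (sp$type == "pool") {
        pidx <- .poolIndices(C, H, W, sp$size[1], sp$size[2],
                             sp$stride[1], sp$stride[2])
        out[[i]] <- list(
          type = "pool", colmMat = pidx$colmMat, C = C,
          inWidth = C * H * W, oHW = pidx$oH * pidx$oW,
          maxWin = pidx$maxWin)
        H <- pidx$oH; W <- pidx$oW
      } else if (sp$type == "dense") {
        inDim <- C * H * W
        out[[i]] <- list(
          type = "dense", activation = sp$activation,
          W = .glorot(inDim, sp$units, inDim, sp$units),
          b = numeric(sp$units))
        C <- sp$units; H <- 1L; W <- 1L
      } else stop(sprintf("unknown layer type '%s'", sp$type),
                  call. = FALSE)
    }
    out
  })
  last <- layers[[length(layers)]]
  if (!(last$type == "dense" && ncol(last$W) == 1L &&
        last$activation == "sigmoid"))
    stop("output layer must be a single sigmoid unit", call. = FALSE)
  new("CnnModel", arch = arch, layers = layers,
      inputDim = arch$inputDim, seed = seed, trained = FALSE,
      history = numeric())
}

# forward pass over a batch of flattened tensors; returns probabilities
# and per-layer caches for backprop
.cnnForward <- function(layers, x) {
  n <- nrow(x)
  caches <- vector("list", length(layers))
  h <- x
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      HW <- ly$HW; CKK <- ly$CKK; Fo <- ly$filters
      X0 <- cbind(h, 0)
      M <- X0[, ly$colIdx, drop = FALSE]
      P <- matrix(aperm(array(M, c(n, CKK, HW)), c(1, 3, 2)),
                  nrow = n * HW, ncol = CKK)
      Z <- P %*% ly$W
      Z <- Z + rep(ly$b, each = nrow(Z))
      out <- matrix(array(Z, c(n, HW, Fo)), nrow = n)
      act <- tanh(out)
      caches[[i]] <- list(P = P, act = act)
      h <- act
    } else if (ly$type == "pool") {
      cm <- ly$colmMat
      X0 <- cbind(h, -Inf)
      best <- X0[, cm[, 1], drop = FALSE]
      bestPos <- matrix(cm[, 1], n, nrow(cm), byrow = TRUE)
      if (ly$maxWin > 1L) for (m in 2:ly$maxWin) {
        cand <- X0[, cm[, m], drop = FALSE]
        upd <- cand > best
        if (any(upd)) {
          best[upd] <- cand[upd]
          posm <- matrix(cm[, m], n, nrow(cm), byrow = TRUE)
          bestPos[upd] <- posm[upd]
        }
      }
      caches[[i]] <- list(bestPos = bestPos)
      h <- best
    } else { # dense
      z <- h %*% ly$W
      z <- z + rep(ly$b, each = n)
      act <- switch(ly$activation,
                    tanh = tanh(z),
                    sigmoid = stats::plogis(z),
                    z)
      caches[[i]] <- list(input = h, act = act)
      h <- act
    }
  }
  list(prob = as.vector(h), caches = caches)
}

# backprop; delta is the gradient wrt the OUTPUT layer pre-activation
# (sigmoid folded into the loss gradient). Returns per-layer gradients
# and the gradient wrt the input batch.
.cnnBackward <- function(layers, caches, delta, n) {
  grads <- vector("list", length(layers))
  d <- delta # starts as dL/dz of the output layer
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    ch <- caches[[i]]
    if (ly$type == "dense") {
      if (ly$activation == "tanh")
        d <- d * (1 - ch$act^2)
      # for the sigmoid output layer d is already the pre-activation
      # gradient
      grads[[i]] <- list(W = crossprod(ch$input, d), b = colSums(d))
      d <- d %*% t(ly$W)
    } else if (ly$type == "pool") {
      dX <- matrix(0, n, ly$inWidth + 1L)
      idx <- (as.vector(ch$bestPos) - 1L) * n +
        rep(seq_len(n), times = ncol(ch$bestPos))
      dX[idx] <- as.vector(d)
      d <- dX[, seq_len(ly$inWidth), drop = FALSE]
    } else { # conv
      HW <- ly$HW; CKK <- ly$CKK; Fo <- ly$filters
      d <- d * (1 - ch$act^2) # tanh derivative
      dZ <- matrix(array(d, c(n, HW, Fo)), nrow = n * HW, ncol = Fo)
      grads[[i]] <- list(W = crossprod(ch$P, dZ), b = colSums(dZ))
      dP <- dZ %*% t(ly$W)
      dM <- matrix(aperm(array(dP, c(n, HW, CKK)), c(1, 3, 2)),
                   nrow = n, ncol = CKK * HW)
      d <- as.matrix(dM %*% ly$Tmat)
    }
  }
  list(grads = grads, dInput = d)
}

#' Binary cross-entropy loss
#'
#' Mean over samples of `-(y log(yhat) + (1 - y) log(1 - yhat))`.
#' Predictions are clamped to `[1e-7, 1 - 1e-7]` before the logarithm,
#' so the loss at predictions equal to their labels is 0 up to the
#' clamping tolerance (about 1e-7 per sample) and the loss is finite
#' for boundary predictions.
#'
#' @param predictions numeric vector of predicted probabilities.
#' @param labels numeric/integer vector of 0/1 labels, same length.
#' @return non-negative scalar loss.
#' @examples
#' bceLoss(0.5, 1) # log(2)
#' @export
bceLoss <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("predictions and labels must have equal length", call. = FALSE)
  if (!all(labels %in% c(0, 1)))
    stop("labels must be 0 or 1", call. = FALSE)
  p <- pmin(pmax(predictions, 1e-7), 1 - 1e-7)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Training configuration
#'
#' Optimizer hyperparameters and the graph-convolution training mode.
#' Defaults: Adam, learning rate 1e-3, 100 epochs, batch size 32.
#'
#' @param lr positive learning rate.
#' @param epochs non-negative integer; 0 leaves the model at its
#'   initialization.
#' @param batchSize positive integer.
#' @param seed integer RNG seed governing shuffling (and, in the joint
#'   pipeline, GCN weight initialization).
#' @param optimizer `"adam"` or `"sgd"`.
#' @param gcnMode `"trained"` (GCN weights optimized jointly with the
#'   CNN), `"fixed"` (deterministic identity-weight smoothing) or
#'   `"none"` (no smoothing).
#' @param gcnActivation activation of the trained GCN layer.
#' @param archPreset CNN preset, see [cnnArchitecture()].
#' @return a `trainConfig` list.
#' @export
trainConfig <- function(lr = 1e-3, epochs = 100L, batchSize = 32L,
                        seed = 1L, optimizer = c("adam", "sgd"),
                        gcnMode = c("trained", "fixed", "none"),
                        gcnActivation = c("relu", "identity"),
                        archPreset = "A") {
  optimizer <- match.arg(optimizer)
  gcnMode <- match.arg(gcnMode)
  gcnActivation <- match.arg(gcnActivation)
  stopifnot(lr > 0, epochs >= 0, batchSize >= 1)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 seed = as.integer(seed), optimizer = optimizer,
                 gcnMode = gcnMode, gcnActivation = gcnActivation,
                 archPreset = archPreset),
            class = "trainConfig")
}

.adamInit <- function(param) list(m = param * 0, v = param * 0)

.adamStep <- function(param, grad, state, lr, t,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$m <- b1 * state$m + (1 - b1) * grad
  state$v <- b2 * state$v + (1 - b2) * grad^2
  mhat <- state$m / (1 - b1^t)
  vhat <- state$v / (1 - b2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Train the CNN on flattened pair tensors
#'
#' Mini-batch training with mean-reduced binary cross-entropy; the
#' sigmoid output and the loss gradient are fused for numerical
#' stability. Deterministic given `cfg$seed`: shuffling is the only
#' source of randomness.
#'
#' @param model an untrained or trained [CnnModel-class].
#' @param x numeric n x (C*H*W) matrix of flattened pair tensors.
#' @param labels 0/1 vector of length n; both classes must be present.
#' @param cfg a [trainConfig()].
#' @return the fitted [CnnModel-class] with per-epoch mean loss in
#'   `@history`.
#' @export
trainCnn <- function(model, x, labels, cfg = trainConfig()) {
  stopifnot(is(model, "CnnModel"))
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(labels) != n)
    stop("labels must match the number of tensors", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("training set must contain both classes", call. = FALSE)
  if (ncol(x) != prod(model@inputDim))
    stop(sprintf("tensors have %d values but model expects %d",
                 ncol(x), prod(model@inputDim)), call. = FALSE)
  if (cfg$epochs == 0L) return(model)

  layers <- model@layers
  history <- numeric(cfg$epochs)
  runTraining <- function() {
      states <- lapply(layers, function(ly) {
        if (ly$type %in% c("conv", "dense"))
          list(W = .adamInit(ly$W), b = .adamInit(ly$b))
        else NULL
      })
      t <- 0L
      for (ep in seq_len(cfg$epochs)) {
        perm <- sample.int(n)
        epochLoss <- 0
        for (bStart in seq(1L, n, by = cfg$batchSize)) {
          bIdx <- perm[bStart:min(n, bStart + cfg$batchSize - 1L)]
          xb <- x[bIdx, , drop = FALSE]
          yb <- labels[bIdx]
          fw <- .cnnForward(layers, xb)
          epochLoss <- epochLoss + bceLoss(fw$prob, yb) * length(bIdx)
          dz <- matrix((fw$prob - yb) / length(bIdx), ncol = 1)
          bw <- .cnnBackward(layers, fw$caches, dz, length(bIdx))
          t <- t + 1L
          for (i in seq_along(layers)) {
            if (is.null(bw$grads[[i]])) next
            if (cfg$optimizer == "adam") {
              up <- .adamStep(layers[[i]]$W, bw$grads[[i]]$W,
                              states[[i]]$W, cfg$lr, t)
              layers[[i]]$W <<- up$param; states[[i]]$W <- up$state
              up <- .adamStep(layers[[i]]$b, as.vector(bw$grads[[i]]$b),
                              states[[i]]$b, cfg$lr, t)
              layers[[i]]$b <<- up$param; states[[i]]$b <- up$state
            } else {
              layers[[i]]$W <<- layers[[i]]$W - cfg$lr * bw$grads[[i]]$W
              layers[[i]]$b <<- layers[[i]]$b -
                cfg$lr * as.vector(bw$grads[[i]]$b)
            }
          }
        }
        history[ep] <<- epochLoss / n
      }
  }
  .withSeed(cfg$seed, runTraining)
  new("CnnModel", arch = model@arch, layers = layers,
      inputDim = model@inputDim, seed = model@seed, trained = TRUE,
      history = c(model@history, history))
}

#' Score flattened pair tensors with a fitted CNN
#'
#' @param model a [CnnModel-class].
#' @param x numeric n x (C*H*W) matrix.
#' @return numeric vector of n scores in (0, 1); deterministic given
#'   the model.
#' @export
predictCnn <- function(model, x) {
  stopifnot(is(model, "CnnModel"))
  x <- as.matrix(x)
  if (ncol(x) != prod(model@inputDim))
    stop(sprintf("tensors have %d values but model expects %d",
                 ncol(x), prod(model@inputDim)), call. = FALSE)
  .cnnForward(model@layers, x)$prob
}
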