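# Disease-gene pair scoring: assemble the 3-channel D x K pair tensor
# (GWAS layer, eQTL layer, tiled disease-similarity row) and train or
# apply the CNN, optionally optimizing a graph-convolution weight
# matrix jointly with the CNN against the classification loss.

#' Assemble the 3-channel pair tensor for one disease-gene pair
#'
#' Channel 1 is the gene's GWAS D x K block (rows = diseases in panel
#' order, columns = top-SNP rank), channel 2 the eQTL block, and
#' channel 3 the target disease's 1 x D similarity row replicated K
#' times as rows (columns ordered by the panel's disease order). The
#' square-image reading requires D = K.
#'
#' @param geneFeature either a 2 x D x K array (see
#'   [geneFeatureArray()]) or its length-2DK layer-major flattening.
#' @param similarity a [DiseaseSimilarity-class].
#' @param targetDisease disease id of the pair.
#' @return numeric 3 x D x K array.
#' @export
assemblePairTensor <- function(geneFeature, similarity, targetDisease) {
  stopifnot(is(similarity, "DiseaseSimilarity"))
  D <- length(similarity@diseaseIds)
  if (is.null(dim(geneFeature))) {
    K <- length(geneFeature) / (2 * D)
    if (K != floor(K))
      stop("gene feature length is not 2*D*K", call. = FALSE)
    geneFeature <- unflattenFeature(geneFeature, D, as.integer(K))
  }
  dims <- dim(geneFeature)
  if (length(dims) != 3L || dims[1] != 2L || dims[2] != D)
    stop("gene feature must be a 2 x D x K block", call. = FALSE)
  K <- dims[3]
  if (D != K)
    stop(sprintf(
      "square pair tensor requires D = K (got D = %d, K = %d)", D, K),
      call. = FALSE)
  di <- match(targetDisease, similarity@diseaseIds)
  if (is.na(di))
    stop(sprintf("unknown disease '%s'", targetDisease), call. = FALSE)
  tensor <- array(0, dim = c(3L, D, K))
  tensor[1, , ] <- geneFeature[1, , ]
  tensor[2, , ] <- geneFeature[2, , ]
  tensor[3, , ] <- matrix(similarity@values[di, ], nrow = D, ncol = K,
                          byrow = TRUE)
  tensor
}

# K-fold tiling of each disease's similarity row: row d is
# rep(S[d, ], K), i.e. the flattened third channel for target disease d
.simTileMatrix <- function(similarity, K) {
  S <- similarity@values
  t(apply(S, 1, rep, times = K))
}

# flattened pair inputs for a batch of (disease, gene) pairs given the
# embedded gene feature matrix H (N x 2DK) and the tiled similarity
.pairInputs <- function(H, simTile, geneIdx, diseaseIdx) {
  cbind(H[geneIdx, , drop = FALSE],
        simTile[diseaseIdx, , drop = FALSE])
}

.checkPairs <- function(pairs, geneIds, diseaseIds) {
  gi <- match(pairs$gene_id, geneIds)
  di <- match(pairs$disease_id, diseaseIds)
  if (anyNA(gi))
    stop(sprintf("pair(s) reference unknown gene(s): %s",
                 paste(unique(pairs$gene_id[is.na(gi)]), collapse = ", ")),
         call. = FALSE)
  if (anyNA(di))
    stop(sprintf("pair(s) reference unknown disease(s): %s",
                 paste(unique(pairs$disease_id[is.na(di)]),
                       collapse = ", ")), call. = FALSE)
  list(gene = gi, disease = di)
}

# residual-style deterministic GCN weight initialization: identity plus
# small Gaussian noise, so training starts from near-pure smoothing
.initGcnWeights <- function(Fdim, seed) {
  .withSeed(seed + 1L, function()
    diag(Fdim) + matrix(stats::rnorm(Fdim * Fdim, sd = 0.01),
                        Fdim, Fdim))
}

#' Train the disease-gene pair scorer
#'
#' Builds the propagation operator from the gene network, embeds the
#' gene features, assembles a pair tensor per labeled (disease, gene)
#' pair and trains the CNN. In `gcnMode = "trained"` (default) a single
#' graph-convolution weight matrix (F x F, F = 2*D*K, ReLU) is
#' optimized jointly with the CNN against the same binary cross-entropy
#' loss; in `"fixed"` mode the features are smoothed once with identity
#' weights and identity activation (fully deterministic); `"none"`
#' skips smoothing.
#'
#' @param features a raw [GeneFeatureSet-class].
#' @param network a [GeneNetwork-class] whose gene order equals the
#'   feature set's.
#' @param similarity a [DiseaseSimilarity-class] over the same disease
#'   panel.
#' @param pairs data.frame with columns `disease_id`, `gene_id`,
#'   `label` (0/1); both classes required.
#' @param cfg a [trainConfig()].
#' @return a fitted [PairModel-class].
#' @export
trainPairModel <- function(features, network, similarity, pairs,
                           cfg = trainConfig()) {
  stopifnot(is(features, "GeneFeatureSet"), is(network, "GeneNetwork"),
            is(similarity, "DiseaseSimilarity"))
  if (!identical(features@geneIds, network@geneIds))
    stop("feature and network gene orders differ", call. = FALSE)
  if (!identical(features@diseaseIds, similarity@diseaseIds))
    stop("feature and similarity disease panels differ", call. = FALSE)
  D <- length(features@diseaseIds)
  K <- features@topK
  if (D != K)
    stop("pair tensors require D = K", call. = FALSE)
  if (!all(c("disease_id", "gene_id", "label") %in% names(pairs)))
    stop("pairs must have columns disease_id, gene_id, label",
         call. = FALSE)
  if (length(unique(pairs$label)) < 2L)
    stop("training set must contain both classes", call. = FALSE)

  idx <- .checkPairs(pairs, features@geneIds, features@diseaseIds)
  L <- buildPropagationMatrix(network)
  LX <- as.matrix(L %*% features@values)
  simTile <- .simTileMatrix(similarity, K)
  Fdim <- ncol(features@values)
  labels <- as.numeric(pairs$label)
  n <- nrow(pairs)

  cnn <- buildCnn(cnnArchitecture(cfg$archPreset, c(3L, D, K)),
                  seed = cfg$seed)

  if (cfg$gcnMode != "trained") {
    H <- switch(cfg$gcnMode, fixed = LX, none = features@values)
    x <- .pairInputs(H, simTile, idx$gene, idx$disease)
    cnn <- trainCnn(cnn, x, labels, cfg)
    return(new("PairModel", cnn = cnn, gcnMode = cfg$gcnMode,
               gcnWeights = matrix(numeric(), 0, 0),
               gcnActivation = "identity",
               diseaseIds = features@diseaseIds, topK = K,
               config = unclass(cfg)))
  }

  # joint training: the CNN gradient wrt its gene-feature channels is
  # pushed back through H = act(LX %*% Wg) into Wg. Only the rows of H
  # belonging to the batch genes are needed per step.
  Wg <- .initGcnWeights(Fdim, cfg$seed)
  act <- cfg$gcnActivation
  layers <- cnn@layers
  history <- numeric(cfg$epochs)
  geneCols <- seq_len(Fdim)

  runJoint <- function() {
    states <- lapply(layers, function(ly) {
      if (ly$type %in% c("conv", "dense"))
        list(W = .adamInit(ly$W), b = .adamInit(ly$b))
      else NULL
    })
    gState <- .adamInit(Wg)
    t <- 0L
    for (ep in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      epochLoss <- 0
      for (bStart in seq(1L, n, by = cfg$batchSize)) {
        bIdx <- perm[bStart:min(n, bStart + cfg$batchSize - 1L)]
        gIdx <- idx$gene[bIdx]
        dIdx <- idx$disease[bIdx]
        yb <- labels[bIdx]
        m <- length(bIdx)
        uGenes <- unique(gIdx)
        LXu <- LX[uGenes, , drop = FALSE]
        preU <- LXu %*% Wg
        Hu <- if (act == "relu") pmax(preU, 0) else preU
        rowOf <- match(gIdx, uGenes)
        xb <- cbind(Hu[rowOf, , drop = FALSE],
                    simTile[dIdx, , drop = FALSE])
        fw <- .cnnForward(layers, xb)
        epochLoss <- epochLoss + bceLoss(fw$prob, yb) * m
        dz <- matrix((fw$prob - yb) / m, ncol = 1)
        bw <- .cnnBackward(layers, fw$caches, dz, m)
        # gradient wrt the embedded gene rows, accumulated over
        # duplicate genes in the batch
        dHpairs <- bw$dInput[, geneCols, drop = FALSE]
        dHu <- rowsum(dHpairs, group = rowOf, reorder = FALSE)
        ord <- as.integer(rownames(dHu))
        dHu <- dHu[order(ord), , drop = FALSE]
        if (act == "relu") dHu <- dHu * (preU > 0)
        gradWg <- crossprod(LXu, dHu)
        t <- t + 1L
        for (i in seq_along(layers)) {
          if (is.null(bw$grads[[i]])) next
          up <- .adamStep(layers[[i]]$W, bw$grads[[i]]$W,
                          states[[i]]$W, cfg$lr, t)
          layers[[i]]$W <<- up$param; states[[i]]$W <- up$state
          up <- .adamStep(layers[[i]]$b, as.vector(bw$grads[[i]]$b),
                          states[[i]]$b, cfg$lr, t)
          layers[[i]]$b <<- up$param; states[[i]]$b <- up$state
        }
        up <- .adamStep(Wg, gradWg, gState, cfg$lr, t)
        Wg <<- up$param; gState <- up$state
      }
      history[ep] <<- epochLoss / n
    }
  }
  if (cfg$epochs > 0L) .withSeed(cfg$seed, runJoint)

  cnn <- new("CnnModel", arch = cnn@arch, layers = layers,
             inputDim = cnn@inputDim, seed = cnn@seed,
             trained = cfg$epochs > 0L, history = history)
  new("PairModel", cnn = cnn, gcnMode = "trained", gcnWeights = Wg,
      gcnActivation = act, diseaseIds = features@diseaseIds, topK = K,
      config = unclass(cfg))
}

# embed features with a fitted model's GCN configuration
.embedForModel <- function(model, features, network) {
  if (!identical(features@geneIds, network@geneIds))
    stop("feature and network gene orders differ", call. = FALSE)
  switch(model@gcnMode,
    none = features@values,
    fixed = as.matrix(buildPropagationMatrix(network) %*%
                        features@values),
    trained = {
      LX <- as.matrix(buildPropagationMatrix(network) %*%
                        features@values)
      pre <- LX %*% model@gcnWeights
      if (model@gcnActivation == "relu") pmax(pre, 0) else pre
    })
}

#' Score disease-gene pairs with a fitted model
#'
#' Re-embeds the gene features with the model's graph-convolution
#' configuration, assembles the pair tensors and returns one CNN score
#' in [0, 1] per pair. Deterministic given the fitted model.
#'
#' @param model a fitted [PairModel-class].
#' @param features raw [GeneFeatureSet-class] (same panel/K as at
#'   training time).
#' @param network [GeneNetwork-class] over the feature genes.
#' @param similarity [DiseaseSimilarity-class].
#' @param pairs data.frame with columns `disease_id`, `gene_id` and
#'   optionally `label`.
#' @return data.frame `disease_id`, `gene_id`, `score` (plus `label`
#'   when supplied).
#' @export
scorePairs <- function(model, features, network, similarity, pairs) {
  stopifnot(is(model, "PairModel"), is(features, "GeneFeatureSet"))
  if (!identical(model@diseaseIds, features@diseaseIds))
    stop("model and features disagree on the disease panel",
         call. = FALSE)
  if (!identical(features@diseaseIds, similarity@diseaseIds))
    stop("feature and similarity disease panels differ", call. = FALSE)
  idx <- .checkPairs(pairs, features@geneIds, features@diseaseIds)
  H <- .embedForModel(model, features, network)
  simTile <- .simTileMatrix(similarity, model@topK)
  x <- .pairInputs(H, simTile, idx$gene, idx$disease)
  score <- predictCnn(model@cnn, x)
  out <- data.frame(disease_id = pairs$disease_id,
                    gene_id = pairs$gene_id, score = score,
                    stringsAsFactors = FALSE)
  if ("label" %in% names(pairs)) out$label <- pairs$label
  rownames(out) <- NULL
  out
}
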