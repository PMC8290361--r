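# Graph embedding: the self-looped symmetrically normalized propagation
# operator L = D^{-1/2} (A + I) D^{-1/2} and graph-convolutional
# propagation H^{l+1} = sigma(L H^l W^l) with H^0 = X.

#' Construct a GeneNetwork from an edge list
#'
#' Builds the symmetric sparse adjacency matrix over the supplied gene
#' universe. Genes without any edge become isolated nodes; after
#' normalization their propagation row is the standard basis vector, so
#' their features pass through unsmoothed. Duplicate undirected edges
#' are rejected.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `weight`
#'   (see [readNetworkEdges()]); may have zero rows.
#' @param geneIds gene universe defining node order; defaults to the
#'   sorted genes present in `edges`.
#' @return a [GeneNetwork-class].
#' @export
GeneNetwork <- function(edges, geneIds = NULL) {
  stopifnot(is.data.frame(edges))
  if (is.null(geneIds))
    geneIds <- sort(unique(c(edges$gene_a, edges$gene_b)))
  geneIds <- as.character(geneIds)
  N <- length(geneIds)
  if (nrow(edges) > 0) {
    ia <- match(edges$gene_a, geneIds)
    ib <- match(edges$gene_b, geneIds)
    if (anyNA(ia) || anyNA(ib)) {
      unknown <- unique(c(edges$gene_a[is.na(ia)], edges$gene_b[is.na(ib)]))
      stop(sprintf("edge(s) reference gene(s) outside the universe: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    if (any(ia == ib))
      stop("self-edges are not allowed", call. = FALSE)
    key <- paste(pmin(ia, ib), pmax(ia, ib))
    if (anyDuplicated(key))
      stop("duplicate undirected edge(s) in input", call. = FALSE)
    A <- Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia),
                              x = rep(edges$weight, 2), dims = c(N, N))
    A <- Matrix::forceSymmetric(A)
  } else {
    A <- Matrix::forceSymmetric(
      Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                           dims = c(N, N)))
  }
  obj <- new("GeneNetwork", geneIds = geneIds, adjacency = A)
  validObject(obj)
  obj
}

#' Build the normalized propagation matrix
#'
#' Computes `L = D^{-1/2} (A + I) D^{-1/2}` where `A` is the weighted
#' adjacency and `D` the degree matrix of `A + I` (row sums). The
#' self-loop guarantees every degree is at least 1, so L is always
#' defined; its spectrum lies in [-1, 1] and an isolated node's row is
#' the corresponding standard basis vector.
#'
#' @param network a [GeneNetwork-class].
#' @return symmetric sparse `Matrix` L.
#' @export
buildPropagationMatrix <- function(network) {
  stopifnot(is(network, "GeneNetwork"))
  N <- length(network@geneIds)
  At <- network@adjacency + Matrix::Diagonal(N)
  dInvSqrt <- 1 / sqrt(Matrix::rowSums(At))
  Dm <- Matrix::Diagonal(N, x = dInvSqrt)
  Matrix::forceSymmetric(Dm %*% At %*% Dm)
}

#' Define a graph-convolution layer
#'
#' @param weights either the string `"identity"` (no feature mixing) or
#'   a numeric F_in x F_out weight matrix; entries must be finite.
#' @param activation `"relu"` or `"identity"`.
#' @return a `gcnLayer` list.
#' @export
gcnLayer <- function(weights = "identity",
                     activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  if (!identical(weights, "identity")) {
    weights <- as.matrix(weights)
    if (!all(is.finite(weights)))
      stop("layer weights must be finite", call. = FALSE)
  }
  structure(list(weights = weights, activation = activation),
            class = "gcnLayer")
}

.applyActivation <- function(x, activation) {
  switch(activation,
         relu = pmax(x, 0),
         identity = x,
         stop(sprintf("unknown activation '%s'", activation),
              call. = FALSE))
}

#' One round of graph-convolutional propagation
#'
#' Returns `sigma(L %*% H %*% W)` for the layer's weights W and
#' activation sigma.
#'
#' @param L propagation matrix from [buildPropagationMatrix()].
#' @param H numeric N x F_in feature matrix.
#' @param layer a [gcnLayer()].
#' @return numeric N x F_out matrix.
#' @export
gcnPropagate <- function(L, H, layer = gcnLayer()) {
  H <- as.matrix(H)
  if (nrow(H) != nrow(L))
    stop(sprintf("feature matrix has %d rows but graph has %d nodes",
                 nrow(H), nrow(L)), call. = FALSE)
  Z <- as.matrix(L %*% H)
  if (!identical(layer$weights, "identity")) {
    if (ncol(Z) != nrow(layer$weights))
      stop(sprintf("layer expects %d input features, got %d",
                   nrow(layer$weights), ncol(Z)), call. = FALSE)
    Z <- Z %*% layer$weights
  }
  .applyActivation(Z, layer$activation)
}

#' Sequentially embed gene features over the network
#'
#' Applies [gcnPropagate()] for each layer in order, starting from X.
#' An empty layer list returns X unchanged. With the default single
#' identity layer the output keeps the 2*D*K feature geometry, so the
#' embedded features still reshape into the 2 x D x K block.
#'
#' @param network a [GeneNetwork-class].
#' @param X numeric N x F matrix; row order must equal the network's
#'   gene order.
#' @param layers list of [gcnLayer()] objects.
#' @param geneIds optional gene ids of X's rows; checked against the
#'   network's gene order when supplied.
#' @return numeric matrix of embedded features.
#' @export
embedGenes <- function(network, X, layers = list(gcnLayer()),
                       geneIds = NULL) {
  stopifnot(is(network, "GeneNetwork"))
  X <- as.matrix(X)
  if (!is.null(geneIds) && !identical(as.character(geneIds),
                                      network@geneIds))
    stop("gene order of X does not match the network", call. = FALSE)
  if (nrow(X) != length(network@geneIds))
    stop("X must have one row per network gene", call. = FALSE)
  if (length(layers) == 0) return(X)
  L <- buildPropagationMatrix(network)
  H <- X
  for (layer in layers) H <- gcnPropagate(L, H, layer)
  H
}

#' Smooth a GeneFeatureSet over the gene network
#'
#' Convenience wrapper: embeds the flat feature matrix with
#' [embedGenes()] and returns a new [GeneFeatureSet-class] marked as
#' smoothed. The network must cover the feature genes in identical
#' order (use [GeneNetwork()] with `geneIds = geneIds(features)` to add
#' unconnected genes as isolated nodes).
#'
#' @param features a [GeneFeatureSet-class].
#' @param network a [GeneNetwork-class] over the same genes.
#' @param layers list of [gcnLayer()]s; default one identity layer
#'   with identity activation (pure deterministic network smoothing).
#' @return a smoothed [GeneFeatureSet-class].
#' @export
smoothFeatures <- function(features, network,
                           layers = list(gcnLayer(activation = "identity"))) {
  stopifnot(is(features, "GeneFeatureSet"))
  H <- embedGenes(network, features@values, layers,
                  geneIds = features@geneIds)
  if (ncol(H) != ncol(features@values))
    stop("smoothing layers must preserve the 2*D*K feature width",
         call. = FALSE)
  geneFeatureSet(H, features@geneIds, features@diseaseIds,
                 features@topK, transform = features@transform,
                 smoothed = TRUE)
}
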