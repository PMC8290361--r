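#' Gene identifiers of an object
#'
#' @param x an object carrying gene identifiers.
#' @return character vector of gene ids in the object's canonical order.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Disease panel of an object
#'
#' @param x an object carrying a disease panel.
#' @return character vector of disease ids in panel order.
#' @export
setGeneric("diseaseIds", function(x) standardGeneric("diseaseIds"))

#' Flat feature matrix of a GeneFeatureSet
#'
#' @param x a [GeneFeatureSet-class].
#' @return numeric N x (2*D*K) matrix, rows in gene order, columns in
#'   layer-major `layer.disease.rank` order.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Adjacency matrix of a gene network
#'
#' @param x a [GeneNetwork-class].
#' @return symmetric sparse `Matrix` of edge weights, zero diagonal.
#' @export
setGeneric("adjacencyMatrix",
           function(x) standardGeneric("adjacencyMatrix"))

#' Similarity values of a DiseaseSimilarity
#'
#' @param x a [DiseaseSimilarity-class].
#' @return numeric D x D matrix with disease ids as dimnames.
#' @export
setGeneric("similarityValues",
           function(x) standardGeneric("similarityValues"))

#' Per-fold cross-validation metrics
#'
#' @param x a [CvResult-class].
#' @return data.frame with columns `fold`, `auc`, `aupr`.
#' @export
setGeneric("foldMetrics", function(x) standardGeneric("foldMetrics"))

#' @rdname geneIds
#' @export
setMethod("geneIds", "GeneSnpMap", function(x) x@geneIds)
#' @rdname geneIds
#' @export
setMethod("geneIds", "GeneFeatureSet", function(x) x@geneIds)
#' @rdname geneIds
#' @export
setMethod("geneIds", "GeneNetwork", function(x) x@geneIds)

#' @rdname diseaseIds
#' @export
setMethod("diseaseIds", "GeneSnpMap", function(x) x@diseaseIds)
#' @rdname diseaseIds
#' @export
setMethod("diseaseIds", "GeneFeatureSet", function(x) x@diseaseIds)
#' @rdname diseaseIds
#' @export
setMethod("diseaseIds", "DiseaseSimilarity", function(x) x@diseaseIds)
#' @rdname diseaseIds
#' @export
setMethod("diseaseIds", "PairModel", function(x) x@diseaseIds)

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "GeneFeatureSet", function(x) {
  m <- x@values
  dimnames(m) <- list(x@geneIds, featureColumnNames(x@diseaseIds, x@topK))
  m
})

#' @rdname adjacencyMatrix
#' @export
setMethod("adjacencyMatrix", "GeneNetwork", function(x) x@adjacency)

#' @rdname similarityValues
#' @export
setMethod("similarityValues", "DiseaseSimilarity", function(x) {
  m <- x@values
  dimnames(m) <- list(x@diseaseIds, x@diseaseIds)
  m
})

#' @rdname foldMetrics
#' @export
setMethod("foldMetrics", "CvResult", function(x) x@folds)

setMethod("show", "GeneSnpMap", function(object) {
  cat(sprintf(
    "GeneSnpMap: %d assignments | %d genes annotated | %d diseases | window %d bp\n",
    nrow(object@assignments), length(object@geneIds),
    length(object@diseaseIds), object@windowBp))
})

setMethod("show", "GeneFeatureSet", function(object) {
  cat(sprintf(
    "GeneFeatureSet: %d genes x (2 layers x %d diseases x top-%d SNPs) [%s%s]\n",
    length(object@geneIds), length(object@diseaseIds), object@topK,
    object@transform, if (object@smoothed) ", smoothed" else ""))
})

setMethod("show", "GeneNetwork", function(object) {
  nEdges <- Matrix::nnzero(object@adjacency) / 2
  cat(sprintf("GeneNetwork: %d genes, %d weighted undirected edges\n",
              length(object@geneIds), nEdges))
})

setMethod("show", "DiseaseSimilarity", function(object) {
  cat(sprintf("DiseaseSimilarity: %d diseases (%s)\n",
              length(object@diseaseIds),
              paste(object@diseaseIds, collapse = ", ")))
})

setMethod("show", "CnnModel", function(object) {
  cat(sprintf(
    "CnnModel: input %s, %d layers, %strained (seed %d)\n",
    paste(object@inputDim, collapse = "x"), length(object@arch$layers),
    if (object@trained) "" else "un", object@seed))
  if (length(object@history))
    cat(sprintf("  final training loss: %.6f\n",
                object@history[length(object@history)]))
})

setMethod("show", "PairModel", function(object) {
  cat(sprintf("PairModel: gcn mode '%s', %d diseases, top-%d SNPs\n",
              object@gcnMode, length(object@diseaseIds), object@topK))
})

setMethod("show", "CvResult", function(object) {
  f <- object@folds
  cat(sprintf("CvResult: %d folds | mean AUC %.3f | mean AUPR %.3f\n",
              nrow(f), mean(f$auc), mean(f$aupr)))
})

setMethod("show", "SyntheticBundle", function(object) {
  cat(sprintf(
    "SyntheticBundle: %d genes, %d diseases, %d GWAS rows, %d eQTL rows, %d edges, %d curated pairs\n",
    nrow(object@annotations), length(object@similarity@diseaseIds),
    nrow(object@gwas), nrow(object@eqtl), nrow(object@network),
    nrow(object@associations)))
})
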