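#' @import methods
#' @importClassesFrom Matrix Matrix
NULL

#' GeneSnpMap: SNPs assigned to genes by genomic position
#'
#' Container for the SNP-to-gene assignment produced by
#' [mapSnpsToGenes()]. Each row of the internal table records one
#' (gene, omics layer, disease, SNP) assignment together with the SNP's
#' summary p-value.
#'
#' @slot assignments data.frame with columns `gene_id`, `source`
#'   (`"GWAS"` or `"EQTL"`), `disease_id`, `snp_id`, `chrom`, `pos`,
#'   `p_value`.
#' @slot geneIds character, all annotated gene identifiers (mapped or not).
#' @slot diseaseIds character, the disease panel in fixed order.
#' @slot windowBp integer, the flanking window (bp) used for mapping.
#'
#' @seealso [mapSnpsToGenes()], [filterGenes()], [buildGeneFeatures()]
#' @export
setClass("GeneSnpMap",
  representation(
    assignments = "data.frame",
    geneIds = "character",
    diseaseIds = "character",
    windowBp = "integer"
  )
)

setValidity("GeneSnpMap", function(object) {
  req <- c("gene_id", "source", "disease_id", "snp_id", "chrom", "pos",
           "p_value")
  if (!all(req %in% names(object@assignments)))
    return(sprintf("assignments must have columns: %s",
                   paste(req, collapse = ", ")))
  if (anyDuplicated(object@geneIds))
    return("geneIds must be unique")
  if (anyDuplicated(object@diseaseIds))
    return("diseaseIds must be unique")
  a <- object@assignments
  if (nrow(a) > 0) {
    if (!all(a$gene_id %in% object@geneIds))
      return("assignments reference genes absent from geneIds")
    if (!all(a$source %in% c("GWAS", "EQTL")))
      return("source must be GWAS or EQTL")
    if (!all(a$p_value > 0 & a$p_value <= 1))
      return("p_value entries must lie in (0, 1]")
  }
  TRUE
})

#' GeneFeatureSet: per-gene p-value feature blocks
#'
#' Each gene carries a 2 x D x K block of summary p-values: two omics
#' layers (GWAS, eQTL), D diseases, and the K most significant SNP
#' p-values per (layer, disease), sorted ascending and padded with 1
#' when fewer than K SNPs map to the gene. Rows of the flat matrix are
#' genes; columns follow layer-major order `layer.disease.rank`.
#'
#' @slot values numeric matrix, N genes x (2 * D * K).
#' @slot geneIds character of length N.
#' @slot diseaseIds character of length D.
#' @slot topK integer, K.
#' @slot transform `"raw"` (p-values as-is) or `"log10"` (capped
#'   -log10 p).
#' @slot smoothed logical; `TRUE` after graph-convolutional smoothing,
#'   in which case only finiteness is required of the entries.
#'
#' @seealso [buildGeneFeatures()], [featureMatrix()], [smoothFeatures()]
#' @export
setClass("GeneFeatureSet",
  representation(
    values = "matrix",
    geneIds = "character",
    diseaseIds = "character",
    topK = "integer",
    transform = "character",
    smoothed = "logical"
  )
)

setValidity("GeneFeatureSet", function(object) {
  N <- length(object@geneIds)
  D <- length(object@diseaseIds)
  K <- object@topK
  if (length(K) != 1L || is.na(K) || K < 1L)
    return("topK must be a single positive integer")
  if (nrow(object@values) != N)
    return("values must have one row per gene")
  if (ncol(object@values) != 2L * D * K)
    return(sprintf("values must have 2*D*K = %d columns", 2L * D * K))
  if (anyDuplicated(object@geneIds))
    return("geneIds must be unique")
  if (!all(is.finite(object@values)))
    return("feature values must be finite")
  if (!object@smoothed && identical(object@transform, "raw") && N > 0) {
    v <- object@values
    if (any(v <= 0) || any(v > 1))
      return("raw feature values must lie in (0, 1]")
    for (b in seq_len(2L * D)) {
      blk <- v[, ((b - 1L) * K + 1L):(b * K), drop = FALSE]
      if (K > 1L && any(blk[, -1L, drop = FALSE] <
                        blk[, -K, drop = FALSE]))
        return("each (layer, disease) block must be sorted ascending")
    }
  }
  TRUE
})

#' GeneNetwork: weighted undirected gene interaction graph
#'
#' Holds the gene order and the symmetric non-negative adjacency matrix
#' of a functional gene-interaction network (HumanNet-style edge
#' weights). The diagonal is zero on input; self-connections are added
#' analytically by [buildPropagationMatrix()].
#'
#' @slot geneIds character, node order.
#' @slot adjacency symmetric sparse `Matrix` with zero diagonal and
#'   non-negative weights.
#'
#' @seealso [GeneNetwork()], [buildPropagationMatrix()]
#' @export
setClass("GeneNetwork",
  representation(geneIds = "character", adjacency = "Matrix")
)

setValidity("GeneNetwork", function(object) {
  N <- length(object@geneIds)
  A <- object@adjacency
  if (nrow(A) != N || ncol(A) != N)
    return("adjacency must be N x N for N genes")
  if (anyDuplicated(object@geneIds))
    return("geneIds must be unique")
  if (N > 0) {
    if (!Matrix::isSymmetric(A, tol = 0))
      return("adjacency must be symmetric")
    if (any(Matrix::diag(A) != 0))
      return("adjacency diagonal must be zero (self-loops are added by normalization)")
    if (any(A@x < 0))
      return("edge weights must be non-negative")
  }
  TRUE
})

#' DiseaseSimilarity: D x D disease similarity matrix
#'
#' A precomputed symmetric disease-disease similarity matrix with unit
#' diagonal and entries in [0, 1]; its rows supply the third channel of
#' each disease-gene pair tensor.
#'
#' @slot diseaseIds character, the disease panel in fixed order.
#' @slot values numeric D x D matrix.
#'
#' @seealso [readSimilarityMatrix()], [assemblePairTensor()]
#' @export
setClass("DiseaseSimilarity",
  representation(diseaseIds = "character", values = "matrix")
)

setValidity("DiseaseSimilarity", function(object) {
  D <- length(object@diseaseIds)
  S <- object@values
  if (nrow(S) != D || ncol(S) != D)
    return("similarity matrix must be D x D")
  if (anyDuplicated(object@diseaseIds))
    return("diseaseIds must be unique")
  if (D > 0) {
    if (any(abs(S - t(S)) > 1e-9))
      return("similarity matrix must be symmetric (tolerance 1e-9)")
    if (any(abs(diag(S) - 1) > 1e-9))
      return("similarity matrix diagonal must equal 1")
    if (any(S < -1e-9) || any(S > 1 + 1e-9))
      return("similarity entries must lie in [0, 1]")
  }
  TRUE
})

#' CnnModel: convolutional pair-scoring network
#'
#' A small CNN mapping a flattened 3-channel D x K pair tensor to a
#' score in (0, 1). Hidden convolutional and dense layers use tanh;
#' the output layer is a single sigmoid unit. Weight initialization is
#' deterministic given the seed.
#'
#' @slot arch list, the architecture specification (see
#'   [cnnArchitecture()]).
#' @slot layers list of compiled layer states (weights plus precomputed
#'   gather/scatter indices).
#' @slot inputDim integer(3), channels x height x width.
#' @slot seed integer used for weight initialization.
#' @slot trained logical.
#' @slot history numeric, mean training loss per epoch.
#'
#' @seealso [buildCnn()], [trainCnn()], [predictCnn()]
#' @export
setClass("CnnModel",
  representation(
    arch = "list",
    layers = "list",
    inputDim = "integer",
    seed = "integer",
    trained = "logical",
    history = "numeric"
  )
)

#' PairModel: fitted disease-gene pair scorer
#'
#' Bundles the fitted CNN with the graph-convolution configuration used
#' to embed gene features: either the deterministic fixed smoothing mode
#' (identity weights) or a trained GCN weight matrix optimized jointly
#' with the CNN against the classification loss.
#'
#' @slot cnn fitted [CnnModel-class].
#' @slot gcnMode `"fixed"`, `"trained"`, or `"none"`.
#' @slot gcnWeights numeric F x F matrix (empty for fixed/none modes).
#' @slot gcnActivation `"relu"` or `"identity"`.
#' @slot diseaseIds character, the disease panel the model was trained on.
#' @slot topK integer.
#' @slot config list, the resolved training configuration.
#'
#' @seealso [trainPairModel()], [scorePairs()]
#' @export
setClass("PairModel",
  representation(
    cnn = "CnnModel",
    gcnMode = "character",
    gcnWeights = "matrix",
    gcnActivation = "character",
    diseaseIds = "character",
    topK = "integer",
    config = "list"
  )
)

#' CvResult: cross-validation metrics
#'
#' Per-fold AUC and AUPR from stratified k-fold cross-validation of the
#' pair classifier, plus the fold assignment and out-of-fold scores.
#'
#' @slot folds data.frame with columns `fold`, `auc`, `aupr`.
#' @slot assignments integer, test-fold index per pair.
#' @slot pairs data.frame with columns `disease_id`, `gene_id`, `label`.
#' @slot scores numeric, out-of-fold score per pair.
#' @slot config list.
#'
#' @seealso [runCV()]
#' @export
setClass("CvResult",
  representation(
    folds = "data.frame",
    assignments = "integer",
    pairs = "data.frame",
    scores = "numeric",
    config = "list"
  )
)

setValidity("CvResult", function(object) {
  n <- nrow(object@pairs)
  if (length(object@assignments) != n || length(object@scores) != n)
    return("assignments and scores must have one entry per pair")
  TRUE
})

#' SyntheticBundle: a complete simulated input set
#'
#' The six input tables consumed by the pipeline (gene annotations, GWAS
#' and eQTL SNP summary tables, network edge list, curated associations,
#' disease similarity matrix) plus the planted ground-truth causal map
#' and the generating configuration.
#'
#' @slot annotations data.frame (`gene_id`, `chrom`, `start`, `end`).
#' @slot gwas data.frame (`snp_id`, `chrom`, `pos`, `disease_id`,
#'   `p_value`).
#' @slot eqtl data.frame, same schema as `gwas`.
#' @slot network data.frame (`gene_a`, `gene_b`, `weight`).
#' @slot associations data.frame (`disease_id`, `gene_id`), the curated
#'   positives (equal to the planted causal map).
#' @slot similarity [DiseaseSimilarity-class].
#' @slot truth data.frame (`disease_id`, `gene_id`), planted causal map.
#' @slot config list, the generating [syntheticConfig()].
#'
#' @seealso [generateBundle()], [writeBundle()]
#' @export
setClass("SyntheticBundle",
  representation(
    annotations = "data.frame",
    gwas = "data.frame",
    eqtl = "data.frame",
    network = "data.frame",
    associations = "data.frame",
    similarity = "DiseaseSimilarity",
    truth = "data.frame",
    config = "list"
  )
)
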