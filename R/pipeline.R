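# End-to-end orchestration: validated inputs -> features -> network ->
# cross-validation / training / prediction. Shared by the command-line
# interface and the acceptance checks.

#' Prepare pipeline inputs from validated tables
#'
#' Maps SNPs to genes, keeps genes with at least one mapped SNP, builds
#' the feature set, aligns the network to the retained genes (genes
#' without edges become isolated nodes) and restricts the curated
#' positives to the retained genes.
#'
#' @param inputs list as returned by [readBundle()] (or a
#'   [SyntheticBundle-class]).
#' @param windowBp SNP-to-gene flanking window in bp (default 0).
#' @param topK top-SNP count per (layer, disease) (default 5).
#' @param restrictEqtl,logTransform see [buildGeneFeatures()].
#' @return list with `features` ([GeneFeatureSet-class]), `network`
#'   ([GeneNetwork-class] aligned to the feature genes), `similarity`,
#'   `positives` (data.frame restricted to retained genes), `map`
#'   (the [GeneSnpMap-class]).
#' @export
prepareInputs <- function(inputs, windowBp = 0L, topK = 5L,
                          restrictEqtl = TRUE, logTransform = FALSE) {
  if (is(inputs, "SyntheticBundle"))
    inputs <- list(annotations = inputs@annotations,
                   snps = rbind(
                     cbind(inputs@gwas, source = "GWAS"),
                     cbind(inputs@eqtl, source = "EQTL")),
                   network = inputs@network,
                   associations = inputs@associations,
                   similarity = inputs@similarity)
  panel <- diseaseIds(inputs$similarity)
  map <- mapSnpsToGenes(inputs$snps, inputs$annotations,
                        windowBp = windowBp, diseaseIds = panel)
  features <- buildGeneFeatures(map, k = topK,
                                restrictEqtl = restrictEqtl,
                                logTransform = logTransform)
  kept <- geneIds(features)
  edges <- inputs$network
  edges <- edges[edges$gene_a %in% kept & edges$gene_b %in% kept, ,
                 drop = FALSE]
  network <- GeneNetwork(edges, geneIds = kept)
  positives <- inputs$associations
  positives <- positives[positives$gene_id %in% kept, , drop = FALSE]
  rownames(positives) <- NULL
  list(features = features, network = network,
       similarity = inputs$similarity, positives = positives,
       map = map)
}

#' Cross-validate the pipeline on a bundle
#'
#' Convenience wrapper: [prepareInputs()] then [runCV()].
#'
#' @param bundle a [SyntheticBundle-class] or a [readBundle()] list.
#' @param k folds (default 10).
#' @param negSeed,cvSeed seeds of the negative draw and fold split.
#' @param cfg a [trainConfig()].
#' @param ... passed to [prepareInputs()].
#' @return a [CvResult-class].
#' @export
runCvOnBundle <- function(bundle, k = 10L, negSeed = 1L, cvSeed = 1L,
                          cfg = trainConfig(), ...) {
  prep <- prepareInputs(bundle, ...)
  runCV(prep$features, prep$network, prep$similarity, prep$positives,
        k = k, negSeed = negSeed, cvSeed = cvSeed, cfg = cfg)
}

#' Train the pair scorer on all curated data
#'
#' Builds the balanced dataset (positives plus an equal uniform draw
#' from the unlabeled complement) and fits the pair model on all of it.
#'
#' @param prep output of [prepareInputs()].
#' @param negSeed seed of the negative draw.
#' @param cfg a [trainConfig()].
#' @return list with `model` (a [PairModel-class]) and `pairs` (the
#'   labeled training pairs).
#' @export
trainFullModel <- function(prep, negSeed = 1L, cfg = trainConfig()) {
  positives <- prep$positives
  negatives <- sampleNegatives(
    enumerateCandidateNegatives(geneIds(prep$features),
                                diseaseIds(prep$similarity),
                                positives),
    nrow(positives), seed = negSeed)
  pairs <- rbind(
    data.frame(disease_id = positives$disease_id,
               gene_id = positives$gene_id, label = 1,
               stringsAsFactors = FALSE),
    data.frame(disease_id = negatives$disease_id,
               gene_id = negatives$gene_id, label = 0,
               stringsAsFactors = FALSE))
  model <- trainPairModel(prep$features, prep$network,
                          prep$similarity, pairs, cfg)
  list(model = model, pairs = pairs)
}

#' Score and screen the unknown disease-gene pairs
#'
#' Scores every pair outside the curated positives with a fitted model
#' and screens the scores at the threshold.
#'
#' @param model a fitted [PairModel-class].
#' @param prep output of [prepareInputs()].
#' @param threshold screening cutoff (default 0.5).
#' @return list with `scores` (all unknown pairs), `retained` and
#'   `summary` from [screenPredictions()].
#' @export
predictNovel <- function(model, prep, threshold = 0.5) {
  unknown <- enumerateCandidateNegatives(geneIds(prep$features),
                                         diseaseIds(prep$similarity),
                                         prep$positives)
  scores <- scorePairs(model, prep$features, prep$network,
                       prep$similarity, unknown)
  scr <- screenPredictions(scores, threshold)
  list(scores = scores, retained = scr$retained,
       summary = scr$summary)
}
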