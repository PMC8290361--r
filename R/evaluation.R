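# Evaluation protocol: balanced negative sampling from the unlabeled
# complement, stratified k-fold cross-validation, ranking metrics
# (AUC by the Mann-Whitney identity, AUPR by step integration of the
# precision-recall curve), and threshold screening of unknown pairs.

#' Enumerate candidate negative pairs
#'
#' Returns the full disease-gene cross product minus the curated
#' positives, in canonical order (disease panel order, then gene
#' order). With 4,212 genes, 5 diseases and 6,258 positives this
#' yields the 14,802 unlabeled pairs of the balanced-sampling protocol.
#'
#' @param geneIds character vector of genes.
#' @param diseaseIds character vector of diseases.
#' @param positives data.frame with columns `disease_id`, `gene_id`;
#'   every pair must reference a known gene and disease.
#' @return data.frame `disease_id`, `gene_id` of size
#'   `length(geneIds) * length(diseaseIds) - nrow(positives)`.
#' @export
enumerateCandidateNegatives <- function(geneIds, diseaseIds,
                                        positives) {
  geneIds <- as.character(geneIds)
  diseaseIds <- as.character(diseaseIds)
  if (nrow(positives) > 0) {
    badG <- setdiff(unique(positives$gene_id), geneIds)
    badD <- setdiff(unique(positives$disease_id), diseaseIds)
    if (length(badG) > 0 || length(badD) > 0)
      stop(sprintf("positive pair(s) reference unknown %s: %s",
                   if (length(badG) > 0) "gene(s)" else "disease(s)",
                   paste(c(badG, badD), collapse = ", ")),
           call. = FALSE)
  }
  grid <- data.frame(
    disease_id = rep(diseaseIds, each = length(geneIds)),
    gene_id = rep(geneIds, times = length(diseaseIds)),
    stringsAsFactors = FALSE)
  posKey <- paste(positives$disease_id, positives$gene_id, sep = "\r")
  keep <- !(paste(grid$disease_id, grid$gene_id, sep = "\r") %in% posKey)
  out <- grid[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample negative pairs uniformly without replacement
#'
#' Reproducible given `seed`; the sampled pairs are returned in
#' canonical (input) order.
#'
#' @param candidates data.frame of candidate pairs, e.g. from
#'   [enumerateCandidateNegatives()].
#' @param n number of pairs to draw; must not exceed the pool size.
#' @param seed integer RNG seed.
#' @return data.frame `disease_id`, `gene_id` with n rows.
#' @export
sampleNegatives <- function(candidates, n, seed = 1L) {
  n <- as.integer(n)
  if (n > nrow(candidates))
    stop(sprintf("cannot sample %d negatives from %d candidates",
                 n, nrow(candidates)), call. = FALSE)
  idx <- .withSeed(as.integer(seed), function()
    sort(sample.int(nrow(candidates), n)))
  out <- candidates[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratified k-fold assignment
#'
#' Assigns every sample to exactly one test fold. Folds are stratified
#' by label (each class spread as evenly as possible across folds, so
#' every test fold holds both classes) and near-equal in size (total
#' sizes differ by at most 1). Deterministic given `seed`.
#'
#' @param labels 0/1 vector.
#' @param k number of folds, at least 2; each class must have at least
#'   k members.
#' @param seed integer RNG seed.
#' @return integer vector of fold indices in 1..k.
#' @export
kfoldSplit <- function(labels, k = 10L, seed = 1L) {
  k <- as.integer(k)
  n <- length(labels)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (n < k) stop("fewer samples than folds", call. = FALSE)
  classes <- unique(labels)
  if (any(table(labels) < k))
    stop("every class must have at least k members for stratified folds",
         call. = FALSE)
  folds <- integer(n)
  .withSeed(as.integer(seed), function() {
    load <- integer(k)
    for (cl in classes) {
      members <- which(labels == cl)
      members <- members[sample.int(length(members))]
      for (m in members) {
        # least-loaded fold, ties broken by fold index: keeps both the
        # per-class and the total fold sizes within 1
        f <- which.min(load)
        folds[m] <<- f
        load[f] <- load[f] + 1L
      }
    }
  })
  folds
}

#' Area under the ROC curve
#'
#' Computed through the Mann-Whitney identity: the probability that a
#' uniformly drawn positive outscores a uniformly drawn negative, with
#' ties counted 1/2.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector of the same length; both classes required.
#' @return AUC in [0, 1].
#' @export
computeAUC <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  pos <- labels == 1
  nP <- sum(pos)
  nN <- sum(!pos)
  if (nP == 0 || nN == 0)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
}

#' Area under the precision-recall curve
#'
#' Step integration (average precision): thresholds sweep the unique
#' scores in descending order, tied scores enter together, and each
#' recall increment contributes its precision —
#' `sum_k (R_k - R_{k-1}) * P_k` with no trapezoidal interpolation.
#'
#' @inheritParams computeAUC
#' @return AUPR in (0, 1].
#' @export
computeAUPR <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  nP <- sum(labels == 1)
  if (nP == 0 || sum(labels == 0) == 0)
    stop("both classes must be present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # group tied scores: cumulative counts at the last member of each tie
  lastOfTie <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[lastOfTie]
  np <- lastOfTie
  prec <- tp / np
  rec <- tp / nP
  sum(diff(c(0, rec)) * prec)
}

#' Run k-fold cross-validation of the pair classifier
#'
#' Builds the balanced labeled dataset (curated positives plus an
#' equal number of uniformly sampled unlabeled pairs), splits it into
#' stratified folds, and for each fold trains the pair model on the
#' remaining folds and scores the held-out fold, recording AUC and
#' AUPR. Negative sampling happens once on the full dataset before
#' fold splitting. With `nRepeats > 1` the fold split (and per-fold
#' training) is repeated with incremented seeds and all folds are
#' reported.
#'
#' @param features raw [GeneFeatureSet-class].
#' @param network [GeneNetwork-class] over the feature genes.
#' @param similarity [DiseaseSimilarity-class].
#' @param positives data.frame `disease_id`, `gene_id` of curated
#'   associations (restricted to the feature genes).
#' @param k number of folds (default 10).
#' @param negSeed seed of the negative draw.
#' @param cvSeed seed of the fold split.
#' @param cfg a [trainConfig()]; fold f trains with seed
#'   `cfg$seed + f` so folds are independent but reproducible.
#' @param nRepeats number of repeated CV rounds (default 1).
#' @return a [CvResult-class].
#' @export
runCV <- function(features, network, similarity, positives, k = 10L,
                  negSeed = 1L, cvSeed = 1L, cfg = trainConfig(),
                  nRepeats = 1L) {
  stopifnot(is(features, "GeneFeatureSet"))
  # canonicalize so results do not depend on the input row order
  positives <- positives[order(positives$disease_id,
                               positives$gene_id), , drop = FALSE]
  negatives <- sampleNegatives(
    enumerateCandidateNegatives(features@geneIds,
                                features@diseaseIds, positives),
    nrow(positives), seed = negSeed)
  pairs <- rbind(
    data.frame(disease_id = positives$disease_id,
               gene_id = positives$gene_id, label = 1,
               stringsAsFactors = FALSE),
    data.frame(disease_id = negatives$disease_id,
               gene_id = negatives$gene_id, label = 0,
               stringsAsFactors = FALSE))

  allFolds <- integer(nrow(pairs))
  rows <- list()
  scores <- numeric(nrow(pairs))
  for (rep_ in seq_len(nRepeats)) {
    folds <- kfoldSplit(pairs$label, k, seed = as.integer(cvSeed) +
                          rep_ - 1L)
    for (f in seq_len(k)) {
      test <- folds == f
      foldCfg <- cfg
      foldCfg$seed <- cfg$seed + (rep_ - 1L) * k + f
      model <- trainPairModel(features, network, similarity,
                              pairs[!test, , drop = FALSE], foldCfg)
      sc <- scorePairs(model, features, network, similarity,
                       pairs[test, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        fold = (rep_ - 1L) * k + f,
        auc = computeAUC(sc$score, sc$label),
        aupr = computeAUPR(sc$score, sc$label))
      if (rep_ == 1L) {
        scores[test] <- sc$score
        allFolds[test] <- f
      }
    }
  }
  new("CvResult", folds = do.call(rbind, rows),
      assignments = allFolds, pairs = pairs, scores = scores,
      config = list(k = k, negSeed = negSeed, cvSeed = cvSeed,
                    nRepeats = nRepeats, train = unclass(cfg)))
}

#' Write a cross-validation report
#'
#' TSV of per-fold AUC/AUPR plus a summary row with the means.
#'
#' @param cv a [CvResult-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCvReport <- function(cv, path) {
  f <- cv@folds
  out <- data.frame(fold = as.character(f$fold),
                    auc = sprintf("%.6f", f$auc),
                    aupr = sprintf("%.6f", f$aupr),
                    stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(fold = "mean",
                               auc = sprintf("%.6f", mean(f$auc)),
                               aupr = sprintf("%.6f", mean(f$aupr))))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Screen predictions at a score threshold
#'
#' Keeps pairs scoring strictly above the threshold (default 0.5) and
#' summarizes the retained counts per disease.
#'
#' @param scores data.frame with columns `disease_id`, `gene_id`,
#'   `score`.
#' @param threshold score cutoff in [0, 1].
#' @return list with `retained` (the screened pairs) and `summary`
#'   (data.frame `disease_id`, `n_screened`, `n_candidates`).
#' @export
screenPredictions <- function(scores, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  keep <- scores$score > threshold
  retained <- scores[keep, , drop = FALSE]
  rownames(retained) <- NULL
  diseases <- sort(unique(scores$disease_id))
  summary <- data.frame(
    disease_id = diseases,
    n_screened = vapply(diseases, function(d)
      sum(retained$disease_id == d), integer(1)),
    n_candidates = vapply(diseases, function(d)
      sum(scores$disease_id == d), integer(1)),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(retained = retained, summary = summary)
}
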