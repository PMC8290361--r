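test_that("candidate negative enumeration is the complement of the positives", {
  # full cross product with no positives
  cand <- enumerateCandidateNegatives(c("G1", "G2"), c("D1", "D2"),
                                      data.frame(disease_id = character(),
                                                 gene_id = character()))
  expect_equal(nrow(cand), 4L)
  # exhausted complement
  pos <- data.frame(disease_id = "D1", gene_id = c("G1", "G2"))
  expect_equal(nrow(enumerateCandidateNegatives(c("G1", "G2"), "D1",
                                                pos)), 0L)
  # unknown gene in positives is a validation error
  expect_error(enumerateCandidateNegatives(
    "G1", "D1", data.frame(disease_id = "D1", gene_id = "GX")), "GX")
  # never contains a positive
  genes <- sprintf("G%d", 1:30)
  set.seed(9)
  pos <- data.frame(disease_id = sample(c("D1", "D2"), 20, TRUE),
                    gene_id = sample(genes, 20, TRUE))
  pos <- unique(pos)
  cand <- enumerateCandidateNegatives(genes, c("D1", "D2"), pos)
  expect_equal(nrow(cand), 60L - nrow(pos))
  expect_false(any(paste(cand$disease_id, cand$gene_id) %in%
                     paste(pos$disease_id, pos$gene_id)))
})

test_that("negative sampling is deterministic, exhaustive at n = |pool|, and near-uniform", {
  cand <- data.frame(disease_id = rep("D1", 10),
                     gene_id = sprintf("G%d", 1:10))
  # n = |candidates| returns all in canonical order
  expect_identical(sampleNegatives(cand, 10, seed = 1),
                   cand)
  # same seed twice -> identical samples
  expect_identical(sampleNegatives(cand, 5, seed = 7),
                   sampleNegatives(cand, 5, seed = 7))
  expect_error(sampleNegatives(cand, 11, seed = 1), "cannot sample")
  # selection frequency for n = 5 of 10 within 3 sigma of 0.5 over
  # 2000 seeds
  counts <- integer(10)
  for (s in 1:2000) {
    idx <- match(sampleNegatives(cand, 5, seed = s)$gene_id,
                 cand$gene_id)
    counts[idx] <- counts[idx] + 1L
  }
  freq <- counts / 2000
  sigma <- sqrt(0.5 * 0.5 / 2000)
  expect_true(all(abs(freq - 0.5) <= 3 * sigma))
})

test_that("stratified k-fold split partitions the data with balanced classes", {
  labels <- rep(c(1, 0), each = 50)
  folds <- kfoldSplit(labels, k = 10, seed = 2)
  expect_equal(sort(unique(folds)), 1:10)
  # every sample in exactly one test fold; folds of size 10
  expect_equal(as.vector(table(folds)), rep(10L, 10))
  # perfect stratification: 5 of each class per fold
  for (f in 1:10) {
    expect_equal(sum(labels[folds == f] == 1), 5L)
    expect_equal(sum(labels[folds == f] == 0), 5L)
  }
  # uneven totals: sizes differ by at most 1, both classes everywhere
  labels2 <- c(rep(1, 23), rep(0, 31))
  folds2 <- kfoldSplit(labels2, k = 7, seed = 3)
  sizes <- as.vector(table(folds2))
  expect_lte(max(sizes) - min(sizes), 1L)
  for (f in 1:7)
    expect_setequal(unique(labels2[folds2 == f]), c(0, 1))
  expect_error(kfoldSplit(c(1, 0), k = 5), "fewer samples")
  expect_error(kfoldSplit(rep(c(1, 0), c(3, 20)), k = 5),
               "at least k members")
})

test_that("AUC matches the exhaustive pairwise oracle and the boundary cases", {
  # perfect ranking
  expect_equal(computeAUC(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  # inverted ranking
  expect_equal(computeAUC(c(0.2, 0.8), c(1, 0)), 0.0)
  # random instances (with ties) vs the O(P*N) oracle
  set.seed(44)
  for (rep_ in 1:30) {
    n <- sample(4:30, 1)
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(c(1, 2, 6), 1)) # force some ties
    expect_equal(computeAUC(scores, labels), bruteAUC(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(computeAUC(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUC and AUPR agree with independent reference implementations", {
  set.seed(45)
  for (rep_ in 1:20) {
    n <- sample(6:30, 1)
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(c(1, 3), 1))
    expect_equal(computeAUPR(scores, labels),
                 bruteAUPR(scores, labels), tolerance = 1e-12)
  }
  # cross-check AUC against pROC on a fixed instance
  set.seed(46)
  labels <- sample(0:1, 40, replace = TRUE)
  labels[1:2] <- c(0, 1)
  scores <- runif(40)
  procAuc <- as.numeric(pROC::auc(pROC::roc(labels, scores,
                                            quiet = TRUE,
                                            direction = "<")))
  expect_equal(computeAUC(scores, labels), procAuc, tolerance = 1e-12)
  # perfect ranking -> AUPR 1
  expect_equal(computeAUPR(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1.0)
})

test_that("screening keeps scores above the threshold with a per-disease summary", {
  scores <- data.frame(
    disease_id = c("D1", "D1", "D2", "D2", "D2"),
    gene_id = sprintf("G%d", 1:5),
    score = c(0.6, 0.4, 0.9, 0.5, 0.51))
  scr <- screenPredictions(scores, 0.5)
  expect_equal(nrow(scr$retained), 3L)
  expect_equal(scr$summary$n_screened, c(1L, 2L))
  expect_equal(scr$summary$n_candidates, c(2L, 3L))
  # boundary thresholds
  expect_equal(nrow(screenPredictions(scores, 1.0)$retained), 0L)
  expect_equal(nrow(screenPredictions(scores, 0.0)$retained), 5L)
})

test_that("cross-validation produces k folds and is invariant to pair order", {
  b <- generateBundle(smallConfig())
  prep <- prepareInputs(b)
  cfg <- fastTrainConfig(epochs = 6L)
  cv1 <- runCV(prep$features, prep$network, prep$similarity,
               prep$positives, k = 4L, negSeed = 2L, cvSeed = 2L,
               cfg = cfg)
  expect_s4_class(cv1, "CvResult")
  expect_equal(nrow(foldMetrics(cv1)), 4L)
  expect_true(all(foldMetrics(cv1)$auc >= 0 &
                    foldMetrics(cv1)$auc <= 1))
  # every labeled pair lands in exactly one test fold
  expect_equal(sort(unique(cv1@assignments)), 1:4)
  expect_length(cv1@assignments, 2L * nrow(prep$positives))
  # sampled negatives never collide with the positives
  neg <- cv1@pairs[cv1@pairs$label == 0, ]
  posKey <- paste(prep$positives$disease_id, prep$positives$gene_id)
  expect_false(any(paste(neg$disease_id, neg$gene_id) %in% posKey))
  # shuffling the positive rows leaves the metrics unchanged
  set.seed(99)
  shuffled <- prep$positives[sample(nrow(prep$positives)), ]
  cv2 <- runCV(prep$features, prep$network, prep$similarity,
               shuffled, k = 4L, negSeed = 2L, cvSeed = 2L, cfg = cfg)
  expect_equal(foldMetrics(cv1), foldMetrics(cv2))
})
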