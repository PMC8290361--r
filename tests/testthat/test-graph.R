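test_that("propagation matrix matches hand-computed values", {
  # single isolated node: Atilde = D = 1 -> L = [[1]]
  net1 <- GeneNetwork(data.frame(gene_a = character(),
                                 gene_b = character(),
                                 weight = numeric()), geneIds = "G1")
  expect_equal(as.matrix(buildPropagationMatrix(net1)),
               matrix(1, 1, 1), ignore_attr = TRUE)

  # two nodes, one unit edge: Atilde = [[1,1],[1,1]], D = diag(2,2)
  net2 <- GeneNetwork(data.frame(gene_a = "G1", gene_b = "G2",
                                 weight = 1),
                      geneIds = c("G1", "G2"))
  expect_equal(as.matrix(buildPropagationMatrix(net2)),
               matrix(0.5, 2, 2), ignore_attr = TRUE)
})

test_that("propagation matrix spectrum lies in [-1, 1] and isolated rows are basis vectors", {
  set.seed(33)
  for (rep_ in 1:10) {
    n <- sample(3:12, 1)
    A <- randomAdjacency(n)
    ids <- sprintf("G%d", seq_len(n + 1)) # n+1-th node isolated
    net <- GeneNetwork(edgesFromAdjacency(A, ids), geneIds = ids)
    L <- as.matrix(buildPropagationMatrix(net))
    ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1 - 1e-12 & ev <= 1 + 1e-12))
    # isolated node row is its standard basis vector
    expect_equal(L[n + 1, ], c(rep(0, n), 1))
    expect_true(isSymmetric(L))
  }
})

test_that("network constructor validates edges", {
  expect_error(GeneNetwork(data.frame(gene_a = "G1", gene_b = "G1",
                                      weight = 1),
                           geneIds = "G1"), "self-edge")
  expect_error(GeneNetwork(data.frame(gene_a = c("G1", "G2"),
                                      gene_b = c("G2", "G1"),
                                      weight = c(1, 2)),
                           geneIds = c("G1", "G2")), "duplicate")
  expect_error(GeneNetwork(data.frame(gene_a = "G1", gene_b = "GX",
                                      weight = 1),
                           geneIds = c("G1", "G2")), "GX")
})

test_that("gcn propagation equals the per-node brute-force oracle", {
  set.seed(55)
  # identity weights, identity activation -> exactly L %*% H
  for (rep_ in 1:8) {
    n <- sample(2:20, 1)
    Fdim <- sample(2:6, 1)
    A <- randomAdjacency(n)
    ids <- sprintf("G%d", seq_len(n))
    net <- GeneNetwork(edgesFromAdjacency(A, ids), geneIds = ids)
    L <- buildPropagationMatrix(net)
    H <- matrix(rnorm(n * Fdim), n, Fdim)
    W <- matrix(rnorm(Fdim * Fdim), Fdim, Fdim)
    got <- gcnPropagate(L, H, gcnLayer(W, activation = "relu"))
    want <- bruteGcnPropagate(A, H, W, activation = "relu")
    expect_equal(got, want, tolerance = 1e-10)
  }
  # 4-node path graph, explicit check with identity weights
  A <- matrix(0, 4, 4)
  A[cbind(1:3, 2:4)] <- 1; A <- A + t(A)
  ids <- sprintf("G%d", 1:4)
  net <- GeneNetwork(edgesFromAdjacency(A, ids), geneIds = ids)
  H <- matrix(rnorm(8), 4, 2)
  got <- gcnPropagate(buildPropagationMatrix(net), H,
                      gcnLayer("identity", activation = "identity"))
  expect_equal(got, bruteGcnPropagate(A, H, diag(2)),
               tolerance = 1e-10)
})

test_that("propagation with identity activation is a linear operator", {
  set.seed(66)
  n <- 9
  A <- randomAdjacency(n)
  ids <- sprintf("G%d", seq_len(n))
  net <- GeneNetwork(edgesFromAdjacency(A, ids), geneIds = ids)
  L <- buildPropagationMatrix(net)
  ly <- gcnLayer(matrix(rnorm(9), 3, 3), activation = "identity")
  H1 <- matrix(rnorm(n * 3), n, 3)
  H2 <- matrix(rnorm(n * 3), n, 3)
  a <- 2.5; b <- -1.3
  expect_equal(gcnPropagate(L, a * H1 + b * H2, ly),
               a * gcnPropagate(L, H1, ly) + b * gcnPropagate(L, H2, ly),
               tolerance = 1e-10)
})

test_that("permuting gene order permutes embeddings identically (equivariance)", {
  set.seed(77)
  n <- 8
  A <- randomAdjacency(n)
  ids <- sprintf("G%d", seq_len(n))
  H <- matrix(rnorm(n * 4), n, 4)
  net <- GeneNetwork(edgesFromAdjacency(A, ids), geneIds = ids)
  emb <- embedGenes(net, H, list(gcnLayer(activation = "identity")))
  perm <- sample(n)
  netP <- GeneNetwork(edgesFromAdjacency(A[perm, perm], ids),
                      geneIds = ids)
  embP <- embedGenes(netP, H[perm, , drop = FALSE],
                     list(gcnLayer(activation = "identity")))
  expect_equal(embP, emb[perm, , drop = FALSE], tolerance = 1e-12)
})

test_that("embedGenes composes layers and honours the identity edge cases", {
  set.seed(88)
  X <- matrix(runif(12), 4, 3)
  ids <- sprintf("G%d", 1:4)
  noEdges <- GeneNetwork(data.frame(gene_a = character(),
                                    gene_b = character(),
                                    weight = numeric()), geneIds = ids)
  # empty layer list -> X unchanged
  expect_identical(embedGenes(noEdges, X, list()), X)
  # identity layer on an edgeless graph: L = I -> X unchanged
  expect_equal(embedGenes(noEdges, X,
                          list(gcnLayer(activation = "identity"))),
               X, tolerance = 1e-12)
  # one layer on a 6-node toy graph equals the oracle composition
  A <- randomAdjacency(6)
  ids6 <- sprintf("G%d", 1:6)
  net6 <- GeneNetwork(edgesFromAdjacency(A, ids6), geneIds = ids6)
  H6 <- matrix(rnorm(6 * 4), 6, 4)
  W6 <- matrix(rnorm(16), 4, 4)
  expect_equal(
    embedGenes(net6, H6, list(gcnLayer(W6, activation = "relu"))),
    bruteGcnPropagate(A, H6, W6, activation = "relu"),
    tolerance = 1e-10)
  # gene-order mismatch is a validation error
  expect_error(embedGenes(net6, H6, geneIds = rev(ids6)), "order")
})

test_that("smoothFeatures preserves geometry and marks the result smoothed", {
  b <- generateBundle(smallConfig())
  prep <- prepareInputs(b)
  sm <- smoothFeatures(prep$features, prep$network)
  expect_s4_class(sm, "GeneFeatureSet")
  expect_true(sm@smoothed)
  expect_equal(dim(featureMatrix(sm)), dim(featureMatrix(prep$features)))
  # smoothing equals L %*% X
  L <- buildPropagationMatrix(prep$network)
  expect_equal(unname(featureMatrix(sm)),
               as.matrix(L %*% prep$features@values),
               tolerance = 1e-12)
})
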