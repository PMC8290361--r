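# Independent reference implementations (deliberately slow and direct)
# and small fixture builders shared by the test files.

# exhaustive O(|snps| * |genes|) interval-overlap scan
bruteOverlapScan <- function(snps, genes, windowBp = 0L) {
  out <- list()
  for (i in seq_len(nrow(snps))) for (j in seq_len(nrow(genes))) {
    if (snps$chrom[i] == genes$chrom[j] &&
        snps$pos[i] >= genes$start[j] - windowBp &&
        snps$pos[i] <= genes$end[j] + windowBp) {
      out[[length(out) + 1L]] <- data.frame(
        gene_id = genes$gene_id[j], snp_id = snps$snp_id[i],
        source = snps$source[i], disease_id = snps$disease_id[i],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(gene_id = character(), snp_id = character(),
                      source = character(), disease_id = character()))
  do.call(rbind, out)
}

# per-node neighborhood-sum GCN propagation: sigma(L H W) computed with
# explicit loops from the raw adjacency
bruteGcnPropagate <- function(A, H, W = diag(ncol(H)),
                              activation = "identity") {
  N <- nrow(A)
  At <- A + diag(N)
  d <- rowSums(At)
  out <- matrix(0, N, ncol(H))
  for (i in seq_len(N)) {
    acc <- rep(0, ncol(H))
    for (j in seq_len(N))
      acc <- acc + At[i, j] / sqrt(d[i] * d[j]) * H[j, ]
    out[i, ] <- acc
  }
  out <- out %*% W
  if (activation == "relu") out <- pmax(out, 0)
  out
}

# exhaustive pairwise-comparison AUC (ties count 1/2)
bruteAUC <- function(scores, labels) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    if (scores[i] > scores[j]) tot <- tot + 1
    else if (scores[i] == scores[j]) tot <- tot + 0.5
  }
  tot / (length(pos) * length(neg))
}

# step-integrated average precision by explicit threshold counting
bruteAUPR <- function(scores, labels) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  nP <- sum(labels == 1)
  prevR <- 0
  ap <- 0
  for (t in thresholds) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / nP
    ap <- ap + (rec - prevR) * prec
    prevR <- rec
  }
  ap
}

# direct 2D same-padded convolution + ceil-mode max pooling + dense
# reference forward pass, reading the model's own weights
slowCnnForward <- function(model, xrow) {
  dims <- model@inputDim
  h <- array(0, dim = c(dims[1], dims[2], dims[3]))
  for (c in seq_len(dims[1])) for (i in seq_len(dims[2]))
    for (j in seq_len(dims[3]))
      h[c, i, j] <- xrow[(c - 1) * dims[2] * dims[3] +
                           (i - 1) * dims[3] + j]
  for (ly in model@layers) {
    if (ly$type == "conv") {
      C <- dim(h)[1]; H <- dim(h)[2]; W <- dim(h)[3]
      spec <- NULL
      KK <- ly$CKK / C
      KH <- as.integer(sqrt(KK)); KW <- KH
      pad <- (KH - 1) %/% 2
      out <- array(0, dim = c(ly$filters, H, W))
      for (f in seq_len(ly$filters)) for (i in seq_len(H))
        for (j in seq_len(W)) {
          acc <- ly$b[f]
          for (c in seq_len(C)) for (kh in seq_len(KH))
            for (kw in seq_len(KW)) {
              ih <- i + kh - 1 - pad
              iw <- j + kw - 1 - pad
              if (ih >= 1 && ih <= H && iw >= 1 && iw <= W) {
                wIdx <- (c - 1) * KH * KW + (kh - 1) * KW + kw
                acc <- acc + h[c, ih, iw] * ly$W[wIdx, f]
              }
            }
          out[f, i, j] <- tanh(acc)
        }
      h <- out
    } else if (ly$type == "pool") {
      C <- dim(h)[1]; H <- dim(h)[2]; W <- dim(h)[3]
      oH <- ceiling(H / 2); oW <- ceiling(W / 2)
      out <- array(-Inf, dim = c(C, oH, oW))
      for (c in seq_len(C)) for (i in seq_len(oH))
        for (j in seq_len(oW)) {
          for (ih in ((i - 1) * 2 + 1):min(H, i * 2))
            for (iw in ((j - 1) * 2 + 1):min(W, j * 2))
              out[c, i, j] <- max(out[c, i, j], h[c, ih, iw])
        }
      h <- out
    } else {
      v <- as.vector(aperm(h, c(3, 2, 1)))
      z <- as.vector(v %*% ly$W) + ly$b
      h <- if (ly$activation == "tanh") tanh(z)
           else 1 / (1 + exp(-z))
      h <- array(h, dim = c(length(h), 1, 1))
    }
  }
  as.vector(h)[1]
}

# random symmetric non-negative adjacency with zero diagonal
randomAdjacency <- function(n, density = 0.4) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  on <- up[runif(length(up)) < density]
  A[on] <- runif(length(on), 0.1, 2)
  A + t(A)
}

edgesFromAdjacency <- function(A, geneIds) {
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  data.frame(gene_a = geneIds[idx[, 1]], gene_b = geneIds[idx[, 2]],
             weight = A[idx], stringsAsFactors = FALSE)
}

# ten genes on two chromosomes with a known number of SNPs each
toyAnnotations <- function() {
  data.frame(
    gene_id = sprintf("G%02d", 1:10),
    chrom = rep(c("chr1", "chr2"), each = 5),
    start = rep(c(1000L, 5000L, 9000L, 13000L, 17000L), 2),
    end = rep(c(2000L, 6000L, 10000L, 14000L, 18000L), 2),
    stringsAsFactors = FALSE)
}

# SNP table giving gene g exactly nSnps[g] in-body SNPs for each of the
# diseases; p-values drawn deterministically from the supplied seed
toySnps <- function(nSnps, diseases = sprintf("D%d", 1:5),
                    source = "GWAS", seed = 42) {
  ann <- toyAnnotations()
  set.seed(seed)
  rows <- list()
  for (g in seq_len(nrow(ann))) {
    if (nSnps[g] == 0) next
    pos <- ann$start[g] + seq_len(nSnps[g]) * 10L
    for (d in diseases) {
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = sprintf("s%d_%d", g, seq_len(nSnps[g])),
        chrom = ann$chrom[g], pos = pos, disease_id = d,
        p_value = round(runif(nSnps[g]), 6), source = source,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# small planted-signal bundle for fast end-to-end tests
smallConfig <- function(seed = 3L, nGenes = 60L) {
  syntheticConfig(nGenes = nGenes,
                  nTrueGenesPerDisease = c(8L, 6L, 5L, 4L, 2L),
                  seed = seed)
}

fastTrainConfig <- function(epochs = 20L, seed = 11L, ...) {
  trainConfig(epochs = epochs, seed = seed, ...)
}
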