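# Synthetic summary-statistics generator. Produces internally
# consistent input bundles (annotations, GWAS/eQTL SNP tables, network,
# curated associations, disease similarity) with planted disease-gene
# signal: causal (gene, disease) pairs draw sub-uniform Beta(a, 1)
# p-values while everything else is Uniform(0, 1). This is a test
# harness emulating the statistical structure of summary data, not a
# model of endocrine genetics: no LD, allele frequencies or
# genotype-level effects are simulated.

#' Synthetic bundle configuration
#'
#' Defaults describe a desk-scale analogue of a five-disease endocrine
#' panel: 500 genes; per-disease causal-gene counts
#' `c(90, 60, 40, 24, 6)` mirroring a heavily skewed panel (a
#' T2DM-like majority class down to an IGFI-deficiency-like rare
#' class); half of disease 2's causal genes shared with disease 1 (the
#' T1DM/T2DM overlap analogue); Beta(0.1, 1) signal p-values against a
#' Uniform(0, 1) null; eQTL concordance 0.8 (the probability that a
#' causal gene also carries regulatory signal).
#'
#' @param nGenes number of genes.
#' @param nDiseases panel size D (default 5).
#' @param nTrueGenesPerDisease scalar or length-D vector of planted
#'   causal-gene counts.
#' @param snpsPerGene integer range (min, max) of SNPs per gene.
#' @param signalBetaA shape a of the Beta(a, 1) causal p-value
#'   distribution; smaller is stronger signal.
#' @param eqtlConcordance probability in [0, 1] that a causal
#'   (gene, disease) pair also draws eQTL signal.
#' @param networkDensity background edge probability.
#' @param enrichmentFactor multiplier on the edge probability for gene
#'   pairs sharing a causal disease.
#' @param sharedGeneFraction fraction of disease `sharedPair[2]`'s
#'   causal genes drawn from disease `sharedPair[1]`'s causal set.
#' @param sharedPair integer(2), the overlapping disease pair.
#' @param similarityModel `"overlap"` (Jaccard similarity of the
#'   planted causal sets, unit diagonal) or `"identity"`.
#' @param seed integer RNG seed; the bundle is a deterministic function
#'   of the full configuration.
#' @return a validated `syntheticConfig` list.
#' @export
syntheticConfig <- function(nGenes = 500L, nDiseases = 5L,
                            nTrueGenesPerDisease = c(90L, 60L, 40L, 24L, 6L),
                            snpsPerGene = c(3L, 8L),
                            signalBetaA = 0.1,
                            eqtlConcordance = 0.8,
                            networkDensity = 0.005,
                            enrichmentFactor = 30,
                            sharedGeneFraction = 0.5,
                            sharedPair = c(1L, 2L),
                            similarityModel = c("overlap", "identity"),
                            seed = 1L) {
  similarityModel <- match.arg(similarityModel)
  nGenes <- as.integer(nGenes)
  nDiseases <- as.integer(nDiseases)
  if (length(nTrueGenesPerDisease) == 1L)
    nTrueGenesPerDisease <- rep(nTrueGenesPerDisease, nDiseases)
  nTrueGenesPerDisease <- as.integer(nTrueGenesPerDisease)
  if (length(nTrueGenesPerDisease) != nDiseases)
    stop("nTrueGenesPerDisease must have one entry per disease",
         call. = FALSE)
  if (any(nTrueGenesPerDisease > nGenes))
    stop("more causal genes than genes", call. = FALSE)
  if (any(nTrueGenesPerDisease < 1L))
    stop("each disease needs at least one causal gene", call. = FALSE)
  stopifnot(length(snpsPerGene) == 2L, snpsPerGene[1] >= 1L,
            snpsPerGene[2] >= snpsPerGene[1],
            signalBetaA > 0,
            eqtlConcordance >= 0, eqtlConcordance <= 1,
            networkDensity >= 0, networkDensity <= 1,
            enrichmentFactor >= 1,
            sharedGeneFraction >= 0, sharedGeneFraction <= 1,
            length(sharedPair) == 2L)
  if (nDiseases >= 2L && (any(sharedPair < 1L) ||
                          any(sharedPair > nDiseases) ||
                          sharedPair[1] == sharedPair[2]))
    stop("sharedPair must name two distinct diseases", call. = FALSE)
  structure(list(
    nGenes = nGenes, nDiseases = nDiseases,
    nTrueGenesPerDisease = nTrueGenesPerDisease,
    snpsPerGene = as.integer(snpsPerGene),
    signalBetaA = signalBetaA, eqtlConcordance = eqtlConcordance,
    networkDensity = networkDensity,
    enrichmentFactor = enrichmentFactor,
    sharedGeneFraction = sharedGeneFraction,
    sharedPair = as.integer(sharedPair),
    similarityModel = similarityModel, seed = as.integer(seed)),
    class = "syntheticConfig")
}

# p-values never exactly 0 (validators and ranking require p > 0)
.drawSignalP <- function(n, a) pmax(stats::rbeta(n, a, 1), 1e-300)
.drawNullP <- function(n) pmax(stats::runif(n), 1e-300)

.generate <- function(cfg, withSignal) {
  stopifnot(inherits(cfg, "syntheticConfig"))
  G <- cfg$nGenes
  D <- cfg$nDiseases
  if (!withSignal) {
    # a null bundle must carry no label signal at all. With a skewed
    # panel the per-disease positive rate itself is predictive from
    # the similarity channel (uniform negative sampling leaves
    # P(label = 1 | disease) far from constant), so the null fixture
    # flattens the panel to equal per-disease counts (same total).
    total <- sum(cfg$nTrueGenesPerDisease)
    base <- total %/% D
    counts <- rep(base, D)
    if (total %% D > 0) counts[seq_len(total %% D)] <- base + 1L
    cfg$nTrueGenesPerDisease <- as.integer(counts)
  }
  diseaseIds <- sprintf("D%d", seq_len(D))
  geneIds <- sprintf("G%04d", seq_len(G))

  .withSeed(cfg$seed, function() {
    # --- gene placement: non-overlapping intervals on 5 chromosomes
    nChrom <- 5L
    chromOf <- rep(sprintf("chr%d", seq_len(nChrom)), length.out = G)
    lens <- sample(5000:50000, G, replace = TRUE)
    gaps <- sample(10000:100000, G, replace = TRUE)
    start <- integer(G)
    for (ch in unique(chromOf)) {
      idx <- which(chromOf == ch)
      start[idx] <- cumsum(gaps[idx]) +
        c(0L, cumsum(lens[idx])[-length(idx)])
    }
    annotations <- data.frame(gene_id = geneIds, chrom = chromOf,
                              start = start, end = start + lens - 1L,
                              stringsAsFactors = FALSE)

    # --- planted causal sets (disease order: sharedPair[1] first so
    # the overlap can be drawn from it)
    causal <- vector("list", D)
    names(causal) <- diseaseIds
    drawOrder <- if (D >= 2L)
      c(cfg$sharedPair, setdiff(seq_len(D), cfg$sharedPair))
    else seq_len(D)
    for (d in drawOrder) {
      nd <- cfg$nTrueGenesPerDisease[d]
      if (D >= 2L && d == cfg$sharedPair[2]) {
        src <- causal[[cfg$sharedPair[1]]]
        nShared <- min(length(src), floor(cfg$sharedGeneFraction * nd))
        shared <- if (nShared > 0) sample(src, nShared) else character()
        rest <- sample(setdiff(geneIds, shared), nd - nShared)
        causal[[d]] <- sort(c(shared, rest))
      } else {
        causal[[d]] <- sort(sample(geneIds, nd))
      }
    }
    truth <- do.call(rbind, lapply(seq_len(D), function(d)
      data.frame(disease_id = diseaseIds[d], gene_id = causal[[d]],
                 stringsAsFactors = FALSE)))
    rownames(truth) <- NULL

    # --- SNPs inside gene bodies, shared by both omics layers
    nSnp <- sample(cfg$snpsPerGene[1]:cfg$snpsPerGene[2], G,
                   replace = TRUE)
    snpGene <- rep(seq_len(G), nSnp)
    snpPos <- unlist(lapply(seq_len(G), function(g)
      sort(sample(annotations$start[g]:annotations$end[g], nSnp[g]))))
    snpIds <- sprintf("rs%s_%d", snpGene,
                      unlist(lapply(nSnp, seq_len)))
    totalSnp <- length(snpIds)

    causalMat <- matrix(FALSE, G, D)
    for (d in seq_len(D))
      causalMat[match(causal[[d]], geneIds), d] <- TRUE
    concord <- matrix(stats::runif(G * D) < cfg$eqtlConcordance, G, D)

    buildLayer <- function(useSignal) {
      rows <- vector("list", D)
      for (d in seq_len(D)) {
        sig <- withSignal & useSignal[match(snpGene, seq_len(G)), d]
        p <- numeric(totalSnp)
        nSig <- sum(sig)
        if (nSig > 0) p[sig] <- .drawSignalP(nSig, cfg$signalBetaA)
        p[!sig] <- .drawNullP(totalSnp - nSig)
        rows[[d]] <- data.frame(
          snp_id = snpIds, chrom = annotations$chrom[snpGene],
          pos = snpPos, disease_id = diseaseIds[d], p_value = p,
          stringsAsFactors = FALSE)
      }
      out <- do.call(rbind, rows)
      rownames(out) <- NULL
      out
    }
    gwas <- buildLayer(causalMat)
    eqtl <- buildLayer(causalMat & concord)

    # --- network: background density, enriched among co-causal genes
    coCausal <- (causalMat %*% t(causalMat)) > 0
    pairIdx <- which(upper.tri(coCausal), arr.ind = TRUE)
    pEdge <- ifelse(withSignal & coCausal[pairIdx],
                    pmin(0.9, cfg$networkDensity * cfg$enrichmentFactor),
                    cfg$networkDensity)
    isEdge <- stats::runif(nrow(pairIdx)) < pEdge
    ei <- pairIdx[isEdge, , drop = FALSE]
    weight <- round(stats::runif(nrow(ei), 0.1, 1.5), 4)
    network <- data.frame(gene_a = geneIds[ei[, 1]],
                          gene_b = geneIds[ei[, 2]],
                          weight = weight, stringsAsFactors = FALSE)

    # --- disease similarity
    if (cfg$similarityModel == "identity" || D == 1L) {
      S <- diag(D)
    } else {
      S <- diag(D)
      for (i in seq_len(D - 1)) for (j in (i + 1):D) {
        inter <- length(intersect(causal[[i]], causal[[j]]))
        uni <- length(union(causal[[i]], causal[[j]]))
        S[i, j] <- S[j, i] <- round(inter / uni, 6)
      }
    }
    similarity <- new("DiseaseSimilarity", diseaseIds = diseaseIds,
                      values = S)
    validObject(similarity)

    bundle <- new("SyntheticBundle",
                  annotations = annotations, gwas = gwas, eqtl = eqtl,
                  network = network, associations = truth,
                  similarity = similarity, truth = truth,
                  config = c(unclass(cfg),
                             list(withSignal = withSignal)))
    bundle
  })
}

#' Generate a synthetic input bundle with planted signal
#'
#' Genes get non-overlapping intervals on synthetic chromosomes and
#' SNPs inside their bodies (the same loci feed both omics layers).
#' Causal (gene, disease) pairs draw GWAS p-values from Beta(a, 1) and,
#' with probability `eqtlConcordance`, eQTL p-values from the same
#' signal distribution; all other p-values are Uniform(0, 1). Network
#' edges are enriched among genes sharing a causal disease; the
#' similarity matrix reflects causal-set overlap; the curated
#' association table equals the planted causal map. Byte-identical
#' given the same configuration.
#'
#' @param cfg a [syntheticConfig()].
#' @return a [SyntheticBundle-class].
#' @export
generateBundle <- function(cfg = syntheticConfig()) {
  .generate(cfg, withSignal = TRUE)
}

#' Generate a matched null bundle
#'
#' As [generateBundle()] but with all p-values Uniform(0, 1) and
#' uninformative (background-density, unenriched) network edges. The
#' curated associations are still the planted causal map, so labels
#' carry no recoverable signal: full-pipeline cross-validation on such
#' a bundle calibrates the null AUC near 0.5.
#'
#' @param cfg a [syntheticConfig()].
#' @return a [SyntheticBundle-class].
#' @export
generateNullBundle <- function(cfg = syntheticConfig()) {
  .generate(cfg, withSignal = FALSE)
}

#' Write a bundle as the TSV fixture directory
#'
#' Emits the six pipeline input files in the exact dialects the readers
#' consume (`genes.tsv`, `gwas.tsv`, `eqtl.tsv`, `network.tsv`,
#' `associations.tsv`, `similarity.tsv`), plus `ground_truth.tsv`
#' (excluded from pipeline input) and the generating configuration as
#' `config.txt` key-value pairs.
#'
#' @param bundle a [SyntheticBundle-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
  stopifnot(is(bundle, "SyntheticBundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, f)
    utils::write.table(df, file.path(dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(bundle@annotations, "genes.tsv")
  fmtP <- function(df) {
    df$p_value <- format(df$p_value, digits = 15, scientific = TRUE,
                         trim = TRUE)
    df
  }
  wt(fmtP(bundle@gwas), "gwas.tsv")
  wt(fmtP(bundle@eqtl), "eqtl.tsv")
  wt(bundle@network, "network.tsv")
  wt(bundle@associations, "associations.tsv")
  S <- similarityValues(bundle@similarity)
  simDf <- data.frame(disease_id = rownames(S),
                      apply(S, 2, sprintf, fmt = "%.6f"),
                      check.names = FALSE, stringsAsFactors = FALSE)
  names(simDf) <- c("disease_id", colnames(S))
  utils::write.table(simDf, file.path(dir, "similarity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  wt(bundle@truth, "ground_truth.tsv")
  cfg <- bundle@config
  cfgLines <- vapply(names(cfg), function(k)
    sprintf("%s=%s", k, paste(format(cfg[[k]]), collapse = ",")),
    character(1))
  writeLines(cfgLines, file.path(dir, "config.txt"))
  invisible(dir)
}

#' Read and validate a bundle fixture directory
#'
#' Loads the six input TSVs through the validating readers and checks
#' cross-file consistency (edges and associations resolve against the
#' annotations, SNP diseases against the similarity panel).
#'
#' @param dir directory written by [writeBundle()] (or assembled by
#'   hand in the same dialect).
#' @return list with `annotations`, `snps` (both layers, row-bound),
#'   `network` (edge data.frame), `associations`, `similarity`.
#' @export
readBundle <- function(dir) {
  annotations <- readGeneAnnotations(file.path(dir, "genes.tsv"))
  similarity <- readSimilarityMatrix(file.path(dir, "similarity.tsv"))
  panel <- diseaseIds(similarity)
  gwas <- readSnpAssociations(file.path(dir, "gwas.tsv"), "GWAS",
                              diseaseIds = panel)
  eqtl <- readSnpAssociations(file.path(dir, "eqtl.tsv"), "EQTL",
                              diseaseIds = panel)
  network <- readNetworkEdges(file.path(dir, "network.tsv"),
                              geneIds = annotations$gene_id)
  associations <- readKnownAssociations(
    file.path(dir, "associations.tsv"),
    geneIds = annotations$gene_id, diseaseIds = panel)
  list(annotations = annotations, snps = rbind(gwas, eqtl),
       network = network, associations = associations,
       similarity = similarity)
}
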