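# Feature construction: position-based SNP-to-gene assignment, gene
# filtering, and the 2 x D x K top-SNP p-value block per gene.

.LAYERS <- c("GWAS", "EQTL")

#' Column names of the flat feature matrix
#'
#' Layer-major flattening order `layer.disease.rank`: all D*K GWAS
#' columns first, then the D*K eQTL columns; within a layer, diseases in
#' panel order; within a disease, SNP ranks 1..K (ascending p-value).
#'
#' @param diseaseIds disease panel.
#' @param k top-SNP count K.
#' @return character vector of length 2*D*K.
#' @export
featureColumnNames <- function(diseaseIds, k) {
  as.vector(vapply(.LAYERS, function(l)
    as.vector(vapply(diseaseIds, function(d)
      paste(l, d, seq_len(k), sep = "."), character(k))),
    character(length(diseaseIds) * k)))
}

#' Assign SNPs to genes by genomic position
#'
#' A SNP is assigned to a gene iff both lie on the same chromosome and
#' the SNP position falls inside the gene interval extended by
#' `windowBp` on both sides (`start - windowBp <= pos <= end +
#' windowBp`). A SNP overlapping several genes is assigned to all of
#' them. Interval overlap is computed with
#' [GenomicRanges::findOverlaps()].
#'
#' @param snps data.frame of SNP associations (columns `snp_id`,
#'   `chrom`, `pos`, `disease_id`, `p_value`, `source`), typically the
#'   row-bound output of [readSnpAssociations()] for both layers.
#' @param genes data.frame of gene annotations
#'   (see [readGeneAnnotations()]).
#' @param windowBp non-negative flanking window in base pairs
#'   (default 0: SNP inside the gene body).
#' @param diseaseIds optional disease panel order; defaults to the
#'   sorted unique disease ids present in `snps`.
#' @return a [GeneSnpMap-class].
#' @export
mapSnpsToGenes <- function(snps, genes, windowBp = 0L,
                           diseaseIds = NULL) {
  stopifnot(is.data.frame(snps), is.data.frame(genes))
  if (length(windowBp) != 1L || is.na(windowBp) || windowBp < 0)
    stop("windowBp must be a single non-negative integer", call. = FALSE)
  windowBp <- as.integer(windowBp)
  if (is.null(diseaseIds))
    diseaseIds <- sort(unique(as.character(snps$disease_id)))

  if (nrow(snps) == 0 || nrow(genes) == 0) {
    empty <- data.frame(gene_id = character(), source = character(),
                        disease_id = character(), snp_id = character(),
                        chrom = character(), pos = integer(),
                        p_value = numeric(), stringsAsFactors = FALSE)
    return(new("GeneSnpMap", assignments = empty,
               geneIds = as.character(genes$gene_id),
               diseaseIds = diseaseIds, windowBp = windowBp))
  }

  geneGr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = pmax(1L, genes$start - windowBp),
                              end = genes$end + windowBp))
  snpGr <- GenomicRanges::GRanges(
    seqnames = snps$chrom,
    ranges = IRanges::IRanges(start = snps$pos, width = 1L))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(snpGr, geneGr, ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)

  assignments <- data.frame(
    gene_id = genes$gene_id[si],
    source = snps$source[qi],
    disease_id = snps$disease_id[qi],
    snp_id = snps$snp_id[qi],
    chrom = snps$chrom[qi],
    pos = snps$pos[qi],
    p_value = snps$p_value[qi],
    stringsAsFactors = FALSE)
  rownames(assignments) <- NULL

  obj <- new("GeneSnpMap", assignments = assignments,
             geneIds = as.character(genes$gene_id),
             diseaseIds = diseaseIds, windowBp = windowBp)
  validObject(obj)
  obj
}

#' Keep genes with at least one mapped SNP
#'
#' Returns exactly the genes carrying one or more assigned SNPs in
#' either omics layer for any disease, in annotation order.
#'
#' @param map a [GeneSnpMap-class].
#' @return character vector of retained gene ids.
#' @export
filterGenes <- function(map) {
  stopifnot(is(map, "GeneSnpMap"))
  mapped <- unique(map@assignments$gene_id)
  map@geneIds[map@geneIds %in% mapped]
}

# top-k ascending p-values for one (gene, layer, disease) slice, ties
# broken by (chrom, pos, snp_id), padded with 1
.topK <- function(p, chrom, pos, snpId, k) {
  if (length(p) == 0) return(rep(1, k))
  ord <- order(p, chrom, pos, snpId)
  v <- p[ord]
  if (length(v) >= k) v[seq_len(k)] else c(v, rep(1, k - length(v)))
}

#' Build the per-gene 2 x D x K p-value feature block
#'
#' For every retained gene and every (omics layer, disease) the K
#' smallest assigned p-values are kept, sorted ascending (most
#' significant first); slots beyond the number of assigned SNPs are
#' padded with 1. Ties in p are broken deterministically by genomic
#' coordinate, then SNP id.
#'
#' By default the eQTL layer of a gene-disease slice is restricted to
#' SNPs that also appear in the gene's GWAS-assigned set for the same
#' disease, so the transcriptome layer reports regulatory evidence for
#' the same susceptible loci; `restrictEqtl = FALSE` disables the
#' restriction.
#'
#' @param map a [GeneSnpMap-class].
#' @param k top-SNP count per (layer, disease), default 5.
#' @param genes genes to build features for; default
#'   `filterGenes(map)`. A gene with no assignment at all raises a
#'   lookup error.
#' @param restrictEqtl logical, see above; default TRUE.
#' @param logTransform if TRUE, feature values are `-log10(p)` capped at
#'   20 (so the padding value 1 maps to 0); default FALSE (raw
#'   p-values, the scale on which padding with 1 is defined).
#' @return a [GeneFeatureSet-class].
#' @export
buildGeneFeatures <- function(map, k = 5L, genes = NULL,
                              restrictEqtl = TRUE, logTransform = FALSE) {
  stopifnot(is(map, "GeneSnpMap"))
  if (length(k) != 1L || is.na(k) || k < 1L)
    stop("k must be a single positive integer", call. = FALSE)
  k <- as.integer(k)
  if (is.null(genes)) genes <- filterGenes(map)
  mapped <- unique(map@assignments$gene_id)
  absent <- setdiff(genes, mapped)
  if (length(absent) > 0)
    stop(sprintf("gene(s) without any mapped SNP: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)

  D <- length(map@diseaseIds)
  a <- map@assignments
  a <- a[a$gene_id %in% genes, , drop = FALSE]
  # per (gene, layer, disease) slices
  sliceKey <- paste(a$gene_id, a$source, a$disease_id, sep = "\r")
  slices <- split(seq_len(nrow(a)), sliceKey)

  if (restrictEqtl) {
    # GWAS snp sets per (gene, disease)
    gw <- a[a$source == "GWAS", , drop = FALSE]
    gwKey <- paste(gw$gene_id, gw$disease_id, sep = "\r")
    gwSnps <- split(gw$snp_id, gwKey)
  }

  values <- matrix(1, nrow = length(genes), ncol = 2L * D * k)
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    for (li in 1:2) {
      layer <- .LAYERS[li]
      for (di in seq_len(D)) {
        d <- map@diseaseIds[di]
        idx <- slices[[paste(g, layer, d, sep = "\r")]]
        if (is.null(idx)) next
        sl <- a[idx, , drop = FALSE]
        if (restrictEqtl && layer == "EQTL") {
          keepSnps <- gwSnps[[paste(g, d, sep = "\r")]]
          sl <- sl[sl$snp_id %in% keepSnps, , drop = FALSE]
          if (nrow(sl) == 0) next
        }
        col0 <- ((li - 1L) * D + (di - 1L)) * k
        values[gi, (col0 + 1L):(col0 + k)] <-
          .topK(sl$p_value, sl$chrom, sl$pos, sl$snp_id, k)
      }
    }
  }

  transform <- "raw"
  if (logTransform) {
    values <- pmin(-log10(values), 20)
    transform <- "log10"
  }
  obj <- new("GeneFeatureSet", values = values, geneIds = genes,
             diseaseIds = map@diseaseIds, topK = k,
             transform = transform, smoothed = FALSE)
  validObject(obj)
  obj
}

#' Extract one gene's feature block as a 2 x D x K array
#'
#' @param x a [GeneFeatureSet-class].
#' @param geneId gene identifier.
#' @return numeric array of dim (2, D, K): layer x disease x rank.
#' @export
geneFeatureArray <- function(x, geneId) {
  stopifnot(is(x, "GeneFeatureSet"))
  gi <- match(geneId, x@geneIds)
  if (is.na(gi))
    stop(sprintf("gene '%s' not in feature set", geneId), call. = FALSE)
  unflattenFeature(x@values[gi, ], length(x@diseaseIds), x@topK)
}

#' Flatten a 2 x D x K feature block to a length-2DK vector
#'
#' Layer-major order: index of (layer l, disease d, rank r) is
#' `(l-1)*D*K + (d-1)*K + r`. `unflattenFeature()` is its exact inverse.
#'
#' @param arr numeric array of dim (2, D, K).
#' @return numeric vector of length 2*D*K.
#' @export
flattenFeature <- function(arr) {
  stopifnot(length(dim(arr)) == 3L, dim(arr)[1] == 2L)
  as.vector(aperm(arr, c(3, 2, 1)))
}

#' @rdname flattenFeature
#' @param v numeric vector of length 2*D*K.
#' @param D number of diseases.
#' @param K top-SNP count.
#' @export
unflattenFeature <- function(v, D, K) {
  stopifnot(length(v) == 2L * D * K)
  aperm(array(v, dim = c(K, D, 2L)), c(3, 2, 1))
}

#' Assemble a GeneFeatureSet from a flat matrix
#'
#' Used to rebuild a feature set after external manipulation (e.g.
#' reading a feature export); columns must follow the layer-major
#' `layer.disease.rank` order of [featureMatrix()].
#'
#' @param values numeric N x (2*D*K) matrix.
#' @param geneIds,diseaseIds,topK the feature geometry.
#' @param transform `"raw"` or `"log10"`.
#' @param smoothed logical.
#' @return a [GeneFeatureSet-class].
#' @export
geneFeatureSet <- function(values, geneIds, diseaseIds, topK,
                           transform = "raw", smoothed = FALSE) {
  obj <- new("GeneFeatureSet", values = unname(as.matrix(values)),
             geneIds = as.character(geneIds),
             diseaseIds = as.character(diseaseIds),
             topK = as.integer(topK), transform = transform,
             smoothed = smoothed)
  validObject(obj)
  obj
}

#' Export a feature matrix as TSV
#'
#' One row per gene; columns `gene_id` then `layer.disease.rank`.
#'
#' @param x a [GeneFeatureSet-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFeatureMatrix <- function(x, path) {
  m <- featureMatrix(x)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
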