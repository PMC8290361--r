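# Readers and writers for the five TSV input tables and the score
# output. All tables are UTF-8, tab-separated with a header row and '.'
# as the decimal separator; gene and disease identifiers are assumed to
# be pre-harmonized to one namespace, so readers validate cross-file
# consistency rather than converting ids.

.readTsv <- function(path, requiredCols) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  missing <- setdiff(requiredCols, names(df))
  if (length(missing) > 0)
    stop(sprintf("%s: missing required column(s): %s",
                 basename(path), paste(missing, collapse = ", ")),
         call. = FALSE)
  df[requiredCols]
}

# first offending data row, reported as its line number in the file
# (header is line 1)
.failRow <- function(path, rowIdx, what) {
  stop(sprintf("%s, line %d: %s", basename(path), rowIdx + 1L, what),
       call. = FALSE)
}

.checkWholeNumber <- function(x) {
  is.numeric(x) & is.finite(x) & x == floor(x)
}

#' Read a gene annotation table
#'
#' Parses a tab-separated table with header columns `gene_id`, `chrom`,
#' `start`, `end` (1-based inclusive coordinates, GTF convention) and
#' enforces the row invariants: non-empty chromosome, `start <= end`,
#' unique gene ids.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\tchrom\tstart\tend", "G1\tchr1\t100\t200"), tf)
#' readGeneAnnotations(tf)
#' @export
readGeneAnnotations <- function(path) {
  df <- .readTsv(path, c("gene_id", "chrom", "start", "end"))
  df$gene_id <- as.character(df$gene_id)
  df$chrom <- as.character(df$chrom)
  for (i in seq_len(nrow(df))) {
    if (is.na(df$gene_id[i]) || !nzchar(df$gene_id[i]))
      .failRow(path, i, "empty gene_id")
    if (is.na(df$chrom[i]) || !nzchar(df$chrom[i]))
      .failRow(path, i, sprintf("empty chrom for gene %s", df$gene_id[i]))
    if (!.checkWholeNumber(df$start[i]) || !.checkWholeNumber(df$end[i]) ||
        df$start[i] < 1)
      .failRow(path, i, sprintf("invalid coordinates for gene %s",
                                df$gene_id[i]))
    if (df$start[i] > df$end[i])
      .failRow(path, i, sprintf("start > end for gene %s", df$gene_id[i]))
  }
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup) > 0)
    stop(sprintf("%s: duplicate gene_id: %s", basename(path),
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  rownames(df) <- NULL
  df
}

#' Read a SNP association summary table
#'
#' Parses a tab-separated table with header columns `snp_id`, `chrom`,
#' `pos`, `disease_id`, `p_value` and tags every row with the given
#' omics layer. P-values must lie in (0, 1]: 1 is the padding value of
#' the feature construction and is accepted, while 0 is rejected because
#' ranking and log-loss semantics are defined on (0, 1] only.
#'
#' @param path path to the TSV file.
#' @param source omics layer, `"GWAS"` or `"EQTL"`.
#' @param diseaseIds optional disease panel; rows referencing a disease
#'   outside the panel raise a validation error.
#' @return data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `disease_id`, `p_value`, `source`.
#' @export
readSnpAssociations <- function(path, source = c("GWAS", "EQTL"),
                                diseaseIds = NULL) {
  source <- match.arg(source)
  df <- .readTsv(path, c("snp_id", "chrom", "pos", "disease_id",
                         "p_value"))
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$disease_id <- as.character(df$disease_id)
  for (i in seq_len(nrow(df))) {
    if (is.na(df$snp_id[i]) || !nzchar(df$snp_id[i]))
      .failRow(path, i, "empty snp_id")
    if (is.na(df$chrom[i]) || !nzchar(df$chrom[i]))
      .failRow(path, i, sprintf("empty chrom for SNP %s", df$snp_id[i]))
    if (!.checkWholeNumber(df$pos[i]) || df$pos[i] < 1)
      .failRow(path, i, sprintf("invalid position for SNP %s",
                                df$snp_id[i]))
    p <- df$p_value[i]
    if (!is.numeric(p) || is.na(p) || p <= 0 || p > 1)
      .failRow(path, i,
               sprintf("p_value %s outside (0, 1] for SNP %s",
                       format(p), df$snp_id[i]))
    if (!is.null(diseaseIds) && !(df$disease_id[i] %in% diseaseIds))
      .failRow(path, i, sprintf("unknown disease_id '%s'",
                                df$disease_id[i]))
  }
  df$pos <- as.integer(df$pos)
  df$source <- source
  rownames(df) <- NULL
  df
}

#' Read a weighted gene-gene interaction edge list
#'
#' Parses a tab-separated edge list with header columns `gene_a`,
#' `gene_b`, `weight` (non-negative, HumanNet-style functional
#' association scores). Self-edges are rejected: self-connections are
#' added analytically by the propagation-matrix construction.
#'
#' @param path path to the TSV file.
#' @param geneIds optional gene universe; edges referencing a gene
#'   outside it raise a consistency error naming the gene.
#' @return data.frame with columns `gene_a`, `gene_b`, `weight`.
#' @export
readNetworkEdges <- function(path, geneIds = NULL) {
  df <- .readTsv(path, c("gene_a", "gene_b", "weight"))
  df$gene_a <- as.character(df$gene_a)
  df$gene_b <- as.character(df$gene_b)
  for (i in seq_len(nrow(df))) {
    if (!is.numeric(df$weight[i]) || is.na(df$weight[i]) ||
        df$weight[i] < 0)
      .failRow(path, i, sprintf("negative or missing weight for edge %s-%s",
                                df$gene_a[i], df$gene_b[i]))
    if (df$gene_a[i] == df$gene_b[i])
      .failRow(path, i, sprintf("self-edge on gene %s", df$gene_a[i]))
  }
  if (!is.null(geneIds)) {
    unknown <- setdiff(unique(c(df$gene_a, df$gene_b)), geneIds)
    if (length(unknown) > 0)
      stop(sprintf("%s: edge(s) reference gene(s) absent from annotations: %s",
                   basename(path), paste(unknown, collapse = ", ")),
           call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Read a curated disease-gene association list
#'
#' @param path path to a TSV with header columns `disease_id`, `gene_id`.
#' @param geneIds optional gene universe for referential validation.
#' @param diseaseIds optional disease panel for referential validation.
#' @return data.frame with columns `disease_id`, `gene_id`; pairs unique.
#' @export
readKnownAssociations <- function(path, geneIds = NULL,
                                  diseaseIds = NULL) {
  df <- .readTsv(path, c("disease_id", "gene_id"))
  df$disease_id <- as.character(df$disease_id)
  df$gene_id <- as.character(df$gene_id)
  key <- paste(df$disease_id, df$gene_id, sep = "\r")
  if (anyDuplicated(key))
    .failRow(path, which(duplicated(key))[1],
             "duplicate (disease_id, gene_id) pair")
  if (!is.null(geneIds)) {
    unknown <- setdiff(unique(df$gene_id), geneIds)
    if (length(unknown) > 0)
      stop(sprintf("%s: association(s) reference unknown gene(s): %s",
                   basename(path), paste(unknown, collapse = ", ")),
           call. = FALSE)
  }
  if (!is.null(diseaseIds)) {
    unknown <- setdiff(unique(df$disease_id), diseaseIds)
    if (length(unknown) > 0)
      stop(sprintf("%s: association(s) reference unknown disease(s): %s",
                   basename(path), paste(unknown, collapse = ", ")),
           call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Read a disease-disease similarity matrix
#'
#' Parses a square labeled TSV (first column holds row labels, header
#' holds column labels) into a [DiseaseSimilarity-class]. The matrix
#' must be square with matching row/column labels, have unit diagonal,
#' entries in [0, 1], and be symmetric within tolerance 1e-9.
#'
#' @param path path to the TSV file.
#' @return a [DiseaseSimilarity-class].
#' @export
readSimilarityMatrix <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, quote = "")
  m <- as.matrix(df)
  if (nrow(m) != ncol(m))
    stop(sprintf("%s: similarity matrix must be square (got %d x %d)",
                 basename(path), nrow(m), ncol(m)), call. = FALSE)
  if (!identical(rownames(m), colnames(m)))
    stop(sprintf("%s: row and column labels differ", basename(path)),
         call. = FALSE)
  storage.mode(m) <- "double"
  obj <- new("DiseaseSimilarity", diseaseIds = rownames(m),
             values = unname(m))
  validObject(obj)
  obj
}

#' Write disease-gene pair scores
#'
#' Writes a TSV with columns `disease_id`, `gene_id`, `score` and, when
#' present, `label`, sorted by disease id then descending score. Scores
#' are written with six decimal places, the declared round-trip
#' precision of [readScores()].
#'
#' @param scores data.frame with columns `disease_id`, `gene_id`,
#'   `score` and optionally `label`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeScores <- function(scores, path) {
  req <- c("disease_id", "gene_id", "score")
  if (!all(req %in% names(scores)))
    stop("scores must have columns disease_id, gene_id, score",
         call. = FALSE)
  if (nrow(scores) > 0 && !all(is.finite(scores$score)))
    stop("scores must be finite", call. = FALSE)
  hasLabel <- "label" %in% names(scores)
  ord <- order(scores$disease_id, -scores$score, scores$gene_id)
  s <- scores[ord, , drop = FALSE]
  out <- data.frame(disease_id = s$disease_id, gene_id = s$gene_id,
                    score = sprintf("%.6f", s$score),
                    stringsAsFactors = FALSE)
  if (hasLabel) out$label <- s$label
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a score table written by [writeScores()]
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `disease_id`, `gene_id`, `score`
#'   and, if present in the file, `label`.
#' @export
readScores <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  req <- c("disease_id", "gene_id", "score")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0)
    stop(sprintf("%s: missing column(s): %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  df$disease_id <- as.character(df$disease_id)
  df$gene_id <- as.character(df$gene_id)
  df
}

#' Write a gene annotation table
#'
#' Inverse of [readGeneAnnotations()]; the write-then-read round trip
#' reproduces the input table.
#'
#' @param annotations data.frame with columns `gene_id`, `chrom`,
#'   `start`, `end`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGeneAnnotations <- function(annotations, path) {
  utils::write.table(
    annotations[c("gene_id", "chrom", "start", "end")], path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
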