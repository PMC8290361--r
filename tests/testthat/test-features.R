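test_that("SNP-to-gene mapping matches the windowed interval definition", {
  genes <- data.frame(gene_id = "G1", chrom = "chr1", start = 100L,
                      end = 200L, stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = c("rs1", "rs2"), chrom = "chr1",
                     pos = c(150L, 250L), disease_id = "D1",
                     p_value = c(0.1, 0.2), source = "GWAS",
                     stringsAsFactors = FALSE)
  m0 <- mapSnpsToGenes(snps, genes, windowBp = 0L)
  expect_equal(m0@assignments$snp_id, "rs1")
  m50 <- mapSnpsToGenes(snps, genes, windowBp = 50L)
  expect_setequal(m50@assignments$snp_id, c("rs1", "rs2"))
  # chromosome mismatch never maps
  snps2 <- transform(snps, chrom = "chr2")
  expect_equal(nrow(mapSnpsToGenes(snps2, genes)@assignments), 0L)
})

test_that("mapping agrees with the exhaustive overlap scan on random instances", {
  set.seed(101)
  for (rep_ in 1:5) {
    nG <- sample(5:30, 1)
    nS <- sample(20:200, 1)
    genes <- data.frame(
      gene_id = sprintf("G%d", seq_len(nG)),
      chrom = sample(c("chr1", "chr2", "chr3"), nG, replace = TRUE),
      start = sample(1:5000, nG), stringsAsFactors = FALSE)
    genes$end <- genes$start + sample(50:800, nG, replace = TRUE)
    snps <- data.frame(
      snp_id = sprintf("rs%d", seq_len(nS)),
      chrom = sample(c("chr1", "chr2", "chr3"), nS, replace = TRUE),
      pos = sample(1:6000, nS, replace = TRUE),
      disease_id = sample(c("D1", "D2"), nS, replace = TRUE),
      p_value = runif(nS), source = "GWAS",
      stringsAsFactors = FALSE)
    w <- sample(c(0L, 25L, 100L), 1)
    got <- mapSnpsToGenes(snps, genes, windowBp = w)@assignments
    want <- bruteOverlapScan(snps, genes, windowBp = w)
    key <- function(df) sort(paste(df$gene_id, df$snp_id))
    expect_identical(key(got), key(want))
  }
})

test_that("filterGenes keeps exactly the genes with a mapped SNP in either layer", {
  ann <- toyAnnotations()[1:3, ]
  snps <- rbind(
    data.frame(snp_id = "a", chrom = "chr1", pos = 1500L,
               disease_id = "D1", p_value = 0.1, source = "GWAS"),
    data.frame(snp_id = "b", chrom = "chr1", pos = 5500L,
               disease_id = "D1", p_value = 0.2, source = "EQTL"))
  map <- mapSnpsToGenes(snps, ann)
  # G03 has no SNP; G02 mapped only in the eQTL layer but retained
  expect_equal(filterGenes(map), c("G01", "G02"))
  # all genes unmapped -> empty result
  mapEmpty <- mapSnpsToGenes(snps[0, ], ann)
  expect_equal(length(filterGenes(mapEmpty)), 0L)
})

test_that("top-k selection sorts ascending, pads with 1 and breaks ties deterministically", {
  ann <- toyAnnotations()[1, ]
  snps <- data.frame(
    snp_id = c("s1", "s2", "s3", "s4"),
    chrom = "chr1", pos = c(1100L, 1200L, 1300L, 1400L),
    disease_id = "D1",
    p_value = c(0.01, 0.005, 0.5, 0.5), source = "GWAS",
    stringsAsFactors = FALSE)
  map <- mapSnpsToGenes(snps, ann, diseaseIds = c("D1", "D2"))
  fs <- buildGeneFeatures(map, k = 5L)
  m <- featureMatrix(fs)
  # two p-values for D1 -> sorted ascending then padded with 1
  expect_equal(unname(m[1, paste0("GWAS.D1.", 1:5)]),
               c(0.005, 0.01, 0.5, 0.5, 1))
  # disease with no SNPs -> pure padding
  expect_equal(unname(m[1, paste0("GWAS.D2.", 1:5)]), rep(1, 5))
  # eQTL layer had nothing -> padding
  expect_equal(unname(m[1, paste0("EQTL.D1.", 1:5)]), rep(1, 5))

  # tie on p broken by genomic position: the rank-3 slot must be s3
  snps7 <- data.frame(
    snp_id = sprintf("t%d", 1:7), chrom = "chr1",
    pos = 1100L + 10L * (1:7), disease_id = "D1",
    p_value = c(0.3, 0.2, 0.1, 0.4, 0.5, 0.6, 0.7), source = "GWAS",
    stringsAsFactors = FALSE)
  m7 <- featureMatrix(buildGeneFeatures(
    mapSnpsToGenes(snps7, ann, diseaseIds = "D1"), k = 5L))
  expect_equal(unname(m7[1, 1:5]), c(0.1, 0.2, 0.3, 0.4, 0.5))
})

test_that("requesting features for an unmapped gene is a lookup error", {
  ann <- toyAnnotations()[1:2, ]
  snps <- data.frame(snp_id = "a", chrom = "chr1", pos = 1500L,
                     disease_id = "D1", p_value = 0.1, source = "GWAS")
  map <- mapSnpsToGenes(snps, ann)
  expect_error(buildGeneFeatures(map, genes = c("G01", "G02")), "G02")
})

test_that("feature geometry is 2*D*K with layer-major flattening that round-trips", {
  D <- 5L; K <- 5L
  cfgSnps <- toySnps(nSnps = rep(3L, 10))
  map <- mapSnpsToGenes(cfgSnps, toyAnnotations(),
                        diseaseIds = sprintf("D%d", 1:5))
  fs <- buildGeneFeatures(map, k = K)
  expect_equal(ncol(featureMatrix(fs)), 2L * D * K) # the 2 x 25 block
  # empty gene list -> 0 x F matrix
  fs0 <- buildGeneFeatures(map, k = K, genes = character())
  expect_equal(dim(featureMatrix(fs0)), c(0L, 50L))
  # unflatten(flatten(x)) == x on random blocks
  set.seed(7)
  for (i in 1:10) {
    arr <- array(runif(2 * D * K), dim = c(2, D, K))
    expect_identical(unflattenFeature(flattenFeature(arr), D, K), arr)
  }
  # the array accessor agrees with the flat matrix layout
  arr <- geneFeatureArray(fs, "G01")
  m <- featureMatrix(fs)
  expect_equal(arr[1, 2, 3], unname(m["G01", "GWAS.D2.3"]))
  expect_equal(arr[2, 5, 1], unname(m["G01", "EQTL.D5.1"]))
})

test_that("adding a significant SNP never increases any feature entry (padding monotonicity)", {
  ann <- toyAnnotations()[1, ]
  set.seed(20)
  base <- data.frame(
    snp_id = sprintf("b%d", 1:4), chrom = "chr1",
    pos = 1100L + 10L * (1:4), disease_id = "D1",
    p_value = round(runif(4), 4), source = "GWAS",
    stringsAsFactors = FALSE)
  for (pNew in c(0.9999, 0.5, 0.001)) {
    extra <- data.frame(snp_id = "new", chrom = "chr1", pos = 1500L,
                        disease_id = "D1", p_value = pNew,
                        source = "GWAS", stringsAsFactors = FALSE)
    fBase <- featureMatrix(buildGeneFeatures(
      mapSnpsToGenes(base, ann, diseaseIds = "D1")))
    fMore <- featureMatrix(buildGeneFeatures(
      mapSnpsToGenes(rbind(base, extra), ann, diseaseIds = "D1")))
    expect_true(all(fMore <= fBase))
  }
})

test_that("eQTL layer restriction to GWAS-mapped loci is applied and can be disabled", {
  ann <- toyAnnotations()[1, ]
  gwas <- data.frame(snp_id = c("s1", "s2"), chrom = "chr1",
                     pos = c(1100L, 1200L), disease_id = "D1",
                     p_value = c(0.1, 0.2), source = "GWAS",
                     stringsAsFactors = FALSE)
  eqtl <- data.frame(snp_id = c("s1", "sX"), chrom = "chr1",
                     pos = c(1100L, 1300L), disease_id = "D1",
                     p_value = c(0.05, 0.01), source = "EQTL",
                     stringsAsFactors = FALSE)
  map <- mapSnpsToGenes(rbind(gwas, eqtl), ann, diseaseIds = "D1")
  mRestr <- featureMatrix(buildGeneFeatures(map, restrictEqtl = TRUE))
  # sX is not a GWAS locus of this gene: excluded under restriction
  expect_equal(unname(mRestr[1, 6:10]), c(0.05, 1, 1, 1, 1))
  mFree <- featureMatrix(buildGeneFeatures(map, restrictEqtl = FALSE))
  expect_equal(unname(mFree[1, 6:10]), c(0.01, 0.05, 1, 1, 1))
})

test_that("log transform caps at 20 and maps the padding value to 0", {
  ann <- toyAnnotations()[1, ]
  snps <- data.frame(snp_id = c("s1", "s2"), chrom = "chr1",
                     pos = c(1100L, 1200L), disease_id = "D1",
                     p_value = c(1e-30, 0.01), source = "GWAS",
                     stringsAsFactors = FALSE)
  map <- mapSnpsToGenes(snps, ann, diseaseIds = "D1")
  m <- featureMatrix(buildGeneFeatures(map, logTransform = TRUE))
  expect_equal(unname(m[1, 1:3]), c(20, 2, 0))
})
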