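test_that("reference generation is seed-deterministic", {
  a <- simulateReference(nTypes = 3, nCellsPerType = 10, nFeatures = 50,
                         nMarkersPerType = 5, seed = 42)
  b <- simulateReference(nTypes = 3, nCellsPerType = 10, nFeatures = 50,
                         nMarkersPerType = 5, seed = 42)
  expect_identical(as.matrix(assay(a$ref, "counts")),
                   as.matrix(assay(b$ref, "counts")))
  expect_identical(a$truth$marker_map, b$truth$marker_map)
  c <- simulateReference(nTypes = 3, nCellsPerType = 10, nFeatures = 50,
                         nMarkersPerType = 5, seed = 43)
  expect_false(identical(as.matrix(assay(a$ref, "counts")),
                         as.matrix(assay(c$ref, "counts"))))
})

test_that("planted markers at fourfold enrichment are recovered", {
  sim <- simulateReference(nTypes = 7, nCellsPerType = 50, nFeatures = 200,
                           nMarkersPerType = 10, fold = 4, seed = 7)
  ref <- sim$ref
  expressed <- filterExpressedFeatures(assay(ref, "counts"),
                                       colData(ref)$cell_type)
  norm <- normalizeRna(assay(ref, "counts"))
  means <- meanActivityByType(norm[expressed, , drop = FALSE],
                              colData(ref)$cell_type)
  sel <- selectTopFraction(specificityScores(means), 0.10, expressed)
  recov <- vapply(names(sim$truth$marker_map), function(ty)
    mean(sim$truth$marker_map[[ty]] %in% sel[[ty]]), 0)
  expect_gte(mean(recov), 0.95)
})

test_that("a fold-1 (null) reference selects planted ids only at chance", {
  sim <- simulateReference(nTypes = 4, nCellsPerType = 40, nFeatures = 200,
                           nMarkersPerType = 20, fold = 1, seed = 19)
  ref <- sim$ref
  expressed <- filterExpressedFeatures(assay(ref, "counts"),
                                       colData(ref)$cell_type)
  norm <- normalizeRna(assay(ref, "counts"))
  means <- meanActivityByType(norm[expressed, , drop = FALSE],
                              colData(ref)$cell_type)
  sel <- selectTopFraction(specificityScores(means), 0.10, expressed)
  recov <- vapply(names(sim$truth$marker_map), function(ty)
    mean(sim$truth$marker_map[[ty]] %in% sel[[ty]]), 0)
  # chance level is |selected| / |expressed| ~= 0.10
  expect_lt(mean(recov), 0.35)
})

test_that("genotype dosages follow the binomial model and fixed seeds", {
  dm <- simulateGenotypes(2000, 5, mafRange = c(0.5, 0.5), seed = 3)
  mns <- colMeans(dosages(dm))
  se <- sqrt(2 * 0.5 * 0.5 / 2000)
  expect_true(all(abs(mns - 1) < 3 * se + 0.02))
  dm2 <- simulateGenotypes(2000, 5, mafRange = c(0.5, 0.5), seed = 3)
  expect_identical(dosages(dm), dosages(dm2))
  one <- simulateGenotypes(10, 1, seed = 1)
  expect_equal(dim(dosages(one)), c(10L, 1L))
  expect_equal(nrow(variantLoci(one)), 1L)
})

test_that("phenotypes hit the target heritability and prevalence", {
  dm <- simulateGenotypes(2000, 50, seed = 5)
  cm <- data.frame(variant_id = variantLoci(dm)$variant_id[1:10],
                   effect = 0.3)
  ph <- simulatePhenotypes(dm, cm, h2 = 0.3, seed = 6, prevalence = 0.4)
  G <- attr(ph, "G")
  r2 <- summary(lm(ph$neuritic_plaque ~ G))$r.squared
  expect_equal(r2, 0.3, tolerance = 0.05)
  expect_equal(mean(ph$ad_pathdx), 0.4, tolerance = 3 * sqrt(0.24 / 2000) + 0.02)
  expect_true(all(ph$apoe_e2_dosage + ph$apoe_e4_dosage <= 2))
  expect_error(simulatePhenotypes(dm, cm[0, ], h2 = 0.3), "unreachable")
  null <- simulatePhenotypes(dm, cm[0, ], h2 = 0, seed = 6)
  expect_true(all(is.finite(null$neuritic_plaque)))
})

test_that("cohort sumstats recover planted effects through the meta-analysis", {
  cm <- data.frame(variant_id = c("var00003", "var00007"), effect = 0.4)
  hits <- 0
  reps <- 10
  for (r in seq_len(reps)) {
    sim <- simulateCohortSumstats(5, 2000, nVariants = 10, causalMap = cm,
                                  seed = 100 + r)
    row <- sim$meta[sim$meta$variant_id == "var00003", ]
    if (nrow(row) == 1 && abs(row$beta - 0.4) <= 2 * row$se)
      hits <- hits + 1
  }
  expect_gte(hits, reps - 1)
})

test_that("single-cohort meta equals the cohort and null z is standard normal", {
  sim <- simulateCohortSumstats(1, 800, nVariants = 20, seed = 11)
  expect_equal(sim$meta$beta,
               sim$cohorts[[1]]$beta[match(sim$meta$variant_id,
                                           sim$cohorts[[1]]$variant_id)])
  simNull <- simulateCohortSumstats(3, 700, nVariants = 60, seed = 12)
  z <- simNull$meta$z
  expect_equal(mean(z), 0, tolerance = 3 / sqrt(length(z)) + 0.05)
  expect_equal(sd(z), 1, tolerance = 0.3)
  expect_gt(ks.test(pnorm(z), "punif")$p.value, 0.01)
})

test_that("peak-based variant sets are more type-exclusive than window-based sets", {
  # same toy genome: 500 bp peaks cannot blanket it the way 30 kb gene
  # windows do, so pairwise Jaccard overlap must be lower for peaks
  rna <- simulateReference(nTypes = 4, nCellsPerType = 30, nFeatures = 150,
                           nMarkersPerType = 10, fold = 4, seed = 21,
                           modality = "RNA", featureSpacing = 6e4)
  atac <- simulateReference(nTypes = 4, nCellsPerType = 30, nFeatures = 150,
                            nMarkersPerType = 10, fold = 4, seed = 22,
                            modality = "ATAC")
  variants <- variantLoci(simulateGenotypes(2, 4000, seed = 23))
  snpSets <- function(sim, mkRanges) {
    ref <- sim$ref
    expressed <- filterExpressedFeatures(assay(ref, "counts"),
                                         colData(ref)$cell_type)
    norm <- if (modality(ref) == "RNA") normalizeRna(assay(ref, "counts"))
    else tfidfTransform(assay(ref, "counts"))
    means <- meanActivityByType(norm[expressed, , drop = FALSE],
                                colData(ref)$cell_type,
                                clipNegative = modality(ref) == "ATAC")
    sel <- selectTopFraction(specificityScores(means), 0.2, expressed)
    lapply(sel, function(ids) snpsInRanges(variants, mkRanges(ids)))
  }
  feats <- function(sim) featureGRanges(sim$truth$features)
  rnaSets <- snpSets(rna, function(ids) geneWindows(feats(rna)[ids], 30000))
  atacSets <- snpSets(atac, function(ids) peakRanges(ids, feats(atac)))
  jac <- function(sets) {
    prs <- combn(length(sets), 2)
    mean(apply(prs, 2, function(ij) {
      a <- sets[[ij[1]]]; b <- sets[[ij[2]]]
      if (length(union(a, b)) == 0) return(0)
      length(intersect(a, b)) / length(union(a, b))
    }))
  }
  expect_lt(jac(atacSets), jac(rnaSets))
})

test_that("generator parameter contradictions are refused", {
  expect_error(simulateReference(nTypes = 5, nFeatures = 20,
                                 nMarkersPerType = 10), "markers")
  expect_error(simulateGenotypes(0, 5), "nSamples")
  expect_error(simulatePhenotypes(simulateGenotypes(10, 2, seed = 1),
                                  data.frame(variant_id = "zz",
                                             effect = 1), 0.3),
               "absent")
})

test_that("the full synthetic study ranks the causal cell type first", {
  st <- simulateStudy(seed = 101, nSamples = 1000)
  bat <- st$battery[st$battery$predictor != "genome", ]
  expect_equal(bat$predictor[which.min(bat$p)], "AST")
  # causal variants sit inside the causal type's derivable ranges
  inRange <- snpsInRanges(variantLoci(st$dosageMatrix), st$ranges$AST)
  expect_true(all(st$causalMap$variant_id %in% inRange))
})
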