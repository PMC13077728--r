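test_that("a noiseless linear outcome is fit exactly", {
  ph <- makePhenos(200)
  pred <- rnorm(200)
  ph$neuritic_plaque <- 2 * pred
  rec <- suppressWarnings(
    fitOutcomeModel(pred, "neuritic_plaque", ph, "linear"))
  expect_equal(rec$beta, 2, tolerance = 1e-6)
  expect_lt(rec$p, 1e-12)
  expect_equal(rec$n, 200)
})

test_that("education enters the covariate list only for MMSE", {
  ph <- makePhenos(100)
  pred <- rnorm(100)
  recM <- fitOutcomeModel(pred, "mmse", ph, "linear")
  expect_match(recM$covariate_list, "education_years")
  recO <- fitOutcomeModel(pred, "nft_burden", ph, "linear")
  expect_false(grepl("education_years", recO$covariate_list))
})

test_that("collinear designs error with the offending columns named", {
  ph <- makePhenos(100)
  pred <- ph$age_at_death * 2    # exact combination of a covariate
  expect_error(fitOutcomeModel(pred, "nft_burden", ph, "linear"),
               "collinear")
  ph2 <- ph; ph2$pc2 <- ph$pc1
  expect_error(fitOutcomeModel(rnorm(100), "nft_burden", ph2, "linear"),
               "pc2|pc1")
})

test_that("model preconditions are enforced", {
  ph <- makePhenos(100)
  expect_error(fitOutcomeModel(rnorm(100), "nft_burden", ph, "logistic"),
               "0/1")
  ph$nft_burden[1:90] <- NA
  expect_error(fitOutcomeModel(rnorm(100), "nft_burden", ph, "linear"),
               "complete cases")
  expect_error(fitOutcomeModel(rnorm(100), "zzz", ph, "linear"),
               "not in phenotype")
})

test_that("the multiplicative adjustment is min(1, p*m), monotone, capped", {
  expect_equal(adjustFdrMultiply(0.001, 6), 0.006)
  expect_equal(adjustFdrMultiply(0.3, 6), 1.0)
  p <- sort(runif(50))
  f6 <- adjustFdrMultiply(p, 6)
  expect_true(all(diff(f6) >= 0))                 # monotone in p
  expect_true(all(f6 >= p))                       # never below p
  expect_true(all(adjustFdrMultiply(p, 8) >= f6)) # monotone in m
  # the BH option is a different quantity
  expect_false(isTRUE(all.equal(adjustFdrBH(p), f6)))
})

test_that("per-SNP scan finds a planted causal variant and reports the line", {
  set.seed(99)
  hits <- 0
  for (r in 1:10) {
    n <- 1000
    d <- matrix(rbinom(n * 20, 2, 0.3), n, 20)
    dm <- makeDosage(d)
    ph <- makePhenos(n, seed = 1000 + r)
    ph$neuritic_plaque <- 0.3 * d[, 7] + rnorm(n)
    res <- perSnpAssociation(variantLoci(dm)$variant_id, dm,
                             "neuritic_plaque", ph)
    expect_equal(attr(res, "significance_line"), 0.05 / 20)
    if (res$predictor[which.min(res$p)] == "v007") hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("per-SNP scan rejects empty and unknown sets", {
  dm <- makeDosage(matrix(rbinom(40, 2, 0.3), 20, 2))
  ph <- makePhenos(20)
  expect_error(perSnpAssociation(character(0), dm, "mmse", ph), "empty")
  expect_error(perSnpAssociation("nope", dm, "mmse", ph), "absent")
})

test_that("conditioning behaves as orthogonality and mediation predict", {
  set.seed(55)
  n <- 500
  d <- matrix(rbinom(n * 2, 2, 0.3), n, 2)
  dm <- makeDosage(d)
  ph <- makePhenos(n, seed = 7)
  ph$neuritic_plaque <- 0.4 * d[, 1] + rnorm(n)
  base <- perSnpAssociation("v001", dm, "neuritic_plaque", ph)
  # conditioning on an orthogonal, independently generated covariate
  ph$ortho <- rnorm(n)
  cond <- conditionalAssociation("v001", "neuritic_plaque", "ortho", dm, ph)
  expect_equal(cond$beta, base$beta, tolerance = 0.02)
  expect_match(cond$covariate_list, "ortho")
  # full mediation: outcome is a function of the mediator only
  ph$mediator <- 0.5 * d[, 1] + 0.05 * rnorm(n)
  ph$neuritic_plaque <- 2 * ph$mediator + rnorm(n)
  raw <- perSnpAssociation("v001", dm, "neuritic_plaque", ph)
  med <- conditionalAssociation("v001", "neuritic_plaque", "mediator",
                                dm, ph)
  expect_lt(abs(med$beta), abs(raw$beta) / 2)
  expect_error(
    conditionalAssociation("v001", "neuritic_plaque", "neuritic_plaque",
                           dm, ph), "identical")
})

test_that("locus scans are window-inclusive, ordered and monotone", {
  n <- 100
  d <- matrix(rbinom(n * 5, 2, 0.3), n, 5)
  dm <- makeDosage(d, pos = c(1000L, 2000L, 302000L, 302001L, 5000000L))
  ph <- makePhenos(n)
  only <- locusWindowScan("v002", dm, "mmse", ph, windowBp = 0)
  expect_equal(only$predictor, "v002")
  w <- locusWindowScan("v002", dm, "mmse", ph, windowBp = 300000)
  expect_identical(w$predictor, c("v001", "v002", "v003"))  # 302000 is +300000
  expect_true(!is.unsorted(w$pos))
  wBig <- locusWindowScan("v002", dm, "mmse", ph, windowBp = 400000)
  expect_true(all(w$predictor %in% wBig$predictor))
  expect_error(locusWindowScan("nope", dm, "mmse", ph), "absent")
})

test_that("pseudobulk eQTL recovers a planted dosage effect on expression", {
  set.seed(12)
  hits <- 0
  reps <- 10
  for (r in seq_len(reps)) {
    nDonor <- 390
    dos <- rbinom(nDonor, 2, 0.3)
    dm <- makeDosage(matrix(as.numeric(dos), ncol = 1))
    ph <- makePhenos(nDonor, seed = 300 + r)
    # 3 cells per donor; gene counts scale with dosage
    nCells <- nDonor * 3
    donor <- rep(seq_len(nDonor), each = 3)
    counts <- matrix(rpois(2 * nCells, 5) + 1, 2, nCells,
                     dimnames = list(c("NPY", "other"), NULL))
    counts["NPY", ] <- rpois(nCells, 2 + 2 * dos[donor])
    cells <- makeCells(nCells, cellType = "GAB")
    cells$cell_id <- sprintf("cell%05d", seq_len(nCells))
    cells$donor_id <- sprintf("s%03d", donor)
    feats <- makeFeatures(2); feats$feature_id <- c("NPY", "other")
    ref <- ScReference(Matrix::Matrix(counts, sparse = TRUE,
                                      dimnames = list(rownames(counts),
                                                      cells$cell_id)),
                       cells, feats, "RNA")
    rec <- singleCellEqtl("v001", "NPY", "GAB", ref, dm, ph)
    trueBeta <- stats::coef(lm(tapply(
      as.numeric(normalizeRna(assay(ref, "counts"))["NPY", ]),
      cells$donor_id, mean)[sprintf("s%03d", seq_len(nDonor))] ~ dos))[2]
    if (abs(rec$beta - trueBeta) <= 2 * rec$se) hits <- hits + 1
  }
  expect_gte(hits, reps - 1)
})

test_that("eQTL degenerate inputs are refused or flagged", {
  nDonor <- 30
  dm <- makeDosage(matrix(1, nDonor, 1))
  ph <- makePhenos(nDonor)
  cells <- makeCells(nDonor, cellType = "GAB")
  cells$donor_id <- sprintf("s%03d", seq_len(nDonor))
  counts <- matrix(c(rpois(nDonor, 3) + 1, rep(0, nDonor)), 2, nDonor,
                   byrow = TRUE, dimnames = list(c("g1", "gz"), cells$cell_id))
  feats <- makeFeatures(2); feats$feature_id <- c("g1", "gz")
  ref <- ScReference(Matrix::Matrix(counts, sparse = TRUE), cells, feats,
                     "RNA")
  expect_error(singleCellEqtl("v001", "g1", "GAB", ref, dm, ph),
               "constant")
  dm2 <- makeDosage(matrix(rbinom(nDonor, 2, 0.4), nDonor, 1))
  expect_error(singleCellEqtl("v001", "zz", "GAB", ref, dm2, ph), "absent")
  recz <- singleCellEqtl("v001", "gz", "GAB", ref, dm2, ph, minDonors = 20)
  expect_equal(recz$beta, 0)
  expect_true(isTRUE(attr(recz, "degenerate")))
})
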