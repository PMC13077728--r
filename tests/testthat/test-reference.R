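test_that("control-cell selection applies the conjunction of criteria", {
  cells <- rbind(
    makeCells(1, braak = 2, plaque = "possible", status = "NCI", mmse = 28),
    makeCells(1, braak = 3, plaque = "none", status = "NCI", mmse = 28),
    makeCells(1, braak = 1, plaque = "moderate", status = "NCI", mmse = 28),
    makeCells(1, braak = 1, plaque = "none", status = "MCI", mmse = 28),
    makeCells(1, braak = 1, plaque = "none", status = "NCI", mmse = 23))
  cells$cell_id <- sprintf("c%03d", 1:5)
  got <- selectControlCells(cells, rnaControlCriteria())
  expect_identical(got, "c001")
})

test_that("ATAC control selection uses a strict TSS threshold", {
  cells <- makeCells(3)
  cells$tss_enrichment <- c(1.0, 1.01, 5)
  got <- selectControlCells(cells, atacControlCriteria())
  expect_identical(got, c("c002", "c003"))
})

test_that("control selection errors on missing fields, empty results and unknown types", {
  cells <- makeCells(3)
  cells$mmse[2] <- NA
  expect_error(selectControlCells(cells, rnaControlCriteria()), "missing")
  cells2 <- makeCells(2, braak = 5)
  expect_error(selectControlCells(cells2, rnaControlCriteria()),
               "no control cells")
  cells3 <- makeCells(2, cellType = "XXX")
  expect_error(
    selectControlCells(cells3, rnaControlCriteria(),
                       knownTypes = c("AST", "MIC")),
    "unknown cell_type")
})

test_that("expression filter keeps features expressed in >= minFrac of one type", {
  counts <- matrix(0, 3, 20,
                   dimnames = list(c("g1", "g2", "g3"), NULL))
  types <- rep(c("AST", "MIC"), each = 10)
  counts["g1", 1:3] <- 1          # 3/10 AST
  counts["g3", 1] <- 2            # exactly 1/10 AST (boundary, inclusive)
  expect_identical(filterExpressedFeatures(counts, types, 0.10),
                   c("g1", "g3"))
  expect_error(filterExpressedFeatures(counts, rep("AST", 20), 0.1),
               NA)
  expect_error(
    filterExpressedFeatures(counts[, 0, drop = FALSE], character(0), 0.1))
})

test_that("RNA normalization is counts-per-scale with zeros preserved", {
  counts <- Matrix::Matrix(matrix(c(1, 1, 2,  0, 0, 5), ncol = 2,
                                  dimnames = list(paste0("g", 1:3),
                                                  c("c1", "c2"))),
                           sparse = TRUE)
  norm <- normalizeRna(counts)
  expect_equal(as.numeric(norm[, "c1"]), c(2500, 2500, 5000))
  expect_equal(as.numeric(norm[, "c2"]), c(0, 0, 1e4))
  # proportional cells give identical normalized columns
  counts2 <- cbind(counts[, 1, drop = FALSE], counts[, 1, drop = FALSE] * 7)
  norm2 <- normalizeRna(counts2)
  expect_equal(as.numeric(norm2[, 1]), as.numeric(norm2[, 2]))
  bad <- counts; bad[, 2] <- 0
  expect_error(normalizeRna(bad), "c2")
})

test_that("TF-IDF transform matches the stated formula", {
  counts <- Matrix::Matrix(matrix(1, 2, 2,
                                  dimnames = list(c("p1", "p2"),
                                                  c("c1", "c2"))),
                           sparse = TRUE)
  out <- tfidfTransform(counts)
  expect_equal(as.numeric(out), rep(log(1 + 1e4 * 0.5 * 1), 4),
               tolerance = 1e-12)
  # peak absent everywhere -> zero column by the IDF = 0 convention
  counts2 <- rbind(counts, p3 = c(0, 0))
  counts2["p1", ] <- c(3, 1)
  out2 <- tfidfTransform(counts2)
  expect_equal(as.numeric(out2["p3", ]), c(0, 0))
  # doubling a cell's counts leaves its transformed column unchanged
  counts3 <- counts2
  counts3[, "c1"] <- counts2[, "c1"] * 2
  expect_equal(as.numeric(tfidfTransform(counts3)[, "c1"]),
               as.numeric(out2[, "c1"]), tolerance = 1e-12)
  expect_error(tfidfTransform(cbind(counts, c3 = c(0, 0))), "all-zero")
})

test_that("mean activity averages per group with optional clipping", {
  mat <- matrix(c(2, 4, -1, 3), 1, 4,
                dimnames = list("f1", paste0("c", 1:4)))
  groups <- c("A", "A", "B", "B")
  m <- meanActivityByType(mat, groups)
  expect_equal(m["f1", "A"], 3)
  expect_equal(m["f1", "B"], 1)        # unclipped: (-1 + 3)/2
  mc <- meanActivityByType(mat, groups, clipNegative = TRUE)
  expect_equal(mc["f1", "B"], 1.5)     # clipped: (0 + 3)/2
  single <- meanActivityByType(mat[, 1, drop = FALSE], "A")
  expect_equal(single["f1", "A"], 2)
})

test_that("specificity scores normalize per feature and flag silent rows", {
  means <- rbind(u = rep(2, 7), x = c(5, rep(0, 6)), z = rep(0, 7))
  colnames(means) <- paste0("T", 1:7)
  sp <- specificityScores(means)
  expect_equal(unname(specificity(sp)["u", ]), rep(1 / 7, 7))
  expect_equal(unname(specificity(sp)["x", ]), c(1, rep(0, 6)))
  expect_equal(unname(specificity(sp)["z", ]), rep(0, 7))
  expect_true(sp@zeroSum["z"])
  two <- specificityScores(cbind(A = 3, B = 1))
  expect_equal(as.numeric(specificity(two)), c(0.75, 0.25))
})

test_that("specificity is scale-invariant and rows sum to 1 or 0", {
  set.seed(11)
  for (i in 1:20) {
    means <- matrix(rexp(60), 10, 6,
                    dimnames = list(sprintf("g%02d", 1:10), paste0("T", 1:6)))
    means[sample(10, 2), ] <- 0
    sp <- specificityScores(means)
    rs <- rowSums(specificity(sp))
    expect_true(all(abs(rs - 1) <= 1e-9 | rs == 0))
    sp2 <- specificityScores(means * 17.3)
    expect_equal(specificity(sp2), specificity(sp), tolerance = 1e-12)
  }
})

test_that("top-fraction selection has exact size and matches a sort oracle", {
  set.seed(7)
  for (i in 1:100) {
    n <- 200
    means <- matrix(round(rexp(n * 4), 2), n, 4,
                    dimnames = list(sprintf("g%03d", seq_len(n)),
                                    paste0("T", 1:4)))
    sp <- specificityScores(means)
    q <- sample(c(0.05, 0.1, 0.25), 1)
    sel <- selectTopFraction(sp, q, rownames(means))
    expect_true(all(lengths(sel) == floor(q * n)))
    # brute-force oracle: full sort by the documented keys
    s <- specificity(sp)
    for (ty in colnames(s)) {
      ord <- order(-s[, ty], -means[, ty], rownames(means))
      expect_identical(sel[[ty]],
                       rownames(means)[ord][seq_len(floor(q * n))])
    }
  }
})

test_that("top-fraction selection breaks ties deterministically and validates q", {
  means <- cbind(A = c(9, 5, 5, 2, 1), B = c(1, 5, 5, 8, 9))
  rownames(means) <- c("f1", "f2", "f3", "f4", "f5")
  sp <- specificityScores(means)
  sel <- selectTopFraction(sp, 0.4, rownames(means))
  expect_identical(sel$A, c("f1", "f2"))  # f2 beats tied f3 by id order
  expect_error(selectTopFraction(sp, 0.1, rownames(means)), "< 1")
  # determinism across repeated runs
  expect_identical(sel, selectTopFraction(sp, 0.4, rownames(means)))
})

test_that("hierarchical subtype selection follows the two-stage rule", {
  set.seed(3)
  n <- 50
  primMeans <- matrix(rexp(n * 3), n, 3,
                      dimnames = list(sprintf("p%02d", 1:n),
                                      c("GAB", "GLU", "AST")))
  subMeans <- matrix(rexp(n * 4), n, 4,
                     dimnames = list(rownames(primMeans),
                                     paste0("GAB_", c("SST", "PV", "VIP",
                                                      "LAMP5"))))
  res <- hierarchicalSubtypeSelection(specificityScores(primMeans), "GAB",
                                      subMeans, 0.2, 0.2)
  expect_length(res$parent, 10)           # floor(0.2 * 50)
  expect_true(all(lengths(res$subtype) == 2))  # floor(0.2 * 10)
  expect_true(all(unlist(res$subtype) %in% res$parent))
  # step 2 recomputes specificity among subtypes on the step-1 set only
  subSpec <- specificityScores(subMeans[res$parent, ])
  manual <- selectTopFraction(subSpec, 0.2, res$parent)
  expect_identical(res$subtype, manual)
  expect_error(
    hierarchicalSubtypeSelection(specificityScores(primMeans), "XXX",
                                 subMeans), "not in")
})

test_that("hierarchical selection recovers a planted subtype signal", {
  # subtype markers planted as effectively exclusive to their subtype
  sim <- simulateReference(nTypes = 3, nCellsPerType = 40, nFeatures = 200,
                           nMarkersPerType = 15, fold = 16,
                           modality = "ATAC", seed = 5,
                           typeNames = c("GAB", "GLU", "AST"),
                           subtypesPerType = list(
                             GAB = c("GAB_SST", "GAB_PV")),
                           nMarkersPerSubtype = 8)
  ref <- sim$ref
  tf <- tfidfTransform(assay(ref, "counts"))
  cd <- as.data.frame(colData(ref))
  primMeans <- meanActivityByType(tf, cd$cell_type, clipNegative = TRUE)
  gab <- !is.na(cd$subtype)
  subMeans <- meanActivityByType(tf[, gab, drop = FALSE], cd$subtype[gab],
                                 clipNegative = TRUE)
  full <- matrix(0, nrow(primMeans), ncol(subMeans),
                 dimnames = list(rownames(primMeans), colnames(subMeans)))
  full[rownames(subMeans), ] <- subMeans
  res <- hierarchicalSubtypeSelection(specificityScores(primMeans), "GAB",
                                      full, 0.2, 0.35)
  # planted SST markers are parent-specific and subtype-specific
  recov <- mean(sim$truth$marker_map$GAB_SST %in% res$subtype$GAB_SST)
  expect_gte(recov, 0.75)
})
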