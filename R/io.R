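#' Read a single-cell reference from MTX + TSV files
#'
#' The counts MTX stores cells x features (the common exchange layout);
#' it is transposed to the features-in-rows orientation used internally.
#' The features TSV carries feature_id, chrom, start (0-based), end and
#' optional strand; the cells TSV carries the per-cell metadata columns.
#'
#' @param countsPath MatrixMarket file, cells x features.
#' @param cellsPath cell metadata TSV (must include cell_id, donor_id,
#'   cell_type).
#' @param featuresPath feature annotation TSV.
#' @param modality \code{"RNA"} or \code{"ATAC"}.
#' @return An \code{\linkS4class{ScReference}}.
#' @export
readScReference <- function(countsPath, cellsPath, featuresPath,
                            modality = c("RNA", "ATAC")) {
  modality <- match.arg(modality)
  counts <- Matrix::t(Matrix::readMM(countsPath))
  cells <- utils::read.delim(cellsPath, stringsAsFactors = FALSE)
  feats <- utils::read.delim(featuresPath, stringsAsFactors = FALSE)
  rownames(counts) <- feats$feature_id
  colnames(counts) <- cells$cell_id
  ScReference(counts, cells, feats, modality = modality)
}

#' Write a single-cell reference to MTX + TSV files
#'
#' @param ref An \code{\linkS4class{ScReference}}.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the three file paths.
#' @export
writeScReference <- function(ref, dir, prefix = "reference") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  countsPath <- file.path(dir, paste0(prefix, "_counts.mtx"))
  cellsPath <- file.path(dir, paste0(prefix, "_cells.tsv"))
  featsPath <- file.path(dir, paste0(prefix, "_features.tsv"))
  Matrix::writeMM(Matrix::t(assay(ref, "counts")), countsPath)
  utils::write.table(as.data.frame(colData(ref)), cellsPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gr <- rowRanges(ref)
  feats <- data.frame(feature_id = names(gr),
                      chrom = as.character(seqnames(gr)),
                      start = start(gr) - 1L, end = end(gr),
                      strand = as.character(strand(gr)))
  utils::write.table(feats, featsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(countsPath, cellsPath, featsPath))
}

#' Write a range set as BED
#'
#' Three columns (chrom, 0-based start, exclusive end) plus an optional
#' name column; internal 1-based closed coordinates convert back to BED
#' here.
#'
#' @param gr \code{GRanges}.
#' @param path output file.
#' @param label optional 4th-column label.
#' @export
writeBed <- function(gr, path, label = NULL) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  if (!is.null(label)) df$name <- label
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file as GRanges
#'
#' @param path BED file (3+ columns, no header).
#' @return \code{GRanges}; a 4th column becomes names.
#' @export
readBed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  gr <- GRanges(df[[1]], IRanges(start = df[[2]] + 1L, end = df[[3]]))
  if (ncol(df) >= 4) names(gr) <- df[[4]]
  gr
}

#' Read GWAS summary statistics
#'
#' Whitespace-delimited with a header; required columns CHR, POS, ID, A1
#' (effect allele), A2, BETA, SE, P, EAF in any order; optional R2,
#' N_CASES, N_CONTROLS. Strict on names, tolerant of order.
#'
#' @param path file path.
#' @return data.frame in the package's record layout (variant_id, chrom,
#'   pos, a1, a2, beta, se, p, eaf, info_r2, n_cases, n_controls).
#' @export
readSumstats <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("CHR", "POS", "ID", "A1", "A2", "BETA", "SE", "P", "EAF")
  missing <- setdiff(need, colnames(tab))
  if (length(missing))
    stop("summary statistics missing column(s): ",
         paste(missing, collapse = ", "))
  data.frame(
    variant_id = tab$ID, chrom = tab$CHR, pos = tab$POS,
    a1 = tab$A1, a2 = tab$A2, beta = tab$BETA, se = tab$SE, p = tab$P,
    eaf = tab$EAF,
    info_r2 = if ("R2" %in% colnames(tab)) tab$R2 else NA_real_,
    n_cases = if ("N_CASES" %in% colnames(tab)) tab$N_CASES else NA_integer_,
    n_controls = if ("N_CONTROLS" %in% colnames(tab)) tab$N_CONTROLS
    else NA_integer_
  )
}

#' Write GWAS summary statistics
#'
#' @param records data.frame in the package layout (see
#'   \code{\link{readSumstats}}).
#' @param path output file.
#' @export
writeSumstats <- function(records, path) {
  out <- data.frame(CHR = records$chrom, POS = records$pos,
                    ID = records$variant_id, A1 = records$a1,
                    A2 = records$a2, BETA = records$beta, SE = records$se,
                    P = records$p, EAF = records$eaf)
  if ("info_r2" %in% colnames(records)) out$R2 <- records$info_r2
  if ("n_cases" %in% colnames(records)) {
    out$N_CASES <- records$n_cases
    out$N_CONTROLS <- records$n_controls
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-SNP weight table
#'
#' Six whitespace-delimited columns, the de-facto output layout of
#' effect-size shrinkage tools: CHR, ID, POS, A1 (effect allele), A2,
#' WEIGHT. Raw GWAS betas in the same layout are accepted unchanged (the
#' pass-through raw-beta mode); the shrinkage estimation itself is an
#' upstream tool, not part of this package.
#'
#' @param path file path (no header expected; a header line naming the
#'   columns is tolerated).
#' @return data.frame with chrom, variant_id, pos, a1, a2, weight.
#' @export
readWeights <- function(path) {
  first <- strsplit(trimws(readLines(path, n = 1)), "\\s+")[[1]]
  # a header line has a non-numeric POS field
  hasHeader <- length(first) >= 3 &&
    is.na(suppressWarnings(as.numeric(first[3])))
  tab <- utils::read.table(path, header = hasHeader,
                           stringsAsFactors = FALSE)
  if (ncol(tab) != 6)
    stop("weight table must have 6 columns (CHR ID POS A1 A2 WEIGHT); got ",
         ncol(tab))
  colnames(tab) <- c("chrom", "variant_id", "pos", "a1", "a2", "weight")
  tab
}

#' Write a per-SNP weight table
#'
#' @param weights data.frame with chrom, variant_id, pos, a1, a2, weight.
#' @param path output file.
#' @export
writeWeights <- function(weights, path) {
  utils::write.table(
    weights[, c("chrom", "variant_id", "pos", "a1", "a2", "weight")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read dosages from a samples x variants TSV pair
#'
#' The dosage TSV has a sample_id column followed by one column per
#' variant (NA for missing calls); the variants TSV carries variant_id,
#' chrom, pos, a1 (counted allele), a2.
#'
#' @param dosagePath dosage TSV.
#' @param variantsPath variant annotation TSV.
#' @return A \code{\linkS4class{DosageMatrix}}.
#' @export
readDosageTsv <- function(dosagePath, variantsPath) {
  d <- utils::read.delim(dosagePath, stringsAsFactors = FALSE,
                         check.names = FALSE)
  v <- utils::read.delim(variantsPath, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m <- m[, v$variant_id, drop = FALSE]
  DosageMatrix(m, v)
}

#' Write dosages as a samples x variants TSV pair
#'
#' @param dosageMatrix A \code{\linkS4class{DosageMatrix}}.
#' @param dosagePath,variantsPath output files.
#' @export
writeDosageTsv <- function(dosageMatrix, dosagePath, variantsPath) {
  D <- dosageMatrix@dosage
  out <- data.frame(sample_id = rownames(D), D, check.names = FALSE)
  utils::write.table(out, dosagePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(variantLoci(dosageMatrix), variantsPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(dosagePath, variantsPath))
}

#' Write a long-format specificity table
#'
#' @param spec A \code{\linkS4class{SpecificityResult}}.
#' @param path output TSV.
#' @param selected optional selection (see \code{\link{specificityTable}}).
#' @export
writeSpecificityTable <- function(spec, path, selected = NULL) {
  utils::write.table(specificityTable(spec, selected), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write or read a truth manifest as JSON
#'
#' The manifest echoes the generation parameters, planted marker map and
#' causal map of a synthetic study so downstream checks can recover the
#' ground truth; it round-trips through serialization unchanged.
#'
#' @param manifest list (e.g. the \code{truth} element of
#'   \code{\link{simulateReference}}).
#' @param path JSON file.
#' @export
writeManifest <- function(manifest, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for manifest I/O")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for manifest I/O")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read a phenotype table
#'
#' TSV with the phenotype record columns (sample_id, outcomes,
#' covariates); empty fields and "NA" are read as missing.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readPhenotypes <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    na.strings = c("", "NA"))
}

#' @rdname readPhenotypes
#' @param phenos phenotype data.frame.
#' @export
writePhenotypes <- function(phenos, path) {
  utils::write.table(phenos, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
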