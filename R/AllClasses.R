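#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment assay assayNames colData rowData rowRanges
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

#' Single-cell reference container
#'
#' An \code{ScReference} holds a sparse feature-by-cell raw count matrix
#' together with per-cell metadata (donor, cell type and optional subtype
#' labels, pathology and QC fields) and per-feature genomic annotation.
#' It extends \linkS4class{SingleCellExperiment}; the modality tag
#' distinguishes snRNA gene-count references from snATAC peak-count
#' references, which take different normalizations downstream.
#'
#' @slot modality Either \code{"RNA"} or \code{"ATAC"}.
#' @export
setClass("ScReference",
  contains = "SingleCellExperiment",
  slots = c(modality = "character")
)

setValidity("ScReference", function(object) {
  msg <- NULL
  if (length(object@modality) != 1L || !object@modality %in% c("RNA", "ATAC"))
    msg <- c(msg, "modality must be one of 'RNA', 'ATAC'")
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- assay(object, "counts")
    mn <- if (methods::is(cts, "sparseMatrix")) min(0, cts@x) else min(cts)
    if (length(cts) && mn < 0)
      msg <- c(msg, "counts must be nonnegative")
  }
  cd <- colData(object)
  if (!all(c("cell_id", "donor_id", "cell_type") %in% colnames(cd)))
    msg <- c(msg, "colData needs cell_id, donor_id, cell_type")
  else if (anyDuplicated(cd$cell_id))
    msg <- c(msg, "cell_id must be unique")
  if ("subtype" %in% colnames(cd)) {
    st <- !is.na(cd$subtype)
    if (any(st)) {
      tab <- unique(data.frame(subtype = cd$subtype[st],
                               parent = cd$cell_type[st]))
      if (anyDuplicated(tab$subtype))
        msg <- c(msg, "each subtype must map to exactly one parent cell_type")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct an ScReference
#'
#' @param counts Sparse or dense nonnegative matrix, features in rows and
#'   cells in columns. Row names are feature ids, column names cell ids.
#' @param cells data.frame of per-cell metadata. Must contain
#'   \code{cell_id}, \code{donor_id} and \code{cell_type}; may carry
#'   \code{subtype}, \code{tss_enrichment}, \code{braak},
#'   \code{neuritic_plaque_status}, \code{mmse}, \code{cognitive_status}
#'   and \code{control_flag}.
#' @param features \link[GenomicRanges]{GRanges} of feature spans, named by
#'   feature id (genes or fixed-width accessible-chromatin peaks), or a
#'   data.frame with columns \code{feature_id}, \code{chrom}, \code{start}
#'   (0-based), \code{end} (exclusive) and optional \code{strand}.
#' @param modality \code{"RNA"} or \code{"ATAC"}.
#' @return An \code{ScReference}.
#' @export
ScReference <- function(counts, cells, features, modality = c("RNA", "ATAC")) {
  modality <- match.arg(modality)
  if (is.data.frame(features))
    features <- featureGRanges(features)
  if (is.null(rownames(counts)))
    rownames(counts) <- names(features)
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (nrow(counts) != length(features))
    stop("feature annotation length (", length(features),
         ") does not match feature count (", nrow(counts), ")")
  if (!identical(rownames(counts), names(features)))
    features <- features[rownames(counts)]
  if (is.null(colnames(counts)))
    colnames(counts) <- cells$cell_id
  cells <- DataFrame(cells, row.names = cells$cell_id)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    rowRanges = features,
    colData = cells[colnames(counts), , drop = FALSE]
  )
  methods::new("ScReference", sce, modality = modality)
}

#' @describeIn ScReference modality accessor
#' @param x An \code{ScReference}.
#' @export
modality <- function(x) {
  stopifnot(methods::is(x, "ScReference"))
  x@modality
}

#' @describeIn ScReference feature annotation as GRanges
#' @export
featureRanges <- function(x) {
  stopifnot(methods::is(x, "ScReference"))
  rowRanges(x)
}

setMethod("show", "ScReference", function(object) {
  cat("ScReference (", object@modality, "): ",
      nrow(object), " features x ", ncol(object), " cells\n", sep = "")
  ct <- table(colData(object)$cell_type)
  cat("cell types:",
      paste(sprintf("%s=%d", names(ct), as.integer(ct)), collapse = " "), "\n")
})

#' Per-feature, per-group specificity results
#'
#' Holds the group means (average normalized expression per gene and cell
#' type, or average accessibility per peak and cell type), the specificity
#' scores (each feature's mean in one group divided by the sum of its means
#' across all groups), within-group specificity ranks, and a flag for
#' features whose means are zero in every group (these carry no cell-type
#' signal; their specificity is set to 0 rather than NaN and they sort last
#' in every ranking).
#'
#' @slot means numeric matrix, features x groups.
#' @slot specificity numeric matrix in [0, 1], rows summing to 1 or 0.
#' @slot rank integer matrix; 1 = most specific within the group.
#' @slot zeroSum logical; TRUE where a feature's means sum to zero.
#' @export
setClass("SpecificityResult", slots = c(
  means = "matrix",
  specificity = "matrix",
  rank = "matrix",
  zeroSum = "logical"
))

setValidity("SpecificityResult", function(object) {
  msg <- NULL
  if (!identical(dim(object@means), dim(object@specificity)))
    msg <- c(msg, "means and specificity dimensions differ")
  rs <- rowSums(object@specificity)
  ok <- abs(rs - 1) <= 1e-9 | rs == 0
  if (!all(ok))
    msg <- c(msg, "specificity rows must sum to 1 (or 0 for silent features)")
  for (j in seq_len(ncol(object@rank)))
    if (!identical(sort(unname(object@rank[, j])),
                   seq_len(nrow(object@rank))))
      msg <- c(msg, "rank must be a permutation of 1..N within each group")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "SpecificityResult", function(object) {
  cat("SpecificityResult:", nrow(object@means), "features x",
      ncol(object@means), "groups (", sum(object@zeroSum),
      "silent )\n")
  cat("groups:", paste(colnames(object@means), collapse = " "), "\n")
})

#' @describeIn SpecificityResult specificity matrix accessor
#' @param x A \code{SpecificityResult}.
#' @export
specificity <- function(x) {
  stopifnot(methods::is(x, "SpecificityResult"))
  x@specificity
}

#' @describeIn SpecificityResult mean-activity matrix accessor
#' @export
meanActivity <- function(x) {
  stopifnot(methods::is(x, "SpecificityResult"))
  x@means
}

#' @describeIn SpecificityResult within-group rank accessor
#' @export
specificityRank <- function(x) {
  stopifnot(methods::is(x, "SpecificityResult"))
  x@rank
}

#' Long-format specificity table
#'
#' One row per (feature, group) with mean activity, specificity, rank and,
#' when a selection has been attached via \code{\link{selectTopFraction}},
#' selected-set membership.
#'
#' @param x A \code{SpecificityResult}.
#' @param selected optional named list (group -> feature ids) marking the
#'   selected sets.
#' @return data.frame with columns feature_id, cell_type, mean_activity,
#'   specificity, rank, selected.
#' @export
specificityTable <- function(x, selected = NULL) {
  stopifnot(methods::is(x, "SpecificityResult"))
  groups <- colnames(x@means)
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(
      feature_id = rownames(x@means),
      cell_type = g,
      mean_activity = x@means[, g],
      specificity = x@specificity[, g],
      rank = x@rank[, g],
      selected = if (is.null(selected)) NA else
        rownames(x@means) %in% selected[[g]],
      row.names = NULL
    )
  }))
  out
}

#' Sample-by-variant dosage matrix
#'
#' Genotype dosages (expected counts of the counted allele, in [0, 2] and
#' possibly fractional after imputation; NA allowed for missing calls) for a
#' set of samples at a set of variant loci. The counted allele is \code{a1}
#' for every variant.
#'
#' @slot dosage numeric matrix, samples x variants; rownames are sample ids,
#'   colnames variant ids.
#' @slot variants data.frame with columns variant_id, chrom, pos (1-based),
#'   a1 (counted allele), a2.
#' @export
setClass("DosageMatrix", slots = c(
  dosage = "matrix",
  variants = "data.frame"
))

setValidity("DosageMatrix", function(object) {
  msg <- NULL
  v <- object@variants
  need <- c("variant_id", "chrom", "pos", "a1", "a2")
  if (!all(need %in% colnames(v)))
    msg <- c(msg, paste("variants must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (ncol(object@dosage) != nrow(v))
      msg <- c(msg, "dosage columns must match variant table rows")
    if (!identical(colnames(object@dosage), as.character(v$variant_id)))
      msg <- c(msg, "dosage colnames must equal variant_id")
    if (any(v$pos < 1))
      msg <- c(msg, "variant pos must be >= 1 (1-based)")
    if (any(v$a1 == v$a2))
      msg <- c(msg, "a1 and a2 must differ")
  }
  d <- object@dosage
  if (length(d)) {
    rng <- range(d, na.rm = TRUE)
    if (is.finite(rng[1]) && (rng[1] < -1e-6 || rng[2] > 2 + 1e-6))
      msg <- c(msg, "dosages must lie in [0, 2]")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a DosageMatrix
#'
#' @param dosage numeric matrix, samples x variants.
#' @param variants data.frame with variant_id, chrom, pos, a1, a2.
#' @return A \code{DosageMatrix}.
#' @export
DosageMatrix <- function(dosage, variants) {
  variants <- as.data.frame(variants)
  if (is.null(colnames(dosage)))
    colnames(dosage) <- as.character(variants$variant_id)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("sample%04d", seq_len(nrow(dosage)))
  methods::new("DosageMatrix", dosage = dosage, variants = variants)
}

#' @describeIn DosageMatrix sample ids
#' @param x A \code{DosageMatrix}.
#' @export
sampleIds <- function(x) {
  stopifnot(methods::is(x, "DosageMatrix"))
  rownames(x@dosage)
}

#' @describeIn DosageMatrix variant locus table
#' @export
variantLoci <- function(x) {
  stopifnot(methods::is(x, "DosageMatrix"))
  x@variants
}

#' @describeIn DosageMatrix raw dosage matrix (samples x variants)
#' @export
dosages <- function(x) {
  stopifnot(methods::is(x, "DosageMatrix"))
  x@dosage
}

setMethod("show", "DosageMatrix", function(object) {
  cat("DosageMatrix:", nrow(object@dosage), "samples x",
      ncol(object@dosage), "variants\n")
  cat("chromosomes:",
      paste(unique(object@variants$chrom), collapse = " "), "\n")
})
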