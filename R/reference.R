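#' Control-cell selection criteria
#'
#' A small config object describing which cells of a single-cell reference
#' count as pathology-free controls. Each component is individually
#' toggleable (set to NULL to disable); active components are combined by
#' conjunction. Two presets match the usual definitions for the two
#' modalities: for RNA references, controls have possible or no neuritic
#' plaques, Braak stage at most 2, no cognitive impairment, and MMSE above
#' 23; for ATAC references, controls are nuclei from pathologically
#' diagnosed controls with TSS enrichment strictly greater than 1.
#'
#' @param allowedPlaques character vector of acceptable
#'   neuritic_plaque_status levels, or NULL to skip the check.
#' @param maxBraak maximum Braak stage (inclusive), or NULL.
#' @param allowedCognition acceptable cognitive_status levels, or NULL.
#' @param minMmse MMSE must be strictly greater than this, or NULL.
#' @param requireControlFlag if TRUE, control_flag must be TRUE.
#' @param minTss TSS enrichment must be strictly greater than this, or NULL.
#' @return An object of class \code{ControlCriteria}.
#' @export
controlCriteria <- function(allowedPlaques = NULL, maxBraak = NULL,
                            allowedCognition = NULL, minMmse = NULL,
                            requireControlFlag = FALSE, minTss = NULL) {
  structure(list(
    allowedPlaques = allowedPlaques, maxBraak = maxBraak,
    allowedCognition = allowedCognition, minMmse = minMmse,
    requireControlFlag = requireControlFlag, minTss = minTss
  ), class = "ControlCriteria")
}

#' @rdname controlCriteria
#' @export
rnaControlCriteria <- function() {
  controlCriteria(allowedPlaques = c("none", "possible"), maxBraak = 2,
                  allowedCognition = "NCI", minMmse = 23)
}

#' @rdname controlCriteria
#' @export
atacControlCriteria <- function() {
  controlCriteria(requireControlFlag = TRUE, minTss = 1)
}

.requireField <- function(cells, field) {
  if (!field %in% colnames(cells))
    stop("control criteria reference missing cell field '", field, "'")
  v <- cells[[field]]
  if (anyNA(v))
    stop("cell field '", field, "' has missing values; cannot apply criteria")
  v
}

#' Select control cells
#'
#' Applies the active components of a \code{\link{controlCriteria}} object
#' to per-cell metadata and returns the ids of cells passing every active
#' predicate. All thresholds follow the control definitions exactly: Braak
#' is an inclusive upper bound, MMSE and TSS enrichment are strict
#' lower bounds.
#'
#' @param cells data.frame (or \code{colData}) of cell metadata, or an
#'   \code{\linkS4class{ScReference}}.
#' @param criteria A \code{ControlCriteria}.
#' @param knownTypes optional character vector; any cell_type outside it is
#'   an error.
#' @return character vector of cell ids.
#' @export
selectControlCells <- function(cells, criteria, knownTypes = NULL) {
  if (methods::is(cells, "ScReference"))
    cells <- as.data.frame(colData(cells))
  stopifnot(inherits(criteria, "ControlCriteria"))
  ct <- .requireField(cells, "cell_type")
  if (!is.null(knownTypes) && !all(ct %in% knownTypes))
    stop("unknown cell_type label(s): ",
         paste(unique(setdiff(ct, knownTypes)), collapse = ", "))
  keep <- rep(TRUE, nrow(cells))
  if (!is.null(criteria$allowedPlaques))
    keep <- keep &
      .requireField(cells, "neuritic_plaque_status") %in% criteria$allowedPlaques
  if (!is.null(criteria$maxBraak))
    keep <- keep & .requireField(cells, "braak") <= criteria$maxBraak
  if (!is.null(criteria$allowedCognition))
    keep <- keep &
      .requireField(cells, "cognitive_status") %in% criteria$allowedCognition
  if (!is.null(criteria$minMmse))
    keep <- keep & .requireField(cells, "mmse") > criteria$minMmse
  if (isTRUE(criteria$requireControlFlag))
    keep <- keep & .requireField(cells, "control_flag")
  if (!is.null(criteria$minTss))
    keep <- keep & .requireField(cells, "tss_enrichment") > criteria$minTss
  ids <- cells$cell_id[keep]
  if (length(ids) == 0L)
    stop("no control cells satisfy the active criteria")
  ids
}

.asSparseCounts <- function(matrix) {
  if (methods::is(matrix, "ScReference"))
    matrix <- assay(matrix, "counts")
  methods::as(methods::as(matrix, "CsparseMatrix"), "generalMatrix")
}

#' Filter features by expression breadth
#'
#' Keeps a feature when, for at least one cell type, the fraction of that
#' type's cells with a nonzero count reaches \code{minFrac} (inclusive).
#' Input order is preserved.
#'
#' @param counts features x cells count matrix, or an
#'   \code{ScReference} (its control subset should be taken beforehand).
#' @param cellTypes character/factor of cell-type labels, one per column.
#'   Taken from colData when \code{counts} is an \code{ScReference}.
#' @param minFrac minimum expressed fraction, default 0.10.
#' @return character vector of surviving feature ids.
#' @export
filterExpressedFeatures <- function(counts, cellTypes = NULL, minFrac = 0.10) {
  if (methods::is(counts, "ScReference")) {
    if (is.null(cellTypes)) cellTypes <- colData(counts)$cell_type
    counts <- .asSparseCounts(counts)
  }
  stopifnot(minFrac > 0, minFrac <= 1, length(cellTypes) == ncol(counts),
            ncol(counts) > 0)
  types <- if (is.factor(cellTypes)) levels(cellTypes) else
    unique(as.character(cellTypes))
  cellTypes <- as.character(cellTypes)
  nz <- counts != 0
  keep <- rep(FALSE, nrow(counts))
  for (ty in types) {
    idx <- which(cellTypes == ty)
    if (length(idx) == 0L)
      stop("cell type '", ty, "' has zero cells")
    frac <- Matrix::rowSums(nz[, idx, drop = FALSE]) / length(idx)
    keep <- keep | (frac >= minFrac)
  }
  rownames(counts)[keep]
}

#' Depth-normalize RNA counts
#'
#' Counts-per-\code{scale} per cell: each cell's counts are divided by its
#' total and multiplied by \code{scale} (default 10,000), with no log
#' transform. The specificity score downstream is a ratio of means, so the
#' common scale cancels per feature; a log transform would distort that
#' ratio and is deliberately not applied.
#'
#' @param counts features x cells nonnegative matrix or \code{ScReference}.
#' @param scale per-cell target total, default 1e4.
#' @return sparse normalized matrix whose columns each sum to \code{scale}.
#' @export
normalizeRna <- function(counts, scale = 1e4) {
  counts <- .asSparseCounts(counts)
  cs <- Matrix::colSums(counts)
  if (any(cs == 0))
    stop("all-zero cell(s): ",
         paste(colnames(counts)[cs == 0], collapse = ", "))
  out <- counts %*% Matrix::Diagonal(x = scale / cs, names = FALSE)
  dimnames(out) <- dimnames(counts)
  out
}

#' TF-IDF transform for ATAC peak counts
#'
#' The latent-semantic-indexing style normalization used for accessible
#' chromatin: each entry becomes \code{log(1 + scale * TF * IDF)} where TF
#' is the peak's fraction of its cell's total counts and IDF is the number
#' of cells divided by the number of cells in which the peak is detected.
#' Peaks detected in no cell get IDF 0 by convention, hence a zero column.
#'
#' @param counts features x cells nonnegative matrix or \code{ScReference}
#'   with ATAC modality.
#' @param scale TF scaling constant, default 1e4.
#' @return sparse transformed matrix.
#' @export
tfidfTransform <- function(counts, scale = 1e4) {
  if (methods::is(counts, "ScReference") && modality(counts) != "ATAC")
    stop("tfidfTransform expects an ATAC reference")
  counts <- .asSparseCounts(counts)
  cs <- Matrix::colSums(counts)
  if (any(cs == 0))
    stop("all-zero cell(s): ",
         paste(colnames(counts)[cs == 0], collapse = ", "))
  df <- Matrix::rowSums(counts != 0)
  idf <- ifelse(df > 0, ncol(counts) / df, 0)
  out <- Matrix::Diagonal(x = idf, names = FALSE) %*%
    counts %*% Matrix::Diagonal(x = scale / cs, names = FALSE)
  out <- methods::as(methods::as(out, "CsparseMatrix"), "generalMatrix")
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts)
  out
}

#' Mean activity per feature and group
#'
#' Arithmetic mean of the (normalized or TF-IDF-transformed) values over
#' the cells of each group. For ATAC activity any negative input (possible
#' under some upstream transforms) is clipped to 0 before averaging so the
#' group means, and hence the specificity scores, stay in [0, 1].
#'
#' @param mat features x cells numeric matrix (normalized/transformed).
#' @param groups character/factor group label per column (cell type or
#'   subtype).
#' @param clipNegative clip negative values to 0 first (use for ATAC).
#' @return dense matrix features x groups of means.
#' @export
meanActivityByType <- function(mat, groups, clipNegative = FALSE) {
  stopifnot(length(groups) == ncol(mat))
  levs0 <- if (is.factor(groups)) levels(groups) else NULL
  groups <- as.character(groups)
  if (clipNegative) {
    if (methods::is(mat, "sparseMatrix")) {
      mat <- methods::as(methods::as(mat, "CsparseMatrix"), "generalMatrix")
      mat@x <- pmax(mat@x, 0)
    } else mat <- pmax(mat, 0)
  }
  levs <- if (is.null(levs0)) unique(groups) else levs0
  out <- matrix(0, nrow(mat), length(levs),
                dimnames = list(rownames(mat), levs))
  for (g in levs) {
    idx <- which(groups == g)
    if (length(idx) == 0L) stop("empty group: ", g)
    out[, g] <- Matrix::rowSums(mat[, idx, drop = FALSE]) / length(idx)
  }
  out
}

.specOrder <- function(specCol, meanCol, ids) {
  order(-specCol, -meanCol, ids)
}

#' Specificity scores
#'
#' For each feature the specificity to a group is its mean activity in that
#' group divided by the sum of its mean activities across all groups, so
#' each feature's scores sum to 1 (or to 0 for features silent everywhere,
#' which are flagged and carry no signal). Within each group features are
#' ranked by descending specificity with a deterministic tie-break:
#' descending mean activity, then lexicographic feature id.
#'
#' @param means nonnegative matrix features x groups (see
#'   \code{\link{meanActivityByType}}).
#' @return A \code{\linkS4class{SpecificityResult}}.
#' @export
specificityScores <- function(means) {
  means <- as.matrix(means)
  if (any(means < 0)) stop("means must be nonnegative")
  if (is.null(rownames(means)))
    rownames(means) <- sprintf("feat%05d", seq_len(nrow(means)))
  rs <- rowSums(means)
  spec <- means
  nz <- rs > 0
  spec[nz, ] <- means[nz, , drop = FALSE] / rs[nz]
  spec[!nz, ] <- 0
  rk <- matrix(0L, nrow(means), ncol(means), dimnames = dimnames(means))
  ids <- rownames(means)
  for (j in seq_len(ncol(means))) {
    o <- .specOrder(spec[, j], means[, j], ids)
    rk[o, j] <- seq_len(nrow(means))
  }
  methods::new("SpecificityResult", means = means, specificity = spec,
               rank = rk, zeroSum = !nz)
}

#' Select the top fraction of most specific features per group
#'
#' Per group, returns the \code{floor(q * length(universe))} features with
#' the highest specificity for that group, restricted to \code{universe}
#' (e.g. the expression-filtered gene list). Selection is independent per
#' group, so sets for different groups may overlap. Ties are broken by
#' descending mean activity, then feature id, making the sets
#' deterministic. Silent (zero-sum) features sort last and can only enter
#' a set when the requested count exceeds the informative features
#' available, which triggers a warning.
#'
#' @param spec A \code{SpecificityResult}.
#' @param q fraction in (0, 1].
#' @param universe feature ids eligible for selection; defaults to all
#'   features in \code{spec}.
#' @return named list, group -> character vector of selected feature ids.
#' @export
selectTopFraction <- function(spec, q, universe = rownames(meanActivity(spec))) {
  stopifnot(methods::is(spec, "SpecificityResult"), q > 0, q <= 1)
  if (!all(universe %in% rownames(spec@means)))
    stop("universe contains features absent from the specificity table")
  n <- floor(q * length(universe))
  if (n < 1)
    stop("q * |universe| < 1: no features would be selected")
  s <- spec@specificity[universe, , drop = FALSE]
  m <- spec@means[universe, , drop = FALSE]
  z <- spec@zeroSum[universe]
  out <- lapply(colnames(s), function(g) {
    o <- .specOrder(s[, g], m[, g], universe)
    sel <- universe[o[seq_len(n)]]
    if (any(z[sel])) {
      warning("selection for '", g, "' includes ", sum(z[sel]),
              " silent feature(s); the universe has fewer informative ",
              "features than requested")
      sel <- sel[!z[sel]]
    }
    sel
  })
  names(out) <- colnames(s)
  out
}

#' Hierarchical subtype-specific selection
#'
#' Two-stage selection for neuron subtypes: first the top
#' \code{qParent} fraction of the full feature universe by parent-type
#' specificity (e.g. GABAergic-neuron-specific peaks among all peaks);
#' then, restricted to that parent set, specificity is recomputed among
#' the subtypes only (the denominator is the sum over subtypes) and the
#' top \code{qSubtype} fraction of the parent set is selected per subtype.
#'
#' @param primarySpec \code{SpecificityResult} across primary cell types.
#' @param parentType label of the parent type in \code{primarySpec}.
#' @param subtypeMeans matrix features x subtypes of mean activity,
#'   covering at least all features of \code{primarySpec}.
#' @param qParent,qSubtype selection fractions, defaults 0.20 each.
#' @return list with elements \code{parent} (feature ids surviving step 1)
#'   and \code{subtype} (named list, subtype -> selected feature ids).
#' @export
hierarchicalSubtypeSelection <- function(primarySpec, parentType, subtypeMeans,
                                         qParent = 0.20, qSubtype = 0.20) {
  stopifnot(methods::is(primarySpec, "SpecificityResult"))
  if (!parentType %in% colnames(meanActivity(primarySpec)))
    stop("parent type '", parentType, "' not in primary specificity table")
  universe <- rownames(meanActivity(primarySpec))
  parentSel <- selectTopFraction(primarySpec, qParent, universe)[[parentType]]
  if (length(parentSel) < 1)
    stop("no features survive the parent-type selection")
  subtypeMeans <- as.matrix(subtypeMeans)
  if (!all(parentSel %in% rownames(subtypeMeans)))
    stop("subtype means do not cover all parent-selected features")
  subSpec <- specificityScores(subtypeMeans[parentSel, , drop = FALSE])
  subSel <- selectTopFraction(subSpec, qSubtype, parentSel)
  if (any(lengths(subSel) < 1))
    stop("no features survive the subtype selection")
  list(parent = parentSel, subtype = subSel)
}
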