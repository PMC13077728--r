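#' Harmonize per-SNP weights to a dosage panel
#'
#' Matches weight entries to the dosage panel's variants by id (falling
#' back to chrom:pos when the id is absent) and records, per matched
#' variant, whether the weight's effect allele is the panel's counted
#' allele or the other allele. In the latter case the scorer counts
#' \code{2 - dosage}, which is equivalent to flipping the sign of the
#' weight up to a constant shift that standardization removes. Weights
#' whose allele pair matches neither orientation, and weights for
#' variants absent from the panel, are dropped with a message/warning.
#'
#' @param weights data.frame with variant_id, a1 (effect allele), a2,
#'   weight; optionally chrom, pos (see \code{\link{readWeights}}).
#' @param dosages A \code{\linkS4class{DosageMatrix}}.
#' @return data.frame with variant_id, weight, flip (logical; TRUE when
#'   the effect allele is the panel's non-counted allele).
#' @export
harmonizeWeights <- function(weights, dosages) {
  stopifnot(methods::is(dosages, "DosageMatrix"))
  stopifnot(all(c("variant_id", "a1", "a2", "weight") %in% colnames(weights)))
  panel <- variantLoci(dosages)
  idx <- match(weights$variant_id, panel$variant_id)
  if (anyNA(idx) && all(c("chrom", "pos") %in% colnames(weights))) {
    key <- paste(panel$chrom, panel$pos)
    idx2 <- match(paste(weights$chrom, weights$pos)[is.na(idx)], key)
    idx[is.na(idx)] <- idx2
  }
  unmatched <- sum(is.na(idx))
  if (unmatched)
    message(unmatched, " weight(s) not present in the dosage panel; dropped")
  keep <- !is.na(idx)
  w <- weights[keep, , drop = FALSE]
  pv <- panel[idx[keep], , drop = FALSE]
  same <- w$a1 == pv$a1 & w$a2 == pv$a2
  flip <- w$a1 == pv$a2 & w$a2 == pv$a1
  bad <- !(same | flip)
  if (any(bad))
    warning("dropped ", sum(bad), " weight(s) with irreconcilable alleles: ",
            paste(utils::head(w$variant_id[bad], 5), collapse = ", "))
  data.frame(variant_id = pv$variant_id[!bad],
             weight = w$weight[!bad],
             flip = flip[!bad])
}

#' Compute raw polygenic scores
#'
#' The raw score of a sample is the sum over scored variants of the
#' effect-allele dosage times the per-SNP weight, optionally restricted
#' to a genomic range mask (the cell-type strategy masks from the regions
#' functions); with \code{ranges = NULL} every harmonized weight is used,
#' giving the genome-wide score. Missing dosages are mean-imputed as
#' twice the variant's allele frequency within the scored sample set, the
#' usual scorer default.
#'
#' @param dosageMatrix A \code{\linkS4class{DosageMatrix}}.
#' @param aligned harmonized weights from \code{\link{harmonizeWeights}}.
#' @param ranges normalized \code{GRanges} mask, or NULL for genome-wide.
#' @param label label stored on the profile rows (cell type + method).
#' @return data.frame: sample_id, raw_score, z_score (NA until
#'   \code{\link{standardizeScores}}), n_snps_used, label.
#' @export
computePrs <- function(dosageMatrix, aligned, ranges = NULL,
                       label = "genome") {
  stopifnot(methods::is(dosageMatrix, "DosageMatrix"))
  ids <- aligned$variant_id
  if (!is.null(ranges)) {
    inRange <- snpsInRanges(variantLoci(dosageMatrix), ranges)
    ids <- ids[ids %in% inRange]
  }
  if (length(ids) == 0L)
    stop("zero variants in range for label '", label, "'")
  D <- dosageMatrix@dosage[, ids, drop = FALSE]
  if (anyNA(D)) {
    eaf2 <- colMeans(D, na.rm = TRUE)
    for (j in which(colSums(is.na(D)) > 0))
      D[is.na(D[, j]), j] <- eaf2[j]
  }
  al <- aligned[match(ids, aligned$variant_id), , drop = FALSE]
  flip <- which(al$flip)
  if (length(flip)) D[, flip] <- 2 - D[, flip, drop = FALSE]
  raw <- as.numeric(D %*% al$weight)
  data.frame(sample_id = rownames(D), raw_score = raw,
             z_score = NA_real_, n_snps_used = length(ids),
             label = label, row.names = NULL)
}

#' Standardize score profiles
#'
#' Within each label, subtracts the sample mean raw score and divides by
#' the sample standard deviation (n - 1 denominator), filling the
#' \code{z_score} column. Degenerate (constant) score distributions are
#' an error rather than silent NaN.
#'
#' @param profiles data.frame from \code{\link{computePrs}} (one or more
#'   labels stacked).
#' @return the profiles with z_score filled.
#' @export
standardizeScores <- function(profiles) {
  stopifnot(all(c("raw_score", "label") %in% colnames(profiles)))
  for (lab in unique(profiles$label)) {
    i <- profiles$label == lab
    x <- profiles$raw_score[i]
    if (length(x) < 2)
      stop("need at least 2 samples to standardize label '", lab, "'")
    s <- stats::sd(x)
    if (s == 0)
      stop("degenerate score distribution for label '", lab, "'")
    profiles$z_score[i] <- (x - mean(x)) / s
  }
  profiles
}

#' Cross-score correlation matrix
#'
#' Pairwise Pearson correlations between standardized score vectors of
#' different labels over the same samples, with the mean off-diagonal
#' correlation as a one-number summary of how distinct the cell-type
#' scores are. The genome-wide label (if present) is excluded from the
#' cell-type average, and named label pairs (e.g. the two neuronal
#' classes) can be summarized separately.
#'
#' @param zByLabel named list (label -> z vector, identical sample order)
#'   or a samples x labels numeric matrix.
#' @param excludeFromAverage labels excluded from the off-diagonal
#'   average, default \code{"genome"}.
#' @param pairs optional list of length-2 character vectors naming label
#'   pairs to summarize individually.
#' @return list with \code{r} (correlation matrix), \code{averageR}
#'   (mean upper-triangle off-diagonal, exclusions applied), and
#'   \code{pairR} (named numeric, when \code{pairs} given).
#' @export
scoreCorrelationMatrix <- function(zByLabel, excludeFromAverage = "genome",
                                   pairs = NULL) {
  if (is.list(zByLabel)) {
    len <- unique(lengths(zByLabel))
    if (length(len) != 1L)
      stop("score vectors have differing lengths")
    zByLabel <- do.call(cbind, zByLabel)
  }
  if (nrow(zByLabel) < 3) stop("need at least 3 samples")
  r <- stats::cor(zByLabel)
  keep <- setdiff(colnames(r), excludeFromAverage)
  sub <- r[keep, keep, drop = FALSE]
  avg <- mean(sub[upper.tri(sub)])
  pairR <- NULL
  if (!is.null(pairs)) {
    pairR <- vapply(pairs, function(pr) r[pr[1], pr[2]], 0)
    names(pairR) <- vapply(pairs, paste, "", collapse = "-")
  }
  list(r = r, averageR = avg, pairR = pairR)
}
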