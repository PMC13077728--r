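#' @import GenomicRanges
#' @import IRanges
#' @import S4Vectors
NULL

#' Feature annotation to GRanges
#'
#' Converts a BED-convention feature table (0-based inclusive start,
#' exclusive end) into a named \code{GRanges} (1-based closed, the
#' Bioconductor convention). The conversion between the two coordinate
#' systems happens here and at the BED I/O boundary only; all interval
#' algebra in the package runs on \code{GRanges}.
#'
#' @param features data.frame with feature_id, chrom, start (0-based),
#'   end (exclusive) and optional strand.
#' @return \code{GRanges} named by feature_id.
#' @export
featureGRanges <- function(features) {
  stopifnot(all(c("feature_id", "chrom", "start", "end") %in%
                  colnames(features)))
  if (any(features$start < 0) || any(features$end <= features$start))
    stop("feature spans must satisfy 0 <= start < end")
  gr <- GRanges(
    seqnames = features$chrom,
    ranges = IRanges(start = features$start + 1L, end = features$end),
    strand = if ("strand" %in% colnames(features))
      ifelse(features$strand %in% c("+", "-"), features$strand, "*")
    else "*"
  )
  names(gr) <- features$feature_id
  gr
}

#' Normalize a range set
#'
#' Sorts and merges overlapping or abutting intervals, ignoring strand.
#' A SNP mask is a set of positions, so abutment is irrelevant to
#' membership and merging makes range sets canonical. Idempotent.
#'
#' @param gr A \code{GRanges}.
#' @return reduced, sorted \code{GRanges}.
#' @export
normalizeRanges <- function(gr) {
  GenomicRanges::sort(reduce(gr, ignore.strand = TRUE))
}

#' Gene-window ranges (snRNA strategy)
#'
#' Builds the SNP selection mask of the gene-based cell-type score: each
#' gene body extended by \code{flankBp} on both sides (strand-ignored,
#' so "within 30 kb upstream or downstream" of the gene), clamped at the
#' chromosome start, then merged.
#'
#' @param genes \code{GRanges} of gene spans (e.g. the cell-type-specific
#'   gene set), or a feature data.frame accepted by
#'   \code{\link{featureGRanges}}.
#' @param flankBp symmetric flank in bp, default 30000.
#' @return normalized \code{GRanges}.
#' @export
geneWindows <- function(genes, flankBp = 30000) {
  if (is.data.frame(genes)) genes <- featureGRanges(genes)
  stopifnot(flankBp >= 0)
  if (length(genes) == 0L) stop("empty gene list")
  win <- GRanges(seqnames(genes),
                 IRanges(start = pmax(1L, start(genes) - flankBp),
                         end = end(genes) + flankBp))
  normalizeRanges(win)
}

#' Peak ranges (snATAC strategy)
#'
#' The SNP selection mask of the peak-based cell-type score: the spans of
#' the selected accessible-chromatin peaks verbatim, merged.
#'
#' @param peakIds character vector of selected peak ids.
#' @param annotations named \code{GRanges} covering every peak id.
#' @return normalized \code{GRanges}.
#' @export
peakRanges <- function(peakIds, annotations) {
  if (length(peakIds) == 0L) stop("empty peak set")
  missing <- setdiff(peakIds, names(annotations))
  if (length(missing))
    stop("peaks without annotation: ", paste(missing, collapse = ", "))
  normalizeRanges(annotations[peakIds])
}

#' Multi-omic subtype ranges
#'
#' Retains the subtype-specific peak intervals lying within \code{flankBp}
#' of the nearest neuron-specific gene span (overlap counts as distance 0),
#' then merges. This couples open chromatin evidence (the subtype peaks)
#' with expression evidence (the leniently defined neuron gene set).
#'
#' @param subtypePeaks \code{GRanges} of subtype-specific peak intervals.
#' @param neuronGenes \code{GRanges} of neuron-specific gene spans.
#' @param flankBp maximum gap in bp, default 300000.
#' @return normalized \code{GRanges} of the retained peaks.
#' @export
multiomicRanges <- function(subtypePeaks, neuronGenes, flankBp = 300000) {
  if (length(neuronGenes) == 0L) stop("empty neuron gene list")
  if (length(subtypePeaks) == 0L)
    return(GRanges())
  hits <- distanceToNearest(subtypePeaks, neuronGenes, ignore.strand = TRUE)
  keep <- queryHits(hits)[mcols(hits)$distance <= flankBp]
  normalizeRanges(subtypePeaks[keep])
}

#' Subtract an exclusion window from a range set
#'
#' Removes \code{[center.start - flankBp, center.end + flankBp]} from every
#' interval on the excluded chromosome, leaving other chromosomes
#' untouched; the result is normalized. Used to strip the region around
#' the APOE coding span (default 1 Mb each side) from every cell-type
#' score mask, so that no score is dominated by the APOE locus.
#'
#' @param ranges normalized \code{GRanges}.
#' @param exclusionCenter \code{GRanges} of length 1 (e.g. the APOE gene
#'   span looked up from the gene annotation).
#' @param flankBp flank around the exclusion center, default 1e6.
#' @return normalized \code{GRanges}; empty result triggers a warning.
#' @export
subtractRegion <- function(ranges, exclusionCenter, flankBp = 1e6) {
  stopifnot(length(exclusionCenter) == 1L)
  excl <- GRanges(seqnames(exclusionCenter),
                  IRanges(start = pmax(1L, start(exclusionCenter) - flankBp),
                          end = end(exclusionCenter) + flankBp))
  out <- suppressWarnings(
    GenomicRanges::setdiff(ranges, excl, ignore.strand = TRUE))
  if (length(ranges) && length(out) == 0L)
    warning("range set is empty after exclusion")
  normalizeRanges(out)
}

#' Map variants into a range set
#'
#' A variant is included when its 1-based position falls inside an
#' interval of the mask. This is the single place where the VCF 1-based
#' point convention meets the interval masks.
#'
#' @param variants data.frame with variant_id, chrom, pos (1-based), or a
#'   \code{\linkS4class{DosageMatrix}}.
#' @param ranges normalized \code{GRanges}.
#' @return character vector of variant ids (input order).
#' @export
snpsInRanges <- function(variants, ranges) {
  if (methods::is(variants, "DosageMatrix")) variants <- variantLoci(variants)
  if (length(ranges) == 0L) return(character(0))
  gp <- GRanges(variants$chrom, IRanges(variants$pos, width = 1L))
  hits <- suppressWarnings(findOverlaps(gp, ranges, ignore.strand = TRUE))
  variants$variant_id[sort(unique(queryHits(hits)))]
}

#' Exact intersection counts of variant sets
#'
#' For every nonempty combination of labels, the number of variants
#' belonging to exactly that combination of sets (the counts an UpSet
#' plot displays). Counts over all combinations sum to the union size.
#'
#' @param sets named list, label -> character vector of variant ids.
#' @return data.frame with columns combination (labels joined by
#'   \code{"&"}), degree, count, sorted by degree then count.
#' @export
overlapCounts <- function(sets) {
  stopifnot(length(sets) >= 2L, !is.null(names(sets)))
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1)
  sig <- apply(member, 1L, function(row)
    paste(names(sets)[row], collapse = "&"))
  tab <- table(sig)
  out <- data.frame(combination = names(tab),
                    degree = lengths(strsplit(names(tab), "&", fixed = TRUE)),
                    count = as.integer(tab), row.names = NULL)
  out[order(out$degree, -out$count, out$combination), , drop = FALSE]
}

#' Total covered length of a range set
#'
#' @param gr \code{GRanges}.
#' @return total bp covered after normalization.
#' @export
coveredLength <- function(gr) {
  sum(width(normalizeRanges(gr)))
}
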