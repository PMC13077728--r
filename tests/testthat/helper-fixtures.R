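# Small in-code fixtures shared across test files.

suppressPackageStartupMessages(library(SummarizedExperiment))

# A tiny cell metadata table with controllable fields.
makeCells <- function(n, cellType = "AST", braak = 1, plaque = "none",
                      status = "NCI", mmse = 28, tss = 5,
                      controlFlag = TRUE, donor = NULL) {
  data.frame(
    cell_id = sprintf("c%03d", seq_len(n)),
    donor_id = if (is.null(donor)) sprintf("d%02d", rep_len(1:4, n))
    else rep_len(donor, n),
    cell_type = rep_len(cellType, n),
    subtype = NA_character_,
    tss_enrichment = rep_len(tss, n),
    braak = rep_len(braak, n),
    neuritic_plaque_status = rep_len(plaque, n),
    mmse = rep_len(mmse, n),
    cognitive_status = rep_len(status, n),
    control_flag = rep_len(controlFlag, n)
  )
}

# Feature table on the toy genome, BED-convention coordinates.
makeFeatures <- function(n, width = 1000, spacing = 5000, chrom = "chr1") {
  start0 <- (seq_len(n) - 1L) * spacing
  data.frame(feature_id = sprintf("f%03d", seq_len(n)), chrom = chrom,
             start = start0, end = start0 + width, strand = ".")
}

# Dosage panel with explicit loci.
makeDosage <- function(dosage, chrom = "chr1", pos = NULL,
                       a1 = "A", a2 = "G") {
  nv <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(nv) * 100L
  variants <- data.frame(
    variant_id = sprintf("v%03d", seq_len(nv)),
    chrom = rep_len(chrom, nv), pos = pos,
    a1 = rep_len(a1, nv), a2 = rep_len(a2, nv))
  colnames(dosage) <- variants$variant_id
  rownames(dosage) <- sprintf("s%03d", seq_len(nrow(dosage)))
  DosageMatrix(dosage, variants)
}

# Phenotype table with orthogonal covariates and a pluggable outcome.
makePhenos <- function(n, seed = 42) {
  set.seed(seed)
  e4 <- rbinom(n, 2, 0.15)
  data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    ad_pathdx = rbinom(n, 1, 0.4),
    mmse = runif(n, 10, 30),
    tangle_density = rexp(n), nft_burden = rexp(n),
    abeta_burden = rexp(n), diffuse_plaque = rexp(n),
    neuritic_plaque = rexp(n),
    age_at_death = rnorm(n, 85, 5), sex = rbinom(n, 1, 0.5),
    education_years = rnorm(n, 16, 3),
    pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n),
    apoe_e2_dosage = pmin(rbinom(n, 2, 0.07), 2 - e4),
    apoe_e4_dosage = e4
  )
}

# BED-convention GRanges builder for interval tests.
bedRanges <- function(chrom, start0, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end))
}

# Brute-force membership oracle: per-(variant, interval) scan in BED
# coordinates, independent of the GRanges machinery.
bruteForceSnpsInRanges <- function(variants, bedDf) {
  hits <- vapply(seq_len(nrow(variants)), function(i) {
    p0 <- variants$pos[i] - 1L
    any(bedDf$chrom == variants$chrom[i] &
          bedDf$start <= p0 & p0 < bedDf$end)
  }, logical(1))
  variants$variant_id[hits]
}
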