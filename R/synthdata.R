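#' Toy genome layout
#'
#' Two chromosomes of 10 Mb each: small enough that every interval
#' operation can be checked against a brute-force oracle, large enough to
#' lay out hundreds of gene or peak spans with controllable window
#' overlaps.
#'
#' @return data.frame with chrom and length.
#' @export
toyGenome <- function() {
  data.frame(chrom = c("chr1", "chr2"), length = c(1e7, 1e7))
}

.defaultTypeNames <- function(nTypes) {
  base <- c("AST", "MIC", "ODC", "OPC", "END", "GLU", "GAB")
  if (nTypes <= length(base)) base[seq_len(nTypes)]
  else c(base, sprintf("CT%d", seq(length(base) + 1, nTypes)))
}

.layoutFeatures <- function(nFeatures, width, spacing, genome = toyGenome()) {
  perChrom <- floor(genome$length / spacing)
  if (nFeatures > sum(perChrom))
    stop("cannot place ", nFeatures, " features of spacing ", spacing,
         " on the toy genome (capacity ", sum(perChrom), ")")
  chrom <- character(nFeatures)
  start0 <- integer(nFeatures)
  k <- 0L
  for (i in seq_len(nrow(genome))) {
    nHere <- min(nFeatures - k, perChrom[i])
    if (nHere <= 0) break
    idx <- k + seq_len(nHere)
    chrom[idx] <- genome$chrom[i]
    start0[idx] <- (seq_len(nHere) - 1L) * spacing + 1000L
    k <- k + nHere
  }
  data.frame(feature_id = sprintf("feat%05d", seq_len(nFeatures)),
             chrom = chrom, start = start0, end = start0 + width,
             strand = ".")
}

#' Simulate a single-cell reference with planted markers
#'
#' Background counts are negative-binomial (mean \code{bgMean},
#' dispersion \code{dispersion}, so variance mu + dispersion * mu^2);
#' planted marker features have their mean multiplied by \code{fold} in
#' their own cell type (or subtype) only. Features receive genomic spans
#' on the toy genome (10 kb gene bodies for RNA, 500 bp peaks for ATAC),
#' and every cell carries control-satisfying metadata, so the control
#' filter passes all cells by construction. Optional subtype structure
#' splits a parent type's cells across named subtypes and plants
#' additional markers elevated only within one subtype, which makes them
#' both parent-specific and subtype-specific, the structure the
#' hierarchical selection expects.
#'
#' @param nTypes number of primary cell types (default 7).
#' @param nCellsPerType cells per type.
#' @param nFeatures total features.
#' @param nMarkersPerType planted markers per type.
#' @param fold marker mean multiplier, > 1.
#' @param modality \code{"RNA"} or \code{"ATAC"}.
#' @param seed RNG seed.
#' @param bgMean background NB mean, default 0.2 counts.
#' @param dispersion NB dispersion, default 0.5.
#' @param nDonors donors cells are distributed over, default 12.
#' @param typeNames optional type labels (default AST, MIC, ODC, OPC,
#'   END, GLU, GAB truncated/extended to \code{nTypes}).
#' @param subtypesPerType optional named list, parent type -> subtype
#'   labels.
#' @param nMarkersPerSubtype planted markers per subtype, default 5.
#' @param featureSpacing start-to-start feature spacing in bp; defaults
#'   to 1e5 for RNA (disjoint 30 kb windows) and 2e3 for ATAC.
#' @return list with \code{ref} (an \code{\linkS4class{ScReference}}) and
#'   \code{truth} (the manifest: marker_map, generation parameters,
#'   feature layout).
#' @export
simulateReference <- function(nTypes = 7, nCellsPerType = 50,
                              nFeatures = 200, nMarkersPerType = 10,
                              fold = 4, modality = c("RNA", "ATAC"),
                              seed = 1, bgMean = 0.2, dispersion = 0.5,
                              nDonors = 12, typeNames = NULL,
                              subtypesPerType = NULL,
                              nMarkersPerSubtype = 5,
                              featureSpacing = NULL) {
  modality <- match.arg(modality)
  stopifnot(fold > 1 || fold == 1, nTypes >= 1, nCellsPerType >= 1)
  nSubtypes <- sum(lengths(subtypesPerType))
  if (nMarkersPerType * nTypes + nMarkersPerSubtype * nSubtypes > nFeatures)
    stop("more planted markers than features")
  if (is.null(typeNames)) typeNames <- .defaultTypeNames(nTypes)
  stopifnot(length(typeNames) == nTypes)
  if (is.null(featureSpacing))
    featureSpacing <- if (modality == "RNA") 1e5 else 2e3
  width <- if (modality == "RNA") 10000L else 500L
  set.seed(seed)
  feats <- .layoutFeatures(nFeatures, width, featureSpacing)

  nCells <- nTypes * nCellsPerType
  cellType <- rep(typeNames, each = nCellsPerType)
  subtype <- rep(NA_character_, nCells)
  for (parent in names(subtypesPerType)) {
    idx <- which(cellType == parent)
    subtype[idx] <- rep_len(subtypesPerType[[parent]], length(idx))
  }

  pool <- sample(feats$feature_id)
  markerMap <- list()
  k <- 0L
  for (ty in typeNames) {
    markerMap[[ty]] <- pool[k + seq_len(nMarkersPerType)]
    k <- k + nMarkersPerType
  }
  for (parent in names(subtypesPerType)) {
    for (st in subtypesPerType[[parent]]) {
      markerMap[[st]] <- pool[k + seq_len(nMarkersPerSubtype)]
      k <- k + nMarkersPerSubtype
    }
  }

  mu <- matrix(bgMean, nFeatures, nCells,
               dimnames = list(feats$feature_id, NULL))
  for (ty in typeNames)
    mu[markerMap[[ty]], cellType == ty] <- bgMean * fold
  for (parent in names(subtypesPerType))
    for (st in subtypesPerType[[parent]])
      mu[markerMap[[st]], !is.na(subtype) & subtype == st] <- bgMean * fold
  counts <- matrix(
    stats::rnbinom(length(mu), mu = as.numeric(mu), size = 1 / dispersion),
    nFeatures, nCells, dimnames = list(feats$feature_id, NULL))

  cells <- data.frame(
    cell_id = sprintf("cell%05d", seq_len(nCells)),
    donor_id = sprintf("donor%02d", rep_len(seq_len(nDonors), nCells)),
    cell_type = cellType,
    subtype = subtype,
    tss_enrichment = stats::runif(nCells, 2, 10),
    braak = sample(0:2, nCells, replace = TRUE),
    neuritic_plaque_status = sample(c("none", "possible"), nCells,
                                    replace = TRUE),
    mmse = stats::runif(nCells, 24, 30),
    cognitive_status = "NCI",
    control_flag = TRUE
  )
  colnames(counts) <- cells$cell_id
  ref <- ScReference(Matrix::Matrix(counts, sparse = TRUE), cells, feats,
                     modality = modality)
  truth <- list(
    marker_map = markerMap,
    features = feats,
    params = list(nTypes = nTypes, nCellsPerType = nCellsPerType,
                  nFeatures = nFeatures, nMarkersPerType = nMarkersPerType,
                  nMarkersPerSubtype = nMarkersPerSubtype, fold = fold,
                  modality = modality, bgMean = bgMean,
                  dispersion = dispersion, featureSpacing = featureSpacing,
                  width = width, typeNames = typeNames,
                  subtypesPerType = subtypesPerType),
    seed = seed
  )
  list(ref = ref, truth = truth)
}

#' Simulate independent genotype dosages
#'
#' Per-variant minor allele frequencies drawn uniformly from
#' \code{mafRange}; hard-call dosages are Binomial(2, MAF), independent
#' across variants (no LD: the toolkit's SNP selection is position-based,
#' so independent variants exercise it fully). Variant positions are
#' drawn uniformly on the toy genome so they land inside and outside the
#' gene windows and peaks of \code{\link{simulateReference}}.
#'
#' @param nSamples,nVariants dimensions.
#' @param mafRange MAF range, default c(0.05, 0.5).
#' @param seed RNG seed.
#' @param genome genome layout, default \code{\link{toyGenome}}.
#' @return A \code{\linkS4class{DosageMatrix}}; true MAFs in the
#'   \code{"maf"} attribute.
#' @export
simulateGenotypes <- function(nSamples, nVariants,
                              mafRange = c(0.05, 0.5), seed = 1,
                              genome = toyGenome()) {
  stopifnot(nSamples >= 1, nVariants >= 1)
  set.seed(seed)
  chrom <- sample(genome$chrom, nVariants, replace = TRUE,
                  prob = genome$length / sum(genome$length))
  pos <- integer(nVariants)
  for (i in seq_len(nrow(genome))) {
    idx <- chrom == genome$chrom[i]
    pos[idx] <- sample.int(genome$length[i], sum(idx))
  }
  o <- order(match(chrom, genome$chrom), pos)
  chrom <- chrom[o]; pos <- pos[o]
  maf <- stats::runif(nVariants, mafRange[1], mafRange[2])
  alleles <- t(vapply(seq_len(nVariants), function(i)
    sample(c("A", "C", "G", "T"), 2), character(2)))
  variants <- data.frame(
    variant_id = sprintf("var%05d", seq_len(nVariants)),
    chrom = chrom, pos = pos, a1 = alleles[, 1], a2 = alleles[, 2])
  dosage <- vapply(seq_len(nVariants), function(j)
    stats::rbinom(nSamples, 2L, maf[j]), numeric(nSamples))
  if (nSamples == 1L) dosage <- matrix(dosage, nrow = 1)
  rownames(dosage) <- sprintf("sample%05d", seq_len(nSamples))
  dm <- DosageMatrix(dosage, variants)
  attr(dm, "maf") <- maf
  dm
}

#' Plant a causal architecture inside a range mask
#'
#' Picks causal variants among the panel variants lying inside the given
#' range set (e.g. one cell type's selection mask) and assigns them a
#' constant per-allele effect. This is how the generators guarantee that
#' the causal variants of a cell type lie inside that type's derivable
#' ranges.
#'
#' @param dosageMatrix A \code{\linkS4class{DosageMatrix}}.
#' @param ranges normalized \code{GRanges} mask.
#' @param nCausal number of causal variants.
#' @param effectSize per-allele effect in outcome units.
#' @param seed RNG seed.
#' @return data.frame causal map: variant_id, effect.
#' @export
plantCausalArchitecture <- function(dosageMatrix, ranges, nCausal,
                                    effectSize = 0.3, seed = 1) {
  inRange <- snpsInRanges(variantLoci(dosageMatrix), ranges)
  if (length(inRange) < nCausal)
    stop("only ", length(inRange), " panel variants in range; need ",
         nCausal)
  set.seed(seed)
  data.frame(variant_id = sample(inRange, nCausal), effect = effectSize)
}

#' Simulate the endophenotype battery with a planted genetic architecture
#'
#' The genetic value of each sample is the dosage-weighted sum of the
#' causal effects; continuous outcomes add Gaussian noise scaled so the
#' genetic value explains \code{h2} of the outcome variance; the binary
#' pathology diagnosis thresholds a liability (genetic value plus noise)
#' at the stated prevalence. Covariates (age at death, sex, education,
#' three PCs, APOE e2/e4 dosages) are generated independently of
#' genotype, so they are pure noise terms for the synthetic battery.
#'
#' @param dosageMatrix A \code{\linkS4class{DosageMatrix}}.
#' @param causalMap data.frame with variant_id, effect (may be empty for
#'   a null battery).
#' @param h2 target proportion of outcome variance explained by the
#'   genetic value, in [0, 1).
#' @param seed RNG seed.
#' @param prevalence liability-threshold case fraction, default 0.4.
#' @return phenotype data.frame (sample_id, ad_pathdx, mmse,
#'   tangle_density, nft_burden, abeta_burden, diffuse_plaque,
#'   neuritic_plaque, covariates); genetic values in the \code{"G"}
#'   attribute.
#' @export
simulatePhenotypes <- function(dosageMatrix, causalMap, h2, seed = 1,
                               prevalence = 0.4) {
  stopifnot(h2 >= 0, h2 < 1)
  D <- dosageMatrix@dosage
  n <- nrow(D)
  set.seed(seed)
  if (nrow(causalMap) > 0) {
    missing <- setdiff(causalMap$variant_id, colnames(D))
    if (length(missing))
      stop("causal variants absent from panel: ",
           paste(missing, collapse = ", "))
    G <- as.numeric(D[, causalMap$variant_id, drop = FALSE] %*%
                      causalMap$effect)
  } else G <- numeric(n)
  varG <- stats::var(G)
  if (h2 > 0 && varG == 0)
    stop("h2 target unreachable: genetic value has zero variance")
  noiseVar <- if (h2 > 0) varG * (1 - h2) / h2 else 1
  noiseSd <- sqrt(noiseVar)
  contin <- function() pmax(0, 10 + G + stats::rnorm(n, 0, noiseSd))
  liability <- G + stats::rnorm(n, 0, noiseSd)
  thr <- stats::qnorm(1 - prevalence, mean = mean(G),
                      sd = sqrt(varG + noiseVar))
  e4 <- stats::rbinom(n, 2, 0.15)
  e2 <- pmin(stats::rbinom(n, 2, 0.07), 2 - e4)
  out <- data.frame(
    sample_id = rownames(D),
    ad_pathdx = as.integer(liability > thr),
    mmse = pmin(30, pmax(0, 26 - G + stats::rnorm(n, 0, noiseSd))),
    tangle_density = contin(),
    nft_burden = contin(),
    abeta_burden = contin(),
    diffuse_plaque = contin(),
    neuritic_plaque = contin(),
    age_at_death = stats::rnorm(n, 85, 5),
    sex = stats::rbinom(n, 1, 0.5),
    education_years = stats::rnorm(n, 16, 3),
    pc1 = stats::rnorm(n), pc2 = stats::rnorm(n), pc3 = stats::rnorm(n),
    apoe_e2_dosage = e2,
    apoe_e4_dosage = e4
  )
  attr(out, "G") <- G
  out
}

#' Simulate per-cohort GWAS and their meta-analysis
#'
#' Draws a shared variant panel, then for each cohort independent
#' genotypes and a logistic disease outcome whose log-odds are the causal
#' effects (centered so the case fraction tracks the prevalence), runs
#' \code{\link{cohortAssociation}} per cohort and combines with
#' \code{\link{inverseVarianceMeta}}. True effects are recoverable from
#' the meta table within sampling error.
#'
#' @param nCohorts number of cohorts.
#' @param nPerCohort samples per cohort (scalar or vector).
#' @param nVariants panel size.
#' @param causalMap data.frame variant_id, effect (log-odds ratios);
#'   ids refer to the panel ("var00001", ...). NULL for all-null.
#' @param seed RNG seed.
#' @param prevalence baseline case probability, default 0.5.
#' @param mafRange MAF range for the panel.
#' @return list with \code{cohorts} (per-cohort GWAS tables),
#'   \code{meta} (meta-analyzed table), \code{panel} (variant loci),
#'   \code{maf} (true MAFs).
#' @export
simulateCohortSumstats <- function(nCohorts, nPerCohort, nVariants = 50,
                                   causalMap = NULL, seed = 1,
                                   prevalence = 0.5,
                                   mafRange = c(0.1, 0.5)) {
  stopifnot(nCohorts >= 1)
  nPerCohort <- rep_len(nPerCohort, nCohorts)
  set.seed(seed)
  panel0 <- simulateGenotypes(2, nVariants, mafRange, seed = seed)
  panel <- variantLoci(panel0)
  maf <- attr(panel0, "maf")
  beta <- stats::setNames(numeric(nVariants), panel$variant_id)
  if (!is.null(causalMap) && nrow(causalMap) > 0)
    beta[causalMap$variant_id] <- causalMap$effect
  cohorts <- vector("list", nCohorts)
  for (k in seq_len(nCohorts)) {
    n <- nPerCohort[k]
    dosage <- vapply(seq_len(nVariants), function(j)
      stats::rbinom(n, 2L, maf[j]), numeric(n))
    rownames(dosage) <- sprintf("c%02ds%05d", k, seq_len(n))
    colnames(dosage) <- panel$variant_id
    eta <- stats::qlogis(prevalence) +
      as.numeric(dosage %*% beta) - sum(beta * 2 * maf)
    y <- stats::rbinom(n, 1, stats::plogis(eta))
    dm <- DosageMatrix(dosage, panel)
    cohorts[[k]] <- cohortAssociation(dm, y)
  }
  list(cohorts = cohorts, meta = inverseVarianceMeta(cohorts),
       panel = panel, maf = maf)
}

#' End-to-end synthetic study
#'
#' Generates a full study with a causal architecture planted inside one
#' cell type's selection mask and runs the whole pipeline: single-cell
#' reference, control filtering, expression filter, specificity scoring,
#' top-fraction selection, gene-window (or peak) range construction,
#' genotypes, phenotypes, weights (true causal effects plus small noise
#' weights genome-wide, a pass-through raw-beta weight table), per-type
#' and genome-wide scores, standardization, and the association battery
#' on one outcome.
#'
#' @param seed RNG seed driving every stage.
#' @param causalType the cell type whose mask receives the causal
#'   variants, default "AST".
#' @param nTypes,nCellsPerType,nFeatures,nMarkersPerType,fold reference
#'   generator parameters (see \code{\link{simulateReference}}).
#' @param nSamples,nVariants genotype panel dimensions.
#' @param nCausal,effectSize,h2 architecture parameters.
#' @param q top-fraction for selection, default 0.10.
#' @param flankBp gene window flank, default 30000.
#' @param outcome outcome column for the battery, default
#'   "neuritic_plaque".
#' @param noiseWeightSd SD of the non-causal background weights.
#' @return list: ref, truth, selected (per-type feature sets), ranges
#'   (per-type GRanges), dosageMatrix, causalMap, phenos, profiles
#'   (standardized), battery (association records incl. the genome
#'   label, with the multiplicative adjustment over the cell types).
#' @export
simulateStudy <- function(seed = 1, causalType = "AST", nTypes = 7,
                          nCellsPerType = 40, nFeatures = 200,
                          nMarkersPerType = 10, fold = 4,
                          nSamples = 2000, nVariants = 400,
                          nCausal = 10, effectSize = 0.3, h2 = 0.3,
                          q = 0.10, flankBp = 30000,
                          outcome = "neuritic_plaque",
                          noiseWeightSd = 0.01) {
  sim <- simulateReference(nTypes = nTypes, nCellsPerType = nCellsPerType,
                           nFeatures = nFeatures,
                           nMarkersPerType = nMarkersPerType,
                           fold = fold, modality = "RNA", seed = seed)
  ref <- sim$ref
  ctrl <- selectControlCells(ref, rnaControlCriteria())
  sub <- ref[, ctrl]
  expressed <- filterExpressedFeatures(assay(sub, "counts"),
                                       colData(sub)$cell_type)
  norm <- normalizeRna(assay(sub, "counts"))
  means <- meanActivityByType(norm[expressed, , drop = FALSE],
                              colData(sub)$cell_type)
  spec <- specificityScores(means)
  selected <- selectTopFraction(spec, q, expressed)
  feats <- featureGRanges(sim$truth$features)
  ranges <- lapply(selected, function(ids)
    geneWindows(feats[ids], flankBp = flankBp))

  dm <- simulateGenotypes(nSamples, nVariants, seed = seed + 1000L)
  causalMap <- plantCausalArchitecture(dm, ranges[[causalType]], nCausal,
                                       effectSize, seed = seed + 2000L)
  phenos <- simulatePhenotypes(dm, causalMap, h2, seed = seed + 3000L)

  panel <- variantLoci(dm)
  set.seed(seed + 4000L)
  weights <- data.frame(chrom = panel$chrom, variant_id = panel$variant_id,
                        pos = panel$pos, a1 = panel$a1, a2 = panel$a2,
                        weight = stats::rnorm(nrow(panel), 0, noiseWeightSd))
  ci <- match(causalMap$variant_id, weights$variant_id)
  weights$weight[ci] <- causalMap$effect
  aligned <- harmonizeWeights(weights, dm)

  profiles <- do.call(rbind, c(
    lapply(names(ranges), function(ty)
      computePrs(dm, aligned, ranges[[ty]], label = ty)),
    list(computePrs(dm, aligned, NULL, label = "genome"))))
  profiles <- standardizeScores(profiles)
  battery <- associationBattery(
    profiles, phenos,
    outcomes = stats::setNames("linear", outcome),
    m = length(ranges))
  list(ref = ref, truth = sim$truth, selected = selected, ranges = ranges,
       dosageMatrix = dm, causalMap = causalMap, phenos = phenos,
       profiles = profiles, battery = battery)
}
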