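#' Validate a pipeline run configuration
#'
#' Checks the configuration before any computation: stage names, fraction
#' and flank parameters, multiplier and seed. Returns the config with
#' defaults filled.
#'
#' @param config list; see \code{\link{runPipeline}}.
#' @return validated config.
#' @export
validateRunConfig <- function(config) {
  defaults <- list(
    seed = 1L,
    stages = c("simulate", "reference", "ranges", "score", "assoc"),
    q = 0.10, flankBp = 30000, m = NULL,
    outcome = "neuritic_plaque", model = "linear",
    causalType = "AST", nTypes = 7, nCellsPerType = 40, nFeatures = 200,
    nMarkersPerType = 10, fold = 4, nSamples = 500, nVariants = 600,
    nCausal = 5, effectSize = 0.3, h2 = 0.3, noiseWeightSd = 0.01,
    apoeGene = NULL, apoeFlankBp = 1e6
  )
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  known <- c("simulate", "reference", "ranges", "score", "assoc")
  bad <- setdiff(config$stages, known)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(config$outDir))
    stop("config$outDir is required")
  if (!(config$q > 0 && config$q <= 1))
    stop("q must be in (0, 1]")
  if (config$flankBp < 0) stop("flankBp must be >= 0")
  if (!is.null(config[["m"]]) && config[["m"]] < 1) stop("m must be >= 1")
  if (config$h2 < 0 || config$h2 >= 1) stop("h2 must be in [0, 1)")
  config
}

.configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[order(names(config))]), f)
  unname(tools::md5sum(f))
}

#' Run the end-to-end pipeline
#'
#' Orchestrates the stages (simulate -> reference -> ranges -> score ->
#' assoc) in dependency order, passing all inter-stage data through
#' declared files under \code{config$outDir} so re-runs are reproducible
#' and each stage can also be run standalone on externally supplied
#' files. With identical config and inputs the outputs are identical.
#'
#' @param config list with \code{outDir}, \code{seed}, \code{stages} and
#'   stage parameters (see \code{\link{validateRunConfig}} for names and
#'   defaults). When the simulate stage is disabled the reference files
#'   (reference_counts.mtx, reference_cells.tsv, reference_features.tsv),
#'   dosage pair (dosages.tsv, variants.tsv), weights.txt and
#'   phenotypes.tsv must already exist in \code{outDir}.
#' @return run report: per-stage counts, the exact config used and its
#'   hash.
#' @export
runPipeline <- function(config) {
  config <- validateRunConfig(config)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outDir, ...)
  report <- list(config = config, configHash = .configHash(config),
                 counts = list())

  if ("simulate" %in% config$stages) {
    sim <- simulateReference(
      nTypes = config$nTypes, nCellsPerType = config$nCellsPerType,
      nFeatures = config$nFeatures,
      nMarkersPerType = config$nMarkersPerType,
      fold = config$fold, modality = "RNA", seed = config$seed)
    writeScReference(sim$ref, config$outDir)
    writeManifest(sim$truth["params"], out("manifest.json"))
    dm <- simulateGenotypes(config$nSamples, config$nVariants,
                            seed = config$seed + 1000L)
    writeDosageTsv(dm, out("dosages.tsv"), out("variants.tsv"))
    # plant causal variants inside the causal type's derivable ranges
    feats <- featureGRanges(sim$truth$features)
    causalRanges <- geneWindows(
      feats[sim$truth$marker_map[[config$causalType]]],
      flankBp = config$flankBp)
    causalMap <- plantCausalArchitecture(dm, causalRanges, config$nCausal,
                                         config$effectSize,
                                         seed = config$seed + 2000L)
    phenos <- simulatePhenotypes(dm, causalMap, config$h2,
                                 seed = config$seed + 3000L)
    writePhenotypes(phenos, out("phenotypes.tsv"))
    panel <- variantLoci(dm)
    set.seed(config$seed + 4000L)
    weights <- data.frame(
      chrom = panel$chrom, variant_id = panel$variant_id, pos = panel$pos,
      a1 = panel$a1, a2 = panel$a2,
      weight = stats::rnorm(nrow(panel), 0, config$noiseWeightSd))
    weights$weight[match(causalMap$variant_id, weights$variant_id)] <-
      causalMap$effect
    writeWeights(weights, out("weights.txt"))
    utils::write.table(causalMap, out("causal_map.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$counts$simulate <- list(
      cells = ncol(sim$ref), features = nrow(sim$ref),
      samples = config$nSamples, variants = config$nVariants,
      causal = nrow(causalMap))
  }

  if ("reference" %in% config$stages) {
    ref <- readScReference(out("reference_counts.mtx"),
                           out("reference_cells.tsv"),
                           out("reference_features.tsv"), "RNA")
    ctrl <- selectControlCells(ref, rnaControlCriteria())
    sub <- ref[, ctrl]
    expressed <- filterExpressedFeatures(assay(sub, "counts"),
                                         colData(sub)$cell_type)
    norm <- normalizeRna(assay(sub, "counts"))
    means <- meanActivityByType(norm[expressed, , drop = FALSE],
                                colData(sub)$cell_type)
    spec <- specificityScores(means)
    selected <- selectTopFraction(spec, config$q, expressed)
    writeSpecificityTable(spec, out("specificity.tsv"), selected)
    for (ty in names(selected))
      writeLines(selected[[ty]], out(paste0("selected_", ty, ".txt")))
    report$counts$reference <- list(
      control_cells = length(ctrl), expressed_features = length(expressed),
      selected_per_type = lengths(selected))
  }

  if ("ranges" %in% config$stages) {
    feats <- utils::read.delim(out("reference_features.tsv"))
    gr <- featureGRanges(feats)
    selFiles <- list.files(config$outDir, "^selected_.*\\.txt$",
                           full.names = TRUE)
    if (!length(selFiles)) stop("ranges stage: no selected_* files found")
    nSnps <- list()
    for (f in selFiles) {
      ty <- sub("^selected_(.*)\\.txt$", "\\1", basename(f))
      ids <- readLines(f)
      rg <- geneWindows(gr[ids], flankBp = config$flankBp)
      if (!is.null(config$apoeGene) && config$apoeGene %in% names(gr))
        rg <- subtractRegion(rg, gr[config$apoeGene],
                             flankBp = config$apoeFlankBp)
      writeBed(rg, out(paste0("ranges_", ty, ".bed")), label = ty)
      nSnps[[ty]] <- length(rg)
    }
    report$counts$ranges <- list(intervals_per_type = nSnps)
  }

  if ("score" %in% config$stages) {
    dm <- readDosageTsv(out("dosages.tsv"), out("variants.tsv"))
    weights <- readWeights(out("weights.txt"))
    aligned <- harmonizeWeights(weights, dm)
    bedFiles <- list.files(config$outDir, "^ranges_.*\\.bed$",
                           full.names = TRUE)
    if (!length(bedFiles)) stop("score stage: no ranges_* files found")
    profs <- list()
    for (f in bedFiles) {
      ty <- sub("^ranges_(.*)\\.bed$", "\\1", basename(f))
      profs[[ty]] <- computePrs(dm, aligned, readBed(f), label = ty)
    }
    profs$genome <- computePrs(dm, aligned, NULL, label = "genome")
    profiles <- standardizeScores(do.call(rbind, profs))
    utils::write.table(profiles, out("profiles.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    nsnp <- vapply(profs, function(p) p$n_snps_used[1], 0)
    report$counts$score <- list(samples_scored = nrow(profs$genome),
                                snps_per_label = as.list(nsnp))
  }

  if ("assoc" %in% config$stages) {
    profiles <- utils::read.delim(out("profiles.tsv"))
    phenos <- readPhenotypes(out("phenotypes.tsv"))
    m <- config[["m"]]
    if (is.null(m))
      m <- length(setdiff(unique(profiles$label), "genome"))
    battery <- associationBattery(
      profiles, phenos,
      outcomes = stats::setNames(config$model, config$outcome), m = m)
    utils::write.table(battery, out("battery.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$counts$assoc <- list(models_fitted = nrow(battery), m = m)
  }

  report
}
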