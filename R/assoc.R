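#' Default covariate set for endophenotype models
#'
#' Age at death, sex, the first three ancestry principal components, and
#' the APOE e2 and e4 allele dosages. Models of the MMSE outcome
#' additionally adjust for years of education (added automatically by
#' \code{\link{fitOutcomeModel}}).
#'
#' @return character vector of phenotype column names.
#' @export
defaultCovariates <- function() {
  c("age_at_death", "sex", "pc1", "pc2", "pc3",
    "apoe_e2_dosage", "apoe_e4_dosage")
}

.checkCollinearity <- function(M) {
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    aliased <- colnames(M)[qrM$pivot[(qrM$rank + 1):ncol(M)]]
    stop("collinear model columns: ", paste(aliased, collapse = ", "))
  }
}

#' Fit one predictor-outcome association model
#'
#' Linear or logistic regression of an outcome on a predictor (a
#' standardized score or a SNP dosage) with the mandated covariate set;
#' education in years is added automatically when the outcome is MMSE.
#' Samples with any missing value among outcome, predictor or covariates
#' are dropped casewise and the complete-case n is reported. An exactly
#' collinear design is an error naming the offending columns, never a
#' silent estimate.
#'
#' @param predictor numeric vector aligned with \code{phenos} rows, or a
#'   named vector matched on \code{phenos$sample_id}.
#' @param outcomeName phenotype column to model.
#' @param phenos data.frame of phenotype records (see
#'   \code{\link{simulatePhenotypes}} for the column set).
#' @param model \code{"linear"} or \code{"logistic"}.
#' @param covariates covariate column names, default
#'   \code{\link{defaultCovariates}}.
#' @param extraCovariates additional covariate column names (e.g. a
#'   conditioning variable).
#' @param predictorName label recorded on the output row.
#' @param minN minimum complete cases, default 20.
#' @return one-row data.frame: predictor, outcome, model, beta, se, p,
#'   fdr (NA), n, covariate_list.
#' @export
fitOutcomeModel <- function(predictor, outcomeName, phenos,
                            model = c("linear", "logistic"),
                            covariates = defaultCovariates(),
                            extraCovariates = character(0),
                            predictorName = "score", minN = 20) {
  model <- match.arg(model)
  if (!outcomeName %in% colnames(phenos))
    stop("outcome '", outcomeName, "' not in phenotype table")
  if (!is.null(names(predictor)))
    predictor <- predictor[match(phenos$sample_id, names(predictor))]
  stopifnot(length(predictor) == nrow(phenos))
  covs <- covariates
  if (tolower(outcomeName) == "mmse" &&
      !"education_years" %in% c(covs, extraCovariates))
    covs <- c(covs, "education_years")
  covs <- c(covs, extraCovariates)
  missingCov <- setdiff(covs, colnames(phenos))
  if (length(missingCov))
    stop("covariate(s) absent from phenotype table: ",
         paste(missingCov, collapse = ", "))
  y <- phenos[[outcomeName]]
  df <- data.frame(.y = y, .pred = predictor,
                   phenos[, covs, drop = FALSE])
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  if (nrow(df) < minN)
    stop("only ", nrow(df), " complete cases; need at least ", minN)
  M <- cbind(`(Intercept)` = 1,
             as.matrix(df[, c(covs, ".pred"), drop = FALSE]))
  .checkCollinearity(M)
  if (model == "logistic") {
    if (!all(df$.y %in% c(0, 1)))
      stop("logistic model requires a 0/1 outcome")
    fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
    if (!fit$converged) stop("logistic model failed to converge")
  } else {
    fit <- stats::lm(.y ~ ., data = df)
  }
  cf <- summary(fit)$coefficients
  data.frame(predictor = predictorName, outcome = outcomeName,
             model = model,
             beta = cf[".pred", 1], se = cf[".pred", 2], p = cf[".pred", 4],
             fdr = NA_real_, n = nrow(df),
             covariate_list = paste(covs, collapse = ","),
             row.names = NULL)
}

#' Multiplicative multiple-testing adjustment
#'
#' The study's "FDR" is a Bonferroni-style multiplication: each p-value
#' times the number of cell types tested, capped at 1. With m = 6 primary
#' cell types an adjusted value of 0.05 corresponds to p = 0.00833; with
#' m = 8 neuron subtypes, to p = 0.00625. For the standard
#' Benjamini-Hochberg procedure use \code{\link{adjustFdrBH}}, which is a
#' different quantity and deliberately named differently.
#'
#' @param p p-value(s) in (0, 1].
#' @param m number of tests, >= 1.
#' @return adjusted value(s) \code{min(1, p * m)}.
#' @export
adjustFdrMultiply <- function(p, m) {
  stopifnot(all(p > 0), all(p <= 1), m >= 1)
  pmin(1, p * m)
}

#' Benjamini-Hochberg adjustment (standard FDR)
#'
#' Thin wrapper over \code{stats::p.adjust(method = "BH")}, provided so
#' the multiplicative adjustment of \code{\link{adjustFdrMultiply}} is
#' never confused with the conventional FDR procedure.
#'
#' @param p vector of p-values.
#' @return BH-adjusted values.
#' @export
adjustFdrBH <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Score-outcome association battery
#'
#' Runs \code{\link{fitOutcomeModel}} for every (label, outcome) pair of
#' a standardized score table and applies the multiplicative adjustment
#' across the labels tested for each outcome.
#'
#' @param profiles standardized profiles (see
#'   \code{\link{standardizeScores}}), stacked over labels.
#' @param phenos phenotype table with sample_id.
#' @param outcomes named character vector mapping outcome column ->
#'   \code{"linear"} or \code{"logistic"}.
#' @param m multiplier for the adjustment; defaults to the number of
#'   distinct labels.
#' @param ... passed to \code{fitOutcomeModel}.
#' @return data.frame of association records with fdr filled.
#' @export
associationBattery <- function(profiles, phenos, outcomes,
                               m = length(unique(profiles$label)), ...) {
  labels <- unique(profiles$label)
  rows <- list()
  for (lab in labels) {
    prof <- profiles[profiles$label == lab, , drop = FALSE]
    z <- stats::setNames(prof$z_score, prof$sample_id)
    for (oc in names(outcomes)) {
      rec <- fitOutcomeModel(z, oc, phenos, model = outcomes[[oc]],
                             predictorName = lab, ...)
      rows[[length(rows) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- adjustFdrMultiply(out$p, m)
  out
}

#' Per-SNP association scan over a variant set
#'
#' Tests each variant's dosage against one outcome with the standard
#' covariate scheme, and reports the study-wide significance line
#' 0.05 / (number of SNPs tested) alongside (as the
#' \code{"significance_line"} attribute). Individual model failures are
#' logged as warnings and skipped, not fatal.
#'
#' @param snpSet character vector of variant ids (must be present in the
#'   dosage panel).
#' @param dosageMatrix A \code{\linkS4class{DosageMatrix}}.
#' @param outcomeName outcome column in \code{phenos}.
#' @param phenos phenotype table (rows aligned to the panel's samples by
#'   sample_id).
#' @param model \code{"linear"} (default) or \code{"logistic"}.
#' @param ... passed to \code{\link{fitOutcomeModel}}.
#' @return data.frame of per-SNP association records, attribute
#'   \code{significance_line} = 0.05/|snpSet|.
#' @export
perSnpAssociation <- function(snpSet, dosageMatrix, outcomeName, phenos,
                              model = "linear", ...) {
  stopifnot(methods::is(dosageMatrix, "DosageMatrix"))
  if (length(snpSet) == 0L) stop("empty SNP set")
  panel <- variantLoci(dosageMatrix)
  missing <- setdiff(snpSet, panel$variant_id)
  if (length(missing))
    stop("SNP(s) absent from dosage panel: ",
         paste(utils::head(missing, 5), collapse = ", "))
  D <- dosageMatrix@dosage
  ord <- match(phenos$sample_id, rownames(D))
  rows <- list()
  for (id in snpSet) {
    rec <- tryCatch(
      fitOutcomeModel(D[ord, id], outcomeName, phenos, model = model,
                      predictorName = id, ...),
      error = function(e) {
        warning("SNP ", id, " skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(rec)) {
      v <- panel[panel$variant_id == id, ]
      rec$chrom <- v$chrom
      rec$pos <- v$pos
      rows[[length(rows) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "significance_line") <- 0.05 / length(snpSet)
  out
}

#' Conditional per-SNP association
#'
#' Refits the per-SNP model with one additional covariate (e.g. a second
#' pathology measure, to ask whether the SNP-outcome association survives
#' conditioning on it). Conditioning on the outcome itself is refused.
#'
#' @param snp variant id.
#' @param outcomeName outcome column.
#' @param extraCovariateName conditioning phenotype column.
#' @param dosageMatrix A \code{\linkS4class{DosageMatrix}}.
#' @param phenos phenotype table.
#' @param model \code{"linear"} or \code{"logistic"}.
#' @param ... passed to \code{\link{fitOutcomeModel}}.
#' @return one-row association record (covariate_list includes the
#'   conditioning variable).
#' @export
conditionalAssociation <- function(snp, outcomeName, extraCovariateName,
                                   dosageMatrix, phenos, model = "linear",
                                   ...) {
  if (identical(extraCovariateName, outcomeName))
    stop("conditioning variable is identical to the outcome")
  if (!extraCovariateName %in% colnames(phenos))
    stop("conditioning variable '", extraCovariateName,
         "' not in phenotype table")
  D <- dosageMatrix@dosage
  ord <- match(phenos$sample_id, rownames(D))
  fitOutcomeModel(D[ord, snp], outcomeName, phenos, model = model,
                  extraCovariates = extraCovariateName,
                  predictorName = snp, ...)
}

#' Locus window scan around an index SNP
#'
#' Tests every panel variant on the index SNP's chromosome within
#' \code{windowBp} of its position (inclusive at both ends, so a variant
#' exactly at the window edge is tested), regardless of any cell-type
#' range membership. The output is ordered by position, ready for a
#' locus plot.
#'
#' @param indexSnp variant id present in the panel.
#' @param dosageMatrix A \code{\linkS4class{DosageMatrix}}.
#' @param outcomeName outcome column.
#' @param phenos phenotype table.
#' @param windowBp half-window in bp, default 300000.
#' @param ... passed to \code{\link{perSnpAssociation}}.
#' @return per-SNP association records ordered by pos.
#' @export
locusWindowScan <- function(indexSnp, dosageMatrix, outcomeName, phenos,
                            windowBp = 300000, ...) {
  panel <- variantLoci(dosageMatrix)
  i <- match(indexSnp, panel$variant_id)
  if (is.na(i)) stop("index SNP '", indexSnp, "' absent from panel")
  sel <- panel$chrom == panel$chrom[i] &
    abs(panel$pos - panel$pos[i]) <= windowBp
  ids <- panel$variant_id[sel][order(panel$pos[sel])]
  perSnpAssociation(ids, dosageMatrix, outcomeName, phenos, ...)
}

#' Pseudobulk single-cell eQTL test
#'
#' Regresses per-donor pseudobulk expression of one gene within one cell
#' group (the donor-level mean of depth-normalized, untransformed
#' expression) on the donor's dosage at one variant, with the standard
#' covariate set. Donors are matched between the reference's donor ids
#' and the panel's sample ids.
#'
#' @param snp variant id.
#' @param gene feature id present in the reference.
#' @param cellGroup cell type (or subtype) label restricting the cells.
#' @param ref An \code{\linkS4class{ScReference}} (RNA).
#' @param dosageMatrix A \code{\linkS4class{DosageMatrix}} keyed by donor.
#' @param phenos phenotype table keyed by donor (sample_id).
#' @param groupBy \code{"cell_type"} or \code{"subtype"}.
#' @param minDonors minimum donors with both data types, default 20.
#' @param ... passed to \code{\link{fitOutcomeModel}}.
#' @return one-row association record; a gene with zero expression in
#'   every cell is returned with beta 0 and a \code{degenerate} flag.
#' @export
singleCellEqtl <- function(snp, gene, cellGroup, ref, dosageMatrix, phenos,
                           groupBy = "cell_type", minDonors = 20, ...) {
  stopifnot(methods::is(ref, "ScReference"))
  cd <- as.data.frame(colData(ref))
  if (!gene %in% rownames(ref)) stop("gene '", gene, "' absent from matrix")
  inGroup <- cd[[groupBy]] == cellGroup & !is.na(cd[[groupBy]])
  if (!any(inGroup)) stop("no cells in group '", cellGroup, "'")
  norm <- normalizeRna(assay(ref, "counts")[, inGroup, drop = FALSE])
  expr <- as.numeric(norm[gene, ])
  donors <- cd$donor_id[inGroup]
  pseudobulk <- tapply(expr, donors, mean)
  D <- dosageMatrix@dosage
  common <- intersect(names(pseudobulk), rownames(D))
  common <- intersect(common, phenos$sample_id)
  if (length(common) < minDonors)
    stop("only ", length(common), " donors with expression and dosage; need ",
         minDonors)
  d <- D[common, snp]
  if (stats::sd(d) == 0) stop("dosage constant across donors")
  ph <- phenos[match(common, phenos$sample_id), , drop = FALSE]
  ph$.expr <- as.numeric(pseudobulk[common])
  if (all(ph$.expr == 0)) {
    rec <- data.frame(predictor = snp, outcome = paste0(gene, ":", cellGroup),
                      model = "linear", beta = 0, se = NA_real_, p = NA_real_,
                      fdr = NA_real_, n = length(common),
                      covariate_list = paste(defaultCovariates(),
                                             collapse = ","),
                      row.names = NULL)
    attr(rec, "degenerate") <- TRUE
    return(rec)
  }
  rec <- fitOutcomeModel(stats::setNames(d, common), ".expr", ph,
                         model = "linear", predictorName = snp,
                         minN = minDonors, ...)
  rec$outcome <- paste0(gene, ":", cellGroup)
  rec
}
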