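#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against the proportions expected from the estimated allele frequency.
#' Monomorphic input (allele frequency 0 or 1) returns p = 1 by
#' convention: there is nothing to test.
#'
#' @param nAA,nAa,naa genotype counts (hom-ref, het, hom-alt).
#' @return list with components \code{chisq} and \code{p}.
#' @export
hweTest <- function(nAA, nAa, naa) {
  stopifnot(nAA >= 0, nAa >= 0, naa >= 0)
  n <- nAA + nAa + naa
  if (n == 0) stop("total genotype count is zero")
  p <- (2 * nAA + nAa) / (2 * n)
  if (p == 0 || p == 1)
    return(list(chisq = 0, p = 1))
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chisq <- sum((c(nAA, nAa, naa) - expected)^2 / expected)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Genotype-level variant QC filter
#'
#' Excludes variants with minor allele count below \code{macMin}, HWE
#' p-value below \code{hwePMin}, or missingness above \code{missingMax}.
#' The exclusion rules are strict inequalities, so a variant sitting
#' exactly on any boundary is kept.
#'
#' @param stats data.frame with variant_id, mac, hwe_p, missing_rate.
#' @param macMin minimum minor allele count, default 5.
#' @param hwePMin minimum HWE p, default 1e-6.
#' @param missingMax maximum missing rate, default 0.10.
#' @return character vector of surviving variant ids.
#' @export
genotypeQcFilter <- function(stats, macMin = 5, hwePMin = 1e-6,
                             missingMax = 0.10) {
  need <- c("variant_id", "mac", "hwe_p", "missing_rate")
  stopifnot(all(need %in% colnames(stats)))
  keep <- stats$mac >= macMin &
    stats$hwe_p >= hwePMin &
    stats$missing_rate <= missingMax
  stats$variant_id[keep]
}

#' Imputation-quality filter on summary statistics
#'
#' Drops rare variants (MAF below \code{mafLo}) with imputation R-squared
#' below \code{r2LoRare} and common variants with R-squared below
#' \code{r2LoCommon}. MAF exactly at the boundary falls under the common
#' (lenient) rule. Missing R-squared is treated as 1 with a warning, the
#' behavior appropriate for directly typed or sequenced variants.
#'
#' @param records data.frame with at least eaf and info_r2 columns.
#' @param mafLo MAF boundary, default 0.01.
#' @param r2LoRare,r2LoCommon R-squared thresholds, defaults 0.8 and 0.4.
#' @return filtered data.frame (rows preserved in order).
#' @export
imputationFilter <- function(records, mafLo = 0.01, r2LoRare = 0.8,
                             r2LoCommon = 0.4) {
  stopifnot("eaf" %in% colnames(records))
  r2 <- if ("info_r2" %in% colnames(records)) records$info_r2 else
    rep(NA_real_, nrow(records))
  if (anyNA(r2)) {
    warning(sum(is.na(r2)),
            " record(s) without imputation R2; treated as R2 = 1")
    r2[is.na(r2)] <- 1
  }
  maf <- pmin(records$eaf, 1 - records$eaf)
  rare <- maf < mafLo
  drop <- ifelse(rare, r2 < r2LoRare, r2 < r2LoCommon)
  records[!drop, , drop = FALSE]
}

#' Per-cohort case-control association
#'
#' Plain logistic regression of case status on each variant's dosage plus
#' covariates, giving the maximum-likelihood log-odds ratio, its standard
#' error and the Wald p-value. Cohorts with fewer than five cases or five
#' controls are refused. Variants whose fit fails to converge or shows
#' separation (degenerate standard errors) are excluded with a warning
#' rather than reported as unreliable estimates.
#'
#' @param dosages A \code{\linkS4class{DosageMatrix}}.
#' @param phenotype 0/1 vector, one per sample.
#' @param covariates optional numeric matrix/data.frame of covariates
#'   (samples x k), e.g. age, sex and ancestry PCs.
#' @param minGroup minimum cases and controls, default 5.
#' @return data.frame of per-variant records: variant_id, chrom, pos, a1
#'   (effect allele = counted allele), a2, beta, se, p, eaf, n_cases,
#'   n_controls.
#' @export
cohortAssociation <- function(dosages, phenotype, covariates = NULL,
                              minGroup = 5) {
  stopifnot(methods::is(dosages, "DosageMatrix"))
  D <- dosages@dosage
  stopifnot(length(phenotype) == nrow(D), all(phenotype %in% c(0, 1)))
  nCase <- sum(phenotype == 1)
  nCtrl <- sum(phenotype == 0)
  if (nCase < minGroup || nCtrl < minGroup)
    stop("cohort has fewer than ", minGroup,
         " participants in the case or control group (",
         nCase, " cases, ", nCtrl, " controls)")
  X <- if (is.null(covariates)) NULL else as.matrix(covariates)
  v <- variantLoci(dosages)
  res <- vector("list", ncol(D))
  failed <- character(0)
  for (j in seq_len(ncol(D))) {
    d <- D[, j]
    df <- data.frame(y = phenotype, d = d)
    if (!is.null(X)) df <- cbind(df, as.data.frame(X))
    fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
    cf <- summary(fit)$coefficients
    ok <- fit$converged && "d" %in% rownames(cf) &&
      is.finite(cf["d", 2]) && cf["d", 2] < 100
    if (!ok) {
      failed <- c(failed, colnames(D)[j])
      next
    }
    res[[j]] <- data.frame(
      variant_id = v$variant_id[j], chrom = v$chrom[j], pos = v$pos[j],
      a1 = v$a1[j], a2 = v$a2[j],
      beta = cf["d", 1], se = cf["d", 2], p = cf["d", 4],
      eaf = mean(d, na.rm = TRUE) / 2,
      n_cases = nCase, n_controls = nCtrl
    )
  }
  if (length(failed))
    warning("excluded ", length(failed),
            " variant(s) with non-converged or separated fits: ",
            paste(utils::head(failed, 5), collapse = ", "),
            if (length(failed) > 5) ", ..." else "")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

.harmonizeToReference <- function(rec, ref) {
  # rec, ref: single-variant rows with a1/a2/beta/eaf
  if (rec$a1 == ref$a1 && rec$a2 == ref$a2) return(rec)
  if (rec$a1 == ref$a2 && rec$a2 == ref$a1) {
    rec$beta <- -rec$beta
    if (!is.null(rec$eaf) && !is.na(rec$eaf)) rec$eaf <- 1 - rec$eaf
    tmp <- rec$a1; rec$a1 <- rec$a2; rec$a2 <- tmp
    return(rec)
  }
  NULL
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Combines per-cohort effect estimates with weights 1/SE^2 (the METAL
#' standard-error scheme): the pooled beta is the weighted mean, the
#' pooled SE the inverse square root of the total weight, and the p-value
#' comes from a two-sided normal test on beta/SE. Effect alleles are
#' harmonized to the first cohort reporting each variant (a swapped
#' allele pair flips the sign of beta and complements the frequency);
#' variants whose allele pairs cannot be reconciled are dropped with a
#' warning. Cochran's Q and its p-value are reported informationally.
#'
#' @param recordsByCohort list of per-cohort data.frames as returned by
#'   \code{\link{cohortAssociation}} (or read via
#'   \code{\link{readSumstats}}).
#' @return meta-analyzed data.frame: variant_id, chrom, pos, a1, a2, beta,
#'   se, z, p, eaf, n_cohorts, q_stat, q_p.
#' @export
inverseVarianceMeta <- function(recordsByCohort) {
  stopifnot(length(recordsByCohort) >= 1L)
  ids <- unique(unlist(lapply(recordsByCohort, `[[`, "variant_id")))
  out <- vector("list", length(ids))
  dropped <- character(0)
  for (k in seq_along(ids)) {
    id <- ids[k]
    rows <- lapply(recordsByCohort, function(tab)
      tab[tab$variant_id == id, , drop = FALSE])
    rows <- rows[vapply(rows, nrow, 0L) > 0]
    ref <- rows[[1]]
    harm <- list(ref)
    bad <- FALSE
    for (r in rows[-1]) {
      h <- .harmonizeToReference(r, ref)
      if (is.null(h)) { bad <- TRUE; break }
      harm <- c(harm, list(h))
    }
    if (bad) { dropped <- c(dropped, id); next }
    beta <- vapply(harm, `[[`, 0, "beta")
    se <- vapply(harm, `[[`, 0, "se")
    stopifnot(all(se > 0))
    w <- 1 / se^2
    bMeta <- sum(w * beta) / sum(w)
    seMeta <- 1 / sqrt(sum(w))
    z <- bMeta / seMeta
    q <- sum(w * (beta - bMeta)^2)
    eafs <- vapply(harm, function(h)
      if (is.null(h$eaf)) NA_real_ else h$eaf, 0)
    out[[k]] <- data.frame(
      variant_id = id, chrom = ref$chrom, pos = ref$pos,
      a1 = ref$a1, a2 = ref$a2,
      beta = bMeta, se = seMeta, z = z,
      p = 2 * stats::pnorm(-abs(z)),
      eaf = if (all(is.na(eafs))) NA_real_ else
        sum(w[!is.na(eafs)] * eafs[!is.na(eafs)]) / sum(w[!is.na(eafs)]),
      n_cohorts = length(harm),
      q_stat = q,
      q_p = if (length(harm) > 1)
        stats::pchisq(q, df = length(harm) - 1, lower.tail = FALSE)
      else NA_real_
    )
  }
  if (length(dropped))
    warning("dropped ", length(dropped),
            " variant(s) with irreconcilable alleles: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(variant_id = character(0), chrom = character(0),
                      pos = numeric(0), a1 = character(0),
                      a2 = character(0), beta = numeric(0),
                      se = numeric(0), z = numeric(0), p = numeric(0),
                      eaf = numeric(0), n_cohorts = integer(0),
                      q_stat = numeric(0), q_p = numeric(0))
  rownames(res) <- NULL
  res
}
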