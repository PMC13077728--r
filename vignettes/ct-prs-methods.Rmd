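---
title: "Cell-type-specific polygenic risk scores: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type-specific polygenic risk scores: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(ctPRS)
  library(SummarizedExperiment)
})
```

## The problem

A conventional Alzheimer's disease polygenic risk score (ADPRS) aggregates
risk alleles genome-wide and cannot say *through which brain cell type*
the aggregated risk acts. ctPRS builds cell-type-specific ADPRSs
(ct-ADPRS): polygenic scores restricted to SNPs implicated in one cell
type's expression or regulatory landscape, derived from single-nucleus
RNA (snRNA) and ATAC (snATAC) reference data. Scoring each individual
against six primary brain cell types (astrocytes, microglia,
oligodendrocytes, oligodendrocyte precursors, excitatory and inhibitory
neurons) and against neuron subtypes lets the association of genetic risk
with pathology and cognition endophenotypes be partitioned by cell type.

## Specificity scores from single-cell references

The reference is a sparse feature-by-cell count matrix (`ScReference`,
backed by `SingleCellExperiment`) with per-cell type/subtype labels,
donor ids and pathology metadata, and per-feature genomic spans.

Only pathology-free control cells contribute. The control definition is a
config object (`controlCriteria()`) because RNA and ATAC references use
different definitions: RNA controls have possible or no neuritic plaques,
Braak stage ≤ 2, no cognitive impairment and MMSE > 23
(`rnaControlCriteria()`); ATAC controls are nuclei from pathologically
diagnosed controls with TSS enrichment strictly > 1
(`atacControlCriteria()`). Thresholds are inclusive (Braak) or strict
(MMSE, TSS) exactly as stated, and any missing field referenced by an
active criterion is an error rather than a silent drop.

For RNA, genes expressed in at least 10 % of the cells of at least one
type are retained; expression is depth-normalized to counts-per-10,000
per cell with **no log transform**. The specificity of gene $g$ for cell
type $c$ is

$$S_{gc} = \frac{E_{gc}}{\sum_{c'=1}^{C} E_{gc'}}$$

where $E_{gc}$ is the mean normalized expression over the type's cells.
The log transform is deliberately omitted: $S_{gc}$ is a ratio of means,
so a per-gene scale cancels, while a log would distort the ratio. For
ATAC, peak counts get a TF-IDF transform first,

$$x'_{pc} = \log\!\left(1 + 10^4 \cdot \mathrm{TF}_{pc} \cdot
\mathrm{IDF}_p\right), \quad \mathrm{TF}_{pc} = \frac{x_{pc}}{\sum_p
x_{pc}}, \quad \mathrm{IDF}_p = \frac{N_\text{cells}}{\#\{c : x_{pc} >
0\}},$$

the standard LSI formulation (a peak detected in no cell has IDF 0 by
convention and contributes nothing). Mean activity $A_{pc}$ is averaged
per type after clipping negatives to 0, so $S_{pc} \in [0, 1]$.

Per type, the top fraction $q$ (default 10 %) of the filtered universe is
selected: exactly $\lfloor q \cdot N \rfloor$ features, ranked by
descending specificity with a deterministic tie-break (descending mean
activity, then lexicographic feature id). Selection is independent per
type, so sets may overlap. Features whose means are zero in every group
get specificity 0 (not NaN), are flagged, and sort last. `floor` was
chosen over `round` for the count rule; with a 14,000-gene universe and
$q = 0.10$ both give 1,400 per type, and where the two differ by one the
choice is documented here rather than hidden.

### Neuron subtypes

Subtype selection is hierarchical (`hierarchicalSubtypeSelection`):
first the top 20 % of all peaks by parent-type (e.g. GABAergic)
specificity, then specificity is *recomputed among the subtypes only* —
the denominator runs over the subtypes, restricted to the step-1 peaks —
and the top 20 % of the step-1 set is taken per subtype. The same
transform (TF-IDF) is used at both steps; the reference data do not
restate the subtype-step transform, and reusing the primary-step
transform is the only self-consistent choice. Subtype labels are an
input annotation: transferring labels between modalities is upstream of
this package.

## From feature sets to SNP masks

All interval algebra runs on `GRanges` (1-based closed); BED-convention
0-based half-open coordinates are converted exactly once, at the I/O
boundary (`featureGRanges`, `writeBed`/`readBed`), and the VCF 1-based
variant position meets the masks in exactly one place
(`snpsInRanges`). Three strategies build the SNP mask of a label:

* **Gene windows** (`geneWindows`): gene body ± 30 kb, strand-ignored.
  The window is anchored on the whole gene span, not the TSS, matching
  the "on or within 30 kb, upstream or downstream" reading; windows are
  clamped at the chromosome start (no upper clamp unless a chromosome
  length is supplied — the toolkit never needs one on real annotation).
* **Peak intersection** (`peakRanges`): the 500 bp peak spans verbatim.
* **Multi-omic** (`multiomicRanges`): subtype peaks kept only when
  within 300 kb of a neuron-specific gene (gene sets defined more
  leniently, top 20 % by specificity); overlap counts as distance 0.

Masks are normalized (sorted, overlapping *and abutting* intervals
merged): a SNP mask is a set of positions, so abutment is irrelevant to
membership and merging makes outputs canonical. The region around the
APOE gene span ± 1 Mb is subtracted from every cell-type mask
(`subtractRegion`); the APOE span is looked up from the supplied gene
annotation, never hard-coded, so any genome build works. Whether the
exclusion anchors on the gene body or the TSS is not decidable from the
stated rule; the gene body ± 1 Mb is used, consistent with the window
convention above. Variant membership is tested on position only; indel
allele length is ignored (the method operates on SNPs).
`overlapCounts` reports exact set-intersection cardinalities of the
per-label variant sets (the numbers an UpSet plot displays).

## Summary statistics: QC and meta-analysis

Genotype-level QC (`genotypeQcFilter`) excludes variants with minor
allele count < 5, Hardy–Weinberg p < 1e-6, or missingness > 10 %; the
exclusions are strict inequalities, so boundary values are kept. The HWE
test (`hweTest`) is the 1-df chi-square goodness-of-fit test against
expectations from the estimated allele frequency (monomorphic input
gives p = 1); the chi-square was chosen over an exact test for
determinism and speed. Imputation filtering drops rare variants (MAF <
0.01) with R² < 0.8 and common variants with R² < 0.4; a MAF of exactly
0.01 is unassigned by the two rules and is placed under the lenient
common-variant branch. Missing R² is treated as 1 with a warning, the
correct behavior for directly genotyped variants.

Per-cohort association (`cohortAssociation`) is plain logistic
regression of case status on dosage plus covariates — a deliberate
stand-in for mixed-model GWAS machinery, which is an external tool, not
part of this package's contribution. Cohorts with fewer than five cases
or controls are refused; separated or non-converged fits are excluded
with a warning, never reported as unreliable estimates.
`inverseVarianceMeta` combines cohorts with weights $w_i = 1/\mathrm{SE}_i^2$:

$$\hat\beta = \frac{\sum_i w_i \beta_i}{\sum_i w_i}, \qquad
\mathrm{SE} = \Big(\sum_i w_i\Big)^{-1/2},$$

the standard-error (not sample-size) weighting scheme. Effect alleles
are harmonized to the first cohort reporting each variant — a swapped
pair flips the sign of β and complements the frequency; irreconcilable
pairs are dropped with a warning. Cochran's Q is reported
informationally; no genomic control or heterogeneity correction is
applied.

## Scoring

Per-SNP weights arrive as the six-column shrinkage-tool layout (CHR, ID,
POS, A1, A2, WEIGHT); raw GWAS betas in the same layout pass through
unchanged. The Bayesian shrinkage estimation itself is consumed, not
re-implemented: the package's contribution surface is selection and
scoring. `harmonizeWeights` aligns each weight's effect allele with the
panel's counted allele (counting $2 - d$ when they differ — equivalent,
after standardization, to negating the weight). No p-value thresholding
is applied by default. The raw score of sample $s$ is

$$\mathrm{PRS}_s = \sum_{j \in \text{mask}} d_{sj} \, w_j,$$

with missing dosages mean-imputed as twice the within-sample allele
frequency. The genome-wide score uses every harmonized weight; by
default it retains the APOE region (the exclusion rule speaks of the
cell-type masks), and excluding it is a one-line `subtractRegion` away.
Scores are standardized within label to mean 0, sample SD 1 (n − 1
denominator); a constant score vector is an error.
`scoreCorrelationMatrix` summarizes the pairwise Pearson correlations of
the standardized scores, excluding the genome label from the cell-type
average.

## Association battery

`fitOutcomeModel` regresses each outcome (logistic for the dichotomized
neuropathological diagnosis, coded intermediate/high = 1; linear for
MMSE and the quantitative pathology burdens) on a standardized score or
SNP dosage with covariates: age at death, sex, the first three ancestry
PCs, and APOE ε2/ε4 allele dosages; years of education is added
automatically for MMSE models. Missing data are handled by casewise
deletion with the complete-case n reported; an exactly collinear design
is an error naming the offending columns.

The battery's multiple-testing adjustment (`adjustFdrMultiply`) is a
Bonferroni-style multiplication, $\min(1, p \cdot m)$, with $m = 6$
primary types or $m = 8$ neuron subtypes — so an adjusted 0.05
corresponds to p = 0.00833 and p = 0.00625 respectively. This is not
the Benjamini–Hochberg FDR; the conventional procedure is available
separately as `adjustFdrBH` and deliberately named differently.

Follow-up tools: `perSnpAssociation` scans every SNP of a mask against
one outcome and reports the study-wide line $0.05/|\text{set}|$ derived
from its own set size (the arithmetic is printed, never assumed);
`conditionalAssociation` adds one conditioning covariate (conditioning
on the outcome itself is refused); `locusWindowScan` tests every panel
variant within ± 300 kb of an index SNP, inclusive at both ends, whether
or not it belongs to any mask; `singleCellEqtl` regresses donor-level
pseudobulk expression (mean counts-per-10k, no log — consistent with
the specificity normalization) on dosage with the same covariates. PMI
is accepted as an optional covariate column but is not a default.

## The synthetic-data generator

Every input has a generator with planted ground truth, so the whole
pipeline is testable without access to restricted cohort data.

* **Toy genome**: two 10 Mb chromosomes — small enough for brute-force
  interval oracles.
* **Reference** (`simulateReference`): background counts are
  negative-binomial with mean 0.2 and dispersion 0.5 (variance
  $\mu + 0.5\mu^2$), giving the sparsity typical of single-nucleus
  data (~80 % zeros per gene); planted markers have their mean
  multiplied by `fold` (default 4) in their own type only. Genes are
  10 kb bodies spaced 100 kb apart (so ± 30 kb windows of adjacent genes
  stay disjoint by default and overlap can be induced by narrowing the
  spacing); peaks are 500 bp spaced 2 kb. Cells carry control-satisfying
  metadata by construction.
* **Genotypes** (`simulateGenotypes`): MAF ~ Uniform(0.05, 0.5),
  dosages Binomial(2, MAF), independent across variants. No LD by
  default: the selection logic is position-based, so independent
  variants exercise it fully; LD-aware selection is a stated
  non-goal of the method itself.
* **Phenotypes** (`simulatePhenotypes`): the genetic value $G$ is the
  dosage-weighted sum of planted causal effects; continuous outcomes add
  Gaussian noise scaled so $\mathrm{var}(G)/\mathrm{var}(y) = h^2$
  (default target 0.3); the binary diagnosis thresholds a liability at
  prevalence 0.4. Covariates are generated independently of genotype.
* **Cohort GWAS** (`simulateCohortSumstats`): a shared panel, per-cohort
  independent genotypes and a logistic outcome whose log-odds are the
  planted effects, fed through `cohortAssociation` and
  `inverseVarianceMeta`.
* **Whole study** (`simulateStudy`): plants the causal variants inside
  one cell type's derivable mask (via `plantCausalArchitecture`, which
  guarantees the truth-manifest invariant that causal variants lie in
  the causal type's ranges), builds a pass-through weight table (true
  effects plus Normal(0, 0.01) background weights genome-wide), scores
  all types plus the genome, and runs the battery.

What the generator does **not** emulate: linkage disequilibrium,
population structure, batch and donor effects, realistic cell-type
proportions, and ambient contamination. Passing tests therefore
demonstrate the correctness of the selection/scoring/association
machinery under the stated sampling models — not the real-data effect
sizes, which depend on cohort data the package does not ship.

## Numerical choices and degenerate inputs

* Boundary semantics: a BED interval $[s, e)$ contains 1-based position
  $p$ iff $s < p \le e$; window bounds are inclusive; QC exclusions are
  strict, so boundary variants are kept; the expression filter's 10 %
  is inclusive.
* Ties in ranking are broken by mean activity then feature id — fully
  deterministic and independent of iteration order or platform.
* All-zero cells are an error naming the offending cell ids (for RNA
  normalization and TF-IDF both); all-zero features are flagged, scored
  0 and excluded from meaningful selection.
* Degenerate score distributions (SD = 0) and constant dosages are
  errors, not NaNs; logistic non-convergence and separation are flagged
  exclusions.
* Generators are seed-deterministic; every derived seed stays below
  $2^{31}$.

## Problem sizes

The shipped tests and the acceptance script run the specificity recovery
at 200 features × 350 cells over 50 seeds, the study-level battery at
n = 2,000 samples × 400 variants over 50 replicates, the interval oracle
at 1,000 variants × 50 intervals over 100 trials, and the calibration
checks at 1,000 null SNPs (uniformity) and 500 null logistic fits
(type-I error). These sizes were chosen so each statistical check has
enough replicates for its stated bound while the whole suite completes
in minutes on a laptop.

## A worked example

```{r example}
st <- simulateStudy(seed = 11, nSamples = 1000)
st$battery[, c("predictor", "outcome", "beta", "se", "p", "fdr", "n")]
```

The planted-causal type (astrocytes here) carries the association; the
genome-wide score captures it too (it contains the causal SNPs), while
the other five cell types are null.

```{r correlations}
z <- split(st$profiles$z_score, st$profiles$label)
round(scoreCorrelationMatrix(z)$averageR, 3)
```

## Known limitations

Distance-based SNP selection can omit variants in strong LD with a
cell-type-specific element but physically outside the mask; the masks
inherit any incompleteness of the reference peak/gene calls; the
multiplicative adjustment is conservative relative to BH; and the
logistic stand-in for mixed-model GWAS ignores relatedness, which is
adequate for the independent synthetic cohorts but not for family data.
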