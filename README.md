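# ctPRS — cell-type-specific polygenic risk scores

A genome-wide Alzheimer's disease polygenic risk score (ADPRS) says
*whether* a person carries elevated genetic risk, not *through which
brain cell type* that risk acts. ctPRS partitions polygenic risk by cell
type: it derives cell-type- and neuron-subtype-specific feature sets
from single-nucleus RNA and ATAC reference matrices, converts them into
SNP-selection genomic masks, scores individuals against GWAS-derived
per-SNP weights restricted to each mask, and associates the standardized
scores (and individual SNPs) with pathology and cognition
endophenotypes. It is written for statistical geneticists and
neurogenomics groups who have single-cell reference data, GWAS summary
statistics or weights, genotype dosages and phenotypes, and want the
cell-type decomposition end to end.

## The model

Specificity of gene *g* (or peak *p*) for cell type *c* is its mean
activity in that type divided by the sum over all types:

    S_gc = E_gc / Σ_c' E_gc'

with expression depth-normalized to counts-per-10,000 (no log) for RNA
and TF-IDF-transformed (`log(1 + 1e4 · TF · IDF)`) for ATAC peak counts,
computed over pathology-free control cells only. Per type, the top 10 %
most specific features are selected; neuron subtypes use a two-stage
rule (top 20 % parent-specific peaks, then top 20 % subtype-specific
among those). Three mask strategies follow: gene body ± 30 kb windows
(snRNA), peak intersection (snATAC), and subtype peaks within 300 kb of
a neuron-specific gene (multi-omic), each with the APOE region ± 1 Mb
removed. The score of sample *s* for a mask is Σ d_sj · w_j over the
mask's harmonized weights, standardized to mean 0 / SD 1, and tested
against each outcome by linear or logistic regression with age, sex,
three ancestry PCs and APOE ε2/ε4 dosages (plus education for MMSE),
with the multiplicative adjustment min(1, p·m), m = 6 types or 8
subtypes. Variant QC (MAC ≥ 5, HWE p ≥ 1e-6, missingness ≤ 10 %,
MAF-dependent imputation-R² rules) and fixed-effects inverse-variance
meta-analysis of per-cohort logistic GWAS are included, as are per-SNP
scans with a 0.05/|set| study-wide line, conditional models, ± 300 kb
locus scans and donor-pseudobulk eQTL tests.

A synthetic-data module generates every input with planted ground truth
(markers at known fold enrichment, causal variants inside a chosen cell
type's mask, outcomes at a target heritability), so the full pipeline is
testable without restricted cohort data.

## Worked example

```r
library(ctPRS)
st <- simulateStudy(seed = 11, nSamples = 1000)
st$battery[, c("predictor", "outcome", "beta", "se", "p", "fdr", "n")]
#>   predictor         outcome     beta     se        p      fdr    n
#> 1       AST neuritic_plaque  0.56559 0.0302 4.67e-67 3.27e-66 1000
#> 2       MIC neuritic_plaque -0.00354 0.0350 9.19e-01 1.00e+00 1000
#> 3       ODC neuritic_plaque  0.05503 0.0349 1.16e-01 8.09e-01 1000
#> 4       OPC neuritic_plaque  0.16748 0.0346 1.55e-06 1.08e-05 1000
#> 5       END neuritic_plaque  0.00265 0.0352 9.40e-01 1.00e+00 1000
#> 6       GLU neuritic_plaque  0.24094 0.0342 3.36e-12 2.35e-11 1000
#> 7       GAB neuritic_plaque  0.03749 0.0351 2.86e-01 1.00e+00 1000
#> 8    genome neuritic_plaque  0.56133 0.0304 8.43e-66 5.90e-65 1000
```

The study plants its causal variants inside the astrocyte (AST) mask:
the AST score and the genome-wide score (which contains the causal SNPs)
carry the association — β is the outcome change per SD of score — while
the other cell types are at or near their null. The adjusted values
(`fdr`) are p × 7 capped at 1. Labels whose masks partially overlap the
causal windows (here OPC, GLU) can pick up attenuated signal; the
ranking of the causal type first is the tested property.

Each stage is also available on files, either from R (`runPipeline`)
or the thin CLI:

```sh
Rscript inst/cli/ctprs.R run --seed 4 --out out/
```

which writes the reference (MTX + TSV), specificity tables, per-type BED
masks, dosage/weight/phenotype tables, standardized score profiles and
the association battery, and prints per-stage counts.

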