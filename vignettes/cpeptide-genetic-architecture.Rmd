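---
title: "Methods: genotypic risk scores, HLA serotypes and mixed models for C-peptide persistence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotypic risk scores, HLA serotypes and mixed models for C-peptide persistence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpepgrs)
library(dplyr)
```

## The scientific problem

Many people clinically diagnosed with type 1 diabetes retain measurable
endogenous insulin secretion, detectable as serum C-peptide, years or
decades after diagnosis. Persistence varies enormously with age at onset
and diabetes duration, and part of the residual variation is genetic.
`cpepgrs` implements a complete analysis chain for studying this:

1. **Locus-specific genotypic risk scores** built from published GWAS
   summary statistics, with LD adjustment against a reference panel.
2. **HLA serotype scoring** (DR3 / DR4-DQ8 groups from imputed DRB1/DQB1
   alleles) and an "HLA residual" score isolating HLA-region polygenic
   risk not explained by serotype.
3. **Cohort description**: detection-limit-censored C-peptide
   transforms, autoantibody positivity, a possible-type-2
   reclassification rule, and prevalence cross-tabulations.
4. **Association modelling**: an interaction regression of log
   C-peptide on clinical covariates and scores, and a linear mixed
   model giving SNP heritability and efficient-score GWAS scans.
5. A **synthetic cohort generator** with recorded ground truth, so that
   every estimator above can be validated by parameter recovery.

Individual-level data from the motivating cohort are not public, so the
synthetic generator is a first-class component: it defines the study
conditions under which the pipeline is tested.

## Score construction

### Filtering and locus designation

Summary statistics are filtered at `pvalue < 1e-5` (strict, per the
"less than" convention), minor allele frequency ≥ 0.02 and imputation
info ≥ 0.7. Filtered SNPs are clustered chromosome-wise by single
linkage: consecutive sorted SNPs join one cluster while they are less
than 1 Mb apart. Clusters containing a SNP with `pvalue < 1e-6` become
locus-specific scores; all other filtered SNPs form the residual
genome-wide score. The partition property (every filtered SNP in
exactly one locus or the residual set) is asserted against a
brute-force all-pairs single-linkage oracle in the test suite.

### LD adjustment

Within a locus, univariate coefficients `b` over-count shared signal
between correlated SNPs. The adjusted weights are

```
w = R⁺ b
```

where `R` is the sample correlation matrix of reference-panel dosages
and `R⁺` its Moore–Penrose generalized inverse, computed by
eigendecomposition with eigenvalues below `1e-6 × max(eigenvalue)`
discarded. The cutoff makes the operation deterministic and stable on
rank-deficient panels: two perfectly duplicated SNPs with equal betas
each receive half the weight. When `b = R w_true` (the univariate
pattern implied by true joint weights), the operation recovers
`w_true` exactly on full-rank panels — the package's core recovery
test, held to 1e-6 relative error.

Residual-score SNPs are mutually ≥ 1 Mb apart, so their correlation
matrix is the identity and the unadjusted betas are used directly.

Locus scores are scaled to unit standard deviation in the analysis
cohort (so effects are per SD of score); the summed genome-wide score
is standardized to zero mean and unit SD against an external reference
cohort when one is supplied, else against the cohort itself. Whether
the original platform scaled locus scores by cohort or reference SD is
not documented; cohort SD is the package default and is flagged in the
`compute_score_table()` documentation.

### Allele harmonization

Summary statistics are matched to genotypes on chromosome and
position; swapped effect/other alleles flip the sign of `b`;
strand-ambiguous A/T and C/G SNPs and allele mismatches are dropped
with a warning. This is the conservative standard when the summary
source's strand is unknown.

## HLA serotypes

DRB1 alleles 0301–0304 count as DR3, 0401–0413 as DR4, and DQB1
alleles 0302–0305 as DQ8. Because imputed allele calls are unphased,
DR4-DQ8 haplotypes cannot be read off directly; the package counts
`min(#DR4, #DQ8)` DR4-DQ8 haplotypes by default (a DR4 allele only
counts with a DQ8 allele available to pair with), with
`dr4dq8_rule = "any"` as the more permissive alternative. The six
groups (DR3/DR4-DQ8, DR3/DR3, DR4-DQ8/DR4-DQ8, DR4-DQ8/X, DR3/X, X/X)
partition all genotypes; classification is exhaustively enumerated
against an independent re-derivation in the tests. One DR3 plus DR4
without DQ8 classifies as DR3/X.

Serotype score weights are configuration input (published weight sets
are not redistributed here); a clearly labelled synthetic placeholder
preserving the qualitative risk ordering ships in
`inst/extdata/serotype_weights_synthetic.yaml`. The HLA residual score
is the OLS residual of the HLA-region polygenic score on the serotype
score; its sample correlation with the serotype score is zero to
numerical precision (≤ 1e-10 asserted).

## Cohort analysis

### Censoring and transforms

C-peptide below the assay's lower limit of detection (3 pmol/l by
default) is censored: the log10 transform is set to 0 for below-LOD
values, and age at onset enters models as its square root. Antibody
positivity thresholds are 11 WHO U/ml (GAD), 7.5 (IA2) and, for ZnT8,
65 up to age 30 at sampling and 9.1 above 30. Individuals with
C-peptide strictly above 600 pmol/l and all three antibodies negative
are labelled `possible_t2` (probable misdiagnosed type 2) and excluded
from the regression.

### Tables

Prevalence tables bin age at onset at 0/15/25/35 and duration at
0/5/10/15 years, half-open on the right (the printed labels overlap,
e.g. "0 to 15" and "15 to 25"; the left-closed convention is chosen).
C-peptide ranges are right-closed as printed: [0, 30], (30, 200],
(200, 600], (600, 7000]. Percentages are rounded half away from zero,
matching the printed tables; margins are computed by summation and
asserted equal to the sum of stratum cells on every construction.
`expand_prevalence_records()` inverts a count table into
individual-level records (each individual placed at a representative
value inside its stratum), which is how the published tables are
reproduced exactly by the tabulation code in the tests.

### The interaction regression

`fit_cpeptide_regression()` fits OLS of censored log10 C-peptide on:
glucose dichotomized at 5 mmol/l (8 mmol/l is also reported for random
glucose and is available via `glucose_cut`), √(age at onset), female
sex, duration, the type 1 and type 2 genotypic scores, BMI, and the
interaction of √onset with each of female, duration, both scores and
BMI. All covariates are mean-centred *before* interactions are formed,
so main effects are predicted effects at covariate means; estimates of
interaction terms are invariant to shifting any covariate (tested).
Rank deficiency is reported with the names of collinear terms rather
than silently dropped.

### The C-peptide surface

`loess_surface()` fits a locally weighted polynomial of degree 2 with
span 0.25 to log10 C-peptide over (onset, duration), with predictors
standardized (tricube weights on standardized Euclidean distance — the
`stats::loess` default with `normalize = TRUE`), evaluated with the
exact (`"direct"`) surface rather than interpolation so that the fit
is exact on polynomial data, then back-transformed to a
geometric-mean concentration surface.

## The linear mixed model

The GRM is the VanRaden centred/standardized cross-product,
`K = Z Zᵀ / m` with `z_ij = (g_ij − 2p_j)/√(2p_j(1−p_j))`:
unrelateds have expected relationship 0, full sibs 0.5, and the
diagonal is 1 plus inbreeding. Monomorphic SNPs are skipped with a
message; the GRM must be PSD up to −1e-8 × (largest eigenvalue).

REML works on the eigenbasis of `K`: with `d_i(h²) = h²λ_i + (1−h²)`,
the restricted likelihood is profiled analytically over the total
variance and maximized over `h² ∈ [0, 1]` by bounded one-dimensional
search (tolerance 1e-9), which cannot fail to converge; estimates at
the boundary are flagged and get no curvature-based standard error.
Aliased covariate columns are dropped first, so the fit is invariant
to adding multiples of existing columns. The implementation is checked
against an independently coded direct-matrix restricted likelihood.

Score tests reuse the null model's fitted covariance: for SNP `g` the
statistic is `(gᵀP y)² / (gᵀP g)` with
`P = V⁻¹ − V⁻¹X(XᵀV⁻¹X)⁻¹XᵀV⁻¹`, referred to χ²(1). No per-SNP
refitting occurs; all per-SNP quantities are computed by two matrix
products in the rotated basis. With an identity GRM the statistic
reduces exactly to the ordinary linear-regression score test (tested
to 1e-6), p-values are invariant to phenotype shift and scale, and
zero-variance SNPs are emitted as `NA` with a warning. P-values use
the asymptotic χ²(1) without small-sample correction, appropriate for
a quantitative trait.

## The synthetic cohort generator

The generator defines the study conditions for all recovery tests.

**Genotypes.** Each of `n_loci` loci carries `n_snps_per_locus` SNPs
1 kb apart, loci ≥ 1 Mb apart across chromosomes 1–6. All SNPs of a
locus share one MAF drawn from `maf_range` (default [0.1, 0.5], kept
above the 0.02 filter), and haplotypes follow a first-order Markov
copying process with copy probability `ld_decay` (default 0.7), so
dosage correlation decays as `ld_decay^k` with SNP distance — an AR(1)
LD structure with a closed-form target the tests can assert. An exactly
stationary AR(1) on binary haplotypes requires the common per-locus
frequency; that is why MAF is a locus-level, not SNP-level, parameter.
A configurable fraction of cohort members (default 10%) are full-sib
pairs drawing haplotypes from shared simulated parents, giving the
mixed model genuine relatedness (expected genomic relationship 0.5,
verified empirically).

**External GWAS.** An independent sample of `n_gwas` individuals
(default 4000) gets a liability from one causal SNP per locus (the
middle SNP, effect `gwas_beta = 0.35`, alternating sign; odd loci are
"type 1", even loci "type 2", locus 1 playing the HLA region) plus
standard Gaussian noise; case status is thresholded at the sample
median (a balanced case-control design, as in the large diabetes
meta-analyses) and per-SNP univariate regressions provide the summary
statistics. Null SNPs have uniform p-values and planted effects match
the analytic χ²(1, λ) power curve within Monte-Carlo error (both
tested).

**Phenotypes.** Log10 C-peptide is a linear predictor over centred
covariates — using the same term list and default coefficients as the
interaction regression, so the generator and the estimator share one
model — plus a polygenic value and Gaussian noise. The residual
(non-covariate) variance `sigma_resid²` (default SD 0.5 log10 pmol/l)
is split as `h2_cpep` (default 0.26) genetic versus the rest noise.
The polygenic value is drawn over all SNPs and then residualized on
the two risk scores before scaling: it represents genetic variance
*beyond* the modelled scores (which is what residual C-peptide
heritability means), and without this the score coefficients would be
confounded with the genetic background and unrecoverable. The realized
heritability is recorded in the returned truth object. Values below
`lod` are flagged below-detection. The default intercept (1.5, i.e.
geometric mean ≈ 32 pmol/l) gives a mostly detectable cohort;
censoring is monotone in the intercept (tested), and heavier censoring
regimes can be generated by lowering it. Antibody titres are
log-normal with geometric means declining in duration, reproducing the
qualitative rise of antibody negativity with duration; only threshold
exceedance proportions, not titre distributions, are published, so the
log-normal form is a modelling choice.

**What the generator does not emulate** — and hence what passing tests
do not establish about real data: realistic human LD maps and
haplotype phasing, population structure and ancestry gradients,
genotyping/imputation error correlated with MAF, assay measurement
error in C-peptide, informative missingness, and the empirical joint
distribution of onset, duration and recruitment. Recovery results show
the estimators are correct under their assumptions, not that those
assumptions hold in any particular cohort.

## Numerical choices

- Pseudo-inverse eigenvalue cutoff: relative 1e-6 (deterministic,
  standard, testable); zero-variance reference SNPs get weight 0 with
  a warning.
- Threshold conventions: strict `<` for p-value thresholds, `≥` for
  MAF/info, strict `>` for the 600 pmol/l rule and antibody titres;
  ZnT8's age switch uses "up to 30" inclusive. Genomic intervals are
  1-based and closed at both ends (VCF convention).
- Missing dosages in scoring are mean-imputed from the cohort allele
  frequency; missing titres leave records unclassified with a warning,
  never silently dropped.
- Percentages render by rounding half away from zero.
- REML: profile search tolerance 1e-9; curvature SE by central finite
  differences (step 1e-4); boundary estimates rounded to {0, 1} and
  flagged.
- GWAS p-values are floored at the smallest positive double so they
  stay in (0, 1].

## Problem sizes used by the test suite

Chosen to make Monte-Carlo assertions sharp at interactive scale:
LD/locus oracles use hundreds to 1000 random small instances;
generator calibration uses n = 2000 individuals (LD, MAF) and 500
replicates (p-value uniformity, power); heritability recovery uses 50
replicates at n = 2000 individuals × 2000 SNPs against a generating
h² = 0.5; regression recovery averages three cohorts of n = 5000; the
null scan checks 2000 SNPs at n = 500. The published tables are
reproduced exactly from their expanded counts (n = 5928 and n = 5901
records).

## Known limitations

- The score pipeline assumes summary statistics and genotypes share a
  genome build; no liftover is provided.
- No proxy-SNP lookup: weight SNPs absent from the cohort genotypes
  are an error, not a substitution.
- The mixed model is Gaussian-only (no logistic mixed model, no
  saddlepoint correction) and the REML profile covers a single genetic
  variance component.
- The censored-to-zero log transform is the published convention, not
  a likelihood-based censoring model (e.g. Tobit); coefficients are
  interpretable under light censoring and attenuate as censoring
  grows.
- Serotype classification works at genotype level because imputed
  calls are unphased; with phased haplotypes the DR4-DQ8 count could
  be exact.

## A miniature end-to-end run

```{r pipeline, eval = FALSE}
cfg <- synthetic_config(n_cohort = 500, seed = 1)
study <- simulate_cohort(cfg)

filt <- filter_snps(study$sumstats, study$cohort$snp_meta)
parts <- designate_loci(filt)
scores <- compute_score_table(parts$loci, parts$residual,
                              study$ref$dosage, study$cohort$dosage)

ph <- classify_possible_t2(study$phenotypes)
fit <- fit_cpeptide_regression(ph)
tidy(fit)

K <- compute_grm(study$cohort$dosage)
null_model <- reml_fit(transform_cpeptide(ph$cpeptide), NULL, K)
glance(null_model)
scan <- score_test_scan(null_model, study$cohort$dosage,
                        study$cohort$snp_meta)
plot_manhattan(scan, highlight = parts$loci)
```
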