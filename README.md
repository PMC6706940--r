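# cpepgrs

Genetic-architecture analysis of persistent C-peptide secretion in
type 1 diabetes.

Many people with clinically diagnosed type 1 diabetes keep secreting
some endogenous insulin — measurable as serum C-peptide — long after
diagnosis, and the degree of persistence varies with age at onset,
duration, and genotype. `cpepgrs` is an R package for analysts studying
that variation. It provides, as a tested pipeline over tidy tables:

- **LD-adjusted genotypic risk scores from GWAS summary statistics.**
  Filtered SNPs (p < 1e-5, MAF ≥ 0.02, info ≥ 0.7) are partitioned by
  single-linkage clustering (1 Mb gap rule) into locus-specific scores
  (lead p < 1e-6) plus a residual genome-wide score. Within each locus
  the univariate coefficients *b* are converted to approximate joint
  weights with a reference panel: *w = R⁺ b*, where *R* is the SNP
  dosage correlation matrix and *R⁺* its Moore–Penrose generalized
  inverse (eigendecomposition, relative cutoff 1e-6). A region (e.g.
  HLA) can be excluded from a genome-wide score.
- **HLA serotype scores.** Imputed DRB1/DQB1 4-digit alleles are
  grouped (DRB1 0301–0304 → DR3, 0401–0413 → DR4, DQB1 0302–0305 →
  DQ8) into six serotype classes, scored with a configurable weight
  table, and the "HLA residual" score is formed by residualizing the
  HLA-region polygenic score on the serotype score.
- **Cohort analysis.** Detection-limit-censored log10 C-peptide
  (below 3 pmol/l ↦ 0), antibody positivity (GAD > 11, IA2 > 7.5,
  ZnT8 > 65/9.1 WHO U/ml switching at age 30), the "possible type 2"
  rule (C-peptide > 600 pmol/l and all antibodies negative),
  prevalence cross-tabulations with margins, an interaction regression
  of log C-peptide on centred covariates (√onset interactions), and a
  LOESS geometric-mean C-peptide surface over (onset, duration).
- **Linear mixed models.** VanRaden GRM, REML SNP heritability
  (*h² = σ²g / (σ²g + σ²e)*, profiled on the GRM eigenbasis over
  [0, 1]), and efficient-score association scans
  (*(gᵀPy)² / gᵀPg ~ χ²(1)*) without per-SNP refitting.
- **A synthetic cohort generator** with recorded ground truth —
  AR(1)-LD genotypes, an external case-control GWAS, full-sib pairs,
  HLA serotypes, and censored phenotypes — used by the test suite for
  parameter-recovery validation.

Fitted objects support `tidy()`, `glance()` and `autoplot()`;
`plot_manhattan()` and `plot_cpeptide_surface()` cover the standard
figures. See the methods vignette
(`vignettes/cpeptide-genetic-architecture.Rmd`) for models,
assumptions, and numerical conventions.

## Worked example

```r
library(cpepgrs)

cfg <- synthetic_config(n_cohort = 1000, seed = 1)
study <- simulate_cohort(cfg)

filt <- filter_snps(study$sumstats, study$cohort$snp_meta)
parts <- designate_loci(filt)
scores <- compute_score_table(parts$loci, parts$residual,
                              study$ref$dosage, study$cohort$dosage)

ph <- classify_possible_t2(study$phenotypes)
fit <- fit_cpeptide_regression(ph)
tidy(fit)
#> # A tibble: 13 x 5
#>    term                estimate std.error statistic   p.value
#>  1 (Intercept)          1.48     0.0164       90.4  0
#>  3 sqrt_onset           0.131    0.0126       10.3  7.09e- 24
#>  4 female              -0.0874   0.0330       -2.65 8.27e-  3
#>  5 duration            -0.0323   0.00119     -27.2  1.05e-121
#>  9 sqrt_onset:female   -0.0824   0.0255       -3.23 1.27e-  3
#> 10 sqrt_onset:duration -0.00783  0.000931    -8.41  1.42e- 16
#> # ... (glucose, BMI and score terms elided)
```

Later onset predicts more C-peptide, longer duration less, and both
effects interact: at later onset, the decline with duration and the
female deficit are steeper — recovering the coefficients the cohort
was generated with (truth: √onset 0.11, duration −0.03, female
−0.074). Heritability of the censored log C-peptide in this small
simulated cohort:

```r
K <- compute_grm(study$cohort$dosage)
glance(reml_fit(transform_cpeptide(ph$cpeptide), NULL, K))
#> # A tibble: 1 x 6
#>      h2  se_h2 logLik converged boundary  nobs
#> 1 0.160 0.0394   359. TRUE      FALSE     1000
```

(Unadjusted for covariates and with only 160 SNPs in the GRM, the
estimate is noisy; the acceptance script runs the properly adjusted
version at 2000 individuals × 2000 SNPs.)

The published prevalence tables are reproduced exactly by expanding
their printed counts into records and re-tabulating:

```r
counts <- prevalence_counts("cpeptide")
prevalence_by_onset_duration(expand_prevalence_records(counts, "cpeptide"))
#> Prevalence table (duration x age_onset)
#>    duration      0 to 15     15 to 25     25 to 35   35 or more
#>      0 to 5    76% 13/17  96% 178/186  94% 161/172  92% 262/285
#>     5 to 10   62% 79/128  67% 110/165  78% 107/138  74% 188/253
#>    10 to 15   25% 60/237   55% 89/163  52% 103/197  57% 129/225
#>  15 or more 19% 317/1643  26% 259/996  36% 253/705  42% 174/418
#>         All 23% 469/2025 42% 636/1510 51% 624/1212 64% 753/1181
```

Detectable C-peptide ranges from 19% (onset before 15, duration ≥ 15
years) to 92% (onset after 35, duration < 5 years).

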