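#' Configuration for the synthetic cohort generator
#'
#' Bundles every tunable of the synthetic study: sizes of the reference
#' panel, the external GWAS used to produce summary statistics, and the
#' study cohort; the genotype model (loci, SNPs per locus, allele
#' frequencies, within-locus linkage disequilibrium); the C-peptide
#' phenotype model (true regression coefficients, SNP heritability,
#' residual scale, detection limit); and the random seed.
#'
#' Genotypes are generated as haplotype pairs. Within a locus every SNP
#' shares one minor allele frequency and adjacent SNPs on a haplotype are
#' coupled by a first-order Markov copying process, so the dosage
#' correlation between SNPs `j` and `j + k` of the same locus is
#' `ld_decay^k`; SNPs in different loci are independent and loci are
#' placed more than 1 Mb apart. A configurable fraction of cohort members
#' are full-sib pairs (expected genomic relationship 0.5), so that
#' mixed-model machinery sees genuine relatedness.
#'
#' The phenotype model mirrors the interaction regression of
#' log10 C-peptide on centred clinical covariates and genotypic risk
#' scores: `beta_table` holds the true coefficient for each model term,
#' and the residual (non-covariate) variance `sigma_resid^2` is split
#' into a polygenic part `h2_cpep * sigma_resid^2` and Gaussian noise.
#' Simulated C-peptide below `lod` pmol/l is flagged below-detection.
#'
#' @param n_ref Reference-panel size (individuals).
#' @param n_gwas External GWAS sample size.
#' @param n_cohort Study cohort size.
#' @param n_snps_per_locus SNPs per diabetes-associated locus.
#' @param n_loci Number of loci. Odd loci are assigned to the type 1
#'   trait, even loci to the type 2 trait; locus 1 plays the HLA region.
#' @param maf_range Length-2 numeric, the range minor allele frequencies
#'   are drawn from (one per locus). Must lie within `[0.02, 0.5]` so
#'   every generated SNP survives the default MAF filter.
#' @param ld_decay Adjacent-SNP haplotype correlation within a locus, in
#'   `[0, 1)`.
#' @param h2_cpep Target SNP heritability of the residual (covariate
#'   adjusted) C-peptide variance, in `[0, 1]`.
#' @param beta_table Named numeric vector of true coefficients for the
#'   C-peptide model terms (see [default_beta_table()]).
#' @param sigma_resid Residual standard deviation of log10 C-peptide
#'   after the covariates (log10 pmol/l).
#' @param lod Assay lower limit of detection, pmol/l.
#' @param gwas_beta Liability-scale effect of each locus's causal SNP in
#'   the external GWAS.
#' @param sib_frac Fraction of cohort members belonging to a full-sib
#'   pair, in `[0, 1]`.
#' @param seed Integer random seed.
#'
#' @return An object of class `cpep_config` (a named list).
#' @seealso [simulate_cohort()], [simulate_genotypes()],
#'   [simulate_phenotypes()]
#' @export
#' @examples
#' cfg <- synthetic_config(n_cohort = 200, n_loci = 4, seed = 7)
#' cfg$ld_decay
synthetic_config <- function(n_ref = 400L,
                             n_gwas = 4000L,
                             n_cohort = 1000L,
                             n_snps_per_locus = 10L,
                             n_loci = 8L,
                             maf_range = c(0.1, 0.5),
                             ld_decay = 0.7,
                             h2_cpep = 0.26,
                             beta_table = default_beta_table(),
                             sigma_resid = 0.5,
                             lod = 3,
                             gwas_beta = 0.35,
                             sib_frac = 0.1,
                             seed = 1L) {
  n_ref <- check_count(n_ref, "n_ref")
  n_gwas <- check_count(n_gwas, "n_gwas")
  n_cohort <- check_count(n_cohort, "n_cohort")
  n_snps_per_locus <- check_count(n_snps_per_locus, "n_snps_per_locus")
  n_loci <- check_count(n_loci, "n_loci")
  if (length(maf_range) != 2L || any(!is.finite(maf_range))) {
    stop_cpep("`maf_range` must be two finite allele frequencies.")
  }
  if (maf_range[1] > maf_range[2] ||
      maf_range[1] < 0.02 || maf_range[2] > 0.5) {
    stop_cpep("`maf_range` must be increasing and lie within [0.02, 0.5].")
  }
  check_number(ld_decay, "ld_decay", lower = 0, upper = 1,
               strict_upper = TRUE)
  check_number(h2_cpep, "h2_cpep", lower = 0, upper = 1)
  check_number(sigma_resid, "sigma_resid", lower = 0)
  check_number(lod, "lod", lower = 0)
  check_number(gwas_beta, "gwas_beta")
  check_number(sib_frac, "sib_frac", lower = 0, upper = 1)
  seed <- check_count(seed, "seed", min = 0L)
  if (!is.numeric(beta_table) || is.null(names(beta_table)) ||
      any(!is.finite(beta_table))) {
    stop_cpep("`beta_table` must be a named, finite numeric vector.")
  }
  missing <- setdiff(names(default_beta_table()), names(beta_table))
  if (length(missing)) {
    stop_cpep("`beta_table` is missing terms: ", fmt_ids(missing))
  }
  structure(
    list(
      n_ref = n_ref, n_gwas = n_gwas, n_cohort = n_cohort,
      n_snps_per_locus = n_snps_per_locus, n_loci = n_loci,
      maf_range = as.numeric(maf_range), ld_decay = ld_decay,
      h2_cpep = h2_cpep, beta_table = beta_table,
      sigma_resid = sigma_resid, lod = lod, gwas_beta = gwas_beta,
      sib_frac = sib_frac, seed = seed
    ),
    class = "cpep_config"
  )
}

#' Default true coefficients of the synthetic C-peptide model
#'
#' Named vector of coefficients for the regression of log10 C-peptide on
#' centred clinical covariates, genotypic risk scores, and their
#' interactions with the square root of age at onset. The defaults follow
#' the effect sizes reported for this model in a large Scottish type 1
#' diabetes cohort (log10 pmol/l per unit of the centred covariate);
#' the intercept is the cohort geometric-mean log10 C-peptide.
#'
#' @return Named numeric vector with one entry per model term plus
#'   `"(Intercept)"`.
#' @export
#' @examples
#' default_beta_table()
default_beta_table <- function() {
  c(
    "(Intercept)"          = 1.5,
    glucose_high           = 0.0066,
    sqrt_onset             = 0.11,
    female                 = -0.074,
    duration               = -0.03,
    t1_score               = -0.04,
    t2_score               = 0.024,
    bmi                    = 0.0031,
    "sqrt_onset:female"    = -0.079,
    "sqrt_onset:duration"  = -0.0089,
    "sqrt_onset:t1_score"  = -0.0087,
    "sqrt_onset:t2_score"  = 0.0042,
    "sqrt_onset:bmi"       = 0.0044
  )
}

#' @export
print.cpep_config <- function(x, ...) {
  cat("<cpep_config>\n")
  cat("  samples: ref", x$n_ref, "| gwas", x$n_gwas,
      "| cohort", x$n_cohort, "\n")
  cat("  genome:", x$n_loci, "loci x", x$n_snps_per_locus,
      "SNPs, MAF in [", x$maf_range[1], ",", x$maf_range[2],
      "], ld_decay", x$ld_decay, "\n")
  cat("  phenotype: h2", x$h2_cpep, "| sigma_resid", x$sigma_resid,
      "| LOD", x$lod, "pmol/l\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
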