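#' Simulate an external GWAS and its summary statistics
#'
#' Draws an independent sample of `n_gwas` individuals (stream separate
#' from the reference panel and cohort), builds a liability from the
#' causal SNP effects in `truth` plus standard Gaussian noise, and runs a
#' univariate regression of the outcome on each SNP dosage. For
#' `trait = "binary"` the outcome is case status from a liability
#' threshold at the sample median (a balanced case-control design, as in
#' the large diabetes meta-analyses); `trait = "quantitative"` regresses
#' the liability itself.
#'
#' @param config A [synthetic_config()] object.
#' @param truth A [synthetic_truth()] object (defaults to the truth
#'   implied by `config`).
#' @param trait `"binary"` (case status) or `"quantitative"` (liability).
#'
#' @return A tibble of per-SNP summary statistics: `snp_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`.
#'   Monomorphic SNPs are excluded with a warning.
#' @export
#' @examples
#' cfg <- synthetic_config(n_gwas = 500, n_loci = 2,
#'                         n_snps_per_locus = 4, seed = 2)
#' ss <- simulate_gwas_sumstats(cfg)
#' head(ss)
simulate_gwas_sumstats <- function(config, truth = synthetic_truth(config),
                                   trait = c("binary", "quantitative")) {
  stopifnot(inherits(config, "cpep_config"), inherits(truth, "cpep_truth"))
  trait <- match.arg(trait)

  g <- simulate_genotypes(config, config$n_gwas, stream = 2L)
  eff <- setNames(rep(0, ncol(g$dosage)), colnames(g$dosage))
  eff[truth$causal_effects$snp_id] <- truth$causal_effects$effect
  set.seed(derive_seed(config$seed, 3L))
  liability <- drop(g$dosage %*% eff) + rnorm(config$n_gwas)
  y <- if (trait == "binary") {
    as.numeric(liability > stats::median(liability))
  } else {
    liability
  }
  univariate_sumstats(g$dosage, y, g$snp_meta)
}

# Mass univariate regression of y on every column of the dosage matrix.
univariate_sumstats <- function(dosage, y, snp_meta) {
  n <- nrow(dosage)
  if (n < 3L) stop_cpep("Need at least 3 individuals for summary statistics.")
  gc <- scale(dosage, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(gc^2)
  mono <- sxx <= 0
  if (any(mono)) {
    warn(paste0("Excluding ", sum(mono), " monomorphic SNP(s): ",
                fmt_ids(colnames(dosage)[mono])))
  }
  sxy <- drop(crossprod(gc, yc))
  syy <- sum(yc^2)
  beta <- sxy / sxx
  rss <- pmax(syy - beta * sxy, 0)
  se <- sqrt(rss / ((n - 2) * sxx))
  tstat <- beta / se
  # keep p-values in (0, 1] even when t is extreme
  pvalue <- pmax(2 * pt(-abs(tstat), df = n - 2), .Machine$double.xmin)
  out <- snp_meta |>
    dplyr::select("snp_id", "chrom", "pos", "effect_allele",
                  "other_allele") |>
    dplyr::mutate(beta = beta[.data$snp_id], se = se[.data$snp_id],
                  pvalue = pvalue[.data$snp_id]) |>
    dplyr::filter(!.data$snp_id %in% colnames(dosage)[mono])
  out
}
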