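test_that("genotype generator hits its nominal LD and MAF targets", {
  cfg0 <- synthetic_config(n_loci = 2, n_snps_per_locus = 5,
                           ld_decay = 0, seed = 101)
  g0 <- simulate_genotypes(cfg0, n = 2000)
  r0 <- cor(g0$dosage)
  expect_lt(max(abs(r0[upper.tri(r0)])), 0.1)

  cfg8 <- synthetic_config(n_loci = 2, n_snps_per_locus = 5,
                           ld_decay = 0.8, seed = 102)
  g8 <- simulate_genotypes(cfg8, n = 2000)
  for (l in 1:2) {
    cols <- which(g8$snp_meta$locus == l)
    adjacent <- diag(cor(g8$dosage[, cols])[-1, -length(cols)])
    expect_true(all(abs(adjacent - 0.8) < 0.1))
  }
  # cross-locus independence even at high ld_decay
  r_cross <- cor(g8$dosage[, g8$snp_meta$locus == 1],
                 g8$dosage[, g8$snp_meta$locus == 2])
  expect_lt(max(abs(r_cross)), 0.1)

  expect_true(all(abs(g8$snp_meta$maf_emp - g8$snp_meta$maf) < 0.05))
  expect_true(all(g8$dosage >= 0 & g8$dosage <= 2))
})

test_that("distinct loci are separated by more than 1 Mb", {
  cfg <- synthetic_config(n_loci = 13, n_snps_per_locus = 8, seed = 5)
  meta <- simulate_genotypes(cfg, n = 10)$snp_meta
  spans <- dplyr::summarise(dplyr::group_by(meta, locus, chrom),
                            start = min(pos), end = max(pos),
                            .groups = "drop")
  by_chrom <- split(spans, spans$chrom)
  for (sp in by_chrom) {
    if (nrow(sp) < 2) next
    sp <- sp[order(sp$start), ]
    expect_true(all(sp$start[-1] - sp$end[-nrow(sp)] > 1e6))
  }
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- synthetic_config(n_cohort = 60, n_gwas = 200, n_ref = 50,
                          n_loci = 2, n_snps_per_locus = 4, seed = 77)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort$dosage, s2$cohort$dosage)
  expect_identical(s1$sumstats, s2$sumstats)
  expect_equal(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$serotypes, s2$serotypes)
})

test_that("config validation rejects out-of-range values", {
  expect_error(synthetic_config(ld_decay = 1), "ld_decay")
  expect_error(synthetic_config(h2_cpep = 1.2), "h2_cpep")
  expect_error(synthetic_config(maf_range = c(0.01, 0.3)), "maf_range")
  expect_error(synthetic_config(n_cohort = 0), "n_cohort")
  expect_error(synthetic_config(beta_table = c(female = 1)), "beta_table")
})

test_that("null SNPs give uniform GWAS p-values across replicates", {
  base <- synthetic_config(n_gwas = 400, n_loci = 1, n_snps_per_locus = 2,
                           gwas_beta = 0, ld_decay = 0, seed = 1)
  pvals <- vapply(seq_len(500), function(i) {
    cfg <- synthetic_config(n_gwas = 400, n_loci = 1,
                            n_snps_per_locus = 2, gwas_beta = 0,
                            ld_decay = 0, seed = 1000 + i)
    simulate_gwas_sumstats(cfg)$pvalue[1]
  }, numeric(1))
  # binary outcomes at finite n can tie a few p-values exactly
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("GWAS power matches the analytic chi-square noncentrality", {
  # effect sized for noncentrality lambda = 5 at n_gwas = 400, MAF 0.3
  n_gwas <- 400
  maf <- 0.3
  lambda <- 5
  beta <- sqrt(lambda / (n_gwas * 2 * maf * (1 - maf)))
  hits <- vapply(seq_len(500), function(i) {
    cfg <- synthetic_config(n_gwas = n_gwas, n_loci = 1,
                            n_snps_per_locus = 1, gwas_beta = beta,
                            maf_range = c(maf, maf), seed = 3000 + i)
    ss <- simulate_gwas_sumstats(cfg, trait = "quantitative")
    ss$pvalue[1] < 0.05
  }, logical(1))
  analytic <- 1 - stats::pchisq(stats::qchisq(0.95, 1), 1, ncp = lambda)
  expect_lt(abs(mean(hits) - analytic), 0.05)
})

test_that("monomorphic SNPs are excluded from summary stats with a warning", {
  dosage <- cbind(a = c(0, 1, 2, 1), b = c(2, 2, 2, 2))
  meta <- tibble::tibble(snp_id = c("a", "b"), chrom = "1",
                         pos = c(1L, 2L), effect_allele = "A",
                         other_allele = "G")
  expect_warning(
    ss <- cpepgrs:::univariate_sumstats(dosage, c(0, 1, 0, 1), meta),
    "monomorphic"
  )
  expect_identical(ss$snp_id, "a")
})

test_that("phenotype model degenerates correctly and respects h2 = 0", {
  bt <- default_beta_table()
  bt[] <- 0
  bt["(Intercept)"] <- 2
  cfg <- synthetic_config(n_cohort = 50, n_loci = 2, n_snps_per_locus = 3,
                          beta_table = bt, sigma_resid = 0, h2_cpep = 0,
                          seed = 21)
  tr <- synthetic_truth(cfg)
  g <- simulate_genotypes(cfg, 50, stream = 6L)
  sero <- simulate_serotypes(cfg, 50)
  ph <- simulate_phenotypes(cfg, tr, g, sero)
  expect_equal(ph$cpeptide, rep(100, 50))
  expect_false(any(ph$below_detection))

  # h2 = 0: phenotype variance is covariate variance plus noise variance
  cfg0 <- synthetic_config(n_cohort = 5000, h2_cpep = 0,
                           sigma_resid = 0.4, seed = 22)
  cfg_det <- synthetic_config(n_cohort = 5000, h2_cpep = 0,
                              sigma_resid = 0, seed = 22)
  tr0 <- synthetic_truth(cfg0)
  g0 <- simulate_genotypes(cfg0, 5000, stream = 6L)
  s0 <- simulate_serotypes(cfg0, 5000)
  y <- log10(simulate_phenotypes(cfg0, tr0, g0, s0)$cpeptide)
  lp <- log10(simulate_phenotypes(cfg_det, synthetic_truth(cfg_det),
                                  g0, s0)$cpeptide)
  expect_equal(attr(simulate_phenotypes(cfg0, tr0, g0, s0), "h2_true"), 0)
  expect_lt(abs(var(y) / (var(lp) + 0.4^2) - 1), 0.05)
})

test_that("censoring fraction is monotone non-increasing in the intercept", {
  frac <- vapply(c(0.8, 1.2, 1.6, 2.0), function(b0) {
    bt <- default_beta_table()
    bt["(Intercept)"] <- b0
    cfg <- synthetic_config(n_cohort = 500, beta_table = bt, seed = 33)
    mean(simulate_cohort(cfg)$phenotypes$below_detection)
  }, numeric(1))
  expect_true(all(diff(frac) <= 0))
})

test_that("external GWAS effects are independent of cohort frequencies", {
  cfg <- synthetic_config(n_loci = 12, n_snps_per_locus = 10,
                          gwas_beta = 0, n_gwas = 1000, n_cohort = 500,
                          seed = 44)
  study <- simulate_cohort(cfg)
  dev <- study$cohort$snp_meta$maf_emp - study$cohort$snp_meta$maf
  expect_lt(abs(cor(study$sumstats$beta,
                    dev[match(study$sumstats$snp_id,
                              study$cohort$snp_meta$snp_id)])), 0.25)
})
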