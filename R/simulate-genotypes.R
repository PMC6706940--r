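#' Simulate genotype dosages with block-autoregressive LD
#'
#' Generates haplotype-based genotype dosages for `n` individuals at
#' `n_loci * n_snps_per_locus` SNPs. Every SNP within a locus shares the
#' locus minor allele frequency, and adjacent SNPs on a haplotype are
#' coupled by a Markov copying process with probability `ld_decay`, so
#' the population correlation between dosages at SNPs `j` and `j + k` of
#' one locus is `ld_decay^k` (first-order autoregressive). Loci sit on
#' alternating chromosomes, separated by well over 1 Mb, and are mutually
#' independent.
#'
#' Optionally the last `2 * sib_pairs` individuals are full-sib pairs:
#' each pair draws its haplotypes from the same two simulated parents,
#' locus by locus, giving an expected genomic relationship of 0.5.
#'
#' @param config A [synthetic_config()] object.
#' @param n Number of individuals to simulate.
#' @param sib_pairs Number of full-sib pairs among the `n` individuals
#'   (requires `2 * sib_pairs <= n`).
#' @param stream Integer stream label; samples drawn with different
#'   streams (e.g. reference panel vs cohort) are independent.
#'
#' @return A list with components
#'   \describe{
#'     \item{dosage}{`n x m` integer matrix of minor-allele dosages in
#'       `[0, 2]`, with individual ids as rownames and SNP ids as
#'       colnames.}
#'     \item{snp_meta}{Tibble of per-SNP metadata: `snp_id`, `chrom`,
#'       `pos` (1-based), `effect_allele` (the minor allele),
#'       `other_allele`, `maf` (nominal), `maf_emp` (realized), `info`
#'       (simulated imputation quality), `locus` (locus index).}
#'   }
#' @export
#' @examples
#' cfg <- synthetic_config(n_loci = 2, n_snps_per_locus = 4, seed = 1)
#' g <- simulate_genotypes(cfg, n = 50)
#' dim(g$dosage)
simulate_genotypes <- function(config, n, sib_pairs = 0L, stream = 1L) {
  stopifnot(inherits(config, "cpep_config"))
  n <- check_count(n, "n")
  sib_pairs <- check_count(sib_pairs, "sib_pairs", min = 0L)
  if (2L * sib_pairs > n) {
    stop_cpep("`sib_pairs` = ", sib_pairs, " needs more individuals than n = ", n, ".")
  }
  set.seed(derive_seed(config$seed, stream))

  meta <- locus_map(config)
  m_per <- config$n_snps_per_locus
  a <- config$ld_decay
  n_unrel <- n - 2L * sib_pairs

  dosage <- matrix(0L, nrow = n, ncol = nrow(meta))
  for (l in seq_len(config$n_loci)) {
    cols <- which(meta$locus == l)
    p <- meta$maf[cols[1]]
    if (n_unrel > 0L) {
      h1 <- sim_haplotypes(n_unrel, m_per, p, a)
      h2 <- sim_haplotypes(n_unrel, m_per, p, a)
      dosage[seq_len(n_unrel), cols] <- h1 + h2
    }
    if (sib_pairs > 0L) {
      # 4 parental haplotypes per pair; each child inherits one haplotype
      # from each parent, independently per locus (no recombination
      # within the locus).
      pat <- sim_haplotypes(2L * sib_pairs, m_per, p, a) # paternal hap 1/2
      pat2 <- sim_haplotypes(2L * sib_pairs, m_per, p, a)
      mat <- sim_haplotypes(2L * sib_pairs, m_per, p, a)
      mat2 <- sim_haplotypes(2L * sib_pairs, m_per, p, a)
      for (k in seq_len(sib_pairs)) {
        for (child in 1:2) {
          row <- n_unrel + 2L * (k - 1L) + child
          hp <- if (runif(1) < 0.5) pat[k, , drop = TRUE] else pat2[k, , drop = TRUE]
          hm <- if (runif(1) < 0.5) mat[k, , drop = TRUE] else mat2[k, , drop = TRUE]
          dosage[row, cols] <- hp + hm
        }
      }
    }
  }
  rownames(dosage) <- sprintf("id_%04d", seq_len(n))
  colnames(dosage) <- meta$snp_id
  meta$maf_emp <- colMeans(dosage) / 2
  list(dosage = dosage, snp_meta = meta)
}

# One haplotype per row: first-order Markov chain along SNPs. With a
# common allele frequency p the chain is stationary and
# cor(SNP_j, SNP_{j+k}) = a^k on the haplotype (and dosage) scale.
sim_haplotypes <- function(n_hap, m, p, a) {
  h <- matrix(0L, nrow = n_hap, ncol = m)
  h[, 1] <- rbinom(n_hap, 1L, p)
  if (m > 1L) {
    for (j in 2:m) {
      copy <- runif(n_hap) < a
      h[, j] <- ifelse(copy, h[, j - 1L], rbinom(n_hap, 1L, p))
    }
  }
  h
}

# Static SNP map implied by a config: positions, alleles, nominal MAFs.
# Loci cycle over chromosomes 1..6 with 5 Mb between locus starts on the
# same chromosome; SNPs within a locus are 1 kb apart.
locus_map <- function(config) {
  # Drawn under a fixed sub-seed so the map is a pure function of the
  # config, whatever stream the caller uses.
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(derive_seed(config$seed, 0L))

  pairs <- matrix(c("A", "G", "G", "A", "C", "T", "T", "C"),
                  ncol = 2, byrow = TRUE)
  out <- vector("list", config$n_loci)
  for (l in seq_len(config$n_loci)) {
    chrom <- as.character((l - 1L) %% 6L + 1L)
    start <- 1e6 + ((l - 1L) %/% 6L) * 5e6
    pos <- as.integer(start + (seq_len(config$n_snps_per_locus) - 1L) * 1000L)
    p <- runif(1, config$maf_range[1], config$maf_range[2])
    al <- pairs[sample.int(nrow(pairs), config$n_snps_per_locus,
                           replace = TRUE), , drop = FALSE]
    out[[l]] <- tibble(
      snp_id = sprintf("snp_%s_%d", chrom, pos),
      chrom = chrom,
      pos = pos,
      effect_allele = al[, 1],
      other_allele = al[, 2],
      maf = p,
      info = round(runif(config$n_snps_per_locus, 0.85, 1), 3),
      locus = l
    )
  }
  dplyr::bind_rows(out)
}

#' Ground truth of a synthetic study
#'
#' Fixes the causal structure implied by a configuration: one causal SNP
#' per locus (the middle SNP), with liability-scale effect
#' `gwas_beta` and alternating sign, odd loci assigned to the type 1
#' trait and even loci to the type 2 trait. Locus 1 stands in for the
#' HLA region (shared by both traits and excludable from the type 2
#' genome-wide score).
#'
#' @param config A [synthetic_config()] object.
#' @return A list of class `cpep_truth`: `causal_effects` (tibble of
#'   `snp_id`, `locus`, `trait`, `effect`), `locus_membership` (tibble of
#'   `snp_id`, `locus`, `trait`), `hla_locus` (integer), and
#'   `regression_truth` (the configured `beta_table`). `h2_true` is
#'   filled in by [simulate_phenotypes()].
#' @export
synthetic_truth <- function(config) {
  stopifnot(inherits(config, "cpep_config"))
  meta <- locus_map(config)
  trait <- ifelse(meta$locus %% 2L == 1L, "t1", "t2")
  membership <- tibble(snp_id = meta$snp_id, locus = meta$locus,
                       trait = trait)
  mid <- ceiling(config$n_snps_per_locus / 2)
  causal <- meta |>
    dplyr::group_by(.data$locus) |>
    dplyr::slice(mid) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      .data$snp_id, .data$locus,
      trait = ifelse(.data$locus %% 2L == 1L, "t1", "t2"),
      effect = config$gwas_beta * ifelse(.data$locus %% 2L == 0L, -1, 1)
    )
  structure(
    list(causal_effects = causal, locus_membership = membership,
         hla_locus = 1L, regression_truth = config$beta_table,
         h2_true = NA_real_),
    class = "cpep_truth"
  )
}
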