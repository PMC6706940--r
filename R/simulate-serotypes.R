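#' Simulate imputed HLA DRB1/DQB1 allele calls
#'
#' Draws two DRB1-DQB1 haplotypes per individual from a small table of
#' common European haplotypes with frequencies skewed towards the type 1
#' diabetes risk haplotypes DR3 (DRB1*03:01-DQB1*02:01) and DR4-DQ8
#' (DRB1*04:01/04:04-DQB1*03:02), so the six serotype groups are all
#' realized in cohorts of a few hundred. Alleles are reported unphased,
#' as 4-digit codes, mimicking imputation output.
#'
#' @param config A [synthetic_config()] object.
#' @param n Number of individuals.
#' @param stream Integer stream label (see [simulate_genotypes()]).
#' @return Tibble with columns `individual_id`, `drb1_1`, `drb1_2`,
#'   `dqb1_1`, `dqb1_2`.
#' @export
#' @examples
#' sero <- simulate_serotypes(synthetic_config(seed = 3), n = 10)
#' sero
simulate_serotypes <- function(config, n, stream = 4L) {
  stopifnot(inherits(config, "cpep_config"))
  n <- check_count(n, "n")
  set.seed(derive_seed(config$seed, stream))
  hap <- tibble(
    drb1 = c("0301", "0401", "0404", "0701", "1101", "1501", "1301", "0101"),
    dqb1 = c("0201", "0302", "0302", "0202", "0301", "0602", "0603", "0501"),
    freq = c(0.25, 0.18, 0.07, 0.12, 0.08, 0.10, 0.08, 0.12)
  )
  draw <- function() sample.int(nrow(hap), n, replace = TRUE,
                                prob = hap$freq)
  h1 <- draw()
  h2 <- draw()
  tibble(
    individual_id = sprintf("id_%04d", seq_len(n)),
    drb1_1 = hap$drb1[h1], drb1_2 = hap$drb1[h2],
    dqb1_1 = hap$dqb1[h1], dqb1_2 = hap$dqb1[h2]
  )
}
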