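#' Filter GWAS summary statistics for score construction
#'
#' Keeps SNPs that pass the association threshold (`pvalue < p_max`,
#' strict), the minor allele frequency filter (`maf >= maf_min`), and
#' the imputation quality filter (`info >= info_min`). Input order is
#' preserved.
#'
#' @param sumstats Tibble of summary statistics with at least `snp_id`
#'   and `pvalue` (see [simulate_gwas_sumstats()] for the full layout).
#' @param snp_meta Tibble with `snp_id`, `maf`, `info` for every SNP in
#'   `sumstats`; allele frequencies above 0.5 are folded to the minor
#'   allele.
#' @param p_max Association p-value threshold (default `1e-5`).
#' @param maf_min Minimum minor allele frequency (default `0.02`).
#' @param info_min Minimum imputation info score (default `0.7`).
#' @return The filtered rows of `sumstats`, a tibble.
#' @export
#' @examples
#' ss <- tibble::tibble(snp_id = c("a", "b"), pvalue = c(1e-8, 1e-3))
#' meta <- tibble::tibble(snp_id = c("a", "b"), maf = c(0.3, 0.3),
#'                        info = c(0.99, 0.99))
#' filter_snps(ss, meta)
filter_snps <- function(sumstats, snp_meta, p_max = 1e-5,
                        maf_min = 0.02, info_min = 0.7) {
  missing <- setdiff(sumstats$snp_id, snp_meta$snp_id)
  if (length(missing)) {
    stop_cpep("No metadata for SNP(s): ", fmt_ids(missing))
  }
  meta <- snp_meta |>
    dplyr::transmute(.data$snp_id,
                     .maf = pmin(.data$maf, 1 - .data$maf),
                     .info = .data$info)
  sumstats |>
    dplyr::inner_join(meta, by = "snp_id") |>
    dplyr::filter(.data$pvalue < p_max,
                  .data$.maf >= maf_min,
                  .data$.info >= info_min) |>
    dplyr::select(-".maf", -".info")
}

#' Partition filtered SNPs into loci and a residual genome-wide set
#'
#' Clusters the filtered SNPs chromosome by chromosome with
#' single-linkage: consecutive SNPs (after sorting by position) belong
#' to the same cluster when they are less than `gap_bp` apart. Clusters
#' containing at least one SNP with `pvalue < lead_p` become
#' diabetes-associated loci; SNPs of all other clusters form the
#' residual genome-wide set. Every filtered SNP lands in exactly one
#' locus or in the residual set.
#'
#' @param filtered Tibble of filtered summary statistics carrying
#'   `snp_id`, `chrom`, `pos`, `pvalue`.
#' @param gap_bp Gap (base pairs) at or above which consecutive SNPs are
#'   split into different clusters (default 1 Mb).
#' @param lead_p Lead-SNP p-value threshold for designating a cluster a
#'   locus (default `1e-6`, strict).
#' @return A list with
#'   \describe{
#'     \item{loci}{Tibble, one row per locus: `locus_id`, `chrom`,
#'       `start`, `end`, `n_snps`, `lead_p`, and a `members` list-column
#'       of the member summary-stat rows (sorted by position).}
#'     \item{residual}{Tibble of residual SNPs.}
#'   }
#' @export
#' @examples
#' ss <- tibble::tibble(snp_id = c("s1", "s2", "s3"), chrom = "1",
#'                      pos = c(1e6, 1.5e6, 3e6),
#'                      pvalue = c(1e-8, 5e-6, 1e-8))
#' designate_loci(ss)$loci
designate_loci <- function(filtered, gap_bp = 1e6, lead_p = 1e-6) {
  empty_loci <- tibble(locus_id = character(), chrom = character(),
                       start = numeric(), end = numeric(),
                       n_snps = integer(), lead_p = numeric(),
                       members = list())
  if (nrow(filtered) == 0L) {
    return(list(loci = empty_loci, residual = filtered))
  }
  dat <- filtered |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(.cluster = cumsum(c(TRUE, diff(.data$pos) >= gap_bp))) |>
    dplyr::ungroup()

  clusters <- dat |>
    dplyr::group_by(.data$chrom, .data$.cluster) |>
    dplyr::summarise(min_p = min(.data$pvalue), .groups = "drop") |>
    dplyr::mutate(is_locus = .data$min_p < lead_p)

  dat <- dat |>
    dplyr::left_join(clusters, by = c("chrom", ".cluster"))

  residual <- dat |>
    dplyr::filter(!.data$is_locus) |>
    dplyr::select(-".cluster", -"min_p", -"is_locus")

  locus_rows <- dat |> dplyr::filter(.data$is_locus)
  if (nrow(locus_rows) == 0L) {
    return(list(loci = empty_loci, residual = residual))
  }
  locus_rows <- locus_rows |>
    dplyr::mutate(.key = paste(.data$chrom, .data$.cluster, sep = "@"))
  member_rows <- locus_rows |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::select(-".cluster", -"min_p", -"is_locus")
  members <- split(dplyr::select(member_rows, -".key"), member_rows$.key)
  loci <- locus_rows |>
    dplyr::group_by(.key = .data$.key) |>
    dplyr::summarise(
      chrom = .data$chrom[1],
      start = min(.data$pos), end = max(.data$pos),
      n_snps = dplyr::n(), lead_p = min(.data$pvalue),
      .groups = "drop"
    ) |>
    dplyr::mutate(members = unname(members[.data$.key])) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::mutate(locus_id = sprintf("locus_%s_%d", .data$chrom,
                                     as.integer(.data$start))) |>
    dplyr::select("locus_id", "chrom", "start", "end", "n_snps",
                  "lead_p", "members")
  list(loci = loci, residual = residual)
}

#' Remove a genomic region from a score partition
#'
#' Drops loci whose span overlaps the region and residual SNPs that lie
#' inside it (closed interval at both ends, 1-based coordinates). Used
#' to exclude the HLA region from the type 2 genome-wide score so that
#' the type 2 score discriminates between liability to the two diabetes
#' types.
#'
#' @param loci,residual The two components returned by
#'   [designate_loci()].
#' @param region Either a string `"chrom:start-end"` or a list/tibble
#'   with `chrom`, `start`, `end`.
#' @return A list with the pruned `loci` and `residual`, plus
#'   `removed_loci` and `removed_snps` (counts are also messaged).
#' @export
#' @examples
#' ss <- tibble::tibble(snp_id = "s1", chrom = "6", pos = 32e6,
#'                      pvalue = 1e-9)
#' parts <- designate_loci(ss)
#' exclude_region(parts$loci, parts$residual, "6:25000000-35000000")
exclude_region <- function(loci, residual, region) {
  reg <- parse_region(region)
  hit_locus <- loci$chrom == reg$chrom &
    loci$start <= reg$end & loci$end >= reg$start
  hit_resid <- residual$chrom == reg$chrom &
    residual$pos >= reg$start & residual$pos <= reg$end
  if (any(hit_locus)) {
    inform(paste0("Excluding ", sum(hit_locus), " locus/loci in ",
                  reg$chrom, ":", reg$start, "-", reg$end, ": ",
                  fmt_ids(loci$locus_id[hit_locus])))
  }
  if (any(hit_resid)) {
    inform(paste0("Excluding ", sum(hit_resid),
                  " residual SNP(s) in the region."))
  }
  list(
    loci = loci[!hit_locus, , drop = FALSE],
    residual = residual[!hit_resid, , drop = FALSE],
    removed_loci = loci$locus_id[hit_locus],
    removed_snps = residual$snp_id[hit_resid]
  )
}

parse_region <- function(region) {
  if (is.character(region) && length(region) == 1L) {
    m <- regmatches(region,
                    regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4L) {
      stop_cpep("Region string must look like \"chrom:start-end\".")
    }
    region <- list(chrom = m[2], start = as.numeric(m[3]),
                   end = as.numeric(m[4]))
  }
  if (!all(c("chrom", "start", "end") %in% names(region)) ||
      region$start > region$end) {
    stop_cpep("Region must have chrom, start <= end.")
  }
  region
}

#' Harmonize summary-statistic alleles with genotype data
#'
#' Matches summary statistics to genotyped SNPs on chromosome and
#' position. When the effect/other alleles are swapped relative to the
#' genotype's counted/other alleles, the sign of `beta` is flipped.
#' Strand-ambiguous SNPs (A/T or C/G) and allele-set mismatches are
#' dropped with a warning — the conservative standard when the summary
#' source's strand is unknown.
#'
#' @param sumstats Summary statistics tibble (`chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, ...).
#' @param geno_meta Genotype SNP metadata tibble (`snp_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`), where `effect_allele` is
#'   the allele counted by the dosage.
#' @return Harmonized sumstats tibble using the genotype `snp_id` and
#'   allele orientation.
#' @export
harmonize_sumstats <- function(sumstats, geno_meta) {
  joined <- dplyr::inner_join(
    sumstats |> dplyr::rename(ea_ss = "effect_allele",
                              oa_ss = "other_allele",
                              snp_id_ss = "snp_id"),
    geno_meta |> dplyr::select("snp_id", "chrom", "pos",
                               ea_g = "effect_allele",
                               oa_g = "other_allele"),
    by = c("chrom", "pos")
  )
  ambiguous <- function(a, b) (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
  joined <- joined |>
    dplyr::mutate(
      same = .data$ea_ss == .data$ea_g & .data$oa_ss == .data$oa_g,
      swapped = .data$ea_ss == .data$oa_g & .data$oa_ss == .data$ea_g,
      ambig = ambiguous(.data$ea_ss, .data$oa_ss)
    )
  drop <- joined$ambig | (!joined$same & !joined$swapped)
  if (any(drop)) {
    warn(paste0("Dropping ", sum(drop),
                " strand-ambiguous or allele-mismatched SNP(s): ",
                fmt_ids(joined$snp_id_ss[drop])))
  }
  joined[!drop, , drop = FALSE] |>
    dplyr::mutate(beta = ifelse(.data$swapped, -.data$beta, .data$beta)) |>
    dplyr::transmute(.data$snp_id, .data$chrom, .data$pos,
                     effect_allele = .data$ea_g,
                     other_allele = .data$oa_g,
                     .data$beta, se = .data$se, pvalue = .data$pvalue)
}
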