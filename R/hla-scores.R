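#' Flag DR3, DR4 and DQ8 alleles in imputed HLA calls
#'
#' Classifies 4-digit allele codes: DRB1 alleles 0301-0304 are DR3,
#' DRB1 alleles 0401-0413 are DR4, and DQB1 alleles 0302-0305 are DQ8.
#'
#' @param calls Tibble of serotype calls with columns `individual_id`,
#'   `drb1_1`, `drb1_2`, `dqb1_1`, `dqb1_2`, alleles as 4-digit strings.
#' @return `calls` with logical columns `dr3_1`, `dr3_2`, `dr4_1`,
#'   `dr4_2`, `dq8_1`, `dq8_2` appended.
#' @export
#' @examples
#' calls <- tibble::tibble(individual_id = "a", drb1_1 = "0301",
#'                         drb1_2 = "0401", dqb1_1 = "0201",
#'                         dqb1_2 = "0302")
#' group_alleles(calls)
group_alleles <- function(calls) {
  parse_allele <- function(x, locus) {
    bad <- !grepl("^[0-9]{4}$", x)
    if (any(bad)) {
      stop_cpep("Malformed ", locus, " allele code(s) for individual(s): ",
                fmt_ids(calls$individual_id[bad]))
    }
    as.integer(x)
  }
  d1 <- parse_allele(calls$drb1_1, "DRB1")
  d2 <- parse_allele(calls$drb1_2, "DRB1")
  q1 <- parse_allele(calls$dqb1_1, "DQB1")
  q2 <- parse_allele(calls$dqb1_2, "DQB1")
  in_range <- function(x, lo, hi) x >= lo & x <= hi
  calls |>
    dplyr::mutate(
      dr3_1 = in_range(d1, 301L, 304L), dr3_2 = in_range(d2, 301L, 304L),
      dr4_1 = in_range(d1, 401L, 413L), dr4_2 = in_range(d2, 401L, 413L),
      dq8_1 = in_range(q1, 302L, 305L), dq8_2 = in_range(q2, 302L, 305L)
    )
}

#' Classify individuals into the six HLA serotype groups
#'
#' Assigns each individual to one of DR3/DR4-DQ8, DR3/DR3,
#' DR4-DQ8/DR4-DQ8, DR4-DQ8/X, DR3/X, or X/X. Because imputed allele
#' calls are effectively unphased, DR4-DQ8 haplotypes cannot be read off
#' directly; the number of DR4-DQ8 haplotypes is taken to be
#' `min(#DR4 DRB1 alleles, #DQ8 DQB1 alleles)` by default
#' (`dr4dq8_rule = "min"`), i.e. a DR4 allele only counts with a DQ8
#' allele to pair with. `dr4dq8_rule = "any"` instead credits every DR4
#' allele once at least one DQ8 allele is present. A DR4 allele without
#' DQ8 is not DR4-DQ8, so e.g. one DR3 plus DR4-without-DQ8 is DR3/X.
#'
#' @param calls Serotype call tibble (see [group_alleles()]); flag
#'   columns are computed if absent.
#' @param dr4dq8_rule How to count DR4-DQ8 haplotypes from unphased
#'   calls: `"min"` (default) or `"any"`.
#' @return `calls` with a `serotype_group` factor column appended
#'   (levels in risk order).
#' @export
#' @examples
#' calls <- tibble::tibble(individual_id = c("a", "b"),
#'                         drb1_1 = c("0301", "0701"),
#'                         drb1_2 = c("0401", "1101"),
#'                         dqb1_1 = c("0201", "0202"),
#'                         dqb1_2 = c("0302", "0301"))
#' classify_serotype(calls)$serotype_group
classify_serotype <- function(calls, dr4dq8_rule = c("min", "any")) {
  dr4dq8_rule <- match.arg(dr4dq8_rule)
  if (!all(c("dr3_1", "dq8_1") %in% names(calls))) {
    calls <- group_alleles(calls)
  }
  dr3 <- calls$dr3_1 + calls$dr3_2
  dr4 <- calls$dr4_1 + calls$dr4_2
  dq8 <- calls$dq8_1 + calls$dq8_2
  dr4dq8 <- switch(dr4dq8_rule,
    min = pmin(dr4, dq8),
    any = ifelse(dq8 >= 1L, dr4, 0L)
  )
  group <- dplyr::case_when(
    dr3 >= 1 & dr4dq8 >= 1 ~ "DR3/DR4-DQ8",
    dr3 >= 2 ~ "DR3/DR3",
    dr4dq8 >= 2 ~ "DR4-DQ8/DR4-DQ8",
    dr4dq8 == 1 ~ "DR4-DQ8/X",
    dr3 == 1 ~ "DR3/X",
    .default = "X/X"
  )
  calls$serotype_group <- factor(group, levels = serotype_group_levels())
  calls
}

#' The six serotype group labels
#' @return Character vector of the group labels, highest-risk first.
#' @export
serotype_group_levels <- function() {
  c("DR3/DR4-DQ8", "DR3/DR3", "DR4-DQ8/DR4-DQ8", "DR4-DQ8/X",
    "DR3/X", "X/X")
}

#' Serotype risk score from a weight table
#'
#' Looks up each individual's serotype group in a weight table. The
#' weights are a required configuration input (published serotype score
#' weights, or any user-chosen set); the package ships a clearly
#' labelled synthetic placeholder in
#' `system.file("extdata", "serotype_weights_synthetic.yaml",
#' package = "cpepgrs")`.
#'
#' @param calls Tibble with a `serotype_group` column (see
#'   [classify_serotype()]).
#' @param weights Named numeric vector or single-level named list with
#'   one finite weight per serotype group, or the path of a YAML file
#'   holding one.
#' @return `calls` with a numeric `serotype_score` column appended.
#' @export
serotype_score <- function(calls, weights) {
  w <- read_serotype_weights(weights)
  calls$serotype_score <- unname(w[as.character(calls$serotype_group)])
  calls
}

#' @rdname serotype_score
#' @export
read_serotype_weights <- function(weights) {
  if (is.character(weights) && length(weights) == 1L &&
      file.exists(weights)) {
    weights <- yaml::read_yaml(weights)
  }
  w <- unlist(weights)
  missing <- setdiff(serotype_group_levels(), names(w))
  if (length(missing)) {
    stop_cpep("Serotype weights missing group(s): ", fmt_ids(missing))
  }
  if (!is.numeric(w) || any(!is.finite(w[serotype_group_levels()]))) {
    stop_cpep("Serotype weights must be finite numbers.")
  }
  w[serotype_group_levels()]
}

#' HLA residual score
#'
#' Regresses the HLA region-specific polygenic score on the serotype
#' score (ordinary least squares with intercept) and returns the
#' residuals: the component of HLA-region polygenic risk not captured by
#' DR3/DR4-DQ8 serotype. The output has mean zero and is numerically
#' orthogonal to the serotype score.
#'
#' @param scores Tibble with columns `individual_id`, `hla_polygenic`
#'   and `serotype_score`.
#' @return `scores` with an `hla_residual` column appended.
#' @export
hla_residual_score <- function(scores) {
  if (nrow(scores) < 3L) {
    stop_cpep("Residualization needs at least 3 individuals.")
  }
  if (sd(scores$serotype_score) == 0) {
    stop_cpep("Serotype score is constant; residualization is undefined.")
  }
  fit <- lm(hla_polygenic ~ serotype_score, data = scores)
  scores$hla_residual <- unname(resid(fit))
  scores
}
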