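#' LD-adjust univariate SNP coefficients with a reference panel
#'
#' Converts univariate summary-statistic coefficients into approximate
#' multivariate (joint) weights by premultiplying with the Moore-Penrose
#' generalized inverse of the SNP correlation matrix estimated from a
#' reference panel: `w = R^+ b`. When the reference SNPs are mutually
#' uncorrelated this returns the input coefficients; when SNPs are in
#' LD, shared signal is split between them, approximating the weights a
#' multivariate regression on individual-level data would give.
#'
#' The generalized inverse is computed by eigendecomposition, discarding
#' eigenvalues below `eigen_cutoff` times the largest — deterministic
#' and stable for rank-deficient panels (e.g. duplicated SNPs).
#' Zero-variance (monomorphic) reference SNPs get weight 0 with a
#' warning.
#'
#' @param betas Numeric vector of univariate coefficients, one per SNP,
#'   or a sumstats tibble with columns `snp_id` and `beta`.
#' @param ref_genotypes Reference dosage matrix (individuals x SNPs),
#'   columns aligned with `betas` (and matched by name when both are
#'   named).
#' @param eigen_cutoff Relative eigenvalue cutoff for the pseudo-inverse
#'   (default `1e-6`).
#' @return A tibble with `snp_id`, `beta` (input) and `weight`
#'   (adjusted).
#' @export
#' @examples
#' G <- cbind(a = c(0, 1, 2, 1, 0, 2), b = c(2, 1, 0, 1, 2, 0))
#' ld_adjust_weights(c(a = 0.2, b = -0.1), G)
ld_adjust_weights <- function(betas, ref_genotypes, eigen_cutoff = 1e-6) {
  if (is.data.frame(betas)) {
    b <- setNames(betas$beta, betas$snp_id)
  } else {
    b <- betas
  }
  G <- as.matrix(ref_genotypes)
  if (length(b) != ncol(G)) {
    stop_cpep("Got ", length(b), " coefficients for ", ncol(G),
              " reference SNPs.")
  }
  if (nrow(G) < 2L) stop_cpep("Reference panel needs at least 2 individuals.")
  if (!is.null(names(b)) && !is.null(colnames(G)) &&
      !identical(names(b), colnames(G))) {
    if (!setequal(names(b), colnames(G))) {
      stop_cpep("SNP names of betas and reference genotypes differ.")
    }
    G <- G[, names(b), drop = FALSE]
  }
  snp_ids <- names(b) %||% colnames(G) %||%
    sprintf("snp%02d", seq_along(b))

  v <- apply(G, 2, var)
  const <- v <= 0
  if (all(const)) stop_cpep("All reference SNPs have zero variance.")
  if (any(const)) {
    warn(paste0("Zero-variance reference SNP(s) get weight 0: ",
                fmt_ids(snp_ids[const])))
  }
  w <- numeric(length(b))
  R <- cor(G[, !const, drop = FALSE])
  w[!const] <- drop(pinv_sym(R, eigen_cutoff) %*% b[!const])
  tibble(snp_id = snp_ids, beta = unname(b), weight = w)
}

# Moore-Penrose pseudo-inverse of a symmetric matrix via
# eigendecomposition with a relative eigenvalue cutoff.
pinv_sym <- function(S, cutoff = 1e-6) {
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > cutoff * max(e$values)
  if (!any(keep)) stop_cpep("Correlation matrix has no usable eigenvalues.")
  U <- e$vectors[, keep, drop = FALSE]
  U %*% (t(U) / e$values[keep])
}

#' Per-individual score from a weight vector
#'
#' Dot product of each individual's dosages with the SNP weights:
#' `score_i = sum_j dosage_ij * w_j`. Missing dosages are mean-imputed
#' from the cohort allele frequency of the SNP.
#'
#' @param weights Tibble with `snp_id` and `weight` (from
#'   [ld_adjust_weights()]), or a named numeric vector.
#' @param genotypes Cohort dosage matrix with SNP ids as colnames.
#' @return Tibble with `individual_id` and `score`.
#' @export
compute_locus_score <- function(weights, genotypes) {
  if (is.data.frame(weights)) {
    w <- setNames(weights$weight, weights$snp_id)
  } else {
    w <- weights
  }
  G <- as.matrix(genotypes)
  missing <- setdiff(names(w), colnames(G))
  if (length(missing)) {
    stop_cpep("Weight SNP(s) absent from genotypes: ", fmt_ids(missing))
  }
  G <- G[, names(w), drop = FALSE]
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  tibble(
    individual_id = rownames(G) %||% sprintf("id_%04d", seq_len(nrow(G))),
    score = unname(drop(G %*% w))
  )
}

#' Scale scores to unit SD or standardize against a reference
#'
#' With `reference = NULL`, divides the scores by their own standard
#' deviation (the convention for locus-specific scores, so that effect
#' sizes are per SD of score). With a `reference` vector, centres and
#' scales by the reference mean and SD (the convention for genome-wide
#' scores, standardized against an external reference cohort).
#'
#' @param scores Numeric vector of per-individual scores.
#' @param reference Optional numeric vector of the same score in a
#'   reference population.
#' @return Numeric vector of scaled scores.
#' @export
#' @examples
#' scale_scores(c(0, 2, 4))
#' scale_scores(14, reference = c(8, 10, 12))
scale_scores <- function(scores, reference = NULL) {
  if (is.null(reference)) {
    s <- sd(scores)
    if (!is.finite(s) || s == 0) {
      stop_cpep("Scores have zero variance; cannot scale to unit SD.")
    }
    scores / s
  } else {
    s <- sd(reference)
    if (!is.finite(s) || s == 0) {
      stop_cpep("Reference scores have zero variance.")
    }
    (scores - mean(reference)) / s
  }
}

#' Sum locus scores and the residual score into a genome-wide score
#'
#' Elementwise sum over individuals, computed before any
#' standardization. Inputs are matched on `individual_id`.
#'
#' @param locus_scores Tibble with `individual_id` and one numeric
#'   column per locus score, or a list of [compute_locus_score()]
#'   outputs.
#' @param residual_score Tibble with `individual_id`, `score`.
#' @return Tibble with `individual_id` and `genomewide_score`.
#' @export
combine_scores <- function(locus_scores, residual_score) {
  if (is.list(locus_scores) && !is.data.frame(locus_scores)) {
    stopifnot(length(locus_scores) > 0L)
    wide <- purrr::reduce(
      purrr::imap(locus_scores, function(d, nm) {
        names(d)[names(d) == "score"] <- paste0("score_", nm)
        d
      }),
      dplyr::inner_join, by = "individual_id"
    )
    locus_scores <- wide
  }
  if (!setequal(locus_scores$individual_id, residual_score$individual_id)) {
    stop_cpep("Locus scores and residual score cover different individuals.")
  }
  num <- dplyr::select(locus_scores, -"individual_id")
  tibble(
    individual_id = locus_scores$individual_id,
    genomewide_score = rowSums(as.matrix(num)) +
      residual_score$score[match(locus_scores$individual_id,
                                 residual_score$individual_id)]
  )
}

#' Full score table for a cohort
#'
#' Runs the scoring pipeline over a locus partition: LD-adjusts each
#' locus's coefficients against the reference panel, scores the cohort,
#' scales each locus score to unit SD in the cohort, computes the
#' residual genome-wide score from unadjusted coefficients (residual
#' SNPs are mutually distant, so their correlation matrix is the
#' identity and adjustment is a no-op), and standardizes the summed
#' genome-wide score against a reference cohort's raw scores (the
#' cohort itself by default).
#'
#' @param loci,residual Partition from [designate_loci()] (optionally
#'   after [exclude_region()]).
#' @param ref_genotypes Reference-panel dosage matrix (for LD).
#' @param genotypes Cohort dosage matrix to score.
#' @param standardize_genotypes Optional dosage matrix of an external
#'   reference cohort used to standardize the genome-wide score.
#' @return Tibble with `individual_id`, one `score_<locus_id>` column
#'   per locus (unit SD), `residual_score`, and `genomewide_score`
#'   (standardized). The raw (pre-standardization) genome-wide score is
#'   kept in `genomewide_raw`.
#' @export
compute_score_table <- function(loci, residual, ref_genotypes, genotypes,
                                standardize_genotypes = NULL) {
  ids <- rownames(genotypes) %||% sprintf("id_%04d", seq_len(nrow(genotypes)))
  weights <- purrr::map(loci$members, function(mem) {
    ld_adjust_weights(mem, ref_genotypes[, mem$snp_id, drop = FALSE])
  })
  names(weights) <- loci$locus_id

  raw_locus <- purrr::map(weights, compute_locus_score,
                          genotypes = genotypes)
  resid_score <- if (nrow(residual) > 0L) {
    compute_locus_score(
      tibble(snp_id = residual$snp_id, weight = residual$beta),
      genotypes
    )
  } else {
    tibble(individual_id = ids, score = rep(0, length(ids)))
  }

  gw <- if (length(raw_locus) > 0L) {
    combine_scores(raw_locus, resid_score)
  } else {
    tibble(individual_id = ids,
           genomewide_score = resid_score$score)
  }

  ref_gw <- if (is.null(standardize_genotypes)) {
    gw$genomewide_score
  } else {
    raw_ref <- purrr::map(weights, compute_locus_score,
                          genotypes = standardize_genotypes)
    resid_ref <- if (nrow(residual) > 0L) {
      compute_locus_score(
        tibble(snp_id = residual$snp_id, weight = residual$beta),
        standardize_genotypes
      )
    } else {
      tibble(individual_id = rownames(standardize_genotypes),
             score = rep(0, nrow(standardize_genotypes)))
    }
    if (length(raw_ref) > 0L) {
      combine_scores(raw_ref, resid_ref)$genomewide_score
    } else {
      resid_ref$score
    }
  }

  out <- tibble(individual_id = ids)
  for (lid in names(raw_locus)) {
    sc <- raw_locus[[lid]]$score
    out[[paste0("score_", lid)]] <-
      if (sd(sc) > 0) scale_scores(sc) else sc
  }
  out$residual_score <- resid_score$score
  out$genomewide_raw <- gw$genomewide_score
  out$genomewide_score <- scale_scores(gw$genomewide_score,
                                       reference = ref_gw)
  attr(out, "weights") <- weights
  out
}
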