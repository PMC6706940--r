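#' Simulate clinical phenotypes with a censored C-peptide outcome
#'
#' Builds clinical covariates (sex, age at onset, diabetes duration,
#' random plasma glucose, BMI), true genotypic risk scores from the
#' causal SNP effects in `truth`, and log10 C-peptide as
#' \deqn{\log_{10} C = \beta_0 + X_c \beta + u + e,}
#' where `X_c` are the mean-centred model covariates (main effects plus
#' interactions of each with the square root of age at onset), `u` is a
#' polygenic value over all simulated SNPs scaled so that its sample
#' variance is `h2_cpep * sigma_resid^2`, and `e` is Gaussian noise with
#' variance `(1 - h2_cpep) * sigma_resid^2`. Simulated C-peptide below
#' the detection limit is flagged `below_detection`. The polygenic value
#' is residualized on the two risk scores before scaling, so it is
#' genetic variance beyond the modelled scores and leaves their
#' coefficients recoverable at any heritability. Autoantibody titres
#' (GAD, IA2, ZnT8) are log-normal with means declining in duration, so
#' the proportion antibody-negative rises with duration.
#'
#' @param config A [synthetic_config()] object.
#' @param truth A [synthetic_truth()] object.
#' @param genotypes Cohort genotypes from [simulate_genotypes()].
#' @param serotypes Serotype calls from [simulate_serotypes()] for the
#'   same individuals (currently carried through unchanged; HLA serotype
#'   effects enter via the locus-1 causal SNP).
#' @return A tibble of phenotype records (`individual_id`, `sex`,
#'   `age_onset`, `duration`, `age_sampling`, `glucose`, `bmi`,
#'   `cpeptide`, `below_detection`, `gad`, `ia2`, `znt8`, `t1_score`,
#'   `t2_score`) with the realized heritability in `attr(, "h2_true")`.
#' @export
#' @examples
#' cfg <- synthetic_config(n_cohort = 100, seed = 4)
#' tr <- synthetic_truth(cfg)
#' g <- simulate_genotypes(cfg, 100, stream = 6L)
#' s <- simulate_serotypes(cfg, 100)
#' ph <- simulate_phenotypes(cfg, tr, g, s)
#' mean(ph$below_detection)
simulate_phenotypes <- function(config, truth, genotypes, serotypes) {
  stopifnot(inherits(config, "cpep_config"), inherits(truth, "cpep_truth"))
  dosage <- genotypes$dosage
  n <- nrow(dosage)
  if (!identical(rownames(dosage), serotypes$individual_id)) {
    stop_cpep("Genotypes and serotypes must cover the same individuals, in order.")
  }
  check_number(config$h2_cpep, "h2_cpep", lower = 0, upper = 1)
  set.seed(derive_seed(config$seed, 5L))

  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  sex <- ifelse(runif(n) < 0.5, "female", "male")
  age_onset <- clip(rgamma(n, shape = 3, scale = 7.3), 0.5, 60)
  duration <- clip(rgamma(n, shape = 2, scale = 10), 0.5, 55)
  glucose <- clip(rnorm(n, 10, 4), 2, 30)
  bmi <- clip(rnorm(n, 26, 4), 15, 50)

  score_for <- function(trait) {
    ce <- dplyr::filter(truth$causal_effects, .data$trait == !!trait)
    if (nrow(ce) == 0L) return(rep(0, n))
    s <- drop(dosage[, ce$snp_id, drop = FALSE] %*% ce$effect)
    if (sd(s) > 0) (s - mean(s)) / sd(s) else s - mean(s)
  }
  t1_score <- score_for("t1")
  t2_score <- score_for("t2")

  covars <- tibble(
    glucose_high = as.numeric(glucose > 5),
    sqrt_onset = sqrt(age_onset),
    female = as.numeric(sex == "female"),
    duration = duration,
    t1_score = t1_score,
    t2_score = t2_score,
    bmi = bmi
  )
  X <- cpep_model_matrix(covars)
  bt <- config$beta_table
  lp <- bt[["(Intercept)"]] + drop(X %*% bt[colnames(X)])

  # polygenic value over all SNPs, rescaled to hit the target share of
  # the residual variance exactly in-sample
  h2 <- config$h2_cpep
  sg <- sqrt(h2) * config$sigma_resid
  if (sg > 0) {
    zc <- scale(dosage, center = TRUE, scale = FALSE)
    u <- drop(zc %*% rnorm(ncol(zc)))
    # the polygenic background is residual genetic variance: make it
    # orthogonal to the modelled risk scores so the score coefficients
    # stay interpretable (and recoverable) at any h2
    A <- cbind(1, t1_score, t2_score)
    A <- A[, c(TRUE, sd(t1_score) > 0, sd(t2_score) > 0), drop = FALSE]
    u <- u - drop(A %*% solve(crossprod(A), crossprod(A, u)))
    u <- if (sd(u) > 0) u * sg / sd(u) else u
  } else {
    u <- rep(0, n)
  }
  e_sd <- sqrt(1 - h2) * config$sigma_resid
  e <- if (e_sd > 0) rnorm(n, 0, e_sd) else rep(0, n)

  log10cp <- lp + u + e
  cpeptide <- 10^log10cp

  # titres: log-normal, geometric mean declining with duration
  titre <- function(mu0, slope) exp(rnorm(n, log(mu0) - slope * duration, 1.2))
  gad <- titre(40, 0.10)
  ia2 <- titre(15, 0.12)
  znt8 <- titre(30, 0.12)

  out <- tibble(
    individual_id = rownames(dosage),
    sex = sex,
    age_onset = age_onset,
    duration = duration,
    age_sampling = age_onset + duration,
    glucose = glucose,
    bmi = bmi,
    cpeptide = cpeptide,
    below_detection = cpeptide < config$lod,
    gad = gad, ia2 = ia2, znt8 = znt8,
    t1_score = t1_score, t2_score = t2_score
  )
  tot <- var(u) + var(e)
  attr(out, "h2_true") <- if (tot > 0) var(u) / tot else 0
  out
}

# Model matrix of the C-peptide regression: centred main effects and
# products of centred sqrt_onset with the other centred covariates.
# Column order matches default_beta_table() (minus the intercept).
cpep_model_matrix <- function(covars) {
  cc <- as.matrix(covars)
  cc <- scale(cc, center = TRUE, scale = FALSE)
  mains <- c("glucose_high", "sqrt_onset", "female", "duration",
             "t1_score", "t2_score", "bmi")
  stopifnot(all(mains %in% colnames(cc)))
  inter_with <- c("female", "duration", "t1_score", "t2_score", "bmi")
  inter <- cc[, "sqrt_onset"] * cc[, inter_with, drop = FALSE]
  colnames(inter) <- paste0("sqrt_onset:", inter_with)
  cbind(cc[, mains, drop = FALSE], inter)
}

#' Generate a complete synthetic study
#'
#' One-stop generator: reference panel, external GWAS summary
#' statistics, study cohort with full-sib pairs, HLA serotype calls, and
#' phenotypes, all under a single seed and with the ground truth
#' recorded.
#'
#' @param config A [synthetic_config()] object.
#' @return A list of class `cpep_synthetic` with components `config`,
#'   `truth` (with realized `h2_true`), `ref` and `cohort` (each a
#'   `dosage` matrix plus `snp_meta`), `sumstats`, `serotypes`, and
#'   `phenotypes`.
#' @export
#' @examples
#' study <- simulate_cohort(synthetic_config(n_cohort = 50, n_gwas = 300,
#'                                           n_ref = 80, seed = 9))
#' names(study)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cpep_config"))
  truth <- synthetic_truth(config)
  ref <- simulate_genotypes(config, config$n_ref, stream = 1L)
  sumstats <- simulate_gwas_sumstats(config, truth)
  sib_pairs <- floor(config$sib_frac * config$n_cohort / 2)
  cohort <- simulate_genotypes(config, config$n_cohort,
                               sib_pairs = sib_pairs, stream = 6L)
  serotypes <- simulate_serotypes(config, config$n_cohort)
  phenotypes <- simulate_phenotypes(config, truth, cohort, serotypes)
  truth$h2_true <- attr(phenotypes, "h2_true")
  structure(
    list(config = config, truth = truth, ref = ref, cohort = cohort,
         sumstats = sumstats, serotypes = serotypes,
         phenotypes = phenotypes),
    class = "cpep_synthetic"
  )
}
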