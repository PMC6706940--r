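#' Genomic relationship matrix
#'
#' VanRaden-style GRM: genotype columns are centred at twice the allele
#' frequency and scaled by `sqrt(2 p (1 - p))`, and the GRM is the
#' cross-product of the standardized matrix averaged over SNPs. Under
#' this standardization unrelated individuals have expected relationship
#' 0, full sibs 0.5, and the diagonal is 1 plus the inbreeding
#' coefficient. Monomorphic SNPs are skipped with a message.
#'
#' @param genotypes Dosage matrix (individuals x SNPs), rownames used as
#'   individual ids.
#' @return Symmetric `n x n` matrix with individual ids as dimnames.
#' @export
compute_grm <- function(genotypes) {
  G <- as.matrix(genotypes)
  if (nrow(G) < 2L) stop_cpep("GRM needs at least 2 individuals.")
  p <- colMeans(G) / 2
  poly <- p > 0 & p < 1 & apply(G, 2, var) > 0
  if (!any(poly)) stop_cpep("No polymorphic SNPs; cannot compute a GRM.")
  if (any(!poly)) {
    inform(paste0("Skipping ", sum(!poly), " monomorphic SNP(s)."))
  }
  G <- G[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(G, 2, 2 * p, "-")
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  K <- tcrossprod(Z) / ncol(Z)
  ids <- rownames(genotypes) %||% sprintf("id_%04d", seq_len(nrow(G)))
  dimnames(K) <- list(ids, ids)
  K
}

#' Eigendecomposition of a GRM for reuse across model fits
#'
#' REML fitting and score tests work in the eigenbasis of the GRM;
#' decomposing once and passing the result to [reml_fit()] makes
#' repeated fits against the same relatedness structure cheap.
#'
#' @param grm Symmetric GRM matrix.
#' @param tol Relative tolerance on negative eigenvalues before the GRM
#'   is declared non-positive-semidefinite.
#' @return Object of class `cpep_grm_eigen` (eigenvalues clipped at
#'   zero, eigenvectors, ids).
#' @export
grm_eigen <- function(grm, tol = 1e-8) {
  e <- eigen(grm, symmetric = TRUE)
  lam_max <- max(e$values)
  if (min(e$values) < -tol * max(lam_max, 1)) {
    stop_cpep("GRM is not positive semidefinite (min eigenvalue ",
              format(min(e$values)), ").")
  }
  structure(
    list(values = pmax(e$values, 0), vectors = e$vectors,
         ids = rownames(grm)),
    class = "cpep_grm_eigen"
  )
}

#' REML estimation of SNP heritability under a linear mixed model
#'
#' Fits `y = X b + g + e` with `g ~ N(0, sigma_g^2 K)` and
#' `e ~ N(0, sigma_e^2 I)` by restricted maximum likelihood. The
#' likelihood is profiled over the heritability
#' `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)` on the eigenbasis of the
#' GRM, and maximized on `[0, 1]` by one-dimensional bounded search,
#' which cannot fail to converge. The total variance is profiled out
#' analytically. Redundant (collinear) covariate columns are dropped, so
#' the fit is invariant to adding multiples of existing columns.
#'
#' @param phenotype Numeric vector, one value per individual.
#' @param covariates Design matrix of fixed effects (an intercept is
#'   added when no constant column is present), or `NULL` for intercept
#'   only.
#' @param grm GRM matrix from [compute_grm()], or a precomputed
#'   [grm_eigen()] object.
#' @return Object of class `cpep_reml` with elements `h2`, `sigma_g`
#'   and `sigma_e` (variance components), `se_h2`, `loglik`,
#'   `converged`, `boundary`, fixed-effect estimates `beta`, and the
#'   rotated quantities reused by [score_test_scan()]. [tidy()] and
#'   [glance()] methods are provided.
#' @export
reml_fit <- function(phenotype, covariates = NULL, grm) {
  y <- as.numeric(phenotype)
  n <- length(y)
  X <- build_design(covariates, n)
  if (n < ncol(X) + 2L) {
    stop_cpep("Need at least ", ncol(X) + 2L, " individuals for REML.")
  }
  eig <- if (inherits(grm, "cpep_grm_eigen")) grm else grm_eigen(grm)
  if (length(eig$values) != n) {
    stop_cpep("GRM covers ", length(eig$values),
              " individuals but the phenotype has ", n, ".")
  }
  # drop aliased covariate columns for projection invariance
  qx <- qr(X)
  if (qx$rank < ncol(X)) X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  p <- ncol(X)

  U <- eig$vectors
  lam <- eig$values
  z <- drop(crossprod(U, y))
  W <- crossprod(U, X)

  restricted_ll <- function(h2) {
    d <- h2 * lam + (1 - h2)
    Wd <- W / d
    WtW <- crossprod(W, Wd)
    beta <- solve(WtW, crossprod(Wd, z))
    r <- z - drop(W %*% beta)
    rss <- sum(r^2 / d)
    s2 <- rss / (n - p)
    ll <- -0.5 * (sum(log(d)) + determinant(WtW)$modulus[1] +
                    (n - p) * log(s2))
    list(ll = ll, beta = beta, s2 = s2, d = d, r = r)
  }
  opt <- optimize(function(h2) restricted_ll(h2)$ll,
                  interval = c(0, 1), maximum = TRUE, tol = 1e-9)
  h2 <- opt$maximum
  at_bound <- h2 < 1e-6 || h2 > 1 - 1e-6
  if (at_bound) h2 <- round(h2)
  sol <- restricted_ll(h2)
  s2 <- sol$s2
  se_h2 <- if (at_bound) NA_real_ else {
    h <- 1e-4
    d2 <- (restricted_ll(min(h2 + h, 1))$ll - 2 * opt$objective +
             restricted_ll(max(h2 - h, 0))$ll) / h^2
    if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  }
  structure(
    list(
      h2 = h2, sigma_g = h2 * s2, sigma_e = (1 - h2) * s2,
      se_h2 = se_h2, loglik = opt$objective, converged = TRUE,
      boundary = at_bound, beta = setNames(drop(sol$beta), colnames(X)),
      n = n, p = p,
      .rot = list(U = U, d = sol$d, r = sol$r, W = W, s2 = s2,
                  ids = eig$ids)
    ),
    class = "cpep_reml"
  )
}

build_design <- function(covariates, n) {
  if (is.null(covariates)) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  X <- as.matrix(covariates)
  if (nrow(X) != n) stop_cpep("Covariate rows do not match the phenotype.")
  has_const <- any(apply(X, 2, function(c) sd(c) == 0 & c[1] != 0))
  if (!has_const) {
    X <- cbind(`(Intercept)` = 1, X)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

#' @export
print.cpep_reml <- function(x, ...) {
  cat("<cpep_reml> h2 =", signif(x$h2, 3),
      if (!is.na(x$se_h2)) paste0("(SE ", signif(x$se_h2, 3), ")"),
      "| n =", x$n,
      if (x$boundary) "| at boundary", "\n")
  invisible(x)
}

#' @rdname reml_fit
#' @param x,object A `cpep_reml` object.
#' @param ... Unused.
#' @export
tidy.cpep_reml <- function(x, ...) {
  tibble(
    term = c("h2", "sigma2_g", "sigma2_e"),
    estimate = c(x$h2, x$sigma_g, x$sigma_e),
    std.error = c(x$se_h2, NA_real_, NA_real_)
  )
}

#' @rdname reml_fit
#' @export
glance.cpep_reml <- function(x, ...) {
  tibble(h2 = x$h2, se_h2 = x$se_h2, logLik = x$loglik,
         converged = x$converged, boundary = x$boundary, nobs = x$n)
}

#' Efficient-score association scan under a fitted mixed model
#'
#' One-degree-of-freedom score test for each test SNP using the null
#' model's fitted covariance: the statistic is the squared gradient of
#' the log-likelihood in the SNP effect at zero, divided by its
#' variance, referred to chi-square(1). The null model is fitted once;
#' no per-SNP refitting. Zero-variance SNPs are reported as `NA` with a
#' warning.
#'
#' @param null_fit A [reml_fit()] object (fitted without the test SNP).
#' @param test_genotypes Dosage matrix of test SNPs (individuals in the
#'   same order as the null fit).
#' @param snp_meta Optional tibble with `snp_id`, `chrom`, `pos` merged
#'   into the result.
#' @return Tibble with `snp_id`, `score_stat`, `p` (plus `chrom`, `pos`
#'   when supplied).
#' @export
score_test_scan <- function(null_fit, test_genotypes, snp_meta = NULL) {
  stopifnot(inherits(null_fit, "cpep_reml"))
  G <- as.matrix(test_genotypes)
  rot <- null_fit$.rot
  if (nrow(G) != length(rot$d)) {
    stop_cpep("Test genotypes cover ", nrow(G),
              " individuals; the null model has ", length(rot$d), ".")
  }
  snp_ids <- colnames(G) %||% sprintf("snp%05d", seq_len(ncol(G)))
  zero_var <- apply(G, 2, sd) == 0
  if (any(zero_var)) {
    warn(paste0(sum(zero_var), " zero-variance SNP(s) reported as NA: ",
                fmt_ids(snp_ids[zero_var])))
  }
  Gt <- crossprod(rot$U, G)             # rotated genotypes
  d <- rot$d
  s2 <- rot$s2
  # score: g' P y ; variance: g' P g, both in the rotated basis
  u <- colSums(Gt * (rot$r / d)) / s2
  WdG <- crossprod(rot$W / d, Gt)       # p x m
  WtW <- crossprod(rot$W, rot$W / d)
  quad <- colSums(Gt^2 / d) - colSums(WdG * solve(WtW, WdG))
  v <- quad / s2
  stat <- u^2 / v
  stat[zero_var | v <= 0] <- NA_real_
  out <- tibble(
    snp_id = snp_ids,
    score_stat = unname(stat),
    p = pchisq(stat, df = 1, lower.tail = FALSE)
  )
  if (!is.null(snp_meta)) {
    out <- dplyr::left_join(out,
                            dplyr::select(snp_meta, "snp_id", "chrom", "pos"),
                            by = "snp_id") |>
      dplyr::relocate("snp_id", "chrom", "pos")
  }
  out
}

#' Manhattan plot of a score-test scan
#'
#' Standard -log10(p) Manhattan plot, optionally highlighting
#' diabetes-associated regions (e.g. loci from [designate_loci()]).
#'
#' @param scan Tibble from [score_test_scan()] with `chrom`, `pos`, `p`.
#' @param highlight Optional loci tibble with `chrom`, `start`, `end`.
#' @param truncate Cap on -log10(p) for display (default 15).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(scan, highlight = NULL, truncate = 15) {
  d <- scan |>
    dplyr::filter(!is.na(.data$p)) |>
    dplyr::mutate(
      logp = pmin(-log10(.data$p), truncate),
      chrom = factor(.data$chrom, levels = unique(.data$chrom))
    )
  if (!is.null(highlight)) {
    d <- d |>
      dplyr::rowwise() |>
      dplyr::mutate(hit = any(highlight$chrom == .data$chrom &
                                highlight$start <= .data$pos &
                                highlight$end >= .data$pos)) |>
      dplyr::ungroup()
  } else {
    d$hit <- FALSE
  }
  ggplot(d, aes(x = .data$pos, y = .data$logp,
                colour = .data$hit)) +
    geom_point(size = 0.8) +
    facet_grid(cols = vars(.data$chrom), scales = "free_x",
               space = "free_x", switch = "x") +
    scale_colour_manual(values = c(`FALSE` = "grey40",
                                   `TRUE` = "forestgreen"),
                        guide = "none") +
    labs(x = "Position", y = expression(-log[10](p))) +
    theme_minimal() +
    theme(axis.text.x = element_blank())
}
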