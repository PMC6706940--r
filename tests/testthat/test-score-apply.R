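test_that("LD adjustment reduces to known closed forms", {
  # exactly orthogonal dosage columns: weights equal the input betas
  G <- cbind(a = c(0, 0, 2, 2), b = c(0, 2, 0, 2))
  w <- ld_adjust_weights(c(a = 0.3, b = -0.2), G)
  expect_equal(w$weight, c(0.3, -0.2), tolerance = 1e-12)

  # two correlated SNPs: closed-form inverse of the 2x2 correlation
  set.seed(1)
  G2 <- matrix(rbinom(400, 2, 0.4), ncol = 2,
               dimnames = list(NULL, c("a", "b")))
  G2[, 2] <- pmin(pmax(G2[, 1] + rbinom(200, 1, 0.3) -
                         rbinom(200, 1, 0.3), 0), 2)
  r <- cor(G2)[1, 2]
  b <- c(a = 0.4, b = 0.1)
  w2 <- ld_adjust_weights(b, G2)
  expect_equal(w2$weight,
               c((b[1] - r * b[2]) / (1 - r^2),
                 (b[2] - r * b[1]) / (1 - r^2)),
               ignore_attr = TRUE, tolerance = 1e-10)

  # perfectly duplicated SNPs: pseudo-inverse splits the weight
  G3 <- cbind(a = c(0, 1, 2, 1, 0), b = c(0, 1, 2, 1, 0))
  w3 <- ld_adjust_weights(c(a = 0.6, b = 0.6), G3)
  expect_equal(w3$weight, c(0.3, 0.3), tolerance = 1e-10)
})

test_that("LD adjustment recovers multivariate weights when b = R w", {
  set.seed(2)
  for (i in 1:10) {
    m <- sample(3:8, 1)
    G <- matrix(rbinom(200 * m, 2, runif(1, 0.2, 0.5)), ncol = m)
    G[, -1] <- G[, -1] + G[, 1] %% 2  # induce LD
    G <- pmin(G, 2)
    R <- cor(G)
    if (min(eigen(R)$values) < 1e-4) next
    w_true <- rnorm(m)
    w_hat <- ld_adjust_weights(drop(R %*% w_true), G)$weight
    expect_lt(max(abs(w_hat - w_true)) / max(abs(w_true)), 1e-6)
  }
})

test_that("pseudo-inverse satisfies its contract on rank-deficient panels", {
  set.seed(3)
  base <- matrix(rbinom(300, 2, 0.3), ncol = 3)
  G <- cbind(base, base[, 1])  # rank-deficient: duplicated column
  R <- cor(G)
  Rp <- cpepgrs:::pinv_sym(R)
  # R R+ b = b for b in the column space of R
  for (i in 1:5) {
    b <- drop(R %*% rnorm(4))
    expect_equal(drop(R %*% Rp %*% b), b, tolerance = 1e-8)
  }
  # agrees with an independent generalized-inverse implementation
  skip_if_not_installed("MASS")
  expect_equal(Rp, MASS::ginv(R), tolerance = 1e-8)
})

test_that("degenerate reference panels are rejected or flagged", {
  G <- cbind(a = c(0, 1, 2, 1), b = c(1, 1, 1, 1))
  expect_warning(w <- ld_adjust_weights(c(a = 0.2, b = 0.5), G),
                 "weight 0")
  expect_equal(w$weight[2], 0)
  expect_error(
    suppressWarnings(ld_adjust_weights(c(a = 1), cbind(a = c(1, 1)))),
    "zero variance"
  )
  expect_error(ld_adjust_weights(c(0.1, 0.2), cbind(a = c(0, 1, 2))),
               "coefficients")
})

test_that("locus scores equal the brute-force dot product", {
  set.seed(4)
  G <- matrix(rbinom(50 * 5, 2, 0.3), ncol = 5,
              dimnames = list(sprintf("i%02d", 1:50),
                              sprintf("s%d", 1:5)))
  w <- tibble::tibble(snp_id = sprintf("s%d", 1:5), weight = rnorm(5))
  sc <- compute_locus_score(w, G)
  manual <- vapply(1:50, function(i) sum(G[i, ] * w$weight), numeric(1))
  expect_equal(sc$score, manual)

  # all-zero weights; single-SNP identity
  w0 <- dplyr::mutate(w, weight = 0)
  expect_true(all(compute_locus_score(w0, G)$score == 0))
  w1 <- tibble::tibble(snp_id = "s2", weight = 1)
  expect_equal(compute_locus_score(w1, G)$score, unname(G[, "s2"]))

  # missing SNP errors; missing dosages are mean-imputed
  expect_error(compute_locus_score(
    tibble::tibble(snp_id = "nope", weight = 1), G), "nope")
  Gna <- G
  Gna[1, 1] <- NA
  sc_na <- compute_locus_score(w, Gna)
  expected1 <- sum(c(mean(Gna[-1, 1]), Gna[1, -1]) * w$weight)
  expect_equal(sc_na$score[1], expected1)
})

test_that("score scaling follows the locus and genome-wide conventions", {
  expect_equal(sd(scale_scores(c(0, 2, 4))), 1)
  x <- rnorm(20)
  std <- scale_scores(x, reference = x)
  expect_equal(mean(std), 0, tolerance = 1e-12)
  expect_equal(sd(std), 1, tolerance = 1e-12)
  expect_equal(scale_scores(14, reference = c(8, 10, 12)), 2)
  expect_error(scale_scores(c(1, 1, 1)), "zero variance")
  expect_error(scale_scores(1:3, reference = c(2, 2)), "zero variance")
})

test_that("combining scores is an elementwise sum over matched ids", {
  ids <- sprintf("i%d", 1:8)
  l1 <- tibble::tibble(individual_id = ids, score = rnorm(8))
  l2 <- tibble::tibble(individual_id = ids, score = rnorm(8))
  res <- tibble::tibble(individual_id = rev(ids), score = rnorm(8))
  gw <- combine_scores(list(a = l1, b = l2), res)
  manual <- l1$score + l2$score + res$score[match(ids, res$individual_id)]
  expect_equal(gw$genomewide_score, manual)

  zero_res <- dplyr::mutate(res, score = 0)
  expect_equal(combine_scores(list(a = l1, b = l2),
                              zero_res)$genomewide_score,
               l1$score + l2$score)
  expect_error(combine_scores(list(a = l1), res[-1, ]), "different individuals")
})

test_that("the score table keeps its summation invariant and scaling", {
  cfg <- synthetic_config(n_ref = 200, n_gwas = 2000, n_cohort = 300,
                          n_loci = 4, n_snps_per_locus = 6, seed = 55)
  study <- simulate_cohort(cfg)
  filt <- filter_snps(study$sumstats, study$cohort$snp_meta)
  parts <- designate_loci(filt)
  st <- compute_score_table(parts$loci, parts$residual,
                            study$ref$dosage, study$cohort$dosage)
  # genome-wide = sum of raw locus scores + residual, before scaling
  w <- attr(st, "weights")
  raw <- Reduce(`+`, lapply(w, function(wi) {
    compute_locus_score(wi, study$cohort$dosage)$score
  }))
  expect_equal(st$genomewide_raw, raw + st$residual_score)
  expect_equal(mean(st$genomewide_score), 0, tolerance = 1e-10)
  expect_equal(sd(st$genomewide_score), 1, tolerance = 1e-10)
  for (col in grep("^score_", names(st), value = TRUE)) {
    expect_equal(sd(st[[col]]), 1, tolerance = 1e-10)
  }
  # standardizing against an external panel uses that panel's scale
  st2 <- compute_score_table(parts$loci, parts$residual,
                             study$ref$dosage, study$cohort$dosage,
                             standardize_genotypes = study$ref$dosage)
  expect_false(isTRUE(all.equal(sd(st2$genomewide_score), 1)))
})

test_that("score correlates with the true genetic value", {
  cfg <- synthetic_config(n_ref = 200, n_gwas = 3000, n_cohort = 400,
                          n_loci = 4, n_snps_per_locus = 6, seed = 56)
  study <- simulate_cohort(cfg)
  filt <- filter_snps(study$sumstats, study$cohort$snp_meta)
  parts <- designate_loci(filt)
  st <- compute_score_table(parts$loci, parts$residual,
                            study$ref$dosage, study$cohort$dosage)
  eff <- study$truth$causal_effects
  truth_value <- drop(study$cohort$dosage[, eff$snp_id] %*% eff$effect)
  expect_gt(cor(st$genomewide_raw, truth_value), 0.5)
})
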