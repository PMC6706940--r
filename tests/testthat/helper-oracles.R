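# Independent oracles used across tests. These re-derive expected
# results by brute force or direct linear algebra, deliberately avoiding
# the code paths they check.

# Single-linkage clustering over all pairs: SNPs are linked when on the
# same chromosome and less than gap_bp apart; components found by BFS on
# the full adjacency matrix.
oracle_single_linkage <- function(chrom, pos, gap_bp) {
  n <- length(pos)
  if (n == 0L) return(integer(0))
  adj <- outer(chrom, chrom, "==") & abs(outer(pos, pos, "-")) < gap_bp
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    frontier <- i
    comp[i] <- k
    while (length(frontier)) {
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) &
                     is.na(comp))
      comp[nxt] <- k
      frontier <- nxt
    }
  }
  comp
}

# Expected locus/residual split for a sumstats tibble, via the oracle
# clustering: returns a list of sorted snp_id sets for loci, plus the
# residual id set.
oracle_partition <- function(ss, gap_bp = 1e6, lead_p = 1e-6) {
  comp <- oracle_single_linkage(ss$chrom, ss$pos, gap_bp)
  loci <- list()
  residual <- character(0)
  for (k in unique(comp)) {
    idx <- comp == k
    if (min(ss$pvalue[idx]) < lead_p) {
      loci <- c(loci, list(sort(ss$snp_id[idx])))
    } else {
      residual <- c(residual, ss$snp_id[idx])
    }
  }
  list(loci = loci[order(vapply(loci, `[`, "", 1))],
       residual = sort(residual))
}

# Random sumstats instance for property tests.
random_sumstats <- function(n, n_chrom = 3, max_pos = 5e6) {
  tibble::tibble(
    snp_id = sprintf("s%03d", seq_len(n)),
    chrom = as.character(sample.int(n_chrom, n, replace = TRUE)),
    pos = sample.int(max_pos, n, replace = TRUE),
    pvalue = 10^-runif(n, 0, 9)
  )
}

# Direct-matrix restricted likelihood for the REML oracle: profile over
# h2 with generic solves and determinants (no eigenbasis shortcut).
oracle_reml_h2 <- function(y, X, K) {
  n <- length(y)
  p <- ncol(X)
  ll <- function(h2) {
    V <- h2 * K + (1 - h2) * diag(n)
    Vi <- solve(V)
    XtViX <- t(X) %*% Vi %*% X
    beta <- solve(XtViX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    s2 <- drop(t(r) %*% Vi %*% r) / (n - p)
    -0.5 * (determinant(V)$modulus[1] + determinant(XtViX)$modulus[1] +
              (n - p) * log(s2))
  }
  stats::optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-10)$maximum
}

# OLS score-test statistic for adding SNP g to a linear model with
# design X, using the REML-style residual variance (RSS / (n - p)).
oracle_ols_score <- function(y, X, g) {
  M <- diag(length(y)) - X %*% solve(crossprod(X), t(X))
  My <- M %*% y
  s2 <- drop(t(y) %*% My) / (length(y) - ncol(X))
  drop(t(g) %*% My)^2 / (drop(t(g) %*% M %*% g) * s2)
}

# Direct re-derivation of the six-group serotype rule from allele codes,
# written independently of classify_serotype().
oracle_serotype <- function(drb1, dqb1) {
  code <- as.integer(c(drb1, dqb1))
  dr3 <- sum(code[1:2] >= 301 & code[1:2] <= 304)
  dr4 <- sum(code[1:2] >= 401 & code[1:2] <= 413)
  dq8 <- sum(code[3:4] >= 302 & code[3:4] <= 305)
  ndr4dq8 <- min(dr4, dq8)
  if (dr3 >= 1 && ndr4dq8 >= 1) return("DR3/DR4-DQ8")
  if (dr3 == 2) return("DR3/DR3")
  if (ndr4dq8 >= 2) return("DR4-DQ8/DR4-DQ8")
  if (ndr4dq8 == 1) return("DR4-DQ8/X")
  if (dr3 == 1) return("DR3/X")
  "X/X"
}
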