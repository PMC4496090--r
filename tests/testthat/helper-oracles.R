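# Independent oracles and small fixture builders used across the suite.

# Brute-force OLS via the normal equations: coefficients, SEs from the
# unbiased residual-variance estimate, two-sided t p-values.
ols_oracle <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  list(beta = as.numeric(beta), se = as.numeric(se),
       p = as.numeric(p), rss = sum(resid^2), df = df)
}

# Explicit RSS-ratio partial F between nested design matrices.
partial_f_oracle <- function(X_reduced, X_full, y) {
  rss_r <- ols_oracle(X_reduced, y)$rss
  full <- ols_oracle(X_full, y)
  df1 <- ncol(X_full) - ncol(X_reduced)
  stat <- ((rss_r - full$rss) / df1) / (full$rss / full$df)
  list(statistic = stat,
       p = stats::pf(stat, df1, full$df, lower.tail = FALSE))
}

# Grid-search maximum-likelihood oracle for the Hardy-Weinberg G-test:
# maximises the HWE-constrained multinomial log-likelihood over allele
# frequency (coarse grid refined by optimize), and compares it with the
# saturated log-likelihood.
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  counts <- c(n_aa, n_ab, n_bb)
  n <- sum(counts)
  loglik <- function(p) {
    probs <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
    sum(ifelse(counts > 0, counts * log(probs), 0))
  }
  grid <- seq(1e-9, 1 - 1e-9, length.out = 4001)
  best <- grid[which.max(vapply(grid, loglik, numeric(1)))]
  lo <- max(best - 1e-3, 1e-12)
  hi <- min(best + 1e-3, 1 - 1e-12)
  opt <- stats::optimize(loglik, c(lo, hi), maximum = TRUE, tol = 1e-12)
  ll_hwe <- max(opt$objective, loglik(best))
  ll_sat <- sum(ifelse(counts > 0, counts * log(counts / n), 0))
  max(2 * (ll_sat - ll_hwe), 0)
}

# Genotype matrix with controlled per-SNP missingness (first rows NA'd).
make_geno <- function(n_ind, n_missing_per_snp, seed = 42) {
  n_snps <- length(n_missing_per_snp)
  withr::with_seed(seed, {
    counts <- matrix(sample(0:2, n_ind * n_snps, replace = TRUE),
                     nrow = n_ind,
                     dimnames = list(sprintf("i%03d", seq_len(n_ind)),
                                     sprintf("s%02d", seq_len(n_snps))))
    counts <- matrix(as.double(counts), nrow = n_ind,
                     dimnames = dimnames(counts))
    for (j in seq_len(n_snps)) {
      k <- n_missing_per_snp[j]
      if (k > 0) counts[seq_len(k), j] <- NA_real_
    }
    geno_matrix(counts)
  })
}

# Small three-box ordering over generic continuous variables.
toy_ordering <- function() {
  chain_ordering(boxes = list("y", "m", c("x1", "x2")))
}

toy_data <- function(n = 200, seed = 1) {
  withr::with_seed(seed, {
    x1 <- rnorm(n); x2 <- rnorm(n)
    m <- 0.8 * x1 + rnorm(n)
    y <- 1.5 * m - 0.5 * x2 + rnorm(n)
    data.frame(y = y, m = m, x1 = x1, x2 = x2)
  })
}
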