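# Independent oracles, written against the definitions rather than the
# package's code paths, for cross-checking the fitting and QC routines.

# least squares via explicit normal equations
oracle_ols <- function(y, X) {
  Xi <- cbind(1, as.matrix(X))
  xtx_inv <- solve(t(Xi) %*% Xi)
  beta <- drop(xtx_inv %*% t(Xi) %*% y)
  resid <- y - drop(Xi %*% beta)
  sigma2 <- sum(resid^2) / (length(y) - ncol(Xi))
  list(beta = beta, se = sqrt(sigma2 * diag(xtx_inv)),
       rss = sum(resid^2))
}

# HWE chi-square via the binomial pmf for genotype probabilities
oracle_hwe_chi2 <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) return(0)
  expected <- n * dbinom(2:0, size = 2, prob = p)
  sum((c(n_AA, n_Aa, n_aa) - expected)^2 / expected)
}

# log odds ratio and its SE from a 2x2 table (a,b,c,d = exposed-case,
# exposed-control, unexposed-case, unexposed-control)
oracle_2x2 <- function(a, b, c, d) {
  list(log_or = log((a * d) / (b * c)),
       se = sqrt(1 / a + 1 / b + 1 / c + 1 / d))
}

# 2x2 table -> individual-level binary data
table_to_data <- function(a, b, c, d) {
  tibble::tibble(
    y = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)),
    x = c(rep(1, a + b), rep(0, c + d)))
}

# small complete-data cohort for pipeline tests, bypassing the generator
make_null_cohort <- function(n, seed, gamma = 0, beta_snp = 0) {
  cfg <- cohort_config(seed = seed, n_enrolled = n, dropout_n = 0L,
                       low_dna_n = 0L, gamma_interaction = gamma,
                       beta_snp = beta_snp)
  generate_cohort(cfg)
}

# join GRS profiles onto the phenotype/outcome tables
profile_table <- function(cohort) {
  prof <- grs_profiles(cohort)
  df <- dplyr::inner_join(cohort$participants, prof, by = "sample_id")
  dplyr::inner_join(df, cohort$neonates, by = "sample_id")
}
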