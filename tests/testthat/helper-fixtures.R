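# Shared fixtures and independent oracles, built in code at test time.

# Random positive-definite correlation matrix.
random_corr <- function(m, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(m * m), m)
  cov2cor(crossprod(A) + diag(m))
}

# Variant metadata table for m SNPs (non-palindromic by default).
toy_variants <- function(m, chrom = "1", spacing = 1000L, a1 = "A", a2 = "G") {
  data.frame(chrom = chrom, pos = seq_len(m) * spacing, a1 = a1, a2 = a2,
             stringsAsFactors = FALSE)
}

# Summary statistics table around given z-scores.
toy_stats <- function(z, n = 10000, variants = toy_variants(length(z))) {
  summary_stats(cbind(variants, data.frame(z = z, n = n)), quiet = TRUE)
}

# Direct 2m-dimensional Gaussian log-density of stacked (beta_x, beta_y)
# under the joint model covariance assembled from the marginal-statistic
# distributions; the independent oracle for the eigen-space likelihood.
mvn_loglik_oracle <- function(alpha, s2x, s2y, C, beta_x, beta_y, n_x, n_y,
                              adjust = TRUE) {
  m <- nrow(C)
  h2x <- m * s2x
  h2y <- m * s2y
  fx <- if (adjust) 1 - h2x else 1
  fy <- if (adjust) 1 - alpha^2 * h2x - h2y else 1
  C2 <- C %*% C
  Sxx <- s2x * C2 + C * fx / n_x
  Sxy <- alpha * s2x * C2
  Syy <- (alpha^2 * s2x + s2y) * C2 + C * fy / n_y
  S <- rbind(cbind(Sxx, Sxy), cbind(t(Sxy), Syy))
  v <- c(beta_x, beta_y)
  as.numeric(-m * log(2 * pi) - 0.5 * determinant(S)$modulus -
               0.5 * drop(v %*% solve(S, v)))
}

# Brute-force per-pair Pearson correlation of mean-imputed dosages.
pearson_brute <- function(dos) {
  m <- ncol(dos)
  G <- dos
  for (j in seq_len(m)) {
    mu <- mean(G[, j], na.rm = TRUE)
    G[is.na(G[, j]), j] <- mu
  }
  C <- diag(1, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      C[i, j] <- sum((G[, i] - mean(G[, i])) * (G[, j] - mean(G[, j]))) /
        sqrt(sum((G[, i] - mean(G[, i]))^2) * sum((G[, j] - mean(G[, j]))^2))
    }
  }
  C
}

# Simulate one replicate and fit MR-link-2, reusing a cached eigensystem.
fit_one_rep <- function(ld, spec, seed, cache, se = FALSE) {
  sets <- select_causal_sets(ld, spec$m_causal, spec$r2_min, spec$r2_max,
                             seed = seed)
  sim <- simulate_summary_stats(ld, spec, sets$exposure, sets$outcome,
                                seed = seed * 2 + 1, cache = cache)
  region <- prepare_region(sim$beta_x, sim$beta_y, ld$C, spec$n_x, spec$n_y,
                           eigen_C = cache$eigen)
  fit_mr_link2(region, se = se)
}
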