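test_that("synthetic LD is block-structured, PSD and deterministic", {
  ld <- synth_ld(m = 120, block_size = 30, rho = 0.9, seed = 1)
  expect_s3_class(ld, "ld_matrix")
  expect_equal(dim(ld$C), c(120L, 120L))
  ev <- eigen(ld$C, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
  off <- ld$C[upper.tri(ld$C)]
  expect_lt(max(off), 1)
  expect_gt(max(off), 0.8)          # adjacent within-block pairs

  expect_identical(synth_ld(m = 120, block_size = 30, rho = 0.9, seed = 1)$C,
                   ld$C)
  expect_false(identical(synth_ld(m = 120, block_size = 30, rho = 0.9,
                                  seed = 2)$C, ld$C))

  expect_equal(synth_ld(m = 15, rho = 0, seed = 1)$C, diag(15))
  expect_error(synth_ld(m = 10, rho = 1.2), "rho")
})

test_that("causal-set selection honors the LD window constraints", {
  ld <- synth_ld(m = 100, block_size = 25, rho = 0.92, seed = 2)
  r2 <- ld$C^2

  sets <- select_causal_sets(ld, 5, r2_min = 0.1, r2_max = 0.95, seed = 3)
  expect_false(is.null(sets))
  ex <- sets$exposure
  pair_r2 <- r2[ex, ex][upper.tri(diag(5))]
  expect_true(all(pair_r2 >= 0.1 & pair_r2 <= 0.95))
  for (o in sets$outcome) {
    expect_true(any(r2[o, ex] >= 0.1 & r2[o, ex] <= 0.95))
  }

  # unconstrained selection is plain sampling
  u <- select_causal_sets(ld, 10, seed = 4)
  expect_length(unique(u$exposure), 10)

  # no correlated pairs exist on an identity matrix: infeasible
  ld_id <- ld_matrix(diag(20), toy_variants(20))
  expect_null(select_causal_sets(ld_id, 3, r2_min = 0.1, r2_max = 0.95,
                                 seed = 5, max_restarts = 5))
})

test_that("realized genetic variances hit the target heritability exactly", {
  ld <- synth_ld(m = 50, block_size = 12, rho = 0.85, seed = 6)
  spec <- scenario(alpha = 0.1, h2x = 0.05, h2y = 0.003, m_causal = 7)
  sets <- select_causal_sets(ld, 7, seed = 7)
  sim <- simulate_summary_stats(ld, spec, sets$exposure, sets$outcome,
                                seed = 8)
  expect_equal(drop(sim$gamma_x %*% ld$C %*% sim$gamma_x), 0.05,
               tolerance = 1e-12)
  expect_equal(drop(sim$gamma_y %*% ld$C %*% sim$gamma_y), 0.003,
               tolerance = 1e-12)
  expect_equal(sum(sim$gamma_x != 0), 7L)
  expect_equal(sim$se_x, rep(1 / sqrt(1e4), 50))
})

test_that("simulated moments match the generative model", {
  m <- 40
  C <- synth_ld(m = m, block_size = 10, rho = 0.8, seed = 9)$C
  ld <- ld_matrix(C, toy_variants(m))
  spec <- scenario(alpha = 0, h2x = 0.1, h2y = 1e-20, m_causal = m,
                   n_x = 1e4, n_y = 3e5)
  cache <- cismr:::ld_cache(ld)

  # covariance of beta_x at fixed gamma matches C (1 - h2x)/n_x
  gx_fix <- select_causal_sets(ld, m, seed = 10)
  sims <- lapply(1:3000, function(r) {
    simulate_summary_stats(ld, spec, gx_fix$exposure, gx_fix$outcome,
                           seed = 20000 + r, cache = cache)
  })
  bx <- t(vapply(sims, `[[`, numeric(m), "beta_x"))
  # gamma differs per replicate; recentre on the replicate means is not
  # possible, so fix gamma by subtracting C gamma_x per replicate
  noise <- bx - t(vapply(sims, function(s) drop(C %*% s$gamma_x), numeric(m)))
  emp <- cov(noise)
  target <- C * (1 - 0.1) / 1e4
  expect_lt(max(abs(emp - target)), 6 * max(target) * sqrt(2 / 3000) + 2e-6)

  # null independence: beta_y is uncorrelated with beta_x across replicates
  by <- t(vapply(sims, `[[`, numeric(m), "beta_y"))
  cors <- vapply(seq_len(m), function(j) cor(bx[, j], by[, j]), numeric(1))
  expect_lt(max(abs(cors)), 0.08)

  # non-centrality: causal z-scores are inflated by ~ 1 + n h2/m at
  # identity LD relative to null SNPs
  ld_id <- ld_matrix(diag(m), toy_variants(m))
  spec_id <- scenario(alpha = 0, h2x = 0.1, h2y = 1e-20, m_causal = m)
  cache_id <- cismr:::ld_cache(ld_id)
  z2 <- replicate(1000, {
    s <- simulate_summary_stats(ld_id, spec_id, 1:m, 1:m, cache = cache_id)
    mean((s$beta_x / s$se_x)^2)
  })
  # E[z^2] = (1 - h2x) + n h2x / m with exact-rescaled gamma
  expect_equal(mean(z2), (1 - 0.1) + 1e4 * 0.1 / m, tolerance = 0.05)
})

test_that("reference LD sampling is unbiased and converges with panel size", {
  ld <- synth_ld(m = 30, block_size = 10, rho = 0.8, seed = 11)
  expect_identical(sample_reference_ld(ld, Inf), ld)

  big <- sample_reference_ld(ld, 1e5, seed = 12)
  expect_equal(big$n_ref, 1e5)
  expect_lt(max(abs(big$C - ld$C)), 0.02)

  draws <- lapply(1:400, function(r) {
    sample_reference_ld(ld, 1000, seed = 3000 + r)$C
  })
  avg <- Reduce(`+`, draws) / length(draws)
  expect_lt(max(abs(avg - ld$C)[upper.tri(avg)]), 0.01)
})

test_that("scenario runs are deterministic and respect completion filtering", {
  ld <- synth_ld(m = 50, block_size = 12, rho = 0.85, seed = 13)
  spec <- scenario(alpha = 0.1, h2x = 0.1, h2y = 1e-4, m_causal = 5)
  r1 <- simulate_scenario(ld, spec, n_reps = 5,
                          methods = c("mr_link2", "pca"), seed = 14)
  r2 <- simulate_scenario(ld, spec, n_reps = 5,
                          methods = c("mr_link2", "pca"), seed = 14)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 10L)

  # infeasible causal-set constraints yield zero rows, not an error
  ld_id <- ld_matrix(diag(30), toy_variants(30))
  spec_bad <- scenario(alpha = 0, h2x = 0.01, h2y = 1e-20, m_causal = 3,
                       r2_min = 0.2, r2_max = 0.9)
  expect_equal(nrow(simulate_scenario(ld_id, spec_bad, n_reps = 3, seed = 15)),
               0L)
})
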