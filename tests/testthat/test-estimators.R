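test_that("Wald ratio follows the delta-method form", {
  res <- mr_wald_ratio(0.5, 0.01, 0.1, 0.02)
  expect_equal(res$alpha, 0.2)
  expect_equal(res$se_alpha, 0.04)
  expect_equal(res$p_alpha, 2 * pnorm(-5))

  res0 <- mr_wald_ratio(0.5, 0.01, 0, 0.02)
  expect_equal(res0$alpha, 0)
  expect_equal(res0$p_alpha, 1)

  bad <- mr_wald_ratio(0, 0.01, 0.1, 0.02)
  expect_false(bad$converged)
  expect_true(is.na(bad$alpha))
})

test_that("IVW equals no-intercept WLS and degenerates to the Wald ratio", {
  set.seed(80)
  bx <- rnorm(6, 0.1, 0.03)
  by <- 0.3 * bx + rnorm(6, 0, 0.004)
  se_y <- runif(6, 0.003, 0.008)
  res <- mr_ivw(bx, by, se_y)
  wls <- lm(by ~ bx - 1, weights = 1 / se_y^2)
  expect_equal(res$alpha, unname(coef(wls)["bx"]), tolerance = 1e-12)
  expect_equal(res$se_alpha, 1 / sqrt(sum(bx^2 / se_y^2)), tolerance = 1e-12)

  # identical Wald ratios pool to that ratio
  res_same <- mr_ivw(c(0.2, 0.4), c(0.1, 0.2), c(0.01, 0.01))
  expect_equal(res_same$alpha, 0.5)

  res_1 <- mr_ivw(bx[1], by[1], se_y[1])
  expect_equal(res_1$alpha, by[1] / bx[1])
  expect_equal(res_1$se_alpha, se_y[1] / abs(bx[1]))
})

test_that("LD-aware IVW matches a naive GLS oracle and its limits", {
  set.seed(81)
  bx <- rnorm(5, 0.1, 0.03)
  by <- 0.25 * bx + rnorm(5, 0, 0.004)
  se_y <- runif(5, 0.003, 0.008)
  C <- random_corr(5, seed = 82)

  # naive matrix-inverse implementation
  Omega <- diag(se_y) %*% C %*% diag(se_y)
  Oi <- solve(Omega)
  alpha_naive <- drop(bx %*% Oi %*% by) / drop(bx %*% Oi %*% bx)
  res <- mr_ivw_ld(bx, by, se_y, C)
  expect_equal(res$alpha, alpha_naive, tolerance = 1e-10)
  expect_equal(res$se_alpha, 1 / sqrt(drop(bx %*% Oi %*% bx)),
               tolerance = 1e-10)

  # identity LD reduces exactly to IVW
  res_id <- mr_ivw_ld(bx, by, se_y, diag(5))
  res_ivw <- mr_ivw(bx, by, se_y)
  expect_equal(res_id$alpha, res_ivw$alpha, tolerance = 1e-12)
  expect_equal(res_id$se_alpha, res_ivw$se_alpha, tolerance = 1e-12)

  # two near-duplicate instruments collapse to the single Wald ratio
  C2 <- matrix(c(1, 0.999, 0.999, 1), 2)
  res_dup <- mr_ivw_ld(c(0.2, 0.2), c(0.05, 0.05), c(0.01, 0.01), C2)
  wald <- mr_wald_ratio(0.2, NA, 0.05, 0.01)
  expect_equal(res_dup$alpha, wald$alpha, tolerance = 1e-6)
  expect_equal(res_dup$se_alpha, wald$se_alpha, tolerance = 0.05 * wald$se_alpha)
})

test_that("PCA-IVW reduces to GLS at full retention and to ratios at rank 1", {
  set.seed(83)
  m <- 8
  C <- random_corr(m, seed = 84)
  bx <- rnorm(m, 0.08, 0.02)
  by <- 0.3 * bx + rnorm(m, 0, 0.003)
  se_y <- rep(1 / sqrt(3e5), m)
  res_full <- mr_pca(bx, by, se_y, C, variance_kept = 1)
  res_gls <- mr_ivw_ld(bx, by, se_y, C)
  expect_equal(res_full$alpha, res_gls$alpha, tolerance = 1e-8)
  expect_equal(res_full$se_alpha, res_gls$se_alpha, tolerance = 1e-8)

  # rank-1 LD: single component, estimate equals the projected Wald ratio
  ones <- matrix(1, 4, 4)
  bx1 <- rep(0.1, 4); by1 <- rep(0.04, 4)
  res_r1 <- mr_pca(bx1, by1, rep(0.01, 4), ones, variance_kept = 0.99)
  expect_equal(res_r1$components, 1L)
  expect_equal(res_r1$alpha, 0.4, tolerance = 1e-8)
})

test_that("all estimators are equivariant under joint sign flips", {
  set.seed(85)
  bx <- rnorm(5, 0.1, 0.03)
  by <- 0.2 * bx + rnorm(5, 0, 0.004)
  se_y <- runif(5, 0.003, 0.008)
  C <- random_corr(5, seed = 86)
  expect_equal(mr_ivw(-bx, -by, se_y)$alpha, mr_ivw(bx, by, se_y)$alpha)
  expect_equal(mr_ivw_ld(-bx, -by, se_y, C)$alpha,
               mr_ivw_ld(bx, by, se_y, C)$alpha)
  expect_equal(mr_pca(-bx, -by, se_y, C)$alpha, mr_pca(bx, by, se_y, C)$alpha)
  expect_equal(mr_wald_ratio(-bx[1], NA, -by[1], se_y[1])$alpha,
               mr_wald_ratio(bx[1], NA, by[1], se_y[1])$alpha)
})

test_that("estimators recover the simulated causal effect without pleiotropy", {
  ld <- synth_ld(m = 80, block_size = 20, rho = 0.85, seed = 87)
  spec <- scenario(alpha = 0.2, h2x = 0.1, h2y = 1e-20, m_causal = 10)
  res <- simulate_scenario(ld, spec, n_reps = 30,
                           methods = c("ivw", "ivw_ld", "pca"), seed = 88)
  for (meth in c("ivw", "ivw_ld", "pca")) {
    a <- res$alpha[res$method == meth]
    mc_se <- sd(a) / sqrt(length(a))
    expect_lt(abs(mean(a) - 0.2), 2 * mc_se + 0.01)
  }
})
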