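test_that("the free optimum always dominates the constrained ones", {
  ld <- synth_ld(m = 80, block_size = 20, rho = 0.85, seed = 70)
  cache <- cismr:::ld_cache(ld)
  specs <- list(
    scenario(alpha = 0, h2x = 0.01, h2y = 1e-20, m_causal = 5),
    scenario(alpha = 0.2, h2x = 0.1, h2y = 0.001, m_causal = 5),
    scenario(alpha = -0.1, h2x = 0.05, h2y = 0.01, m_causal = 80)
  )
  for (spec in specs) {
    for (r in 1:5) {
      fit <- fit_one_rep(ld, spec, seed = 100 * r + 1, cache = cache)
      expect_gte(fit$ll_full, fit$ll_alpha0 - 1e-6)
      expect_gte(fit$ll_full, fit$ll_sigy0 - 1e-6)
      expect_true(fit$p_alpha > 0 && fit$p_alpha <= 1)
      expect_true(fit$p_h2y > 0 && fit$p_h2y <= 1)
      expect_gte(fit$h2x, 0)
      expect_gte(fit$h2y, 0)
    }
  }
})

test_that("no outcome signal drives the causal estimate to zero", {
  ld <- synth_ld(m = 60, block_size = 15, rho = 0.8, seed = 71)
  spec <- scenario(alpha = 0, h2x = 0.1, h2y = 1e-20, m_causal = 10)
  sets <- select_causal_sets(ld, 10, seed = 5)
  sim <- simulate_summary_stats(ld, spec, sets$exposure, sets$outcome,
                                seed = 6)
  region <- prepare_region(sim$beta_x, rep(0, 60), ld$C, 1e4, 3e5)
  fit <- fit_mr_link2(region, se = FALSE)
  expect_lt(abs(fit$alpha), 1e-3)
})

test_that("estimates are equivariant under joint sample-size/noise rescaling", {
  C <- random_corr(30, seed = 72)
  ld <- ld_matrix(C, toy_variants(30))
  spec <- scenario(alpha = 0.15, h2x = 0.1, h2y = 1e-20, m_causal = 30)
  sim <- simulate_summary_stats(ld, spec, 1:30, 1:30, seed = 73)
  scale <- 4
  r1 <- prepare_region(sim$beta_x, sim$beta_y, C, 1e4, 3e5)
  r2 <- prepare_region(sim$beta_x / sqrt(scale), sim$beta_y / sqrt(scale),
                       C, 1e4 * scale, 3e5 * scale)
  f1 <- fit_mr_link2(r1, adjust_n = FALSE, se = FALSE)
  f2 <- fit_mr_link2(r2, adjust_n = FALSE, se = FALSE)
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-3)
  expect_equal(f1$h2x, f2$h2x * scale, tolerance = 1e-2)
})

test_that("causal effects are recovered and the se tracks sampling spread", {
  ld <- synth_ld(m = 100, block_size = 25, rho = 0.85, seed = 74)
  cache <- cismr:::ld_cache(ld)
  spec <- scenario(alpha = 0.2, h2x = 0.1, h2y = 1e-20, m_causal = 10)
  fits <- lapply(1:40, function(r) {
    fit_one_rep(ld, spec, seed = 1000 + r, cache = cache, se = TRUE)
  })
  alphas <- vapply(fits, `[[`, numeric(1), "alpha")
  ses <- vapply(fits, `[[`, numeric(1), "se_alpha")
  mc_se <- sd(alphas) / sqrt(length(alphas))
  expect_lt(abs(mean(alphas) - 0.2), 2 * mc_se + 0.005)
  # the curvature-based se should be on the scale of the empirical spread
  expect_gt(median(ses, na.rm = TRUE), 0.2 * sd(alphas))
  expect_lt(median(ses, na.rm = TRUE), 5 * sd(alphas))
  expect_true(all(vapply(fits, `[[`, logical(1), "converged")))
})

test_that("the fitting front end accepts summary_stats and keeps the region", {
  ld <- synth_ld(m = 40, block_size = 10, rho = 0.8, seed = 75)
  spec <- scenario(alpha = 0.2, h2x = 0.1, h2y = 1e-20, m_causal = 40)
  sim <- simulate_summary_stats(ld, spec, 1:40, 1:40, seed = 76)
  ex <- summary_stats(cbind(ld$variants,
                            data.frame(z = sim$beta_x / sim$se_x, n = 1e4)),
                      quiet = TRUE)
  ou <- summary_stats(cbind(ld$variants,
                            data.frame(z = sim$beta_y / sim$se_y, n = 3e5)),
                      quiet = TRUE)
  fit <- mr_link2(ex, ou, ld)
  expect_s3_class(fit, "mr_link2")
  expect_equal(fit$n_x, 1e4)
  expect_s3_class(fit$region, "region_eigen")
  expect_output(print(fit), "MR-link-2")
  expect_named(coef(fit), c("alpha", "h2x", "h2y"))
  expect_equal(unname(confint(fit)[1, 2] - confint(fit)[1, 1]),
               2 * qnorm(0.975) * fit$se_alpha, tolerance = 1e-10)

  # parametric-bootstrap simulation reproduces the marginal scale
  reps <- simulate(fit, nsim = 5, seed = 77)
  expect_length(reps, 5)
  expect_length(reps[[1]]$beta_x, 40)
})
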