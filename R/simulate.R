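# Generative simulator for regional GWAS summary statistics: synthetic
# block-structured LD, LD-constrained causal-SNP selection, marginal-effect
# simulation under the joint exposure/outcome model, and Wishart-style
# sampling of imprecise LD references.

#' Describe one simulation scenario
#'
#' Bundles the generative parameters of a regional two-trait simulation:
#' causal effect `alpha`, exposure cis-heritability `h2x`, pleiotropic
#' outcome heritability `h2y`, the causal-SNP count `m_causal` per trait, the
#' LD (r-squared) bounds between causal SNPs, the LD-reference size `n_ref`
#' (`Inf` = exact), and the GWAS sample sizes. Defaults mirror a molecular
#' exposure measured in 10,000 individuals against an outcome measured in
#' 300,000.
#'
#' @param alpha causal effect of the exposure on the outcome.
#' @param h2x exposure cis-heritability in the region.
#' @param h2y pleiotropic (direct) outcome heritability in the region.
#' @param m_causal number of causal SNPs per trait.
#' @param r2_min,r2_max bounds on the squared correlation between causal SNPs
#'   (defaults 0 and 1: unconstrained placement).
#' @param n_ref LD reference panel size; `Inf` for exactly known LD.
#' @param n_x,n_y exposure and outcome GWAS sample sizes.
#' @return A `scenario` object (named list).
#' @export
scenario <- function(alpha = 0, h2x = 0.01, h2y = 1e-20, m_causal = 10,
                     r2_min = 0, r2_max = 1, n_ref = Inf,
                     n_x = 10000, n_y = 300000) {
  stopifnot(h2x >= 0, h2y >= 0, m_causal >= 1,
            r2_min >= 0, r2_max <= 1, r2_min <= r2_max)
  if (1 - alpha^2 * h2x - h2y <= 0 || h2x >= 1) {
    stop("scenario implies non-positive noise variance")
  }
  structure(list(alpha = alpha, h2x = h2x, h2y = h2y, m_causal = m_causal,
                 r2_min = r2_min, r2_max = r2_max, n_ref = n_ref,
                 n_x = n_x, n_y = n_y),
            class = "scenario")
}

#' Synthetic block-structured LD matrix
#'
#' Builds a haplotype-block-like correlation matrix: variant positions are
#' split into blocks with Poisson-distributed lengths around `block_size`,
#' and within each block the correlation decays as `rho^|i-j|`
#' (autoregressive), which is positive definite by construction; different
#' blocks are uncorrelated. Variant metadata (chromosome 10 positions at
#' 1.5 kb spacing, non-palindromic alleles) and Uniform(0.05, 0.5) MAFs are
#' attached. Deterministic given `seed`.
#'
#' @param m number of SNPs.
#' @param block_size mean LD-block length in SNPs.
#' @param rho within-block per-step correlation decay, in `[0, 1)`; 0 gives
#'   an identity matrix.
#' @param seed RNG seed.
#' @return An [ld_matrix] with `n_ref = Inf`.
#' @export
synth_ld <- function(m, block_size = 50, rho = 0.9, seed = 1) {
  if (!is_scalar_number(rho) || rho < 0 || rho >= 1) {
    stop("rho must lie in [0, 1)")
  }
  stopifnot(m >= 1)
  with_seed(seed, {
    sizes <- integer(0)
    while (sum(sizes) < m) {
      sizes <- c(sizes, max(2L, stats::rpois(1, block_size)))
    }
    sizes[length(sizes)] <- m - sum(sizes[-length(sizes)])
    sizes <- sizes[sizes > 0]
    C <- matrix(0, m, m)
    at <- 0L
    for (s in sizes) {
      idx <- at + seq_len(s)
      C[idx, idx] <- rho^abs(outer(seq_len(s), seq_len(s), `-`))
      at <- at + s
    }
    variants <- data.frame(
      chrom = "10",
      pos = 1000000L + (seq_len(m) - 1L) * 1500L,
      a1 = "A", a2 = "G",
      stringsAsFactors = FALSE
    )
    ld_matrix(C, variants, n_ref = Inf, maf = stats::runif(m, 0.05, 0.5))
  })
}

#' Select causal SNP sets under LD constraints
#'
#' The exposure set is built iteratively: the first SNP is drawn uniformly;
#' each further SNP is drawn from the SNPs whose squared correlation to every
#' previously selected SNP lies within `[r2_min, r2_max]`. The outcome set is
#' then drawn from SNPs within the same LD window of at least one exposure
#' causal SNP. With bounds (0, 1) both selections are uniform over the
#' region. Infeasible constraints (after bounded restarts) return `NULL`, so
#' the scenario can be skipped and logged.
#'
#' @param ld an [ld_matrix].
#' @param m_causal causal SNP count per trait.
#' @param r2_min,r2_max squared-correlation bounds.
#' @param seed RNG seed.
#' @param max_restarts restarts of the greedy selection before giving up.
#' @return list with integer vectors `exposure` and `outcome`, or `NULL` if
#'   infeasible.
#' @export
select_causal_sets <- function(ld, m_causal, r2_min = 0, r2_max = 1,
                               seed = NULL, max_restarts = 100) {
  C <- ld$C
  m <- nrow(C)
  stopifnot(m_causal <= m)
  with_seed(seed, {
    r2 <- C^2
    unconstrained <- r2_min <= 0 && r2_max >= 1
    if (unconstrained) {
      return(list(exposure = sort(sample.int(m, m_causal)),
                  outcome = sort(sample.int(m, m_causal))))
    }
    pick_exposure <- function() {
      sel <- sample.int(m, 1)
      while (length(sel) < m_causal) {
        ok <- setdiff(which(apply(r2[, sel, drop = FALSE], 1, function(r) {
          all(r >= r2_min & r <= r2_max)
        })), sel)
        if (length(ok) == 0L) return(NULL)
        sel <- c(sel, if (length(ok) == 1L) ok else sample(ok, 1))
      }
      sel
    }
    for (i in seq_len(max_restarts)) {
      ex <- pick_exposure()
      if (is.null(ex)) next
      cand <- which(apply(r2[, ex, drop = FALSE], 1, function(r) {
        any(r >= r2_min & r <= r2_max)
      }))
      if (length(cand) < m_causal) next
      ou <- if (length(cand) == m_causal) cand else sort(sample(cand, m_causal))
      return(list(exposure = sort(ex), outcome = ou))
    }
    NULL
  })
}

# Cache of simulation ingredients for one LD matrix: upper Cholesky factor
# for correlated-noise draws and the eigendecomposition for MR-link-2.
ld_cache <- function(ld) {
  C <- symmetrize(ld$C)
  R <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(R)) {
    # PSD repair for rank-deficient C before the noise draws
    ev <- eigen(C, symmetric = TRUE)
    vals <- pmax(ev$values, 0)
    R <- t(ev$vectors %*% (sqrt(vals) * t(ev$vectors)))
    message("[cismr] LD matrix repaired to PSD before Cholesky")
  }
  list(C = C, R = R, eigen = eigen(C, symmetric = TRUE))
}

#' Simulate marginal summary statistics for one replicate
#'
#' Draws sparse multivariable effects `gamma ~ N(0, h2/m_causal)` at the
#' causal SNPs, rescales them so the realized regional genetic variance
#' `gamma' C gamma` equals the target heritability exactly, and forms
#' marginal effects
#' `beta_x = C gamma_x + eta_x`, `eta_x ~ N(0, C (1 - h2x)/n_x)` and
#' `beta_y = C (alpha gamma_x + gamma_y) + eta_y`,
#' `eta_y ~ N(0, C (1 - alpha^2 h2x - h2y)/n_y)`. Standard errors are the
#' theoretical `1/sqrt(n)` of standardized effects.
#'
#' @param ld an [ld_matrix] (the true LD used to generate the data).
#' @param spec a [scenario].
#' @param causal_x,causal_y integer indices of the causal SNPs per trait.
#' @param seed RNG seed (optional; draws from the current stream when NULL).
#' @param cache optional precomputed [ld_cache] ingredients (internal reuse
#'   across replicates).
#' @return list with `beta_x`, `beta_y`, `se_x`, `se_y`, `gamma_x`,
#'   `gamma_y`.
#' @export
simulate_summary_stats <- function(ld, spec, causal_x, causal_y, seed = NULL,
                                   cache = NULL) {
  cache <- cache %||% ld_cache(ld)
  C <- cache$C
  R <- cache$R
  m <- nrow(C)
  draw_gamma <- function(idx, h2) {
    g <- numeric(m)
    if (h2 <= 0) return(g)
    g[idx] <- stats::rnorm(length(idx), 0, sqrt(h2 / length(idx)))
    vg <- drop(g %*% C %*% g)
    if (vg > 0) g <- g * sqrt(h2 / vg)
    g
  }
  with_seed(seed, {
    gx <- draw_gamma(causal_x, spec$h2x)
    gy <- draw_gamma(causal_y, spec$h2y)
    noise <- function(scale) drop(crossprod(R, stats::rnorm(m))) * sqrt(scale)
    vx <- (1 - spec$h2x) / spec$n_x
    vy <- (1 - spec$alpha^2 * spec$h2x - spec$h2y) / spec$n_y
    if (vx <= 0 || vy <= 0) stop("non-positive noise variance in scenario")
    beta_x <- drop(C %*% gx) + noise(vx)
    beta_y <- drop(C %*% (spec$alpha * gx + gy)) + noise(vy)
    list(beta_x = beta_x, beta_y = beta_y,
         se_x = rep(1 / sqrt(spec$n_x), m),
         se_y = rep(1 / sqrt(spec$n_y), m),
         gamma_x = gx, gamma_y = gy)
  })
}

#' Sample an imprecise LD reference
#'
#' Emulates LD measured in a finite reference panel: draws `n_ref` latent
#' Gaussian vectors with covariance `C` and returns their sample correlation
#' matrix (equivalent in distribution to Wishart sampling followed by
#' renormalization to unit diagonal, and valid for `n_ref < m`). A
#' non-positive-definite input is repaired by escalating diagonal
#' regularization capped at 0.5 before sampling. `n_ref = Inf` returns the
#' input unchanged.
#'
#' @param ld an [ld_matrix] holding the true correlations.
#' @param n_ref reference panel size.
#' @param seed RNG seed.
#' @return An [ld_matrix] with `n_ref` recorded.
#' @export
sample_reference_ld <- function(ld, n_ref, seed = NULL) {
  if (is.infinite(n_ref)) return(ld)
  stopifnot(n_ref >= 2)
  C <- symmetrize(ld$C)
  R <- NULL
  for (d in c(0, 1e-8, 1e-4, 1e-2, 0.1, 0.5)) {
    R <- tryCatch(chol(C + diag(d, nrow(C))), error = function(e) NULL)
    if (!is.null(R)) {
      if (d > 0) {
        message(sprintf("[cismr] LD regularized with diagonal constant %g", d))
      }
      break
    }
  }
  if (is.null(R)) {
    stop("LD matrix not positive definite even after diagonal regularization of 0.5")
  }
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n_ref * nrow(C)), nrow = n_ref)
    X <- Z %*% R
    Chat <- stats::cor(X)
    dimnames(Chat) <- NULL
    ld_matrix(Chat, ld$variants, n_ref = n_ref, maf = ld$maf)
  })
}

#' Run one simulation scenario across replicates and methods
#'
#' For each replicate: select causal sets, simulate summary statistics under
#' the scenario, (optionally) sample an imprecise LD reference, and apply the
#' requested estimators. MR-link-2 is fitted on all regional SNPs;
#' IVW/Wald-ratio instruments are clumped at `p <= 5e-8`, `r2 < 0.01` within
#' the region; IVW-LD uses the same instruments with their LD; PCA uses all
#' SNPs. Scenarios where causal-set selection is infeasible return zero rows.
#'
#' @param ld an [ld_matrix] for the region (true LD).
#' @param spec a [scenario].
#' @param n_reps number of replicates.
#' @param methods subset of `c("mr_link2", "ivw", "ivw_ld", "pca")`.
#' @param seed RNG seed for the whole run (replicate r uses `seed + r`).
#' @param variance_kept eigencomponent retention for MR-link-2.
#' @param se compute se(alpha) for MR-link-2 fits (slower; default FALSE).
#' @return data.frame with one row per replicate x method: estimates, P
#'   values and convergence flags.
#' @export
simulate_scenario <- function(ld, spec, n_reps, methods = "mr_link2",
                              seed = 1, variance_kept = 0.99, se = FALSE) {
  stopifnot(inherits(spec, "scenario"))
  methods <- match.arg(methods, c("mr_link2", "ivw", "ivw_ld", "pca"),
                       several.ok = TRUE)
  cache <- ld_cache(ld)
  exact_ld <- is.infinite(spec$n_ref)
  rows <- vector("list", n_reps * length(methods))
  ri <- 0L
  for (r in seq_len(n_reps)) {
    rep_seed <- seed + r
    sets <- select_causal_sets(ld, spec$m_causal, spec$r2_min, spec$r2_max,
                               seed = rep_seed)
    if (is.null(sets)) next
    sim <- simulate_summary_stats(ld, spec, sets$exposure, sets$outcome,
                                  seed = rep_seed * 2L + 1L, cache = cache)
    ref <- if (exact_ld) ld else {
      sample_reference_ld(ld, spec$n_ref, seed = rep_seed * 2L)
    }
    ref_eigen <- if (exact_ld) cache$eigen else NULL
    for (method in methods) {
      res <- fit_one_method(method, sim, ref, spec, variance_kept,
                            ref_eigen, se)
      if (is.null(res)) next
      df <- as.data.frame(res)
      df$replicate <- r
      ri <- ri + 1L
      rows[[ri]] <- df
    }
  }
  if (ri == 0L) {
    return(data.frame())
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  rownames(out) <- NULL
  out
}

# Dispatch one estimator on one simulated replicate.
fit_one_method <- function(method, sim, ref, spec, variance_kept, ref_eigen,
                           se) {
  if (method == "mr_link2") {
    region <- prepare_region(sim$beta_x, sim$beta_y, ref$C, spec$n_x,
                             spec$n_y, variance_kept = variance_kept,
                             eigen_C = ref_eigen)
    return(fit_mr_link2(region, se = se))
  }
  z <- sim$beta_x / sim$se_x
  p <- clip_p(2 * stats::pnorm(-abs(z)))
  if (method %in% c("ivw", "ivw_ld")) {
    stats_df <- data.frame(chrom = ref$variants$chrom, pos = ref$variants$pos,
                           p = p)
    iv <- select_instruments(stats_df, ref)
    if (length(iv) == 0L) return(NULL)
    if (method == "ivw") {
      if (length(iv) == 1L) {
        return(mr_wald_ratio(sim$beta_x[iv], sim$se_x[iv],
                             sim$beta_y[iv], sim$se_y[iv]))
      }
      return(mr_ivw(sim$beta_x[iv], sim$beta_y[iv], sim$se_y[iv]))
    }
    return(mr_ivw_ld(sim$beta_x[iv], sim$beta_y[iv], sim$se_y[iv],
                     ref$C[iv, iv, drop = FALSE]))
  }
  mr_pca(sim$beta_x, sim$beta_y, sim$se_y, ref$C,
         variance_kept = variance_kept)
}
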