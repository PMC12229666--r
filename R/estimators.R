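# Benchmark cis-MR estimators operating on harmonized regional summary
# statistics: single-instrument Wald ratio, fixed-effect IVW over independent
# instruments, LD-aware IVW (generalized least squares), and
# principal-component IVW over all regional SNPs.

cis_mr_result <- function(method, alpha, se, m_snps, converged = TRUE) {
  structure(
    list(method = method,
         alpha = alpha,
         se_alpha = se,
         p_alpha = clip_p(2 * stats::pnorm(-abs(alpha / se))),
         m_snps = as.integer(m_snps),
         converged = converged),
    class = "cis_mr"
  )
}

#' Wald-ratio causal estimate from a single instrument
#'
#' `alpha = by / bx` with first-order (delta-method) standard error
#' `se_y / |bx|` and a two-sided normal P value.
#'
#' @param bx,se_x exposure effect and its standard error.
#' @param by,se_y outcome effect and its standard error.
#' @return A `cis_mr` result.
#' @export
mr_wald_ratio <- function(bx, se_x, by, se_y) {
  stopifnot(length(bx) == 1, length(by) == 1)
  if (bx == 0) {
    return(cis_mr_result("wald_ratio", NA_real_, NA_real_, 1L,
                         converged = FALSE))
  }
  cis_mr_result("wald_ratio", by / bx, se_y / abs(bx), 1L)
}

#' Fixed-effect inverse-variance-weighted MR over independent instruments
#'
#' Weighted least squares of `by` on `bx` without intercept with weights
#' `se_y^-2`: `alpha = sum(bx by / se_y^2) / sum(bx^2 / se_y^2)`. Falls back
#' to the Wald ratio for a single instrument.
#'
#' @param bx exposure effects at the instruments.
#' @param by outcome effects.
#' @param se_y outcome standard errors.
#' @return A `cis_mr` result.
#' @export
mr_ivw <- function(bx, by, se_y) {
  stopifnot(length(bx) == length(by), length(by) == length(se_y))
  if (length(bx) == 0L) stop("no instruments supplied")
  if (length(bx) == 1L) {
    res <- mr_wald_ratio(bx, NA_real_, by, se_y)
    res$method <- "ivw"
    return(res)
  }
  w <- 1 / se_y^2
  denom <- sum(w * bx^2)
  cis_mr_result("ivw", sum(w * bx * by) / denom, 1 / sqrt(denom), length(bx))
}

# Invert a covariance matrix, ridge-repairing near-singularity by adding an
# escalating diagonal constant (1e-8 * mean diagonal, x10 per step, capped at
# 1e-4 * mean diagonal), with a warning when repair was needed.
solve_ridged <- function(Omega) {
  scale <- mean(diag(Omega))
  for (eps in c(0, scale * 10^seq(-8, -4))) {
    Om <- Omega + diag(eps, nrow(Omega))
    inv <- tryCatch(solve(Om), error = function(e) NULL)
    if (!is.null(inv)) {
      if (eps > 0) {
        warning(sprintf("singular instrument covariance; ridge %.1e applied",
                        eps))
      }
      return(inv)
    }
  }
  stop("instrument covariance matrix is singular beyond ridge repair")
}

#' LD-aware inverse-variance-weighted MR
#'
#' Generalized least squares of `by` on `bx` with error covariance
#' `Omega = diag(se_y) C diag(se_y)`, where `C` is the LD between the
#' instruments: `alpha = (bx' Omega^-1 by) / (bx' Omega^-1 bx)`. Reduces to
#' [mr_ivw()] when `C` is the identity.
#'
#' @inheritParams mr_ivw
#' @param C instrument LD (correlation) submatrix.
#' @return A `cis_mr` result.
#' @export
mr_ivw_ld <- function(bx, by, se_y, C) {
  if (inherits(C, "ld_matrix")) C <- C$C
  C <- as.matrix(C)
  stopifnot(length(bx) == nrow(C), length(by) == length(bx),
            length(se_y) == length(bx))
  Omega_inv <- solve_ridged(outer(se_y, se_y) * C)
  denom <- drop(bx %*% Omega_inv %*% bx)
  if (denom <= 0) {
    return(cis_mr_result("ivw_ld", NA_real_, NA_real_, length(bx),
                         converged = FALSE))
  }
  cis_mr_result("ivw_ld", drop(bx %*% Omega_inv %*% by) / denom,
                1 / sqrt(denom), length(bx))
}

#' Principal-component IVW over all regional SNPs
#'
#' Computes principal components of the weighted LD matrix
#' `Phi = (bx/se_y) (bx/se_y)' * C`, keeps the leading components explaining
#' `variance_kept` of its variance, projects `bx`, `by` and the outcome error
#' covariance into component space, and applies GLS there. With full component
#' retention this is identical to [mr_ivw_ld()] on all SNPs.
#'
#' @inheritParams mr_ivw_ld
#' @param variance_kept fraction of the weighted-LD variance retained
#'   (default 0.99).
#' @return A `cis_mr` result.
#' @export
mr_pca <- function(bx, by, se_y, C, variance_kept = 0.99) {
  if (inherits(C, "ld_matrix")) C <- C$C
  C <- as.matrix(C)
  m <- length(bx)
  stopifnot(m >= 2, nrow(C) == m)
  w <- bx / se_y
  if (all(w == 0)) {
    return(cis_mr_result("pca", NA_real_, NA_real_, m, converged = FALSE))
  }
  Phi <- outer(w, w) * C
  ev <- eigen(symmetrize(Phi), symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  k <- which(cumsum(lam) >= variance_kept * sum(lam))[1]
  V <- ev$vectors[, seq_len(k), drop = FALSE]
  bx0 <- drop(crossprod(V, bx))
  by0 <- drop(crossprod(V, by))
  Omega0 <- crossprod(V, (outer(se_y, se_y) * C)) %*% V
  Oi <- solve_ridged(Omega0)
  denom <- drop(bx0 %*% Oi %*% bx0)
  if (denom <= 0) {
    return(cis_mr_result("pca", NA_real_, NA_real_, m, converged = FALSE))
  }
  res <- cis_mr_result("pca", drop(bx0 %*% Oi %*% by0) / denom,
                       1 / sqrt(denom), m)
  res$components <- k
  res
}
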