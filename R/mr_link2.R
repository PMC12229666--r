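# The MR-link-2 likelihood: eigen-space preparation of a regional LD matrix,
# the log-likelihood over rotated summary statistics, three constrained
# maximizations, and likelihood-ratio inference for the causal effect (alpha)
# and the pleiotropic variance component (h2_Y).
#
# Model, on the standardized-effect scale: per-variant multivariable effects
# gamma_X ~ N(0, s2x) and gamma_Y ~ N(0, s2y) for all m variants in a region,
# with regional heritabilities h2x = m * s2x (exposure) and h2y = m * s2y
# (pleiotropy, outcome effects not mediated by the exposure). Marginal GWAS
# estimates are beta_X = C gamma_X + eta_X, beta_Y = C (alpha gamma_X +
# gamma_Y) + eta_Y with eta_X ~ N(0, C (1 - h2x) / nX) and eta_Y ~
# N(0, C (1 - alpha^2 h2x - h2y) / nY). In the eigenbasis C = U L U' the
# rotated statistics (dX_i, dY_i) = (U' beta_X, U' beta_Y)_i are independent
# bivariate Gaussians, which makes the likelihood a sum of m cheap terms.

#' Prepare a region for MR-link-2
#'
#' Eigendecomposes the regional LD matrix, retains the smallest set of leading
#' components whose eigenvalue sum reaches `variance_kept` of the trace, and
#' rotates the effect vectors into the retained eigenbasis.
#'
#' @param beta_x,beta_y standardized marginal effect vectors, aligned with `C`.
#' @param C regional LD matrix (an [ld_matrix] or a plain correlation matrix).
#' @param n_x,n_y exposure and outcome GWAS sample sizes.
#' @param variance_kept fraction of LD variance the retained eigencomponents
#'   must explain (default 0.99).
#' @param eigen_C optional precomputed `eigen(C, symmetric = TRUE)` result,
#'   reused across replicates sharing an LD matrix.
#' @return A `region_eigen` object: `lambdas`, `U`, `delta_x`, `delta_y`, `m`
#'   (retained components), `m_full` (regional SNP count), `n_x`, `n_y`.
#' @export
prepare_region <- function(beta_x, beta_y, C, n_x, n_y,
                           variance_kept = 0.99, eigen_C = NULL) {
  if (inherits(C, "ld_matrix")) C <- C$C
  m_full <- nrow(C)
  stopifnot(length(beta_x) == m_full, length(beta_y) == m_full,
            is_scalar_number(n_x), is_scalar_number(n_y))
  if (is.null(eigen_C)) eigen_C <- eigen(symmetrize(C), symmetric = TRUE)
  lam <- eigen_C$values
  if (any(lam < -1e-8)) {
    warning("LD matrix has negative eigenvalues; clipping to zero")
  }
  lam[lam < 0] <- 0
  total <- sum(lam)
  k <- which(cumsum(lam) >= variance_kept * total)[1]
  keep <- seq_len(k)
  keep <- keep[lam[keep] > 0]
  U <- eigen_C$vectors[, keep, drop = FALSE]
  dx <- drop(crossprod(U, beta_x))
  dy <- drop(crossprod(U, beta_y))
  lams <- lam[keep]
  structure(
    list(lambdas = lams,
         U = U,
         delta_x = dx,
         delta_y = dy,
         m = length(keep),
         m_full = m_full,
         n_x = n_x,
         n_y = n_y,
         # cached cross-terms for fast likelihood evaluation
         lam2 = lams * lams,
         dx2 = dx * dx,
         dy2 = dy * dy,
         dxdy = dx * dy),
    class = "region_eigen"
  )
}

# Effective sample sizes for the generative noise model: the marginal-statistic
# noise has covariance C (1 - h2x)/nX and C (1 - alpha^2 h2x - h2y)/nY, which
# enters the eigen-space likelihood purely as a rescaling of nX, nY.
effective_n <- function(alpha, s2x, s2y, m_full, n_x, n_y, adjust_n) {
  if (!adjust_n) return(list(nx = n_x, ny = n_y))
  h2x <- m_full * s2x
  fy <- 1 - alpha^2 * h2x - m_full * s2y
  fx <- 1 - h2x
  if (fx <= 0 || fy <= 0) return(NULL)
  list(nx = n_x / fx, ny = n_y / fy)
}

#' MR-link-2 log-likelihood
#'
#' Log-density of the rotated summary statistics under the MR-link-2 model,
#' evaluated as a sum of independent per-eigencomponent bivariate Gaussian
#' terms with covariance
#' \deqn{\Sigma_i = \begin{pmatrix} \sigma^2_X \lambda_i^2 + \lambda_i/n_X &
#'   \alpha \sigma^2_X \lambda_i^2 \\ \cdot & (\alpha^2 \sigma^2_X +
#'   \sigma^2_Y) \lambda_i^2 + \lambda_i/n_Y \end{pmatrix}.}
#' This is algebraically identical to the eigen-space closed form written as
#' log-determinant sums and D-weighted quadratic forms (see
#' `ll_mr_link2_terms` in the sources), but remains finite as
#' \eqn{\sigma^2_Y \to 0}, so the constrained fit evaluates the exact limit
#' rather than a small-epsilon approximation.
#'
#' @param alpha causal effect.
#' @param s2x per-variant exposure effect variance (> 0).
#' @param s2y per-variant pleiotropic variance (>= 0).
#' @param region a `region_eigen` from [prepare_region()].
#' @param adjust_n scale the noise by the generative model's heritability factors
#'   `(1 - h2x)` and `(1 - alpha^2 h2x - h2y)` via effective sample sizes
#'   (default TRUE). With FALSE the noise is `C/n` exactly.
#' @return scalar log-likelihood; `-Inf` outside the parameter domain.
#' @export
ll_mr_link2 <- function(alpha, s2x, s2y, region, adjust_n = TRUE) {
  if (!is.finite(alpha) || !is.finite(s2x) || !is.finite(s2y) ||
      s2x <= 0 || s2y < 0) {
    return(-Inf)
  }
  if (adjust_n) {
    h2x <- region$m_full * s2x
    fx <- 1 - h2x
    fy <- 1 - alpha * alpha * h2x - region$m_full * s2y
    if (fx <= 0 || fy <= 0) return(-Inf)
    nx <- region$n_x / fx
    ny <- region$n_y / fy
  } else {
    nx <- region$n_x
    ny <- region$n_y
  }
  lam <- region$lambdas
  lam2 <- region$lam2
  a <- s2x * lam2 + lam / nx
  b <- (alpha * s2x) * lam2
  cc <- (alpha * alpha * s2x + s2y) * lam2 + lam / ny
  det <- a * cc - b * b
  if (!all(det > 0)) return(-Inf)
  ll <- -region$m * log(2 * pi) -
    0.5 * sum(log(det)) -
    0.5 * sum((cc * region$dx2 - (2 * b) * region$dxdy + a * region$dy2) / det)
  if (is.finite(ll)) ll else -Inf
}

# Eigen-space closed form of the MR-link-2 log-likelihood written term by
# term: the -m log(2 pi) constant, the two log-determinant sums over retained
# components, three diagonal-weighted quadratic-form sums, the
# -(n/2) sum(delta^2/lambda) noise-precision terms and the
# sample-size/eigenvalue/sigma log terms. The quadratic weights follow from
# the Woodbury identity applied to the per-component covariance (precision =
# noise precision minus a rank-correction whose X-X weight is
# Dxx = 1/Ax). Requires s2y > 0; the production form above also covers the
# s2y -> 0 limit. Kept as an independent route for testing.
ll_mr_link2_terms <- function(alpha, s2x, s2y, region, adjust_n = TRUE) {
  if (s2x <= 0 || s2y <= 0) return(-Inf)
  en <- effective_n(alpha, s2x, s2y, region$m_full, region$n_x, region$n_y,
                    adjust_n)
  if (is.null(en)) return(-Inf)
  nx <- en$nx
  ny <- en$ny
  lam <- region$lambdas
  dx <- region$delta_x
  dy <- region$delta_y
  m <- region$m
  By <- ny * lam + 1 / s2y
  Ax <- (alpha^2 * ny + nx) * lam + 1 / s2x - alpha^2 * ny^2 * lam^2 / By
  Dxx <- 1 / Ax
  Qxx <- nx^2 * Dxx
  Qxy <- alpha * nx * ny * Dxx / (s2y * By)
  Qyy <- ny^2 * Dxx * (alpha^2 / s2y + 1 / s2x + nx * lam) / By
  -m * log(2 * pi) -
    0.5 * sum(log(Ax)) -
    0.5 * sum(log(By)) +
    0.5 * sum(dx^2 * Qxx) +
    sum(dx * dy * Qxy) +
    0.5 * sum(dy^2 * Qyy) -
    (nx / 2) * sum(dx^2 / lam) -
    (ny / 2) * sum(dy^2 / lam) +
    (m / 2) * (log(nx) + log(ny)) -
    sum(log(lam)) -
    m * (log(sqrt(s2x)) + log(sqrt(s2y)))
}

# Method-of-moments starting values from the rotated statistics.
mom_starts <- function(region) {
  lam <- region$lambdas
  dx <- region$delta_x
  dy <- region$delta_y
  pos_cap <- 0.5 / region$m_full   # keep implied h2 away from 1
  s2x0 <- mean((dx^2 - lam / region$n_x) / lam^2)
  s2x0 <- min(max(s2x0, 1e-3 / region$n_x / region$m_full), pos_cap)
  # GLS slope of beta_Y on beta_X in eigen space (the IVW-LD estimate)
  denom <- sum(dx^2 / lam)
  alpha0 <- if (denom > 0) sum(dx * dy / lam) / denom else 0
  alpha0 <- max(min(alpha0, 10), -10)
  s2y0 <- mean((dy^2 - lam / region$n_y) / lam^2) - alpha0^2 * s2x0
  s2y0 <- min(max(s2y0, 1e-3 / region$n_y / region$m_full), pos_cap)
  list(alpha = alpha0, s2x = s2x0, s2y = s2y0)
}

# One Nelder-Mead maximization of the likelihood over a subset of the
# parameters; fixed values supplied through `fixed`. Variance components are
# searched on the log scale so positivity is unconstrained; the causal effect
# is kept inside |alpha| <= 100 (standardized effects; also cuts off the
# degenerate ridge alpha^2 s2x ~ const of the sigma2_Y = 0 model). A run
# hitting the iteration cap is restarted from its own endpoint and accepted
# once the improvement stalls.
optimize_link2 <- function(region, free, fixed = list(), starts, adjust_n,
                           control = list(maxit = 1000, reltol = 1e-9)) {
  par_names <- free
  to_theta <- function(p) {
    vapply(par_names, function(nm) {
      if (nm == "alpha") p[[nm]] else log(p[[nm]])
    }, numeric(1))
  }
  from_theta <- function(th) {
    p <- fixed
    for (j in seq_along(par_names)) {
      nm <- par_names[j]
      p[[nm]] <- unname(if (nm == "alpha") th[j] else exp(th[j]))
    }
    p
  }
  evals <- 0L
  # specialized objective per constraint pattern (avoids per-eval list work)
  negll <- if (identical(par_names, c("s2x", "s2y"))) {
    a0 <- fixed$alpha %||% 0
    function(th) {
      evals <<- evals + 1L
      ll <- ll_mr_link2(a0, exp(th[1]), exp(th[2]), region, adjust_n)
      if (is.finite(ll)) -ll else 1e12
    }
  } else if (identical(par_names, c("alpha", "s2x"))) {
    y0 <- fixed$s2y %||% 0
    function(th) {
      evals <<- evals + 1L
      if (abs(th[1]) > 100) return(1e12)
      ll <- ll_mr_link2(th[1], exp(th[2]), y0, region, adjust_n)
      if (is.finite(ll)) -ll else 1e12
    }
  } else {
    function(th) {
      evals <<- evals + 1L
      if (abs(th[1]) > 100) return(1e12)
      ll <- ll_mr_link2(th[1], exp(th[2]), exp(th[3]), region, adjust_n)
      if (is.finite(ll)) -ll else 1e12
    }
  }
  run_nm <- function(th0) {
    fit <- tryCatch(
      stats::optim(th0, negll, method = "Nelder-Mead", control = control),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    restarts <- 0L
    while (fit$convergence != 0 && restarts < 2L) {
      nxt <- tryCatch(
        stats::optim(fit$par, negll, method = "Nelder-Mead",
                     control = control),
        error = function(e) NULL
      )
      if (is.null(nxt)) break
      stalled <- fit$value - nxt$value < 1e-6
      fit <- nxt
      if (stalled) fit$convergence <- 0L
      restarts <- restarts + 1L
    }
    fit
  }
  best <- NULL
  for (st in starts) {
    th0 <- to_theta(st)
    if (any(!is.finite(th0))) next
    fit <- run_nm(th0)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(list(ll = -Inf, params = fixed, converged = FALSE, evals = evals))
  }
  list(ll = -best$value,
       params = from_theta(best$par),
       converged = best$convergence == 0 && best$value < 1e11,
       evals = evals)
}

#' Fit the MR-link-2 model to a prepared region
#'
#' Performs the three likelihood maximizations (alpha = 0; sigma2_Y = 0; all
#' three parameters free) with a derivative-free simplex optimizer from
#' method-of-moments and fixed fallback starts, and derives likelihood-ratio
#' P values for the causal effect and for the pleiotropic variance, each on
#' one degree of freedom with negative LR statistics clipped to zero.
#'
#' @param region a `region_eigen` from [prepare_region()].
#' @param adjust_n see [ll_mr_link2()].
#' @param se compute a standard error for alpha from the numerical curvature
#'   of the log-likelihood at the optimum (default TRUE; skipping it speeds up
#'   large simulation studies where only P values are needed).
#' @return An object of class `mr_link2`.
#' @export
fit_mr_link2 <- function(region, adjust_n = TRUE, se = TRUE) {
  stopifnot(inherits(region, "region_eigen"), region$m >= 1)
  mom <- mom_starts(region)
  m_full <- region$m_full
  fb1 <- list(alpha = 0, s2x = 0.01 / m_full, s2y = 0.001 / m_full)
  fb2 <- list(alpha = 0, s2x = 1e-4 / m_full, s2y = 1e-6 / m_full)

  fit_a0 <- optimize_link2(
    region, free = c("s2x", "s2y"), fixed = list(alpha = 0),
    starts = list(mom, fb2), adjust_n = adjust_n
  )
  fit_y0 <- optimize_link2(
    region, free = c("alpha", "s2x"), fixed = list(s2y = 0),
    starts = list(mom, list(alpha = mom$alpha, s2x = fit_a0$params$s2x), fb1),
    adjust_n = adjust_n, control = list(maxit = 600, reltol = 1e-9)
  )
  full_starts <- list(
    mom,
    list(alpha = mom$alpha, s2x = fit_a0$params$s2x, s2y = fit_a0$params$s2y),
    list(alpha = fit_y0$params$alpha, s2x = fit_y0$params$s2x,
         s2y = mom$s2y),
    fb1
  )
  fit_full <- optimize_link2(
    region, free = c("alpha", "s2x", "s2y"), starts = full_starts,
    adjust_n = adjust_n
  )
  # enforce nesting: the free optimum can never sit below a constrained one
  retries <- 0L
  while (fit_full$ll < max(fit_a0$ll, fit_y0$ll) - 1e-8 && retries < 2L) {
    cand <- if (fit_a0$ll >= fit_y0$ll) {
      list(alpha = 1e-4, s2x = fit_a0$params$s2x,
           s2y = max(fit_a0$params$s2y, 1e-12))
    } else {
      list(alpha = fit_y0$params$alpha, s2x = fit_y0$params$s2x,
           s2y = 1e-4 / m_full)
    }
    refit <- optimize_link2(region, free = c("alpha", "s2x", "s2y"),
                            starts = list(cand), adjust_n = adjust_n)
    if (refit$ll > fit_full$ll) fit_full <- refit
    retries <- retries + 1L
  }

  converged <- fit_full$converged && fit_a0$converged && fit_y0$converged
  lr_alpha <- max(0, 2 * (fit_full$ll - fit_a0$ll))
  lr_h2y <- max(0, 2 * (fit_full$ll - fit_y0$ll))
  p_alpha <- if (fit_full$converged && fit_a0$converged) {
    clip_p(stats::pchisq(lr_alpha, df = 1, lower.tail = FALSE))
  } else NA_real_
  p_h2y <- if (fit_full$converged && fit_y0$converged) {
    clip_p(stats::pchisq(lr_h2y, df = 1, lower.tail = FALSE))
  } else NA_real_

  se_alpha <- NA_real_
  if (se && fit_full$converged) {
    se_alpha <- alpha_se_curvature(region, fit_full$params, adjust_n)
  }

  structure(
    list(method = "mr_link2",
         alpha = fit_full$params$alpha,
         se_alpha = se_alpha,
         p_alpha = p_alpha,
         h2x = m_full * fit_full$params$s2x,
         h2y = m_full * fit_full$params$s2y,
         p_h2y = p_h2y,
         sigma2x = fit_full$params$s2x,
         sigma2y = fit_full$params$s2y,
         ll_full = fit_full$ll,
         ll_alpha0 = fit_a0$ll,
         ll_sigy0 = fit_y0$ll,
         m = region$m,
         m_full = m_full,
         n_x = region$n_x,
         n_y = region$n_y,
         converged = converged,
         function_evals = fit_full$evals + fit_a0$evals + fit_y0$evals),
    class = c("mr_link2", "cis_mr")
  )
}

# se(alpha) from the observed information: numerical Hessian of the negative
# log-likelihood in (alpha, log s2x, log s2y) by central differences; the
# [1,1] element of its inverse is the profile curvature of alpha at the
# optimum.
alpha_se_curvature <- function(region, params, adjust_n) {
  th <- c(params$alpha, log(params$s2x), log(max(params$s2y, 1e-300)))
  f <- function(t) {
    ll <- ll_mr_link2(t[1], exp(t[2]), exp(t[3]), region, adjust_n = adjust_n)
    if (!is.finite(ll)) return(NA_real_)
    -ll
  }
  h <- pmax(1e-4, 1e-3 * abs(th))
  k <- length(th)
  H <- matrix(NA_real_, k, k)
  f0 <- f(th)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- numeric(k)
      ei[i] <- h[i]
      ej[j] <- h[j]
      if (i == j) {
        H[i, i] <- (f(th + ei) - 2 * f0 + f(th - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(th + ei + ej) - f(th + ei - ej) -
             f(th - ei + ej) + f(th - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  if (anyNA(H)) return(NA_real_)
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (!is.null(V) && is.finite(V[1, 1]) && V[1, 1] > 0) return(sqrt(V[1, 1]))
  # fall back to the marginal curvature in alpha alone
  if (is.finite(H[1, 1]) && H[1, 1] > 0) return(sqrt(1 / H[1, 1]))
  NA_real_
}

#' Fit MR-link-2 to harmonized regional summary statistics
#'
#' The user-facing fitting front end. Accepts either harmonized
#' [summary_stats] objects (standardized effects, aligned with the LD matrix)
#' or bare standardized effect vectors.
#'
#' @param exposure,outcome [summary_stats] objects or numeric standardized
#'   effect vectors, aligned with `ld`.
#' @param ld an [ld_matrix] (or plain correlation matrix) for the region.
#' @param n_x,n_y GWAS sample sizes; taken from the summary statistics
#'   (median per-variant n) when omitted.
#' @param variance_kept fraction of LD variance retained in the
#'   eigendecomposition (default 0.99).
#' @param adjust_n see [ll_mr_link2()].
#' @param se compute se(alpha) (default TRUE).
#' @param keep_region retain the `region_eigen` on the fit (needed by
#'   [simulate.mr_link2()]; default TRUE).
#' @return An object of class `mr_link2` with components `alpha`, `se_alpha`,
#'   `p_alpha`, `h2x`, `h2y`, `p_h2y`, the three maximized log-likelihoods,
#'   and bookkeeping fields.
#' @examples
#' ld <- synth_ld(m = 60, block_size = 20, rho = 0.8, seed = 1)
#' sim <- simulate_summary_stats(
#'   ld, scenario(alpha = 0.2, h2x = 0.1, h2y = 1e-20, m_causal = 60,
#'                n_x = 1e4, n_y = 3e5),
#'   causal_x = seq_len(60), causal_y = seq_len(60), seed = 2)
#' fit <- mr_link2(sim$beta_x, sim$beta_y, ld, n_x = 1e4, n_y = 3e5)
#' fit
#' @export
mr_link2 <- function(exposure, outcome, ld, n_x = NULL, n_y = NULL,
                     variance_kept = 0.99, adjust_n = TRUE, se = TRUE,
                     keep_region = TRUE) {
  get_beta <- function(s, n_arg, label) {
    if (inherits(s, "summary_stats")) {
      beta <- s$beta
      if (all(is.na(beta))) beta <- standardize_effects(s$z, s$n)$beta
      list(beta = beta, n = n_arg %||% stats::median(s$n))
    } else {
      if (is.null(n_arg)) stop("n_", label, " required with bare effect vectors")
      list(beta = as.numeric(s), n = n_arg)
    }
  }
  ex <- get_beta(exposure, n_x, "x")
  ou <- get_beta(outcome, n_y, "y")
  region <- prepare_region(ex$beta, ou$beta, ld, ex$n, ou$n,
                           variance_kept = variance_kept)
  fit <- fit_mr_link2(region, adjust_n = adjust_n, se = se)
  if (keep_region) fit$region <- region
  fit
}
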