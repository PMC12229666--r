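# S3 methods for fitted cis-MR objects.

#' @export
print.cis_mr <- function(x, ...) {
  cat(sprintf("%s causal estimate\n", toupper(x$method %||% "mr-link-2")))
  cat(sprintf("  alpha = %.4g (se %.3g), p = %.3g, SNPs = %d\n",
              x$alpha, x$se_alpha, x$p_alpha, x$m_snps %||% x$m_full))
  invisible(x)
}

#' @export
print.mr_link2 <- function(x, ...) {
  cat("MR-link-2 fit\n")
  cat(sprintf("  causal effect  alpha = %.4g (se %.3g), LRT p = %.3g\n",
              x$alpha, x$se_alpha, x$p_alpha))
  cat(sprintf("  exposure cis-heritability  h2x = %.3g\n", x$h2x))
  cat(sprintf("  pleiotropic variance       h2y = %.3g, LRT p = %.3g\n",
              x$h2y, x$p_h2y))
  cat(sprintf("  %d/%d eigencomponents retained; n_x = %g, n_y = %g%s\n",
              x$m, x$m_full, x$n_x, x$n_y,
              if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
coef.mr_link2 <- function(object, ...) {
  c(alpha = object$alpha, h2x = object$h2x, h2y = object$h2y)
}

#' @export
coef.cis_mr <- function(object, ...) c(alpha = object$alpha)

#' @export
logLik.mr_link2 <- function(object, ...) {
  structure(object$ll_full, df = 3L, class = "logLik")
}

#' @export
confint.cis_mr <- function(object, parm = "alpha", level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- matrix(c(object$alpha - z * object$se_alpha,
                  object$alpha + z * object$se_alpha), nrow = 1)
  dimnames(out) <- list("alpha", sprintf("%.1f %%", c((1 - level) / 2,
                                                      1 - (1 - level) / 2) * 100))
  out
}

#' @export
summary.mr_link2 <- function(object, ...) {
  tab <- data.frame(
    estimate = c(object$alpha, object$h2y),
    p_value = c(object$p_alpha, object$p_h2y),
    row.names = c("alpha (causal effect)", "h2y (pleiotropy)")
  )
  structure(list(fit = object, tests = tab), class = "summary.mr_link2")
}

#' @export
print.summary.mr_link2 <- function(x, ...) {
  print(x$fit)
  cat("\nLikelihood-ratio tests (1 df):\n")
  print(format(x$tests, digits = 4))
  invisible(x)
}

#' Simulate summary statistics from a fitted MR-link-2 model
#'
#' Draws replicate rotated effect pairs from the fitted per-eigencomponent
#' bivariate Gaussian and maps them back to SNP space, yielding parametric-
#' bootstrap replicates of `(beta_x, beta_y)`.
#'
#' @param object an `mr_link2` fit that retains its `region` (fits produced by
#'   [mr_link2()] keep it when `keep_region = TRUE`) — or supply `region`.
#' @param nsim number of replicates.
#' @param seed RNG seed.
#' @param region a `region_eigen` to simulate from.
#' @param ... unused.
#' @return list of `nsim` lists with `beta_x`, `beta_y`.
#' @export
simulate.mr_link2 <- function(object, nsim = 1, seed = NULL, region = NULL,
                              ...) {
  region <- region %||% object$region
  if (is.null(region)) stop("no region_eigen available to simulate from")
  with_seed(seed, {
    lam <- region$lambdas
    lam2 <- lam^2
    en <- effective_n(object$alpha, object$sigma2x, object$sigma2y,
                      region$m_full, region$n_x, region$n_y, TRUE)
    a <- object$sigma2x * lam2 + lam / en$nx
    b <- object$alpha * object$sigma2x * lam2
    cc <- (object$alpha^2 * object$sigma2x + object$sigma2y) * lam2 +
      lam / en$ny
    sd_x <- sqrt(a)
    cond_sd <- sqrt(pmax(cc - b^2 / a, 0))
    lapply(seq_len(nsim), function(i) {
      dx <- stats::rnorm(region$m, 0, sd_x)
      dy <- b / a * dx + stats::rnorm(region$m, 0, cond_sd)
      list(beta_x = drop(region$U %*% dx), beta_y = drop(region$U %*% dy))
    })
  })
}

#' Turn a fitted cis-MR object into a one-row result table
#'
#' @param x a `cis_mr` or `mr_link2` fit.
#' @param ... unused.
#' @return data.frame with method, alpha, se, p, h2x/h2y (NA for methods that
#'   do not estimate them), SNP count and convergence flag.
#' @export
as.data.frame.cis_mr <- function(x, ...) {
  data.frame(
    method = x$method %||% "mr_link2",
    alpha = x$alpha,
    se_alpha = x$se_alpha,
    p_alpha = x$p_alpha,
    h2x = x$h2x %||% NA_real_,
    h2y = x$h2y %||% NA_real_,
    p_h2y = x$p_h2y %||% NA_real_,
    m_snps = x$m_snps %||% x$m_full %||% NA_integer_,
    converged = x$converged %||% TRUE,
    stringsAsFactors = FALSE
  )
}
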