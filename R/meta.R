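# Fixed-effect meta-analysis of per-region causal estimates, Cochran's Q
# heterogeneity, and benchmark metrics (detection rate, AUC,
# precision/recall).

#' Inverse-variance meta-analysis of regional causal estimates
#'
#' Fixed-effect pooling across associated regions:
#' `alpha_bar = sum(alpha_r / se_r^2) / sum(se_r^-2)` with standard error
#' `1 / sqrt(sum(se_r^-2))` and a two-sided normal P value. With two or more
#' regions, Cochran's Q (`sum(((alpha_r - alpha_bar)/se_r)^2)`, chi-squared
#' on k-1 df under homogeneity) is attached.
#'
#' @param alpha per-region causal estimates (or a data.frame holding columns
#'   `alpha` and `se_alpha`, e.g. rows of pipeline results).
#' @param se per-region standard errors (ignored when `alpha` is a
#'   data.frame).
#' @return An object of class `mr_meta`: `alpha_bar`, `se_bar`, `p`,
#'   `q_stat`, `q_df`, `q_p`, `k`.
#' @export
meta_analyze <- function(alpha, se = NULL) {
  if (is.data.frame(alpha)) {
    se <- alpha$se_alpha
    alpha <- alpha$alpha
  }
  ok <- is.finite(alpha) & is.finite(se) & se > 0
  alpha <- alpha[ok]
  se <- se[ok]
  k <- length(alpha)
  if (k == 0L) stop("no usable regional estimates to meta-analyze")
  w <- 1 / se^2
  alpha_bar <- sum(w * alpha) / sum(w)
  se_bar <- 1 / sqrt(sum(w))
  q <- if (k >= 2L) sum(((alpha - alpha_bar) / se)^2) else NA_real_
  structure(
    list(alpha_bar = alpha_bar,
         se_bar = se_bar,
         p = clip_p(2 * stats::pnorm(-abs(alpha_bar / se_bar))),
         q_stat = q,
         q_df = if (k >= 2L) k - 1L else NA_integer_,
         q_p = if (k >= 2L) stats::pchisq(q, k - 1, lower.tail = FALSE)
               else NA_real_,
         k = k),
    class = "mr_meta"
  )
}

#' @export
print.mr_meta <- function(x, ...) {
  cat(sprintf("Meta-analysis over %d region(s): alpha = %.4g (se %.3g), p = %.3g\n",
              x$k, x$alpha_bar, x$se_bar, x$p))
  if (!is.na(x$q_stat)) {
    cat(sprintf("  heterogeneity: Cochran's Q = %.3g on %d df, p = %.3g\n",
                x$q_stat, x$q_df, x$q_p))
  }
  invisible(x)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(((alpha_r - alpha_bar)/se_r)^2)`, the sum of squared Z-score
#' deviations of each regional estimate from the pooled estimate. Requires at
#' least two regions.
#'
#' @inheritParams meta_analyze
#' @param meta optional precomputed [meta_analyze()] result.
#' @return scalar Q.
#' @export
cochran_q <- function(alpha, se = NULL, meta = NULL) {
  if (is.data.frame(alpha)) {
    se <- alpha$se_alpha
    alpha <- alpha$alpha
  }
  if (length(alpha) < 2L) stop("Cochran's Q needs at least two regions")
  meta <- meta %||% meta_analyze(alpha, se)
  sum(((alpha - meta$alpha_bar) / se)^2)
}

#' Fraction of P values below a significance threshold
#'
#' The empirical detection rate: type-I error under null scenarios, power
#' under causal ones.
#'
#' @param p P values in (0, 1].
#' @param threshold significance level (default 0.05).
#' @return fraction strictly below `threshold` (NA values are dropped).
#' @export
detection_rate <- function(p, threshold = 0.05) {
  p <- p[!is.na(p)]
  if (length(p) == 0L) stop("no P values supplied")
  mean(p < threshold)
}

#' Rank-based AUC from two sets of P values
#'
#' Area under the ROC curve for discriminating causal from null simulations
#' by P value, computed as the Mann-Whitney statistic with smaller P treated
#' as more causal; ties are averaged. Invariant under strictly monotone
#' transforms of the P values.
#'
#' @param p_null P values from null (non-causal) cases.
#' @param p_causal P values from causal cases.
#' @return AUC in `[0, 1]`.
#' @export
auc_from_pvalues <- function(p_null, p_causal) {
  p_null <- p_null[!is.na(p_null)]
  p_causal <- p_causal[!is.na(p_causal)]
  if (length(p_null) == 0L || length(p_causal) == 0L) {
    stop("both P value sets must be non-empty")
  }
  n1 <- length(p_causal)
  n0 <- length(p_null)
  r <- rank(c(-p_causal, -p_null), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Precision and recall of significance calls against truth labels
#'
#' @param calls logical vector: called significant (e.g. at a Bonferroni
#'   threshold).
#' @param truth logical vector: true positives.
#' @return list with `precision` (NA when nothing is called) and `recall`.
#' @export
precision_recall <- function(calls, truth) {
  stopifnot(length(calls) == length(truth))
  tp <- sum(calls & truth)
  fp <- sum(calls & !truth)
  fn <- sum(!calls & truth)
  list(precision = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
       recall = if (tp + fn == 0L) NA_real_ else tp / (tp + fn))
}
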