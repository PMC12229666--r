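---
title: "Pleiotropy-robust cis Mendelian randomization with cismr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pleiotropy-robust cis Mendelian randomization with cismr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cismr)
```

## The problem

Molecular exposures — metabolite levels, gene expression — are typically
instrumented from a *single* associated genomic region (*cis* MR). Within one
region the genetic variants are strongly correlated through linkage
disequilibrium (LD), and a variant can affect the outcome through paths other
than the exposure (horizontal pleiotropy). Classical estimators that treat
instruments as exchangeable Wald ratios are biased in exactly this setting.

`cismr` fits a joint likelihood for the *marginal* GWAS summary statistics of
an exposure and an outcome over **all** SNPs in a region, estimating three
parameters:

* $\alpha$ — the causal effect of the exposure on the outcome,
* $\sigma^2_X = h^2_X / m$ — the per-variant exposure effect variance
  ($h^2_X$ is the regional cis-heritability over the $m$ SNPs),
* $\sigma^2_Y = h^2_Y / m$ — the per-variant *direct* (pleiotropic) outcome
  effect variance.

Estimating $\sigma^2_Y$ alongside $\alpha$ is what makes the estimator robust
to directionally balanced pleiotropy: outcome signal that is not proportional
to the exposure signal is absorbed by the variance component instead of the
causal effect.

## The model

With standardized effect sizes ($\hat\beta = z / \sqrt{n + z^2}$, unitless
trait-SD per allele-SD), multivariable SNP effects are modelled as random,
$\gamma^{(X)}_j \sim N(0, \sigma^2_X)$ and $\gamma^{(Y)}_j \sim N(0,
\sigma^2_Y)$ for all $m$ SNPs, and the marginal statistics follow

$$
\hat\beta_X = C\,\gamma^{(X)} + \eta_X, \qquad
\hat\beta_Y = C\,(\alpha \gamma^{(X)} + \gamma^{(Y)}) + \eta_Y,
$$

where $C$ is the regional LD (correlation) matrix,
$\eta_X \sim N\!\big(0,\, C\,(1-h^2_X)/n_X\big)$ and
$\eta_Y \sim N\!\big(0,\, C\,(1-\alpha^2 h^2_X - h^2_Y)/n_Y\big)$.
Integrating out the $2m$ random effects leaves a 3-parameter Gaussian
likelihood. In the eigenbasis $C = U \Lambda U^T$ the rotated statistics
$\delta^{(X)} = U^T\hat\beta_X$, $\delta^{(Y)} = U^T\hat\beta_Y$ decouple into
independent bivariate Gaussians, one per eigenvalue $\lambda_i$:

$$
\mathrm{Cov}(\delta^{(X)}_i, \delta^{(Y)}_i) =
\begin{pmatrix}
\sigma^2_X \lambda_i^2 + \lambda_i/n_X &
\alpha\,\sigma^2_X \lambda_i^2 \\
\alpha\,\sigma^2_X \lambda_i^2 &
(\alpha^2 \sigma^2_X + \sigma^2_Y)\lambda_i^2 + \lambda_i/n_Y
\end{pmatrix},
$$

so one likelihood evaluation costs $O(m)$. `ll_mr_link2()` evaluates this
form directly; an algebraically identical expanded closed form (log-determinant
sums plus Woodbury-weighted quadratic forms) is kept in the sources as an
independent route and both are tested against the direct $2m$-dimensional
Gaussian density on small regions.

The noise factors $(1-h^2_X)$ and $(1-\alpha^2 h^2_X - h^2_Y)$ enter the
eigen-space algebra purely as *effective sample sizes* $n_X/(1-h^2_X)$ and
$n_Y/(1-\alpha^2h^2_X-h^2_Y)$; this is exact, keeps the likelihood consistent
with the generative model above, and is controlled by `adjust_n` (default
`TRUE`; the difference is negligible for realistic cis-heritabilities below
about 0.1).

### Inference

The likelihood is maximized three times with Nelder–Mead (variance components
on the log scale, so positivity needs no constraints): (i) $\alpha = 0$ free
$(\sigma^2_X,\sigma^2_Y)$; (ii) $\sigma^2_Y = 0$ free $(\alpha,\sigma^2_X)$;
(iii) all three free. P values for $\alpha$ and for $\sigma^2_Y$ are
likelihood-ratio tests on one degree of freedom, with negative LR statistics
(a boundary artifact) clipped to zero, i.e. $p = 1$. Because $\sigma^2_Y = 0$
sits on the parameter boundary, the pleiotropy test is deliberately
conservative — its null rejection rate falls well below the nominal level,
which the acceptance checks assert.

The $\sigma^2_Y = 0$ constrained model is evaluated as the exact analytic
limit of the per-component bivariate density (the covariance above with
$\sigma^2_Y = 0$), not with a small-$\epsilon$ stand-in.

`se(alpha)` is derived from the numerical curvature (central-difference
Hessian in $(\alpha, \log\sigma^2_X, \log\sigma^2_Y)$) at the optimum; the
`[1,1]` element of the inverse Hessian is the profile curvature of $\alpha$.
The headline inference object remains the LRT P value; the standard error
exists mainly for meta-analysis weighting.

### Numerical choices

* **Eigenvalue truncation.** Components are retained until their eigenvalue
  sum reaches `variance_kept` (default 0.99) of the trace; trailing
  near-null-space components of $C$ carry almost no information but dominate
  numerical error. Small negative eigenvalues (beyond $-10^{-8}$ a warning is
  raised) are clipped to zero.
* **Starting values.** Method-of-moments: $\sigma^2_X$ from
  $\mathrm{mean}((\delta_X^2 - \lambda/n_X)/\lambda^2)$, $\alpha$ from the
  GLS slope $\sum \delta_X\delta_Y/\lambda \big/ \sum \delta_X^2/\lambda$
  (the LD-aware IVW estimate in eigenspace), plus fixed fallback starts; the
  best optimum across starts is kept, and the free fit additionally restarts
  from the constrained optima — the free maximum can therefore never sit
  below a constrained one (asserted with $10^{-6}$ slack).
* **Ridge cutoff.** The $\sigma^2_Y = 0$ model has a degenerate ridge
  $\alpha^2\sigma^2_X \approx const$ as $\sigma^2_X \to 0$; the optimizer
  bounds $|\alpha| \le 100$ (meaningless on the standardized scale anyway),
  which terminates ridge crawling. Runs that hit the iteration cap restart
  from their endpoint and are accepted once the improvement stalls below
  $10^{-6}$.

## Surrounding pipeline

Harmonization (`harmonize_pair()`) intersects both studies with the LD
reference on (chromosome, position, alleles), flips signs where the allele
pair is swapped, removes strand-ambiguous A/T and C/G SNPs, applies a
reference MAF filter (default 0.5%) and a per-trait 95% sample-size
completeness filter, and converts to standardized effects. Filters are
applied after the three-way intersection; since every filter is a per-variant
predicate, the surviving set does not depend on this order. Associated
regions come from greedy P-value clumping (`clump()`; defaults 250 kb,
$r^2 \ge 0.01$, $p \le 5\times10^{-8}$, ties on P broken by position) with
overlapping clump windows merged, so regions can grow well beyond a single
window. The classical estimators (`mr_wald_ratio()`, `mr_ivw()`,
`mr_ivw_ld()`, `mr_pca()`) run on the same harmonized inputs; regional
estimates pool by fixed-effect inverse variance (`meta_analyze()`), with
Cochran's Q for heterogeneity. The pooled standard error is
$1/\sqrt{\sum se_r^{-2}}$ — the standard fixed-effect form.

## What the simulator emulates

`synth_ld()` builds a block-diagonal autoregressive correlation matrix
(Poisson block lengths, within-block decay $\rho^{|i-j|}$) that mimics
haplotype blocks; it is positive definite by construction and deterministic
given a seed. The study conditions the generator reproduces by default: a
molecular exposure measured in $n_X = 10{,}000$ individuals against an
outcome measured in $n_Y = 300{,}000$; regional SNP counts of a few hundred
to a few thousand; exposure cis-heritabilities $h^2_X \in \{0.001, 0.01,
0.1\}$; pleiotropic outcome heritabilities from $10^{-20}$ (negligible) to
$0.03$ (extreme); $m_{causal} \in \{1, \dots, 100\}$ causal SNPs per trait,
optionally constrained to lie within an LD window $r^2 \in [r_{min},
r_{max}]$ of each other (which violates the InSIDE assumption on purpose);
and LD references that are either exact or Wishart-sampled at panel sizes of
500–5000 (`sample_reference_ld()`).

Two deliberate conventions:

* **Exact heritability rescaling.** After drawing $\gamma$, the vector is
  rescaled so the realized genetic variance $\gamma^T C \gamma$ equals the
  target $h^2$ exactly. This removes between-replicate heritability jitter
  and makes the $(1-h^2)$ noise terms internally consistent; acceptance
  tolerances would accommodate either convention.
* **The outcome includes $\alpha\, C\gamma^{(X)}$ explicitly**, keeping the
  mediated genetic signal in $\hat\beta_Y$ (the marginal-statistic model
  above), with noise variance $(1-\alpha^2h^2_X-h^2_Y)/n_Y$.

What the generator does *not* emulate: real haplotype structure (long-range
LD, allele-frequency-dependent LD), population stratification, sample overlap
between the two GWAS, binary traits, and technical artifacts in summary
statistics. Passing calibration on synthetic LD therefore demonstrates
correctness of the estimator under its own assumptions, not robustness to
everything real data can do; the imprecise-LD and sparse-architecture
scenarios probe the two violations the method is most sensitive to.

## Problem sizes used in the checks

The packaged calibration checks run on an $m = 500$ SNP synthetic region
(blocks of ~50, $\rho = 0.9$) with 500 replicates per scenario cell: null
type-I error across $h^2_X \times h^2_Y$ grids for 10-causal-SNP and
1-causal-SNP architectures, conservativeness of the pleiotropy test at
$h^2_Y = 10^{-20}$, power at $\alpha = 0.2$, $h^2_X = 0.1$, and parameter
recovery at 200 replicates per effect size. These sizes give binomial Monte
Carlo error of about $\pm 0.01$–0.02 on rejection fractions, matching the
tolerances asserted.

## A worked example

```{r example, eval = FALSE}
ld <- synth_ld(m = 200, block_size = 40, rho = 0.9, seed = 1)
spec <- scenario(alpha = 0.2, h2x = 0.1, h2y = 1e-3, m_causal = 10)
sets <- select_causal_sets(ld, spec$m_causal, seed = 2)
sim <- simulate_summary_stats(ld, spec, sets$exposure, sets$outcome, seed = 3)
fit <- mr_link2(sim$beta_x, sim$beta_y, ld, n_x = 1e4, n_y = 3e5)
summary(fit)
```

## Known limitations

* A single exposure per region; multi-exposure extensions are out of scope.
* The pleiotropy variance models *balanced* pleiotropy; strongly directional
  pleiotropy concentrated in few SNPs in tight LD with the causal set can
  still bias $\hat\alpha$ (the simulator's $r^2$-constrained scenarios
  reproduce this failure mode).
* LD is assumed measured without error by the likelihood; imprecise
  references inflate type-I error, which is why `sample_reference_ld()`
  exists for sensitivity analysis rather than as a fix.
* `se(alpha)` is a curvature approximation; near-boundary fits can leave it
  `NA`, and downstream meta-analysis drops such regions.
* Like most variance-component ML estimators, the point estimate of $\alpha$
  carries a small finite-sample attenuation (a fraction of a percent of the
  effect at $n_X = 10^4$ and $h^2_X = 0.1$), visible only at very large
  replicate counts; LRT calibration is unaffected.
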