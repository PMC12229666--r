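# Harmonization of exposure/outcome summary statistics against an LD
# reference: variant intersection, allele alignment, QC filters, and
# conversion to standardized effect sizes.

#' Convert Z-scores to standardized effect sizes
#'
#' On the standardized scale (trait SD per allele SD),
#' `beta = z / sqrt(n + z^2)` and `se = 1 / sqrt(n + z^2)`, so that
#' `beta / se` returns `z` exactly and `|beta| < 1`.
#'
#' @param z association Z-score vector.
#' @param n per-variant sample size vector (recycled if scalar).
#' @return list with components `beta` and `se`.
#' @export
standardize_effects <- function(z, n) {
  if (any(!is.finite(n)) || any(n <= 0)) stop("sample sizes must be positive")
  denom <- sqrt(n + z^2)
  list(beta = z / denom, se = 1 / denom)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# Align one summary_stats table to the reference variant table. Returns the
# stats rows reordered to ref order with effect sizes flipped where the
# effect/other alleles are swapped relative to the reference; variants absent
# from the reference (or with incompatible alleles) are dropped.
align_to_reference <- function(stats, ref_variants) {
  ref_key <- variant_key(ref_variants)
  same <- match(ref_key, variant_key(stats))
  swapped <- match(ref_key, variant_key(stats, swap = TRUE))
  use_swap <- is.na(same) & !is.na(swapped)
  idx <- ifelse(is.na(same), swapped, same)
  keep <- !is.na(idx)
  out <- stats[idx[keep], , drop = FALSE]
  flip <- use_swap[keep]
  out$a1[flip] <- ref_variants$a1[keep][flip]
  out$a2[flip] <- ref_variants$a2[keep][flip]
  out$beta[flip] <- -out$beta[flip]
  out$z[flip] <- -out$z[flip]
  rownames(out) <- NULL
  list(stats = out, ref_idx = which(keep))
}

#' Harmonize an exposure/outcome pair against an LD reference
#'
#' Restricts both studies and the reference to their three-way variant
#' intersection on (chromosome, position, alleles), aligning effect alleles to
#' the reference (with sign flips where the allele pair is swapped). Then
#' applies, in order: palindromic-SNP removal (A/T and C/G pairs, strand
#' ambiguous), a reference minor-allele-frequency filter, and a per-trait
#' sample-size completeness filter (variants measured in fewer than
#' `completeness * max(n)` individuals are dropped, when per-variant n is
#' available). Surviving records are converted to standardized effect sizes
#' via [standardize_effects()].
#'
#' @param exposure,outcome [summary_stats] objects.
#' @param reference an [ld_matrix] providing the variant universe, allele
#'   orientation, and MAF.
#' @param maf_threshold minimum reference MAF (default 0.005).
#' @param completeness per-trait fraction of the maximum sample size a variant
#'   must reach (default 0.95).
#' @param keep_palindromic retain strand-ambiguous SNPs (default FALSE).
#' @param quiet suppress filter logging.
#' @return list with harmonized `exposure`, `outcome` (standardized
#'   [summary_stats]) and `ld` (the reference subset), all aligned.
#' @export
harmonize_pair <- function(exposure, outcome, reference,
                           maf_threshold = 0.005, completeness = 0.95,
                           keep_palindromic = FALSE, quiet = FALSE) {
  stopifnot(inherits(exposure, "summary_stats"),
            inherits(outcome, "summary_stats"),
            inherits(reference, "ld_matrix"))
  ax <- align_to_reference(exposure, reference$variants)
  ay <- align_to_reference(outcome, reference$variants)
  common <- intersect(ax$ref_idx, ay$ref_idx)
  if (length(common) == 0L) {
    stop("harmonization failed: three-way variant intersection is empty")
  }
  ex <- ax$stats[match(common, ax$ref_idx), , drop = FALSE]
  ou <- ay$stats[match(common, ay$ref_idx), , drop = FALSE]
  ref_idx <- common
  log_count("variant intersection",
            max(nrow(exposure), nrow(outcome)), length(ref_idx), quiet = quiet)

  drop_step <- function(keep, label) {
    if (!any(keep)) {
      stop("harmonization failed: no variants survive the ", label, " filter")
    }
    log_count(label, length(keep), sum(keep), quiet = quiet)
    ex <<- ex[keep, , drop = FALSE]
    ou <<- ou[keep, , drop = FALSE]
    ref_idx <<- ref_idx[keep]
  }

  if (!keep_palindromic) {
    drop_step(!is_palindromic(ex$a1, ex$a2), "palindromic-SNP removal")
  }
  maf <- reference$maf[ref_idx]
  if (!all(is.na(maf))) {
    drop_step(is.na(maf) | maf >= maf_threshold, "reference MAF filter")
  }
  for (trait in list(list(s = quote(ex), lab = "exposure completeness"),
                     list(s = quote(ou), lab = "outcome completeness"))) {
    s <- eval(trait$s)
    if (!all(is.na(s$n)) && length(unique(s$n)) > 1L) {
      drop_step(s$n >= completeness * max(s$n, na.rm = TRUE), trait$lab)
    }
  }

  restandardize <- function(s) {
    st <- standardize_effects(s$z, s$n)
    s$beta <- st$beta
    s$se <- st$se
    s$p <- clip_p(2 * stats::pnorm(-abs(s$z)))
    rownames(s) <- NULL
    class(s) <- c("summary_stats", "data.frame")
    s
  }
  list(exposure = restandardize(ex),
       outcome = restandardize(ou),
       ld = subset_ld(reference, ref_idx))
}
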