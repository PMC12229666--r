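# End-to-end regional cis-MR pipeline: harmonize -> clump/merge regions ->
# per-region estimation per method -> optional meta-analysis, with a
# reproducibility manifest.

#' Run the full regional cis-MR pipeline
#'
#' Harmonizes the exposure/outcome pair against the LD reference, identifies
#' associated regions by P-value clumping of the exposure statistics (merging
#' overlapping clump windows), runs each requested estimator per region, and
#' meta-analyzes regional estimates per method when several regions exist.
#'
#' @param exposure,outcome [summary_stats] objects (or file paths readable by
#'   [read_summary_stats()]).
#' @param ld an [ld_matrix], a prefix readable by [read_ld_matrix()], or a
#'   PLINK prefix readable by [read_genotype_panel()] (detected via the
#'   `.bed` file).
#' @param methods estimators to run, subset of
#'   `c("mr_link2", "ivw", "ivw_ld", "pca")`.
#' @param clump_kb,clump_r2,clump_p clumping window (kb), r-squared and P
#'   thresholds for region definition and instrument selection.
#' @param maf_threshold,completeness,keep_palindromic harmonization filters,
#'   see [harmonize_pair()].
#' @param variance_kept eigencomponent retention for MR-link-2 and MR-PCA.
#' @param n_x,n_y GWAS sample sizes (defaults: per-trait median n).
#' @param out optional output prefix; writes `<out>.results.tsv` and a JSON
#'   manifest `<out>.manifest.json` recording thresholds, seeds and
#'   per-stage record counts.
#' @param seed seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @param quiet suppress per-stage logging.
#' @return list with `results` (one row per region x method), `meta` (one row
#'   per method, when >= 1 region), `regions`, and `manifest`.
#' @export
run_pipeline <- function(exposure, outcome, ld,
                         methods = c("mr_link2", "ivw", "ivw_ld", "pca"),
                         clump_kb = 250, clump_r2 = 0.01, clump_p = 5e-8,
                         maf_threshold = 0.005, completeness = 0.95,
                         keep_palindromic = FALSE, variance_kept = 0.99,
                         n_x = NULL, n_y = NULL, out = NULL, seed = 1,
                         quiet = FALSE) {
  methods <- match.arg(methods, c("mr_link2", "ivw", "ivw_ld", "pca"),
                       several.ok = TRUE)
  if (is.character(exposure)) exposure <- read_summary_stats(exposure, quiet = quiet)
  if (is.character(outcome)) outcome <- read_summary_stats(outcome, quiet = quiet)
  if (is.character(ld)) {
    ld <- if (file.exists(paste0(ld, ".bed"))) {
      compute_ld(read_genotype_panel(ld))
    } else {
      read_ld_matrix(ld)
    }
  }
  if (!inherits(ld, "ld_matrix")) stop("configuration error: no LD reference supplied")

  counts <- list(exposure_in = nrow(exposure), outcome_in = nrow(outcome))
  harm <- harmonize_pair(exposure, outcome, ld,
                         maf_threshold = maf_threshold,
                         completeness = completeness,
                         keep_palindromic = keep_palindromic, quiet = quiet)
  counts$harmonized <- nrow(harm$exposure)
  n_x <- n_x %||% stats::median(harm$exposure$n)
  n_y <- n_y %||% stats::median(harm$outcome$n)

  clumps <- clump(harm$exposure, harm$ld, window_kb = clump_kb,
                  r2_thresh = clump_r2, p_thresh = clump_p)
  regions <- regions_from_clumps(harm$exposure, clumps, window_kb = clump_kb)
  counts$regions <- nrow(regions)

  rows <- list()
  for (g in seq_len(nrow(regions))) {
    rg <- regions[g, ]
    in_region <- which(harm$exposure$chrom == rg$chrom &
                         harm$exposure$pos >= rg$start &
                         harm$exposure$pos <= rg$end)
    ex <- harm$exposure[in_region, , drop = FALSE]
    ou <- harm$outcome[in_region, , drop = FALSE]
    ld_r <- subset_ld(harm$ld, in_region)
    sim_like <- list(beta_x = ex$beta, beta_y = ou$beta,
                     se_x = ex$se, se_y = ou$se)
    spec_like <- list(n_x = n_x, n_y = n_y)
    for (method in methods) {
      res <- tryCatch(
        fit_one_method(method, sim_like, ld_r, spec_like, variance_kept,
                       NULL, TRUE),
        error = function(e) {
          warning(sprintf("%s failed in region %s:%d-%d: %s", method,
                          rg$chrom, rg$start, rg$end, conditionMessage(e)))
          NULL
        }
      )
      if (is.null(res)) next
      df <- as.data.frame(res)
      df$chrom <- rg$chrom
      df$start <- rg$start
      df$end <- rg$end
      rows[[length(rows) + 1L]] <- df
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else data.frame()
  rownames(results) <- NULL

  meta <- NULL
  if (nrow(results) > 0L) {
    meta <- do.call(rbind, lapply(split(results, results$method), function(d) {
      mm <- meta_analyze(d)
      data.frame(method = d$method[1], alpha_bar = mm$alpha_bar,
                 se_bar = mm$se_bar, p = mm$p, q_stat = mm$q_stat,
                 q_df = mm$q_df, q_p = mm$q_p, k = mm$k)
    }))
    rownames(meta) <- NULL
  }

  manifest <- list(
    package = "cismr",
    version = as.character(utils::packageVersion("cismr")),
    seed = seed,
    methods = methods,
    thresholds = list(clump_kb = clump_kb, clump_r2 = clump_r2,
                      clump_p = clump_p, maf_threshold = maf_threshold,
                      completeness = completeness,
                      variance_kept = variance_kept),
    n_x = n_x, n_y = n_y,
    record_counts = counts
  )
  if (!is.null(out)) {
    utils::write.table(results, paste0(out, ".results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, paste0(out, ".manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (!is.null(meta)) {
      utils::write.table(meta, paste0(out, ".meta.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  list(results = results, meta = meta, regions = regions, manifest = manifest)
}
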