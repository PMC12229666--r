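# Summary-statistic container and TSV readers/writers.
#
# A `summary_stats` object is a data.frame with one row per biallelic SNP and
# canonical columns chrom, pos, a1 (effect allele), a2 (other allele), beta,
# se, z, n, p. Effects are on whatever scale the source study reports until
# `standardize_effects()`/`harmonize_pair()` puts them on the standardized
# (trait-SD per allele-SD) scale.

VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a summary-statistics table
#'
#' Validates and normalizes per-variant GWAS association records. Records with
#' identical alleles, non-SNP alleles, non-positive standard errors, or P
#' values outside (0, 1] are dropped with a logged count. If `z` is missing it
#' is reconstructed as `beta/se`; if `p` is missing it is computed from `z`;
#' if per-variant `n` is missing, the study-level maximum is imputed.
#'
#' @param df data.frame with at least chrom, pos, a1, a2 and either z or
#'   beta+se; optional n and p.
#' @param max_n study-level sample size used when `n` is absent.
#' @param quiet suppress filter logging.
#' @return A `summary_stats` object (data.frame subclass).
#' @export
summary_stats <- function(df, max_n = NULL, quiet = FALSE) {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "pos", "a1", "a2")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("summary statistics lack required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  has_z <- "z" %in% names(df) && !all(is.na(df$z))
  has_beta <- all(c("beta", "se") %in% names(df)) &&
    !all(is.na(df$beta) | is.na(df$se))
  if (!has_z && !has_beta) {
    stop("summary statistics need either a z column or beta and se columns")
  }
  n_in <- nrow(df)
  if (n_in == 0L) stop("empty summary statistics table")

  out <- data.frame(
    chrom = as.character(df$chrom),
    pos = as.integer(df$pos),
    a1 = toupper(as.character(df$a1)),
    a2 = toupper(as.character(df$a2)),
    stringsAsFactors = FALSE
  )
  out$beta <- if (has_beta) as.numeric(df$beta) else NA_real_
  out$se <- if (has_beta) as.numeric(df$se) else NA_real_
  out$z <- if (has_z) as.numeric(df$z) else out$beta / out$se
  if (!has_z) {
    # keep beta/se as the authoritative pair
  } else if (!has_beta) {
    out$beta <- NA_real_
    out$se <- NA_real_
  }
  out$n <- if ("n" %in% names(df)) as.numeric(df$n) else NA_real_
  if (anyNA(out$n)) {
    fallback <- max_n %||% suppressWarnings(max(out$n, na.rm = TRUE))
    if (!is.finite(fallback)) {
      stop("no per-variant n and no study-level max_n supplied")
    }
    out$n[is.na(out$n)] <- fallback
  }
  out$p <- if ("p" %in% names(df)) as.numeric(df$p) else clip_p(2 * stats::pnorm(-abs(out$z)))

  keep <- out$a1 %in% VALID_ALLELES & out$a2 %in% VALID_ALLELES &
    out$a1 != out$a2 &
    is.finite(out$z) &
    is.finite(out$n) & out$n > 0 &
    is.finite(out$p) & out$p > 0 & out$p <= 1
  if (has_beta) keep <- keep & is.finite(out$se) & out$se > 0
  keep[is.na(keep)] <- FALSE
  out <- out[keep, , drop = FALSE]
  log_count("summary_stats QC", n_in, nrow(out), quiet = quiet)
  if (nrow(out) == 0L) stop("all summary-statistic records failed QC")

  # duplicate variant keys: keep the first record, log the rest
  key <- variant_key(out)
  if (anyDuplicated(key)) {
    out <- out[!duplicated(key), , drop = FALSE]
    log_count("duplicate variant keys", length(key), nrow(out), quiet = quiet)
  }
  rownames(out) <- NULL
  class(out) <- c("summary_stats", "data.frame")
  out
}

# Canonical variant key string: chrom:pos:a1:a2.
variant_key <- function(x, swap = FALSE) {
  if (swap) paste(x$chrom, x$pos, x$a2, x$a1, sep = ":")
  else paste(x$chrom, x$pos, x$a1, x$a2, sep = ":")
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' @param path TSV file with a header row.
#' @param column_map named character vector mapping canonical names
#'   (`chrom`, `pos`, `a1`, `a2`, `beta`, `se`, `z`, `n`, `p`) to the file's
#'   column names. Only the names present in the file need to be mapped;
#'   canonical names already present are picked up automatically.
#' @param max_n study-level sample size fallback when the file has no n column.
#' @param quiet suppress filter logging.
#' @return A [summary_stats] object.
#' @export
read_summary_stats <- function(path, column_map = NULL, max_n = NULL,
                               quiet = FALSE) {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty summary-statistics file: ", path)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw)) {
        stop("column_map entry '", canon, "' -> '", src,
             "' not found in ", path)
      }
      raw[[canon]] <- raw[[src]]
    }
  }
  need <- c("chrom", "pos", "a1", "a2")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("cannot resolve required columns in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  summary_stats(raw, max_n = max_n, quiet = quiet)
}

#' Write summary statistics to a tab-separated file
#'
#' Uses full precision so that a write/read round trip preserves values.
#'
#' @param x a [summary_stats] object.
#' @param path output file path.
#' @export
write_summary_stats <- function(x, path) {
  stopifnot(inherits(x, "summary_stats"))
  df <- as.data.frame(x)
  for (col in c("beta", "se", "z", "n", "p")) {
    df[[col]] <- vapply(df[[col]], function(v) {
      if (is.na(v)) "NA" else sprintf("%.17g", v)
    }, character(1))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
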