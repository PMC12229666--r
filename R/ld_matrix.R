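# Regional LD matrix container plus dense-file I/O.

#' Construct an LD matrix object
#'
#' Bundles an m x m Pearson correlation matrix with its variant metadata,
#' per-variant minor-allele frequencies, and the reference-panel sample size
#' it was estimated in. Symmetry and a unit diagonal are asserted on
#' construction.
#'
#' @param C square correlation matrix.
#' @param variants data.frame with columns chrom, pos, a1, a2 (one row per
#'   matrix row/column, in order).
#' @param n_ref reference sample count, or `Inf` for an exactly known matrix.
#' @param maf per-variant minor-allele frequency (optional, `NA` if unknown).
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(C, variants, n_ref = Inf, maf = NULL) {
  C <- as.matrix(C)
  m <- nrow(C)
  stopifnot(ncol(C) == m, is.data.frame(variants), nrow(variants) == m)
  if (max(abs(C - t(C))) > 1e-8) stop("LD matrix is not symmetric")
  C <- symmetrize(C)
  if (max(abs(diag(C) - 1)) > 1e-6) stop("LD matrix diagonal is not 1")
  diag(C) <- 1
  if (max(abs(C)) > 1 + 1e-8) stop("LD entries outside [-1, 1]")
  C[C > 1] <- 1
  C[C < -1] <- -1
  maf <- maf %||% rep(NA_real_, m)
  stopifnot(length(maf) == m)
  structure(
    list(C = C,
         variants = data.frame(chrom = as.character(variants$chrom),
                               pos = as.integer(variants$pos),
                               a1 = toupper(as.character(variants$a1)),
                               a2 = toupper(as.character(variants$a2)),
                               stringsAsFactors = FALSE),
         n_ref = n_ref,
         maf = as.numeric(maf)),
    class = "ld_matrix"
  )
}

#' @export
dim.ld_matrix <- function(x) dim(x$C)

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("LD matrix: %d variants, n_ref = %s\n", nrow(x$C),
              if (is.infinite(x$n_ref)) "exact" else format(x$n_ref)))
  invisible(x)
}

# Subset an ld_matrix to variant indices, keeping metadata aligned.
subset_ld <- function(ld, idx) {
  ld_matrix(ld$C[idx, idx, drop = FALSE], ld$variants[idx, , drop = FALSE],
            n_ref = ld$n_ref, maf = ld$maf[idx])
}

#' Write an LD matrix as a dense TSV plus a variant sidecar TSV
#'
#' @param ld an [ld_matrix].
#' @param prefix output prefix; writes `<prefix>.ld.tsv` and
#'   `<prefix>.vars.tsv`.
#' @export
write_ld_matrix <- function(ld, prefix) {
  stopifnot(inherits(ld, "ld_matrix"))
  utils::write.table(format(ld$C, digits = 17, trim = TRUE, scientific = TRUE),
                     paste0(prefix, ".ld.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  vars <- ld$variants
  vars$maf <- ld$maf
  vars$n_ref <- if (is.infinite(ld$n_ref)) "exact" else ld$n_ref
  utils::write.table(vars, paste0(prefix, ".vars.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read an LD matrix written by [write_ld_matrix()]
#'
#' @param prefix file prefix used at write time.
#' @return An [ld_matrix].
#' @export
read_ld_matrix <- function(prefix) {
  ld_path <- paste0(prefix, ".ld.tsv")
  var_path <- paste0(prefix, ".vars.tsv")
  if (!file.exists(ld_path) || !file.exists(var_path)) {
    stop("LD matrix files not found for prefix: ", prefix)
  }
  C <- as.matrix(utils::read.table(ld_path, sep = "\t", header = FALSE))
  dimnames(C) <- NULL
  vars <- utils::read.delim(var_path, sep = "\t", stringsAsFactors = FALSE)
  n_ref <- if (identical(as.character(vars$n_ref[1]), "exact")) Inf
           else as.numeric(vars$n_ref[1])
  ld_matrix(C, vars[c("chrom", "pos", "a1", "a2")], n_ref = n_ref,
            maf = vars$maf)
}
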