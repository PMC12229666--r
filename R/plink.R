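# PLINK-1 binary genotype I/O (.bed/.bim/.fam, SNP-major) and LD estimation.
#
# The 2-bit .bed encoding per variant, packed 4 samples per byte, LSB first:
#   00 homozygous a1 (dosage 2 copies of the .bim A1 allele)
#   01 missing
#   10 heterozygous (dosage 1)
#   11 homozygous a2 (dosage 0)
# Dosages here count the .bim A1 (effect) allele.

BED_MAGIC <- as.raw(c(0x6c, 0x1b))
BED_SNP_MAJOR <- as.raw(0x01)

#' Read a PLINK-1 binary genotype fileset
#'
#' @param bed_prefix path prefix; `<prefix>.bed`, `<prefix>.bim` and
#'   `<prefix>.fam` must exist.
#' @return A `genotype_panel`: list with `dosages` (samples x variants integer
#'   matrix, NA for missing), `variants` (chrom/pos/a1/a2 data.frame) and
#'   `samples` (fid/iid data.frame).
#' @export
read_genotype_panel <- function(bed_prefix) {
  bed <- paste0(bed_prefix, ".bed")
  bim <- paste0(bed_prefix, ".bim")
  fam <- paste0(bed_prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) stop("PLINK file not found: ", f)
  }
  bim_df <- utils::read.table(bim, stringsAsFactors = FALSE,
                              col.names = c("chrom", "id", "cm", "pos",
                                            "a1", "a2"))
  fam_df <- utils::read.table(fam, stringsAsFactors = FALSE,
                              col.names = c("fid", "iid", "pat", "mat",
                                            "sex", "pheno"))
  n <- nrow(fam_df)
  m <- nrow(bim_df)
  raw <- readBin(bed, what = "raw", n = file.info(bed)$size)
  if (length(raw) < 3L || !identical(raw[1:2], BED_MAGIC)) {
    stop(".bed magic bytes missing: not a PLINK-1 binary file")
  }
  if (!identical(raw[3], BED_SNP_MAJOR)) {
    stop(".bed is not in SNP-major mode")
  }
  bytes_per_variant <- ceiling(n / 4)
  expected <- 3L + bytes_per_variant * m
  if (length(raw) != expected) {
    stop(sprintf(".bed size mismatch: %d bytes, expected %d for %d samples x %d variants",
                 length(raw), expected, n, m))
  }
  body <- raw[-(1:3)]
  # decode all 2-bit codes at once
  ints <- as.integer(body)
  codes <- cbind(ints %% 4L, (ints %/% 4L) %% 4L,
                 (ints %/% 16L) %% 4L, (ints %/% 64L) %% 4L)
  codes <- matrix(t(codes), nrow = bytes_per_variant * 4L, ncol = m)
  codes <- codes[seq_len(n), , drop = FALSE]
  # code -> dosage of A1: 0 -> 2, 1 -> NA, 2 -> 1, 3 -> 0
  lookup <- c(2L, NA_integer_, 1L, 0L)
  dosages <- matrix(lookup[codes + 1L], nrow = n, ncol = m)
  structure(
    list(dosages = dosages,
         variants = bim_df[c("chrom", "pos", "a1", "a2")],
         samples = fam_df[c("fid", "iid")]),
    class = "genotype_panel"
  )
}

#' Write a genotype panel as a PLINK-1 binary fileset
#'
#' @param panel a `genotype_panel` (as returned by [read_genotype_panel()], or
#'   a list with the same fields).
#' @param bed_prefix output path prefix.
#' @export
write_genotype_panel <- function(panel, bed_prefix) {
  dos <- panel$dosages
  n <- nrow(dos)
  m <- ncol(dos)
  # dosage -> code: 2 -> 0, NA -> 1, 1 -> 2, 0 -> 3
  codes <- matrix(3L, nrow = n, ncol = m)
  codes[dos == 1L] <- 2L
  codes[dos == 2L] <- 0L
  codes[is.na(dos)] <- 1L
  pad <- (4L - n %% 4L) %% 4L
  if (pad > 0L) codes <- rbind(codes, matrix(0L, nrow = pad, ncol = m))
  i1 <- seq(1L, nrow(codes), by = 4L)
  bytes <- codes[i1, , drop = FALSE] +
    4L * codes[i1 + 1L, , drop = FALSE] +
    16L * codes[i1 + 2L, , drop = FALSE] +
    64L * codes[i1 + 3L, , drop = FALSE]
  con <- file(paste0(bed_prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(c(BED_MAGIC, BED_SNP_MAJOR, as.raw(bytes)), con)
  vars <- panel$variants
  bim <- data.frame(chrom = vars$chrom,
                    id = paste0(vars$chrom, ":", vars$pos),
                    cm = 0, pos = vars$pos, a1 = vars$a1, a2 = vars$a2)
  utils::write.table(bim, paste0(bed_prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  samp <- panel$samples %||% data.frame(fid = seq_len(n), iid = seq_len(n))
  fam <- data.frame(fid = samp$fid, iid = samp$iid, pat = 0, mat = 0,
                    sex = 0, pheno = -9)
  utils::write.table(fam, paste0(bed_prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(bed_prefix)
}

#' Compute a regional LD matrix from a genotype panel
#'
#' Pairwise Pearson correlation of mean-imputed, standardized allele dosages
#' (the `C = G'G/n` definition with genotypes normalized to zero mean and unit
#' variance). Monomorphic variants are excluded with a warning, since their
#' correlation is undefined.
#'
#' @param panel a `genotype_panel`.
#' @param variants optional integer indices (or logical mask) selecting a
#'   variant subset.
#' @return An [ld_matrix] with `n_ref` set to the panel sample count and MAF
#'   computed from the panel.
#' @export
compute_ld <- function(panel, variants = NULL) {
  dos <- panel$dosages
  meta <- panel$variants
  if (!is.null(variants)) {
    dos <- dos[, variants, drop = FALSE]
    meta <- meta[variants, , drop = FALSE]
  }
  n <- nrow(dos)
  if (n < 2L) stop("need at least 2 samples to estimate LD")
  G <- apply(dos, 2, function(g) {
    mu <- mean(g, na.rm = TRUE)
    g[is.na(g)] <- mu
    g
  })
  sds <- apply(G, 2, stats::sd)
  poly <- sds > 0
  if (any(!poly)) {
    warning(sum(!poly), " monomorphic variant(s) excluded from LD computation")
    G <- G[, poly, drop = FALSE]
    meta <- meta[poly, , drop = FALSE]
  }
  if (ncol(G) == 0L) stop("no polymorphic variants left for LD computation")
  C <- stats::cor(G)
  dimnames(C) <- NULL
  af <- colMeans(G) / 2          # frequency of the A1 allele
  maf <- pmin(af, 1 - af)
  ld_matrix(C, meta, n_ref = n, maf = maf)
}
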