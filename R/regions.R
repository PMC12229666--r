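# Associated-region definition: greedy P-value clumping against LD,
# interval merging of clumped windows, and instrument selection for the
# IV-based estimators.

#' Greedy P-value clumping
#'
#' PLINK-style clumping: repeatedly take the smallest-P unassigned variant
#' with `p <= p_thresh` as an index variant, and assign to its clump every
#' unassigned variant on the same chromosome within `window_kb` of it with
#' squared correlation `r2 >= r2_thresh` to it. Ties on P are broken by
#' genomic position (smaller wins) so the result is deterministic.
#'
#' @param stats a [summary_stats] object aligned with `ld` (same variants,
#'   same order).
#' @param ld an [ld_matrix].
#' @param window_kb clumping window in kilobases (default 250).
#' @param r2_thresh LD r-squared threshold (default 0.01).
#' @param p_thresh index P-value threshold (default 5e-8).
#' @return list of clumps, each a list with `index` (variant row index) and
#'   `members` (row indices, including the index). Empty list when nothing is
#'   significant.
#' @export
clump <- function(stats, ld, window_kb = 250, r2_thresh = 0.01,
                  p_thresh = 5e-8) {
  stopifnot(nrow(stats) == nrow(ld$C))
  m <- nrow(stats)
  r2 <- ld$C^2
  window <- window_kb * 1000
  unassigned <- rep(TRUE, m)
  ord <- order(stats$p, stats$pos)
  clumps <- list()
  for (i in ord) {
    if (!unassigned[i] || stats$p[i] > p_thresh) next
    members <- which(unassigned &
                       stats$chrom == stats$chrom[i] &
                       abs(stats$pos - stats$pos[i]) <= window &
                       r2[, i] >= r2_thresh)
    members <- union(i, members)
    unassigned[members] <- FALSE
    clumps[[length(clumps) + 1L]] <- list(index = i, members = sort(members))
  }
  clumps
}

#' Merge clump windows into associated regions
#'
#' Each index variant spawns the interval `[pos - window, pos + window]`;
#' overlapping or adjacent intervals on the same chromosome are unioned, so
#' merged regions can be much larger than a single window.
#'
#' @param stats the [summary_stats] the clumps refer to.
#' @param clumps output of [clump()].
#' @param window_kb half-window in kilobases around each index variant.
#' @return data.frame with columns chrom, start, end (1-based inclusive) and
#'   `n_index` (number of index variants merged into the region).
#' @export
regions_from_clumps <- function(stats, clumps, window_kb = 250) {
  if (length(clumps) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_index = integer()))
  }
  window <- window_kb * 1000
  idx <- vapply(clumps, `[[`, integer(1), "index")
  iv <- data.frame(chrom = stats$chrom[idx],
                   start = pmax(1, stats$pos[idx] - window),
                   end = stats$pos[idx] + window)
  iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
  out <- list()
  cur <- NULL
  n_index <- 0L
  for (k in seq_len(nrow(iv))) {
    row <- iv[k, ]
    if (is.null(cur) || row$chrom != cur$chrom || row$start > cur$end + 1) {
      if (!is.null(cur)) {
        cur$n_index <- n_index
        out[[length(out) + 1L]] <- cur
      }
      cur <- row
      n_index <- 1L
    } else {
      cur$end <- max(cur$end, row$end)
      n_index <- n_index + 1L
    }
  }
  cur$n_index <- n_index
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select approximately independent instruments in a region
#'
#' Returns the clump index variants: mutually `r2 < r2_thresh`, each with
#' `p <= p_thresh`. May be empty (exposure not instrumentable).
#'
#' @inheritParams clump
#' @return integer vector of variant row indices, ordered by position.
#' @export
select_instruments <- function(stats, ld, p_thresh = 5e-8,
                               r2_thresh = 0.01, window_kb = Inf) {
  cl <- clump(stats, ld, window_kb = window_kb, r2_thresh = r2_thresh,
              p_thresh = p_thresh)
  sort(vapply(cl, `[[`, integer(1), "index"))
}

#' Export regions as a BED table (0-based half-open)
#'
#' @param regions data.frame from [regions_from_clumps()].
#' @param path output file.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom, start = regions$start - 1L,
                    end = regions$end)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
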