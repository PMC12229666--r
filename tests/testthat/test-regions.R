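# Independent reference implementations used as oracles.

clump_oracle <- function(p, pos, chrom, r2, window, r2_thresh, p_thresh) {
  assigned <- rep(FALSE, length(p))
  out <- list()
  repeat {
    cand <- which(!assigned & p <= p_thresh)
    if (!length(cand)) break
    idx <- cand[order(p[cand], pos[cand])][1]
    mem <- which(!assigned & chrom == chrom[idx] &
                   abs(pos - pos[idx]) <= window & r2[, idx] >= r2_thresh)
    mem <- sort(union(idx, mem))
    assigned[mem] <- TRUE
    out[[length(out) + 1L]] <- list(index = idx, members = mem)
  }
  out
}

union_oracle <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  res <- list()
  s <- start[1]; e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= e + 1) e <- max(e, end[i]) else {
      res[[length(res) + 1L]] <- c(s, e); s <- start[i]; e <- end[i]
    }
  }
  res[[length(res) + 1L]] <- c(s, e)
  do.call(rbind, res)
}

planted_ld <- function() synth_ld(m = 50, block_size = 10, rho = 0.85, seed = 3)

test_that("clumping matches the reference implementation on planted blocks", {
  ld <- planted_ld()
  set.seed(4)
  z <- rnorm(50)
  z[c(5, 25, 42)] <- c(9, -8, 7.5)        # three planted signals
  z[6] <- 8.5                              # in LD with SNP 5
  stats <- toy_stats(z, n = 1e5, variants = ld$variants)
  cl <- clump(stats, ld, window_kb = 250, r2_thresh = 0.01, p_thresh = 5e-8)
  or <- clump_oracle(stats$p, stats$pos, stats$chrom, ld$C^2,
                     250 * 1000, 0.01, 5e-8)
  expect_equal(length(cl), length(or))
  for (k in seq_along(cl)) {
    expect_equal(cl[[k]]$index, or[[k]]$index)
    expect_equal(cl[[k]]$members, or[[k]]$members)
  }
  # clumps partition: no variant assigned twice
  all_members <- unlist(lapply(cl, `[[`, "members"))
  expect_equal(anyDuplicated(all_members), 0L)
})

test_that("independent distant signals become separate index variants", {
  m <- 20
  vars <- toy_variants(m, spacing = 100000L)   # 100 kb spacing, 2 Mb span
  z <- rep(0.1, m); z[3] <- 9; z[15] <- 8      # 1.2 Mb apart, r2 = 0
  stats <- toy_stats(z, n = 1e5, variants = vars)
  ld <- ld_matrix(diag(m), vars)
  cl <- clump(stats, ld)
  expect_equal(sort(vapply(cl, `[[`, integer(1), "index")), c(3L, 15L))
})

test_that("clump windows merge into regions exactly as interval union", {
  # indices at 1.0 and 1.2 Mb with 250 kb windows merge to [0.75, 1.45] Mb
  vars <- data.frame(chrom = "1", pos = c(1000000L, 1200000L),
                     a1 = "A", a2 = "G")
  stats <- toy_stats(c(9, 9.5), n = 1e5, variants = vars)
  ld <- ld_matrix(diag(2), vars)
  cl <- clump(stats, ld)
  reg <- regions_from_clumps(stats, cl, window_kb = 250)
  expect_equal(nrow(reg), 1L)
  expect_equal(c(reg$start, reg$end), c(750000L, 1450000L))

  # different chromosomes never merge
  vars2 <- vars; vars2$chrom <- c("1", "2")
  stats2 <- toy_stats(c(9, 9.5), n = 1e5, variants = vars2)
  reg2 <- regions_from_clumps(stats2, clump(stats2, ld_matrix(diag(2), vars2)),
                              window_kb = 250)
  expect_equal(nrow(reg2), 2L)

  # random index sets agree with an independent interval-union routine
  set.seed(9)
  for (rep in 1:5) {
    k <- sample(3:8, 1)
    pos <- sort(sample.int(5e6, k))
    vars_r <- data.frame(chrom = "7", pos = pos, a1 = "A", a2 = "G")
    stats_r <- toy_stats(rep(9, k), n = 1e5, variants = vars_r)
    reg_r <- regions_from_clumps(stats_r,
                                 clump(stats_r, ld_matrix(diag(k), vars_r),
                                       r2_thresh = 1.01),
                                 window_kb = 100)
    or <- union_oracle(pmax(1, pos - 100000), pos + 100000)
    expect_equal(cbind(reg_r$start, reg_r$end), unname(or))
  }
})

test_that("region merging is order independent", {
  vars <- data.frame(chrom = "3", pos = c(500000L, 620000L, 2000000L),
                     a1 = "A", a2 = "G")
  stats_fwd <- toy_stats(c(9, 10, 11), n = 1e5, variants = vars)
  ld <- ld_matrix(diag(3), vars)
  stats_rev <- toy_stats(c(11, 10, 9), n = 1e5, variants = vars)
  r1 <- regions_from_clumps(stats_fwd, clump(stats_fwd, ld), window_kb = 100)
  r2 <- regions_from_clumps(stats_rev, clump(stats_rev, ld), window_kb = 100)
  expect_equal(r1[c("chrom", "start", "end")], r2[c("chrom", "start", "end")])
})

test_that("instrument selection returns mutually independent significant SNPs", {
  ld <- planted_ld()
  set.seed(8)
  z <- rnorm(50) * 0.5
  z[c(5, 25, 42)] <- c(9, -8, 7.5)
  stats <- toy_stats(z, n = 1e5, variants = ld$variants)
  iv <- select_instruments(stats, ld)
  expect_equal(iv, c(5L, 25L, 42L))
  r2 <- ld$C[iv, iv]^2
  expect_true(all(r2[upper.tri(r2)] < 0.01))
  expect_true(all(stats$p[iv] <= 5e-8))

  # of two correlated significant SNPs only the smaller-P one survives
  vars <- toy_variants(2)
  C <- matrix(c(1, sqrt(0.5), sqrt(0.5), 1), 2)
  stats2 <- toy_stats(c(8, 9), n = 1e5, variants = vars)
  expect_equal(select_instruments(stats2, ld_matrix(C, vars)), 2L)

  # single significant SNP: sole instrument
  stats3 <- toy_stats(c(0.5, 9), n = 1e5, variants = vars)
  expect_equal(select_instruments(stats3, ld_matrix(diag(2), vars)), 2L)
})
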