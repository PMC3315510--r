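test_that("GC bins are equally sized, consecutive in GC, with extras at the low end", {
  feats6 <- toy_features(seq(0.3, 0.6, length.out = 6))
  expect_equal(make_gc_bins(feats6, 1)$bin, rep(1L, 6))
  b3 <- make_gc_bins(feats6, 3)
  expect_equal(as.integer(table(b3$bin)), c(2L, 2L, 2L))
  expect_equal(b3$bin[order(feats6$gc)][1:2], c(1L, 1L))
  feats7 <- toy_features(c(0.5, 0.31, 0.44, 0.62, 0.38, 0.55, 0.47))
  b7 <- make_gc_bins(feats7, 3)
  sizes <- as.integer(table(b7$bin))
  expect_equal(sort(sizes, decreasing = TRUE), c(3L, 2L, 2L))
  expect_equal(sizes[1], 3L)  # extra gene goes to the lowest-GC bin
  # bin index non-decreasing in gc
  expect_true(all(diff(b7$bin[order(feats7$gc)]) >= 0))
  expect_error(make_gc_bins(feats6, 7), "must not exceed")
  expect_warning(make_gc_bins(toy_features(rep(0.5, 5)), 3), "single bin")
})

test_that("loess normalization recenters residuals at the median", {
  gc <- seq(0.2, 0.8, length.out = 200)
  # constant log-counts pass through unchanged
  expect_equal(loess_normalize(rep(3, 200), gc), rep(3, 200))
  # an exactly linear trend is flattened to the median
  y <- 1 + 2 * gc
  out <- loess_normalize(y, gc)
  interior <- gc > 0.25 & gc < 0.75
  expect_lt(max(abs(out[interior] - median(y))), 1e-6)
  # the median is recentered onto the input median, up to the median of
  # the loess residuals (near but not exactly zero for noisy input)
  set.seed(9)
  y2 <- rnorm(200, 5) - 3 * (gc - 0.5)^2
  expect_lt(abs(median(loess_normalize(y2, gc)) - median(y2)), 0.05)
  expect_error(loess_normalize(y2, rep(0.5, 200)), "constant")
  expect_error(loess_normalize(y2[1:5], gc[1:5]), "at least 10")
})

test_that("global-scaling shifts each GC stratum to the global summary", {
  # K = 1: bin statistic equals the global statistic
  y <- c(2.3, 4.1, 0.7, 3.3)
  expect_equal(global_scaling_normalize(y, rep(1, 4)), y)
  # two-bin hand oracle
  expect_equal(global_scaling_normalize(1:6, c(1, 1, 1, 2, 2, 2)),
               c(2.5, 3.5, 4.5, 2.5, 3.5, 4.5))
  # with odd-sized bins and T = median, the output median equals the input median
  set.seed(3)
  for (i in 1:5) {
    y <- rnorm(15)
    bin <- rep(1:3, each = 5)
    out <- global_scaling_normalize(y, bin)
    expect_equal(median(out), median(y))
  }
  # upper-quartile variant: every bin's upper quartile lands on the global one
  set.seed(8)
  yq <- rnorm(40)
  binq <- rep(1:4, each = 10)
  uq <- function(x) quantile(x, 0.75, names = FALSE)
  outq <- global_scaling_normalize(yq, binq, summary_fn = uq)
  expect_equal(as.numeric(tapply(outq, binq, uq)), rep(uq(yq), 4))
})

test_that("within-bin full-quantile matching equalizes bin distributions", {
  # already-matched bins pass through
  y0 <- c(1, 3, 5, 5, 1, 3)
  expect_equal(full_quantile_normalize_within(y0, c(1, 1, 1, 2, 2, 2)), y0)
  # two-bin hand oracle: reference is the rank-wise median
  out <- full_quantile_normalize_within(c(1, 3, 5, 2, 4, 8), c(1, 1, 1, 2, 2, 2))
  expect_equal(out, c(1.5, 3.5, 6.5, 1.5, 3.5, 6.5))
  # sorted values identical across bins afterwards; ranks preserved within bin
  set.seed(21)
  y <- rnorm(300)
  bin <- make_gc_bins(toy_features(runif(300)), 6)$bin
  out2 <- full_quantile_normalize_within(y, bin)
  srt <- tapply(out2, bin, sort)
  for (b in 2:6) expect_equal(unname(srt[[b]]), unname(srt[[1]]))
  for (b in 1:6) expect_equal(order(out2[bin == b]), order(y[bin == b]))
  # unequal bin sizes (differing by one) still work and preserve ranks
  y3 <- rnorm(20)
  bin3 <- make_gc_bins(toy_features(runif(20)), 3)$bin
  out3 <- full_quantile_normalize_within(y3, bin3)
  for (b in 1:3) expect_equal(order(out3[bin3 == b]), order(y3[bin3 == b]))
})

test_that("lane-level normalization is lane-local and returns integer counts", {
  sim <- simulate_counts(sim_config(n_genes = 400, seed = 31))
  for (m in c("full", "median", "upper", "loess")) {
    norm <- normalize_within_lane(sim$counts, sim$features, method = m, K = 8)
    vals <- as.matrix(norm[, -1])
    expect_true(all(vals >= 0) && all(vals == round(vals)))
    expect_equal(dim(norm), dim(sim$counts))
    expect_equal(norm$gene_id, sim$counts$gene_id)
  }
  # duplicated lane columns normalize identically; other lanes are irrelevant
  cm <- sim$counts
  cm$dup <- cm[[2]]
  norm2 <- normalize_within_lane(cm, sim$features, method = "full", K = 8)
  expect_equal(norm2$dup, norm2[[2]])
  shuffled <- cm[, c(1, 4, 3, 2, sample(5:ncol(cm)))]
  norm3 <- normalize_within_lane(shuffled, sim$features, method = "full", K = 8)
  expect_equal(norm3[[names(cm)[2]]], norm2[[2]])
})

test_that("a lane with no GC dependence is left nearly unchanged", {
  sim <- simulate_counts(sim_config(n_genes = 1500, phi = 0.05,
                                    gc_bias_curvature = 0,
                                    depth_factors = rep(1, 8), seed = 17))
  norm <- normalize_within_lane(sim$counts, sim$features, method = "full", K = 10)
  off <- counts_to_offsets(sim$counts, norm)
  # residual offsets reflect only count discreteness and within-bin
  # sampling noise (~0.05-0.1 on the log scale), far below the ~0.5+
  # offsets seen when a real GC effect is being removed
  expect_lt(median(abs(as.matrix(off[, -1]))), 0.1)
  expect_lt(abs(median(as.matrix(off[, -1]))), 0.02)  # no systematic shift
})

test_that("full-quantile GC normalization removes a strong injected GC trend", {
  sim <- simulate_counts(sim_config(n_genes = 2000, phi = 0.078, seed = 23))
  norm <- normalize_within_lane(sim$counts, sim$features, method = "full", K = 50)
  gc <- sim$features$gc
  for (lane in c("lib1_lane1", "lib3_lane1")) {
    r_raw <- gc_lowess_range(log(sim$counts[[lane]] + 1), gc)
    r_norm <- gc_lowess_range(log(norm[[lane]] + 1), gc)
    expect_lt(r_norm, 0.1 * r_raw)
  }
})

test_that("offsets are the log difference and reconstruct normalized counts", {
  sim <- simulate_counts(sim_config(n_genes = 300, seed = 41))
  expect_equal(as.matrix(counts_to_offsets(sim$counts, sim$counts)[, -1]),
               matrix(0, 300, 8), ignore_attr = TRUE)
  raw <- toy_counts(matrix(c(9, 9), 1), lanes = c("A", "B"))
  nrm <- toy_counts(matrix(c(18, 9), 1), lanes = c("A", "B"))
  off <- counts_to_offsets(raw, nrm, delta = 1)
  expect_equal(off$A, log(19 / 10))
  expect_equal(off$B, 0)
  expect_equal(counts_to_offsets(raw, nrm, scale = "count")$A, 9)
  # round-trip over a real normalization
  norm <- normalize_within_lane(sim$counts, sim$features, "full", K = 10)
  off2 <- counts_to_offsets(sim$counts, norm)
  rebuilt <- round(exp(log(as.matrix(sim$counts[, -1]) + 1) +
                         as.matrix(off2[, -1])) - 1)
  expect_equal(rebuilt, as.matrix(norm[, -1]), ignore_attr = TRUE)
  expect_error(counts_to_offsets(sim$counts, sim$counts[1:10, ]), "shape")
})
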