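test_that("mad_diff follows the lag-1 difference formula", {
  expect_equal(mad_diff(rep(3, 10)), 0)
  expect_equal(mad_diff(seq(0, 9, by = 0.5)), 0)  # constant-step ramp
  # hand enumeration: diffs 2,-1,3,-2; median 0.5; |d-0.5| -> median 2
  expect_equal(mad_diff(c(0, 2, 1, 4, 2)), 1.4826 * 2 / sqrt(2))
  expect_error(mad_diff(c(1, 2)), "3")
  # shift invariance and scale equivariance
  set.seed(71)
  x <- rnorm(100)
  expect_equal(mad_diff(x + 5), mad_diff(x))
  expect_equal(mad_diff(3 * x), 3 * mad_diff(x))
})

test_that("mad_diff agrees with the reference implementation", {
  skip_if_not_installed("matrixStats")
  set.seed(72)
  for (n in c(10, 57, 200)) {
    x <- cumsum(rnorm(n))
    expect_equal(mad_diff(x), matrixStats::madDiff(x), tolerance = 1e-12)
  }
})

test_that("signal-to-noise uses the dominant overlapping segment", {
  segs <- structure(data.frame(chrom = c("chr6", "chr6"),
                               start = c(0, 3e7), end = c(3e7, 1e8),
                               n_bins = c(10L, 20L),
                               mean = c(0.722, 0.05)),
                    class = c("segment_set", "data.frame"))
  region <- list(chrom = "chr6", start = 0, end = 3e7)
  expect_equal(round(signal_to_noise(segs, 0.206, region), 2), 3.50)
  segs$mean <- c(-0.626, 0.05)
  expect_equal(round(signal_to_noise(segs, 0.479, region), 2), 1.31)
  segs$mean <- c(0, 0.05)
  expect_equal(signal_to_noise(segs, 0.2, region), 0)
  expect_error(signal_to_noise(segs, 0, region), "positive")
  expect_error(signal_to_noise(segs, 0.2,
                               list(chrom = "chr7", start = 0, end = 1e7)),
               "overlap")
})

test_that("array pseudo counts match hand enumeration in both modes", {
  layout <- genome_layout("chr1", 30000)
  bins <- make_bins(layout, 10000)
  centred <- data.frame(chrom = "chr1", position = c(5000, 15000, 25000),
                        intensity = c(0.1, -0.5, 1.2))
  expect_equal(array_pseudocounts(centred, bins, "nearest"),
               centred$intensity)
  expect_equal(array_pseudocounts(centred, bins, "mean"), centred$intensity)

  # 7 probes over 3 bins, none in the last bin
  probes <- data.frame(chrom = "chr1",
                       position = c(100, 4000, 9000, 9900, 12000, 19000, 19999),
                       intensity = c(1, 2, 3, 4, 5, 6, 7))
  got_mean <- array_pseudocounts(probes, bins, "mean")
  expect_equal(got_mean, c(mean(c(1, 2, 3, 4)), mean(c(5, 6, 7)), NA))
  got_near <- array_pseudocounts(probes, bins, "nearest")
  # centers 5000, 15000, 25000 -> nearest probes 4000, 12000, 19999
  expect_equal(got_near, c(2, 5, 7))
  expect_error(array_pseudocounts(probes[0, ], bins), "empty")
})

test_that("segment concordance equals its per-bp expansion oracle", {
  a <- structure(data.frame(chrom = "chr1", start = c(0, 10, 30),
                            end = c(10, 30, 50), n_bins = c(1L, 2L, 2L),
                            mean = c(0.5, -1, 0.2)),
                 class = c("segment_set", "data.frame"))
  expect_equal(segment_concordance(a, a)$weighted_euclidean, 0)
  expect_equal(segment_concordance(a, a)$weighted_pearson, 1)

  shifted <- a; shifted$mean <- a$mean + 0.3
  cs <- segment_concordance(a, shifted)
  expect_equal(cs$weighted_euclidean, 0.3)
  expect_equal(cs$weighted_pearson, 1)

  b <- structure(data.frame(chrom = "chr1", start = c(0, 25), end = c(25, 50),
                            n_bins = c(3L, 2L), mean = c(0.4, -0.3)),
                 class = c("segment_set", "data.frame"))
  got <- segment_concordance(a, b)
  # expansion oracle: repeat each overlap's value pair once per bp
  av <- bv <- numeric(0)
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    o <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (o > 0) { av <- c(av, rep(a$mean[i], o)); bv <- c(bv, rep(b$mean[j], o)) }
  }
  expect_equal(got$weighted_euclidean, sqrt(mean((av - bv)^2)))
  expect_equal(got$weighted_pearson, cor(av, bv))
  expect_equal(got$total_weight, length(av))

  far <- a; far$chrom <- "chr9"
  # suppress the GRanges no-common-seqlevels warning; the error is the point
  expect_error(suppressWarnings(segment_concordance(a, far)), "overlap")
})

test_that("random placement recovers the exact enumeration probability", {
  layout <- genome_layout("c1", 100)
  ann <- interval_set("c1", 0, 50)
  query <- interval_set("c1", 10, 20)
  out <- random_placement_overlap(query, ann, layout, n_sim = 4000, seed = 13)
  # exact enumeration over every placement of a width-10 interval
  hits <- sum(vapply(0:90, function(s) s < 50 && s + 10 > 0, logical(1)))
  p_true <- hits / 91
  se <- sqrt(p_true * (1 - p_true) / 4000)
  expect_lt(abs(mean(out$simulated) - p_true), 4 * se)
  expect_equal(out$observed, 1)

  whole <- interval_set("c1", 0, 100)
  res <- random_placement_overlap(query, whole, layout, n_sim = 50, seed = 1)
  expect_true(all(res$simulated == 1))
  expect_equal(res$p, 1)

  none <- random_placement_overlap(query, interval_set(), layout,
                                   n_sim = 50, seed = 1)
  expect_equal(none$observed, 0)
  expect_true(all(none$simulated == 0))
  expect_error(random_placement_overlap(interval_set("c1", 0, 99, layout = layout),
                                        ann,
                                        genome_layout("c1", 50),
                                        n_sim = 10, seed = 1),
               "longer")
})
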