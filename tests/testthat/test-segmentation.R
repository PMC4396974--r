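test_that("best_split matches exhaustive arc enumeration on random vectors", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    x <- rnorm(n) + rep(c(0, sample(c(0, 1.5), 1)), c(n %/% 2, n - n %/% 2))
    got <- offtargetCN:::cpp_max_arc(x, 2L)
    want <- brute_force_max_arc(x, 2)
    expect_true(isTRUE(got$found))
    expect_equal(got$i, want$i)
    expect_equal(got$j, want$j)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-8)
  }
})

test_that("a constant vector is never split", {
  out <- best_split(rep(1.5, 40),
                    segmentation_config(n_permutations = 500, seed = 1))
  expect_false(out$split)
  expect_gte(out$p, 0.99)  # every permutation ties the zero statistic
})

test_that("a noiseless step is split exactly at the change point", {
  x <- c(0, 0, 0, 3, 3, 3)
  set.seed(1)
  out <- best_split(x, segmentation_config(n_permutations = 500))
  # both the low and the high arc identify the boundary between 3 and 4
  expect_true((out$arc_start == 1 && out$arc_end == 3) ||
                (out$arc_start == 4 && out$arc_end == 6))

  prof <- data.frame(chrom = "chr1",
                     start = seq(0, 190000, by = 10000),
                     end = seq(10000, 200000, by = 10000),
                     log2 = rep(c(-0.2, 0.8), each = 10))
  segs <- cbs_segment(prof, segmentation_config(n_permutations = 1000,
                                                seed = 5))
  expect_equal(nrow(segs), 2)
  expect_equal(segs$mean, c(-0.2, 0.8))
  expect_equal(segs$end[1], 100000)
  expect_equal(segs$n_bins, c(10, 10))
})

test_that("flat noise yields one segment per chromosome", {
  set.seed(41)
  prof <- data.frame(chrom = rep(c("chr1", "chr2"), each = 250),
                     start = rep(seq(0, 249) * 20000, 2),
                     end = rep(seq(1, 250) * 20000, 2),
                     log2 = rnorm(500, 0, 0.1))
  segs <- cbs_segment(prof, segmentation_config(n_permutations = 2000,
                                                seed = 6))
  expect_equal(nrow(segs), 2)
  expect_equal(segs$chrom, c("chr1", "chr2"))
})

test_that("breakpoints of a noisy multi-step profile are recovered", {
  set.seed(51)
  n <- 1000
  truth_levels <- rep(c(0, 0.8, 0, -0.7), c(250, 150, 400, 200))
  prof <- data.frame(chrom = "chr1", start = (seq_len(n) - 1) * 20000,
                     end = seq_len(n) * 20000,
                     log2 = truth_levels + rnorm(n, 0, 0.2))
  segs <- cbs_segment(prof, segmentation_config(n_permutations = 2000,
                                                seed = 7))
  expect_equal(nrow(segs), 4)
  got_bp <- segs$start[-1] / 20000
  expect_true(all(abs(got_bp - c(250, 400, 800)) <= 1))
  # conservation: length-weighted mean of segment means = overall mean
  expect_equal(sum(segs$mean * segs$n_bins) / sum(segs$n_bins),
               mean(prof$log2))
})

test_that("segmentation is deterministic and monotone in alpha", {
  set.seed(61)
  n <- 300
  vals <- rep(c(0, 0.6, 0), c(100, 100, 100)) + rnorm(n, 0, 0.25)
  prof <- data.frame(chrom = "chr1", start = (seq_len(n) - 1) * 1000,
                     end = seq_len(n) * 1000, log2 = vals)
  a <- cbs_segment(prof, segmentation_config(n_permutations = 1000, seed = 3))
  b <- cbs_segment(prof, segmentation_config(n_permutations = 1000, seed = 3))
  expect_identical(a, b)
  counts <- vapply(c(0.001, 0.01, 0.2), function(al)
    nrow(cbs_segment(prof, segmentation_config(alpha = al,
                                               n_permutations = 1000,
                                               seed = 3))),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("unusable bins are skipped but spanned by segment coordinates", {
  prof <- data.frame(chrom = "chr1",
                     start = (0:39) * 1000, end = (1:40) * 1000,
                     log2 = c(rep(0, 20), rep(2, 20)),
                     usable = rep(c(TRUE, FALSE), 20))
  segs <- cbs_segment(prof, segmentation_config(n_permutations = 500,
                                                seed = 2))
  expect_equal(sum(segs$n_bins), 20)  # only usable bins counted
  expect_equal(nrow(segs), 2)
  expect_equal(segs$start[2], 20000)  # spans the preceding skipped bin
  expect_error(cbs_segment(prof[0, ], segmentation_config()), "empty")
})

test_that("SEG files round-trip with 1-based inclusive starts", {
  segs <- structure(data.frame(chrom = c("chr1", "chr1"),
                               start = c(0, 100000), end = c(100000, 240000),
                               n_bins = c(5L, 7L), mean = c(0.25, -1.1)),
                    class = c("segment_set", "data.frame"))
  f <- tempfile(fileext = ".seg")
  write_seg(segs, f, sample = "s1")
  txt <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(txt$loc.start, c(1, 100001))
  back <- read_seg(f)
  expect_equal(back$start, segs$start)
  expect_equal(back$mean, segs$mean)
})
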