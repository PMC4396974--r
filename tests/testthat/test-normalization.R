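write_tiny_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- names(seqs)
  Biostrings::writeXStringSet(dna, path)
  Rsamtools::indexFa(path)
  path
}

test_that("GC fractions follow the base-count definition", {
  seqs <- c(chr1 = strrep("G", 100),
            chr2 = strrep("AT", 50),
            chr3 = strrep("ACGTN", 20))
  fa <- write_tiny_fasta(seqs)
  layout <- genome_layout(c("chr1", "chr2", "chr3"), c(100, 100, 100))
  bins <- make_bins(layout, 100)
  gc <- gc_fraction_per_bin(fa, bins)
  expect_equal(gc, c(1, 0, 0.5))  # N excluded from the denominator

  layout2 <- genome_layout("chrZ", 100)
  expect_error(gc_fraction_per_bin(fa, make_bins(layout2, 100)), "chrZ")
})

test_that("mappability is a length-weighted mean with absent bases as 0", {
  layout <- genome_layout("chr1", 40000)
  bins <- make_bins(layout, 20000)
  uni <- interval_set("chr1", 0, 40000, score = 1)
  expect_equal(mappability_per_bin(uni, bins), c(1, 1))
  half <- interval_set("chr1", 0, 10000, score = 1)
  expect_equal(mappability_per_bin(half, bins), c(0.5, 0))

  # fixture track vs per-base brute force
  set.seed(4)
  st <- seq(0, 38000, by = 2000)
  track <- interval_set(rep("chr1", length(st)), st,
                        st + sample(500:1900, length(st)),
                        score = round(runif(length(st)), 2))
  got <- mappability_per_bin(track, bins)
  base <- numeric(40000)
  for (i in seq_len(nrow(track)))
    base[(track$start[i] + 1):track$end[i]] <- track$score[i]
  expect_equal(got, c(mean(base[1:20000]), mean(base[20001:40000])))
})

test_that("loess correction flattens a known multiplicative bias", {
  # constant values stay constant under any covariate
  set.seed(6)
  covar <- runif(200, 0.3, 0.7)
  expect_equal(loess_correct(rep(5, 200), covar), rep(5, 200),
               tolerance = 1e-6)

  # exp(c) bias on a dense grid is corrected to the median within 2%
  c_grid <- seq(0.3, 0.7, length.out = 400)
  vals <- exp(c_grid)
  corr <- loess_correct(vals, c_grid)
  expect_true(all(abs(corr / median(vals) - 1) < 0.02))

  expect_error(loess_correct(1:10, runif(10)), "30")
})

test_that("loess correction preserves the median and is scale-equivariant", {
  set.seed(7)
  covar <- runif(300, 0.3, 0.7)
  vals <- 100 * exp(0.8 * covar) * exp(rnorm(300, sd = 0.05))
  corr <- loess_correct(vals, covar)
  expect_equal(median(corr, na.rm = TRUE), median(vals), tolerance = 0.02)
  corr2 <- loess_correct(3 * vals, covar)
  expect_equal(corr2, 3 * corr, tolerance = 1e-6)
})

test_that("an injected monotone GC bias is removed by the correction", {
  set.seed(8)
  n <- 600
  gc <- runif(n, 0.3, 0.6)
  counts <- rpois(n, 200 * exp(2.5 * (gc - 0.45)))
  log2_before <- log2(counts / median(counts))
  expect_gt(abs(cor(log2_before, gc)), 0.5)
  corr <- loess_correct(as.numeric(counts), gc)
  log2_after <- log2(corr / median(corr, na.rm = TRUE))
  ok <- is.finite(log2_after)
  expect_lt(abs(cor(log2_after[ok], gc[ok])), 0.1)
})

test_that("bin filters combine mappability, blacklist and zero-count rules", {
  prof <- data.frame(chrom = "chr1",
                     start = seq(0, 80000, by = 20000),
                     end = seq(20000, 100000, by = 20000),
                     length = 20000,
                     comp_doc = c(10, 0, 25, 40, NA),
                     mappability = c(0.9, 1, 0.1, 1, 1))
  bl <- interval_set("chr1", 60000, 80000)  # covers bin 4 entirely
  out <- apply_bin_filters(prof, bl, bin_filter_config())
  # bin1 ok; bin2 zero count; bin3 low mappability; bin4 blacklisted;
  # bin5 missing count
  expect_equal(out$usable, c(TRUE, FALSE, FALSE, FALSE, FALSE))

  clean <- apply_bin_filters(transform(prof, comp_doc = 10, mappability = 1),
                             interval_set(), bin_filter_config())
  expect_true(all(clean$usable))
})

test_that("median normalization centres usable autosomal bins at log2 = 0", {
  layout <- genome_layout(c("chr1", "chrX"), c(60000, 60000))
  expect_equal(median_normalize_log2(c(4, 4, 4), rep(TRUE, 3),
                                     rep("chr1", 3), layout),
               c(0, 0, 0))
  expect_equal(median_normalize_log2(c(1, 2, 4), rep(TRUE, 3),
                                     rep("chr1", 3), layout),
               c(-1, 0, 1))
  # sex chromosomes are excluded from the median
  set.seed(9)
  vals <- c(runif(50, 10, 30), runif(20, 5, 8))
  chrom <- c(rep("chr1", 50), rep("chrX", 20))
  l2 <- median_normalize_log2(vals, rep(TRUE, 70), chrom, layout)
  expect_equal(median(l2[chrom == "chr1"]), 0)
  expect_error(median_normalize_log2(c(0, NA), c(TRUE, TRUE),
                                     c("chr1", "chr1"), layout),
               "usable")
})

test_that("relative profiles subtract bin-wise and AND the usable flags", {
  out <- relative_log2(c(1, 0.5, NA), c(0.2, 0.5, 0.1),
                       c(TRUE, TRUE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(out$log2, c(0.8, 0, NA))
  expect_equal(out$usable, c(TRUE, FALSE, FALSE))
  expect_equal(relative_log2(c(1, 2), c(1, 2))$log2, c(0, 0))
  expect_error(relative_log2(1:3, 1:2), "grid")
})
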