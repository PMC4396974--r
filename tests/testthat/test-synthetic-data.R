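test_that("genome simulation is deterministic and carries the GC gradient", {
  cfg <- sim_config(chrom_lengths = c(c1 = 4e5), seed = 91)
  g1 <- simulate_genome(cfg, dir = tempdir(), name = "det_a")
  g2 <- simulate_genome(cfg, dir = tempdir(), name = "det_b")
  expect_identical(readLines(g1$fasta)[-1], readLines(g2$fasta)[-1])

  cfg2 <- sim_config(chrom_lengths = c(c1 = 5e6), seed = 92)
  g <- simulate_genome(cfg2, dir = tempdir(), name = "grad")
  bins <- make_bins(g$layout, 20000)
  gc <- gc_fraction_per_bin(g$fasta, bins)
  expect_gt(cor(gc, seq_along(gc), method = "spearman"), 0.9)

  expect_error(sim_config(chrom_lengths = c(c1 = 0), seed = 1))
  expect_error(sim_config(seed = NULL), "seed")
})

test_that("truth containers tile chromosomes and map to expected log2", {
  cfg <- sim_config(seed = 1)
  truth <- sim_truth(cfg, data.frame(chrom = "chr1", start = 2e6, end = 4e6,
                                     cn = 4))
  for (chr in unique(truth$chrom)) {
    t <- truth[truth$chrom == chr, ]
    expect_equal(t$start[1], 0)
    expect_equal(t$end[nrow(t)], unname(cfg$chrom_lengths[chr]))
    if (nrow(t) > 1) expect_equal(t$start[-1], t$end[-nrow(t)])
  }
  expect_error(sim_truth(cfg, data.frame(chrom = "chr1", start = 0,
                                         end = 2e7, cn = 3)),
               "exceed")

  layout <- genome_layout("chr1", 40000)
  bins <- make_bins(layout, 20000)
  flat <- sim_truth(c(chr1 = 40000))
  expect_equal(expected_log2_truth(flat, bins), c(0, 0))
  half <- sim_truth(c(chr1 = 40000),
                    data.frame(chrom = "chr1", start = 10000, end = 40000,
                               cn = 4))
  # bin 1: half CN2, half CN4 -> (0 + 1)/2
  expect_equal(expected_log2_truth(half, bins), c(0.5, 1))

  # random truth against a per-bp oracle
  set.seed(93)
  bounds <- sort(sample(seq(1000, 39000, by = 1000), 3))
  cns <- sample(1:4, 4, replace = TRUE)
  tr <- structure(data.frame(chrom = "chr1",
                             start = c(0, bounds), end = c(bounds, 40000),
                             cn = cns),
                  class = c("sim_truth", "data.frame"))
  perbase <- rep(log2(cns / 2), times = tr$end - tr$start)
  want <- c(mean(perbase[1:20000]), mean(perbase[20001:40000]))
  expect_equal(expected_log2_truth(tr, bins), want)
})

test_that("off-target read starts are uniform on a diploid genome", {
  cfg <- sim_config(theta_on = 0, frac_low_mapq = 0, seed = 94)
  layout <- genome_layout(names(cfg$chrom_lengths),
                          as.numeric(cfg$chrom_lengths))
  sim <- simulate_capture_experiment(list(fasta = NULL, layout = layout),
                                     sim_truth(cfg), cfg,
                                     name = "uniform_sim")
  reads <- load_filtered_reads(sim$bam, layout)
  bins <- make_bins(layout, 20000)
  # fragment (R1) starts are the independent draws; mates are coupled
  counts <- depth_of_coverage(reads[reads$strand == "+", ], bins)
  pval <- chisq.test(counts, p = rep(1 / length(counts),
                                     length(counts)))$p.value
  expect_gt(pval, 0.01)

  # theta_on = 0: no enrichment for the peak caller to find (per-fragment
  # tags; mate extensions overlap by construction and would double-count)
  expect_equal(nrow(call_enriched_peaks(reads[reads$strand == "+", ],
                                        layout)), 0)
})

test_that("truth/genome mismatch is rejected", {
  cfg <- sim_config(seed = 95)
  layout <- genome_layout("other", 1e6)
  expect_error(
    simulate_capture_experiment(list(fasta = NULL, layout = layout),
                                sim_truth(cfg), cfg),
    "absent")
})

test_that("the pipeline recovers breakpoints across seeded replicates", {
  # scaled-down replicate design: two 3 Mb chromosomes, one CN=4 and one
  # CN=1 Mb-scale region (|dlog2| = 1 >= 0.58), relative mode, no GC track
  cfg0 <- sim_config(chrom_lengths = c(chrA = 3e6, chrB = 3e6), seed = 1)
  layout <- genome_layout(names(cfg0$chrom_lengths),
                          as.numeric(cfg0$chrom_lengths))
  genome <- list(fasta = NULL, layout = layout)
  regions <- data.frame(chrom = c("chrA", "chrB"), start = c(1e6, 1e6),
                        end = c(2e6, 2e6), cn = c(4, 1))
  bait_bp <- 20000
  hits <- 0; total <- 0
  for (rep_seed in 1:10) {
    cfg <- sim_config(chrom_lengths = c(chrA = 3e6, chrB = 3e6),
                      seed = 1000 + rep_seed)
    truth <- sim_truth(cfg, regions)
    tum <- simulate_capture_experiment(genome, truth, cfg,
                                       seed = 2000 + rep_seed,
                                       name = sprintf("rec_t%02d", rep_seed))
    nor <- simulate_capture_experiment(genome, sim_truth(cfg), cfg,
                                       seed = 3000 + rep_seed,
                                       name = sprintf("rec_n%02d", rep_seed))
    fit <- cn_profile(tum$bam, nor$bam, layout,
                      segmentation = segmentation_config(
                        n_permutations = 1000, seed = rep_seed))
    for (chr in c("chrA", "chrB")) {
      want_bp <- c(1e6, 2e6)
      segs <- fit$segments[fit$segments$chrom == chr, ]
      got_bp <- segs$start[-1]
      for (bp in want_bp) {
        total <- total + 1
        if (any(abs(got_bp - bp) <= bait_bp)) hits <- hits + 1
      }
    }
  }
  expect_gte(hits / total, 0.9)
})
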