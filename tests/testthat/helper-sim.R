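# Memoized simulation fixtures shared across test files. testthat sources
# helpers once per run, so these closures cache within one session.

.fixture_cache <- new.env(parent = emptyenv())

# Full-size study fixture: two 10 Mb chromosomes, default rates, one CN=4
# and one CN=1 region in the tumor, diploid matched normal sharing the same
# capture set. Used by the acceptance tests.
study_fixture <- function() {
  if (!is.null(.fixture_cache$study)) return(.fixture_cache$study)
  dir <- file.path(tempdir(), "study_fixture")
  dir.create(dir, showWarnings = FALSE)
  cfg <- sim_config(seed = 11)
  genome <- simulate_genome(cfg, dir = dir)
  truth <- sim_truth(cfg, data.frame(chrom = c("chr1", "chr2"),
                                     start = c(3e6, 4e6), end = c(5e6, 6e6),
                                     cn = c(4, 1)))
  tumor <- simulate_capture_experiment(genome, truth, cfg, seed = 101,
                                       dir = dir, name = "tumor")
  normal <- simulate_capture_experiment(genome, sim_truth(cfg), cfg,
                                        seed = 202, dir = dir,
                                        name = "normal")
  .fixture_cache$study <- list(cfg = cfg, genome = genome, truth = truth,
                               tumor = tumor, normal = normal)
  .fixture_cache$study
}

study_fit <- function(which = c("relative", "absolute", "absolute_nopeaks")) {
  which <- match.arg(which)
  key <- paste0("fit_", which)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  fx <- study_fixture()
  fit <- switch(which,
    relative = cn_profile(fx$tumor$bam, fx$normal$bam, fx$genome$layout,
                          genome_fasta = fx$genome$fasta,
                          segmentation = segmentation_config(seed = 1)),
    absolute = cn_profile(fx$normal$bam, NULL, fx$genome$layout,
                          genome_fasta = fx$genome$fasta,
                          segmentation = segmentation_config(seed = 1)),
    absolute_nopeaks = cn_profile(fx$normal$bam, NULL, fx$genome$layout,
                                  genome_fasta = fx$genome$fasta,
                                  peak_removal = FALSE,
                                  segmentation = segmentation_config(seed = 1),
                                  segment = FALSE))
  .fixture_cache[[key]] <- fit
  fit
}

# Small fast fixture (two 3 Mb chromosomes, no FASTA) for pipeline-mechanics
# tests that do not need GC correction.
small_fixture <- function() {
  if (!is.null(.fixture_cache$small)) return(.fixture_cache$small)
  dir <- file.path(tempdir(), "small_fixture")
  dir.create(dir, showWarnings = FALSE)
  cfg <- sim_config(chrom_lengths = c(chrA = 3e6, chrB = 3e6), seed = 33)
  layout <- genome_layout(names(cfg$chrom_lengths),
                          as.numeric(cfg$chrom_lengths))
  genome <- list(fasta = NULL, layout = layout)
  truth <- sim_truth(cfg, data.frame(chrom = c("chrA", "chrB"),
                                     start = c(1e6, 1e6), end = c(2e6, 2e6),
                                     cn = c(4, 1)))
  tumor <- simulate_capture_experiment(genome, truth, cfg, seed = 44,
                                       dir = dir, name = "tumor_small")
  normal <- simulate_capture_experiment(genome, sim_truth(cfg), cfg,
                                        seed = 55, dir = dir,
                                        name = "normal_small")
  .fixture_cache$small <- list(cfg = cfg, layout = layout, truth = truth,
                               tumor = tumor, normal = normal)
  .fixture_cache$small
}
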