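#' Simulation configuration
#'
#' Parameters of the targeted-capture read simulator. The defaults describe
#' a small but structurally faithful capture experiment: two 10 Mb
#' chromosomes, baits of 120 bp every 10 kb with log-normal per-bait capture
#' efficiencies, strong on-target enrichment with a uniform off-target
#' background proportional to local copy number, paired proper-pair reads,
#' and a configurable fraction of low-mapping-quality reads. Off-target
#' reads make up roughly a tenth of the simulated library — the regime in
#' which off-target profiling is applicable — and give about 80 off-target
#' read starts per 20 kb bin at diploid copy number.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param bait_spacing distance between bait starts (bp).
#' @param bait_width bait width (bp).
#' @param bait_efficiency_sdlog sdlog of the log-normal per-bait capture
#'   efficiency (meanlog 0).
#' @param theta_on expected on-target read pairs per bait at diploid copy
#'   number (scaled by efficiency and CN/2).
#' @param theta_off expected off-target read pairs per bp at diploid copy
#'   number (scaled by CN/2).
#' @param read_length,fragment_length read and fragment lengths (bp).
#' @param frac_low_mapq fraction of read pairs emitted with mapping quality
#'   20 instead of 60.
#' @param gc_range GC fraction at the start and end of each simulated
#'   chromosome (a monotone gradient, so GC correction has something to
#'   work against).
#' @param gc_bias strength of an injected GC coverage bias: fragments are
#'   thinned with acceptance probability proportional to
#'   exp(gc_bias * (local GC - midrange GC)). 0 (default) disables the bias.
#' @param seed RNG seed (mandatory); bait efficiencies derive from this
#'   seed so a sample and its reference share the same capture set.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 1e7, chr2 = 1e7),
                       bait_spacing = 1e4, bait_width = 120,
                       bait_efficiency_sdlog = 0.5,
                       theta_on = 100, theta_off = 2e-3,
                       read_length = 100, fragment_length = 300,
                       frac_low_mapq = 0.15,
                       gc_range = c(0.3, 0.6), gc_bias = 0,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("sim_config requires a seed")
  stopifnot(all(chrom_lengths > 0), bait_spacing > 0, bait_width > 0,
            theta_on >= 0, theta_off >= 0,
            read_length > 0, fragment_length >= read_length,
            frac_low_mapq >= 0, frac_low_mapq <= 1)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  structure(list(chrom_lengths = chrom_lengths, bait_spacing = bait_spacing,
                 bait_width = bait_width,
                 bait_efficiency_sdlog = bait_efficiency_sdlog,
                 theta_on = theta_on, theta_off = theta_off,
                 read_length = read_length,
                 fragment_length = fragment_length,
                 frac_low_mapq = frac_low_mapq,
                 gc_range = gc_range, gc_bias = gc_bias,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Copy-number truth for the simulator
#'
#' Builds a piecewise-constant integer copy-number truth that tiles every
#' chromosome: the supplied aberrant regions, with the remainder filled at
#' the baseline ploidy of 2.
#'
#' @param chrom_lengths named chromosome lengths (or a \code{sim_config}).
#' @param regions data.frame with \code{chrom,start,end,cn} of non-diploid
#'   regions (may be NULL for an all-diploid genome).
#' @return data.frame of class \code{sim_truth} with
#'   \code{chrom,start,end,cn} tiling each chromosome.
#' @export
sim_truth <- function(chrom_lengths, regions = NULL) {
  if (inherits(chrom_lengths, "sim_config"))
    chrom_lengths <- chrom_lengths$chrom_lengths
  out <- list()
  for (chr in names(chrom_lengths)) {
    len <- chrom_lengths[[chr]]
    r <- if (is.null(regions)) NULL else
      regions[regions$chrom == chr, , drop = FALSE]
    if (is.null(r) || nrow(r) == 0) {
      out[[chr]] <- data.frame(chrom = chr, start = 0, end = len, cn = 2)
      next
    }
    r <- r[order(r$start), , drop = FALSE]
    if (any(r$start < 0 | r$end > len) || any(diff(c(r$start)) < 0) ||
        any(r$end[-nrow(r)] > r$start[-1]))
      stop("aberrant regions overlap or exceed chromosome ", chr)
    if (any(r$cn < 0)) stop("copy number must be >= 0")
    bounds <- sort(unique(c(0, r$start, r$end, len)))
    cn <- rep(2, length(bounds) - 1)
    for (i in seq_len(nrow(r))) {
      hit <- bounds[-length(bounds)] >= r$start[i] & bounds[-1] <= r$end[i]
      cn[hit] <- r$cn[i]
    }
    out[[chr]] <- data.frame(chrom = chr, start = bounds[-length(bounds)],
                             end = bounds[-1], cn = cn)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("sim_truth", "data.frame")
  out
}

# default study truth: one gained (CN 4) and one lost (CN 1) region
# against a diploid baseline
default_sim_truth <- function(cfg) {
  cl <- cfg$chrom_lengths
  regions <- data.frame(chrom = c(names(cl)[1], names(cl)[2]),
                        start = c(3e6, 4e6), end = c(5e6, 6e6),
                        cn = c(4, 1))
  sim_truth(cl, regions)
}

#' Simulate a genome FASTA with a GC gradient
#'
#' Random sequence per chromosome whose GC content rises linearly (in 1 kb
#' blocks) from \code{gc_range[1]} to \code{gc_range[2]}, giving the GC
#' correction a realistic monotone covariate. Deterministic per seed.
#'
#' @param cfg \code{sim_config}.
#' @param dir output directory.
#' @param name basename for the FASTA file.
#' @return list with \code{fasta} (path, indexed) and \code{layout}
#'   (\code{genome_layout}).
#' @export
simulate_genome <- function(cfg, dir = tempdir(), name = "sim_genome") {
  set.seed(cfg$seed)
  block <- 1000L
  seqs <- character(length(cfg$chrom_lengths))
  for (ci in seq_along(cfg$chrom_lengths)) {
    len <- as.integer(cfg$chrom_lengths[[ci]])
    if (len <= 0) stop("zero-length chromosome in config")
    nb <- ceiling(len / block)
    # monotone gradient with an isochore-like sinusoidal fluctuation on
    # top, so one GC value maps to many genomic positions
    mids <- (seq_len(nb) - 0.5) * block
    p <- seq(cfg$gc_range[1], cfg$gc_range[2], length.out = nb) +
      0.05 * sin(2 * pi * mids / 7e5)
    p <- pmin(pmax(p, 0.05), 0.95)
    pbase <- rep(p, each = block)[seq_len(len)]
    is_gc <- stats::runif(len) < pbase
    second <- stats::runif(len) < 0.5
    base <- ifelse(is_gc, ifelse(second, "G", "C"),
                   ifelse(second, "A", "T"))
    seqs[ci] <- paste(base, collapse = "")
  }
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- names(cfg$chrom_lengths)
  fasta <- file.path(dir, paste0(name, ".fa"))
  Biostrings::writeXStringSet(dna, fasta)
  if (file.exists(paste0(fasta, ".fai"))) unlink(paste0(fasta, ".fai"))
  Rsamtools::indexFa(fasta)
  list(fasta = fasta,
       layout = genome_layout(names(cfg$chrom_lengths),
                              as.numeric(cfg$chrom_lengths)))
}

# bait tiling and per-bait efficiencies; efficiencies come from the config
# seed so sample and reference runs share one capture set
capture_baits <- function(layout, cfg) {
  pieces <- lapply(seq_len(nrow(layout)), function(i) {
    len <- layout$length[i]
    starts <- seq(cfg$bait_spacing / 2, len - cfg$bait_width,
                  by = cfg$bait_spacing)
    data.frame(chrom = layout$chrom[i], start = starts,
               end = starts + cfg$bait_width, stringsAsFactors = FALSE)
  })
  baits <- do.call(rbind, pieces)
  old <- .Random.seed_save()
  set.seed(cfg$seed)
  baits$efficiency <- stats::rlnorm(nrow(baits), meanlog = 0,
                                    sdlog = cfg$bait_efficiency_sdlog)
  .Random.seed_restore(old)
  rownames(baits) <- NULL
  baits
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# integer copy number at positions (vectorized within one chromosome)
cn_at <- function(truth, chrom, pos) {
  t <- truth[truth$chrom == chrom, , drop = FALSE]
  i <- findInterval(pos, t$start)
  i[i < 1] <- 1L
  t$cn[pmin(i, nrow(t))]
}

#' Simulate a targeted-capture sequencing experiment
#'
#' Emits already-aligned paired reads for a genome and copy-number truth:
#' per bait, a Poisson number of on-target pairs (rate
#' \code{theta_on * efficiency * CN/2}) placed within a fragment length of
#' the bait; off-target pairs placed uniformly with per-bp rate
#' \code{theta_off * CN/2}. Pairs are proper (FLAGs 99/147) with mapping
#' quality 60 except a configured fraction at 20. When \code{cfg$gc_bias}
#' is non-zero, fragments are thinned according to local GC to inject a
#' coverage bias. Output is a coordinate-sorted, indexed BAM (plus the SAM
#' text it came from). Deterministic per seed.
#'
#' @param genome list with \code{fasta} and \code{layout}, from
#'   [simulate_genome()].
#' @param truth \code{sim_truth}.
#' @param cfg \code{sim_config}.
#' @param seed seed for read placement (defaults to \code{cfg$seed}; use a
#'   different value for a matched reference so it is an independent
#'   library on the same capture set).
#' @param dir output directory.
#' @param name basename for the SAM/BAM files.
#' @return list with \code{bam}, \code{sam}, \code{baits} (data.frame with
#'   efficiencies), \code{truth}, \code{layout}, \code{n_pairs},
#'   \code{n_offtarget_pairs}.
#' @export
simulate_capture_experiment <- function(genome, truth, cfg,
                                        seed = cfg$seed, dir = tempdir(),
                                        name = "sim_reads") {
  layout <- genome$layout
  if (!all(unique(truth$chrom) %in% layout$chrom))
    stop("truth regions reference chromosomes absent from the genome")
  bad <- merge(truth, layout, by = "chrom")
  if (any(bad$end > bad$length))
    stop("truth regions extend beyond chromosome ends")
  baits <- capture_baits(layout, cfg)
  set.seed(seed)
  frag <- cfg$fragment_length
  rl <- cfg$read_length

  frag_chrom <- character(0); frag_start <- numeric(0)
  on_target <- logical(0)
  for (chr in layout$chrom) {
    clen <- chrom_length(layout, chr)
    b <- baits[baits$chrom == chr, , drop = FALSE]
    if (nrow(b)) {
      cn <- cn_at(truth, chr, floor((b$start + b$end) / 2))
      npairs <- stats::rpois(nrow(b), cfg$theta_on * b$efficiency * cn / 2)
      tot <- sum(npairs)
      if (tot > 0) {
        bi <- rep(seq_len(nrow(b)), npairs)
        s <- floor(stats::runif(tot, b$start[bi] - frag, b$end[bi]))
        s <- pmin(pmax(s, 0), clen - frag)
        frag_chrom <- c(frag_chrom, rep(chr, tot))
        frag_start <- c(frag_start, s)
        on_target <- c(on_target, rep(TRUE, tot))
      }
    }
    t <- truth[truth$chrom == chr, , drop = FALSE]
    noff <- stats::rpois(nrow(t), cfg$theta_off * (t$end - t$start) * t$cn / 2)
    tot <- sum(noff)
    if (tot > 0) {
      ti <- rep(seq_len(nrow(t)), noff)
      s <- floor(stats::runif(tot, t$start[ti], t$end[ti]))
      s <- pmin(pmax(s, 0), clen - frag)
      frag_chrom <- c(frag_chrom, rep(chr, tot))
      frag_start <- c(frag_start, s)
      on_target <- c(on_target, rep(FALSE, tot))
    }
  }
  if (length(frag_start) == 0) stop("simulation produced no reads")

  if (cfg$gc_bias != 0) {
    gc <- local_gc_blocks(genome$fasta, layout, block = 1000L)
    mid <- floor(frag_start + frag / 2)
    g <- numeric(length(mid))
    for (chr in unique(frag_chrom)) {
      sel <- frag_chrom == chr
      g[sel] <- gc[[chr]][pmin(length(gc[[chr]]), mid[sel] %/% 1000L + 1L)]
    }
    w <- exp(cfg$gc_bias * (g - mean(cfg$gc_range)))
    keep <- stats::runif(length(w)) < w / max(w)
    frag_chrom <- frag_chrom[keep]; frag_start <- frag_start[keep]
    on_target <- on_target[keep]
  }

  n <- length(frag_start)
  low <- stats::runif(n) < cfg$frac_low_mapq
  mapq <- ifelse(low, 20L, 60L)
  qname <- sprintf("frag%07d", seq_len(n))
  pos1 <- frag_start + 1             # R1, 1-based
  pos2 <- frag_start + frag - rl + 1 # R2
  cig <- paste0(rl, "M")
  r1 <- sprintf("%s\t99\t%s\t%d\t%d\t%s\t=\t%d\t%d\t*\t*",
                qname, frag_chrom, as.integer(pos1), mapq, cig,
                as.integer(pos2), as.integer(frag))
  r2 <- sprintf("%s\t147\t%s\t%d\t%d\t%s\t=\t%d\t%d\t*\t*",
                qname, frag_chrom, as.integer(pos2), mapq, cig,
                as.integer(pos1), -as.integer(frag))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", layout$chrom,
                      as.integer(layout$length)))
  sam <- file.path(dir, paste0(name, ".sam"))
  writeLines(c(header, r1, r2), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, name), overwrite = TRUE,
                          indexDestination = TRUE)
  list(bam = bam, sam = sam, baits = baits, truth = truth, layout = layout,
       n_pairs = n, n_offtarget_pairs = sum(!on_target))
}

# per-1kb-block GC fractions, one numeric vector per chromosome
local_gc_blocks <- function(fasta, layout, block = 1000L) {
  grid <- make_bins(layout, block)
  gc <- gc_fraction_per_bin(fasta, grid)
  split(gc, factor(grid$chrom, levels = layout$chrom))
}

#' Expected per-bin log2 ratio implied by a copy-number truth
#'
#' Length-weighted mean of log2(CN/2) over each bin.
#'
#' @param truth \code{sim_truth}.
#' @param bins \code{bin_grid}.
#' @return numeric vector parallel to the bins.
#' @export
expected_log2_truth <- function(truth, bins) {
  out <- numeric(nrow(bins))
  bgr <- as_granges(bins)
  tgr <- as_granges(truth)
  hits <- GenomicRanges::findOverlaps(bgr, tgr)
  ov <- IRanges::pintersect(bgr[S4Vectors::queryHits(hits)],
                            tgr[S4Vectors::subjectHits(hits)])
  w <- as.numeric(GenomicRanges::width(ov))
  val <- log2(truth$cn[S4Vectors::subjectHits(hits)] / 2) * w
  num <- rowsum(val, S4Vectors::queryHits(hits))
  den <- rowsum(w, S4Vectors::queryHits(hits))
  out[as.integer(rownames(num))] <- num[, 1] / den[, 1]
  out
}
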