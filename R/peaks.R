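#' Peak caller configuration
#'
#' Parameters of the single-sample local-Poisson enrichment peak caller used
#' to find and mask capture peaks. Reads are extended to the fragment length
#' from their 5' end, base-level coverage is tested against a Poisson tail
#' with a local rate (the maximum of the genome-wide rate and rates in
#' windows centered on the base), and significant bases are merged into
#' peaks.
#'
#' @param fragment_extension read extension d in bp (approximate fragment
#'   length).
#' @param pvalue_cutoff Poisson tail probability below which a base is
#'   considered enriched.
#' @param local_lambda_windows window widths (bp) for the local background
#'   rate, ascending.
#' @param merge_gap significant bases closer than this (bp) are merged into
#'   one peak.
#' @param min_peak_width peaks narrower than this (bp) are dropped.
#' @param flank bp added to each side of a called peak before reporting.
#'   Sequences adjacent to an enriched region are co-enriched — a fragment
#'   overlapping the region places read starts up to a fragment length
#'   outside it — and the significance ramp at the peak edges would
#'   otherwise leave that shoulder unmasked, with a leakage that depends on
#'   local copy number. The default masks one fragment extension.
#' @return list of class \code{peak_caller_config}.
#' @export
peak_caller_config <- function(fragment_extension = 200,
                               pvalue_cutoff = 1e-5,
                               local_lambda_windows = c(5000, 10000),
                               merge_gap = 100, min_peak_width = 50,
                               flank = fragment_extension) {
  stopifnot(fragment_extension > 0, pvalue_cutoff > 0, pvalue_cutoff < 1,
            all(diff(local_lambda_windows) > 0), flank >= 0)
  structure(list(fragment_extension = fragment_extension,
                 pvalue_cutoff = pvalue_cutoff,
                 local_lambda_windows = local_lambda_windows,
                 merge_gap = merge_gap, min_peak_width = min_peak_width,
                 flank = flank),
            class = "peak_caller_config")
}

# smallest k with P(Pois(lambda) >= k) < cutoff
min_significant_count <- function(lambda, cutoff) {
  k <- stats::qpois(cutoff, lambda, lower.tail = FALSE)
  while (stats::ppois(k - 1, lambda, lower.tail = FALSE) >= cutoff) k <- k + 1L
  while (k > 0 && stats::ppois(k - 2, lambda, lower.tail = FALSE) < cutoff)
    k <- k - 1L
  k
}

#' Call read-enrichment peaks
#'
#' Identifies genomic regions enriched for sequence reads — capture peaks —
#' with a single-sample local-Poisson model. Each read is extended to
#' \code{cfg$fragment_extension} bp from its 5' end; a base with extended
#' coverage k is a candidate when \eqn{P(X \ge k; \lambda_{local})} falls
#' below the cutoff, where \eqn{\lambda_{local}} is the maximum of the
#' genome-wide rate and the rates in the configured local windows centered on
#' the base. Candidate bases within \code{merge_gap} are merged; peaks
#' narrower than \code{min_peak_width} are dropped, and the survivors are
#' widened by \code{flank} bp per side to cover the co-enriched shoulder.
#' Deterministic for fixed input. A precomputed peak BED can be used instead
#' of this caller anywhere a peak set is accepted.
#'
#' @param reads filtered reads (data.frame as returned by
#'   [load_filtered_reads()]).
#' @param layout \code{genome_layout}.
#' @param cfg \code{peak_caller_config}.
#' @return \code{interval_set} of peaks with columns \code{summit} (0-based
#'   position of maximum coverage) and \code{score} (-log10 Poisson tail p at
#'   the summit).
#' @export
call_enriched_peaks <- function(reads, layout, cfg = peak_caller_config()) {
  if (is.null(reads) || nrow(reads) == 0)
    stop("no reads for peak calling")
  d <- cfg$fragment_extension
  keep <- !is_mitochondrial(layout, reads$chrom)
  reads <- reads[keep, , drop = FALSE]
  if (nrow(reads) == 0) stop("no reads for peak calling")
  len <- chrom_length(layout, reads$chrom)
  fwd <- reads$strand != "-"
  ext_start <- ifelse(fwd, reads$start, reads$end - d)
  ext_end <- ext_start + d
  ext_start <- pmax(0, ext_start)
  ext_end <- pmin(len, ext_end)
  ok <- ext_end > ext_start
  ext <- data.frame(chrom = reads$chrom[ok], start = ext_start[ok],
                    end = ext_end[ok])

  genome_len <- sum(layout$length[!is_mitochondrial(layout, layout$chrom)])
  lambda_genome <- sum(ext$end - ext$start) / genome_len
  kmin <- min_significant_count(lambda_genome, cfg$pvalue_cutoff)

  peak_chrom <- character(0); peak_start <- numeric(0); peak_end <- numeric(0)
  peak_summit <- numeric(0); peak_score <- numeric(0)
  for (chr in unique(ext$chrom)) {
    clen <- chrom_length(layout, chr)
    e <- ext[ext$chrom == chr, , drop = FALSE]
    cov <- IRanges::coverage(IRanges::IRanges(e$start + 1, e$end),
                             width = clen)
    cand <- IRanges::slice(cov, lower = max(kmin, 1L), rangesOnly = TRUE)
    if (length(cand) == 0) next
    pos <- unlist(lapply(seq_along(cand), function(i)
      seq(IRanges::start(cand)[i], IRanges::end(cand)[i])))  # 1-based
    k <- as.integer(cov[pos])
    lam <- rep(lambda_genome, length(pos))
    for (w in cfg$local_lambda_windows) {
      ws <- pmax(1, pos - floor(w / 2))
      we <- pmin(clen, pos + ceiling(w / 2) - 1)
      vs <- IRanges::viewSums(IRanges::Views(cov, start = ws, end = we))
      lam <- pmax(lam, vs / (we - ws + 1))
    }
    pval <- stats::ppois(k - 1, lam, lower.tail = FALSE)
    sig <- pval < cfg$pvalue_cutoff
    if (!any(sig)) next
    sp <- pos[sig]
    merged <- IRanges::reduce(IRanges::IRanges(sp, sp),
                              min.gapwidth = cfg$merge_gap + 1L)
    merged <- merged[IRanges::width(merged) >= cfg$min_peak_width]
    if (length(merged) == 0) next
    if (cfg$flank > 0) {
      # mask the co-enriched fragment-length shoulder on both sides
      merged <- IRanges::reduce(IRanges::IRanges(
        pmax(1, IRanges::start(merged) - cfg$flank),
        pmin(clen, IRanges::end(merged) + cfg$flank)))
    }
    for (i in seq_along(merged)) {
      s1 <- IRanges::start(merged)[i]; e1 <- IRanges::end(merged)[i]
      v <- IRanges::Views(cov, start = s1, end = e1)
      summit1 <- IRanges::viewWhichMaxs(v)[1]  # absolute 1-based position
      ks <- as.integer(cov[summit1])
      lams <- lambda_genome
      for (w in cfg$local_lambda_windows) {
        ws <- max(1, summit1 - floor(w / 2))
        we <- min(clen, summit1 + ceiling(w / 2) - 1)
        lams <- max(lams, sum(as.numeric(cov[ws:we])) / (we - ws + 1))
      }
      ps <- stats::ppois(ks - 1, lams, lower.tail = FALSE)
      peak_chrom <- c(peak_chrom, chr)
      peak_start <- c(peak_start, s1 - 1)
      peak_end <- c(peak_end, e1)
      peak_summit <- c(peak_summit, summit1 - 1)
      peak_score <- c(peak_score, -log10(max(ps, 1e-300)))
    }
  }
  out <- interval_set(peak_chrom, peak_start, peak_end, layout = layout)
  out$summit <- peak_summit[order(match(peak_chrom, layout$chrom), peak_start)]
  out$score <- peak_score[order(match(peak_chrom, layout$chrom), peak_start)]
  out
}

#' Discard reads overlapping peaks
#'
#' A read is discarded iff its alignment interval overlaps any peak by at
#' least 1 bp. Applied identically to sample and reference. With an empty
#' peak set this is the identity.
#'
#' @param reads read data.frame.
#' @param peaks \code{interval_set}.
#' @return surviving reads, with attribute \code{n_removed}.
#' @export
remove_reads_in_peaks <- function(reads, peaks) {
  if (nrow(reads) == 0 || nrow(peaks) == 0) {
    attr(reads, "n_removed") <- 0L
    return(reads)
  }
  hit <- overlaps_any(reads[, c("chrom", "start", "end")], peaks)
  out <- reads[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(hit)
  out
}

#' Cumulative peak length per bin
#'
#' The masked territory x: for each bin, the total bp of intersection with
#' the (normalized) peak set, the quantity that drives depth-of-coverage
#' compensation.
#'
#' @param peaks \code{interval_set} of peaks.
#' @param bins \code{bin_grid}.
#' @return numeric vector of masked bp, parallel to the bins.
#' @export
peak_bp_per_bin <- function(peaks, bins) {
  peaks <- normalize_intervals(peaks)
  intersect_bp_per_bin(peaks, bins)
}
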