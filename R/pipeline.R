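#' Copy-number profile from targeted sequencing
#'
#' The package's main fitting function. Runs the full off-target workflow on
#' one sample (optionally against a matched reference): read filtering,
#' enrichment-peak calling (on the reference when present, otherwise on the
#' sample itself) and peak removal, binned depth of coverage with
#' compensation for the masked territory, loess corrections for GC content
#' and mappability, bin filtering, median normalization and log2 transform,
#' reference subtraction (relative mode) and circular binary segmentation.
#' With \code{method = "ontarget"} the exon-level comparator is fitted
#' instead: mean per-bp coverage on the capture regions, no peak removal, no
#' compensation, same normalization and segmentation downstream.
#'
#' @param sample path to the sample SAM/BAM.
#' @param reference optional path to a matched reference SAM/BAM; when given
#'   the profile is relative (sample minus reference).
#' @param layout \code{genome_layout}, or a path understood by
#'   [read_genome_layout()].
#' @param bin_size bin width in bp (20 kb default; use 100 kb for small gene
#'   panels).
#' @param genome_fasta optional indexed FASTA for GC correction.
#' @param mappability optional mappability track (\code{interval_set} with
#'   score, or bedGraph-like path) for mappability correction.
#' @param blacklist optional exclusion regions (\code{interval_set} or BED
#'   path).
#' @param peaks optional precomputed peak set (\code{interval_set} or BED
#'   path), bypassing the internal caller.
#' @param peak_removal logical; disable to skip peak calling and removal
#'   entirely (for comparison runs).
#' @param method \code{"offtarget"} (default) or \code{"ontarget"}.
#' @param capture_regions capture-bait regions (\code{interval_set} or BED
#'   path); required for \code{method = "ontarget"}.
#' @param read_filter,peak_caller,loess,bin_filter,segmentation
#'   configuration objects.
#' @param segment logical; set FALSE to skip segmentation.
#' @return object of class \code{cn_profile} with components \code{bins}
#'   (per-bin table), \code{segments}, \code{peaks}, \code{qc},
#'   \code{method}, \code{mode}.
#' @export
cn_profile <- function(sample, reference = NULL, layout,
                       bin_size = 20000,
                       genome_fasta = NULL, mappability = NULL,
                       blacklist = NULL, peaks = NULL, peak_removal = TRUE,
                       method = c("offtarget", "ontarget"),
                       capture_regions = NULL,
                       read_filter = read_filter_config(),
                       peak_caller = peak_caller_config(),
                       loess = loess_config(),
                       bin_filter = bin_filter_config(),
                       segmentation = segmentation_config(),
                       segment = TRUE) {
  method <- match.arg(method)
  if (is.character(layout)) layout <- read_genome_layout(layout)
  if (is.character(blacklist)) blacklist <- read_bed(blacklist)
  if (is.null(blacklist)) blacklist <- interval_set()
  if (is.character(peaks)) peaks <- read_bed(peaks)
  if (is.character(capture_regions))
    capture_regions <- read_bed(capture_regions)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  reads_s <- stage("read filtering (sample)",
                   load_filtered_reads(sample, layout, read_filter))
  reads_r <- if (!is.null(reference))
    stage("read filtering (reference)",
          load_filtered_reads(reference, layout, read_filter)) else NULL

  if (method == "ontarget") {
    if (is.null(capture_regions) || nrow(capture_regions) == 0)
      stop("[capture regions] method 'ontarget' requires capture_regions")
    return(ontarget_profile_impl(reads_s, reads_r, capture_regions, layout,
                                 genome_fasta, mappability, blacklist,
                                 loess, bin_filter, segmentation, segment,
                                 sample, reference))
  }

  if (peak_removal && is.null(peaks)) {
    base_reads <- if (!is.null(reads_r)) reads_r else reads_s
    peaks <- stage("peak calling",
                   call_enriched_peaks(base_reads, layout, peak_caller))
  }
  if (is.null(peaks)) peaks <- interval_set()
  n_before <- nrow(reads_s)
  if (peak_removal && nrow(peaks) > 0) {
    reads_s <- stage("peak removal", remove_reads_in_peaks(reads_s, peaks))
    if (!is.null(reads_r))
      reads_r <- stage("peak removal", remove_reads_in_peaks(reads_r, peaks))
  }

  bins <- make_bins(layout, bin_size)
  x <- if (peak_removal) peak_bp_per_bin(peaks, bins) else numeric(nrow(bins))

  gc <- if (!is.null(genome_fasta))
    stage("GC annotation", gc_fraction_per_bin(genome_fasta, bins)) else NULL
  mapp <- if (!is.null(mappability))
    stage("mappability annotation", mappability_per_bin(mappability, bins))
    else NULL

  build_side <- function(reads) {
    raw <- depth_of_coverage(reads, bins)
    comp <- compensate_doc(raw, x, bins$length)
    prof <- data.frame(chrom = bins$chrom, start = bins$start,
                       end = bins$end, length = bins$length,
                       raw_doc = raw, x = x, comp_doc = comp,
                       gc = if (is.null(gc)) NA_real_ else gc,
                       mappability = if (is.null(mapp)) NA_real_ else mapp,
                       stringsAsFactors = FALSE)
    corrected <- comp
    for (cv in loess$covariate_order) {
      covar <- switch(cv, gc = gc, mappability = mapp)
      if (!is.null(covar))
        corrected <- stage(paste("loess correction,", cv),
                           loess_correct(corrected, covar, loess))
    }
    prof$corrected <- corrected
    prof <- apply_bin_filters(prof, blacklist, bin_filter)
    prof$log2 <- stage("median normalization",
                       median_normalize_log2(prof$corrected, prof$usable,
                                             prof$chrom, layout))
    prof
  }

  prof_s <- build_side(reads_s)
  mode <- "absolute"
  if (!is.null(reads_r)) {
    prof_r <- build_side(reads_r)
    rel <- stage("reference subtraction",
                 relative_log2(prof_s$log2, prof_r$log2,
                               prof_s$usable, prof_r$usable))
    prof_s$sample_log2 <- prof_s$log2
    prof_s$reference_log2 <- prof_r$log2
    prof_s$log2 <- rel$log2
    prof_s$usable <- rel$usable
    mode <- "relative"
  }

  segs <- if (segment)
    stage("segmentation", cbs_segment(prof_s, segmentation, layout)) else NULL

  mad <- tryCatch(mad_diff(prof_s$log2[prof_s$usable]),
                  error = function(e) NA_real_)
  out <- list(bins = prof_s, segments = segs, peaks = peaks,
              method = "offtarget", mode = mode,
              qc = list(n_reads_sample = n_before,
                        n_reads_after_peak_removal = nrow(reads_s),
                        n_peaks = nrow(peaks),
                        peak_bp = if (nrow(peaks))
                          sum(normalize_intervals(peaks)$end -
                                normalize_intervals(peaks)$start) else 0,
                        mad = mad),
              layout = layout, bin_size = bin_size,
              sample = sample, reference = reference,
              call = match.call())
  class(out) <- "cn_profile"
  out
}

# exon-level comparator: mean per-bp DOC on capture regions, then the shared
# normalization/segmentation path with compensation skipped
ontarget_profile_impl <- function(reads_s, reads_r, capture_regions, layout,
                                  genome_fasta, mappability, blacklist,
                                  loess, bin_filter, segmentation, segment,
                                  sample, reference) {
  regions <- normalize_intervals(capture_regions)
  regions$length <- regions$end - regions$start
  gc <- if (!is.null(genome_fasta))
    gc_fraction_per_bin(genome_fasta, regions) else NULL
  mapp <- if (!is.null(mappability))
    mappability_per_bin(mappability, regions) else NULL

  build_side <- function(reads) {
    doc <- ontarget_mean_doc(reads, regions, layout)
    prof <- data.frame(chrom = regions$chrom, start = regions$start,
                       end = regions$end, length = regions$length,
                       raw_doc = doc, x = 0, comp_doc = doc,
                       gc = if (is.null(gc)) NA_real_ else gc,
                       mappability = if (is.null(mapp)) NA_real_ else mapp,
                       stringsAsFactors = FALSE)
    corrected <- doc
    for (cv in loess$covariate_order) {
      covar <- switch(cv, gc = gc, mappability = mapp)
      if (!is.null(covar)) corrected <- loess_correct(corrected, covar, loess)
    }
    prof$corrected <- corrected
    prof <- apply_bin_filters(prof, blacklist, bin_filter)
    prof$log2 <- median_normalize_log2(prof$corrected, prof$usable,
                                       prof$chrom, layout)
    prof
  }
  prof_s <- build_side(reads_s)
  mode <- "absolute"
  if (!is.null(reads_r)) {
    prof_r <- build_side(reads_r)
    rel <- relative_log2(prof_s$log2, prof_r$log2, prof_s$usable,
                         prof_r$usable)
    prof_s$sample_log2 <- prof_s$log2
    prof_s$reference_log2 <- prof_r$log2
    prof_s$log2 <- rel$log2
    prof_s$usable <- rel$usable
    mode <- "relative"
  }
  segs <- if (segment) cbs_segment(prof_s, segmentation, layout) else NULL
  mad <- tryCatch(mad_diff(prof_s$log2[prof_s$usable]),
                  error = function(e) NA_real_)
  out <- list(bins = prof_s, segments = segs, peaks = interval_set(),
              method = "ontarget", mode = mode,
              qc = list(n_regions = nrow(regions), mad = mad),
              layout = layout, bin_size = NA,
              sample = sample, reference = reference, call = NULL)
  class(out) <- "cn_profile"
  out
}

#' Write the per-bin table of a profile
#'
#' Tab-separated log of every per-bin quantity the workflow computed:
#' coordinates, raw and compensated counts, masked bp, GC, mappability,
#' corrected value, log2 ratio and usability flag.
#'
#' @param x \code{cn_profile} (or its \code{bins} data.frame).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bin_table <- function(x, path) {
  df <- if (inherits(x, "cn_profile")) x$bins else x
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.cn_profile <- function(x, ...) {
  cat(sprintf("cn_profile (%s method, %s mode)\n", x$method, x$mode))
  cat(sprintf("  %d bins on %d chromosomes; %d usable\n",
              nrow(x$bins), length(unique(x$bins$chrom)),
              sum(x$bins$usable)))
  if (!is.null(x$segments))
    cat(sprintf("  %d segments; MAD(diff) = %.3f\n", nrow(x$segments),
                x$qc$mad))
  invisible(x)
}

#' @export
summary.cn_profile <- function(object, ...) {
  x <- object
  cat(sprintf("Copy-number profile: %s method, %s mode\n", x$method, x$mode))
  cat(sprintf("Sample: %s\n", x$sample))
  if (!is.null(x$reference)) cat(sprintf("Reference: %s\n", x$reference))
  if (!is.na(x$bin_size)) cat(sprintf("Bin size: %d bp\n", x$bin_size))
  cat(sprintf("Bins: %d (%d usable)\n", nrow(x$bins), sum(x$bins$usable)))
  if (x$method == "offtarget")
    cat(sprintf("Peaks masked: %d (%.2f Mb); reads: %d -> %d after removal\n",
                x$qc$n_peaks, x$qc$peak_bp / 1e6, x$qc$n_reads_sample,
                x$qc$n_reads_after_peak_removal))
  cat(sprintf("Noise (diff-based MAD): %.4f\n", x$qc$mad))
  if (!is.null(x$segments)) {
    cat(sprintf("Segments: %d\n", nrow(x$segments)))
    print(x$segments)
  }
  invisible(x)
}

#' @export
fitted.cn_profile <- function(object, ...) {
  fitted_from_segments(object$bins, object$segments)
}

#' @export
residuals.cn_profile <- function(object, ...) {
  object$bins$log2 - fitted(object)
}

#' @export
coef.cn_profile <- function(object, ...) {
  if (is.null(object$segments)) return(numeric(0))
  stats::setNames(object$segments$mean,
                  sprintf("%s:%d-%d", object$segments$chrom,
                          object$segments$start, object$segments$end))
}

#' @export
as.data.frame.cn_profile <- function(x, ...) x$bins

#' Plot a copy-number profile
#'
#' Genome-wide scatter of per-bin log2 ratios with segment means overlaid in
#' red, chromosomes concatenated along the x axis.
#'
#' @param x \code{cn_profile}.
#' @param ylim y limits.
#' @param ... passed to \code{plot}.
#' @export
plot.cn_profile <- function(x, ylim = c(-2, 2), ...) {
  b <- x$bins
  chroms <- unique(b$chrom)
  offs <- stats::setNames(cumsum(c(0, chrom_length(x$layout,
                                                   chroms)))[seq_along(chroms)],
                          chroms)
  gx <- offs[b$chrom] + (b$start + b$end) / 2
  graphics::plot(gx[b$usable], pmin(pmax(b$log2[b$usable], ylim[1]),
                                    ylim[2]),
                 pch = 16, cex = 0.3, col = "grey40", ylim = ylim,
                 xlab = "genome position", ylab = "log2 ratio", ...)
  graphics::abline(v = offs[-1], col = "grey80", lty = 2)
  graphics::abline(h = 0, col = "grey60")
  if (!is.null(x$segments))
    graphics::segments(offs[x$segments$chrom] + x$segments$start,
                       x$segments$mean,
                       offs[x$segments$chrom] + x$segments$end,
                       x$segments$mean, col = "red", lwd = 2)
  invisible(x)
}
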