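#' Build a genome-wide bin grid
#'
#' Tiles every chromosome with consecutive fixed-width bins; the terminal bin
#' of a chromosome keeps its true (possibly shorter) length. 20 kb is the
#' default resolution for exome data; 100 kb suits small gene panels with few
#' off-target reads.
#'
#' @param layout \code{genome_layout}.
#' @param bin_size bin width L in bp.
#' @return data.frame of class \code{bin_grid} with columns
#'   \code{chrom,start,end,length}, attributes \code{bin_size} and
#'   \code{layout}.
#' @export
make_bins <- function(layout, bin_size = 20000) {
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size <= 0)
    stop("bin_size must be a positive number")
  pieces <- lapply(seq_len(nrow(layout)), function(i) {
    len <- layout$length[i]
    starts <- seq(0, len - 1, by = bin_size)
    ends <- pmin(starts + bin_size, len)
    data.frame(chrom = layout$chrom[i], start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$length <- out$end - out$start
  rownames(out) <- NULL
  attr(out, "bin_size") <- bin_size
  attr(out, "layout") <- layout
  class(out) <- c("bin_grid", "data.frame")
  out
}

#' Per-bin depth of coverage (read-start counts)
#'
#' Counts, for each bin, the reads whose leftmost aligned base falls in the
#' bin, the standard read-count measure for bin-level copy-number work.
#' Counts sum to the number of reads on chromosomes of the grid.
#'
#' @param reads read data.frame (filtered and, when applicable,
#'   peak-removed).
#' @param bins \code{bin_grid}.
#' @return integer vector of counts parallel to the bins.
#' @export
depth_of_coverage <- function(reads, bins) {
  bin_size <- attr(bins, "bin_size")
  out <- integer(nrow(bins))
  if (nrow(reads) == 0) return(out)
  for (chr in unique(reads$chrom)) {
    rows <- which(bins$chrom == chr)
    if (length(rows) == 0) next
    st <- reads$start[reads$chrom == chr]
    idx <- floor(st / bin_size) + 1L
    idx <- idx[idx >= 1 & idx <= length(rows)]
    out[rows] <- out[rows] + tabulate(idx, nbins = length(rows))
  }
  out
}

#' Compensate depth of coverage for masked territory
#'
#' Rescales the raw count of a bin for the bp removed with peaks:
#' \code{comp = raw * L_b / (L_b - x)}. A bin whose effective (unmasked)
#' fraction falls below \code{min_effective_fraction} is returned as missing
#' rather than wildly extrapolated.
#'
#' @param raw_doc per-bin raw counts.
#' @param x per-bin masked bp (from [peak_bp_per_bin()]).
#' @param bin_length per-bin actual length L_b.
#' @param min_effective_fraction minimum (L_b - x)/L_b for which a
#'   compensated value is produced.
#' @return numeric vector of compensated counts, \code{NA} where the bin is
#'   (nearly) fully masked.
#' @export
compensate_doc <- function(raw_doc, x, bin_length,
                           min_effective_fraction = 0.1) {
  if (any(x > bin_length))
    stop("masked bp exceeds bin length; peak accounting error upstream")
  if (any(x < 0)) stop("negative masked bp")
  eff <- (bin_length - x) / bin_length
  out <- ifelse(eff >= min_effective_fraction,
                raw_doc * bin_length / (bin_length - x), NA_real_)
  out
}

#' Mean per-bp coverage on capture regions (exon-level comparator)
#'
#' The exon depth-of-coverage comparator ("onTarget"): for each capture
#' region, the mean over its bases of the per-base coverage from all reads
#' overlapping the region. Reads are quality-filtered but peaks are not
#' removed and no compensation applies; downstream normalization and
#' segmentation reuse the bin-level machinery with region values in place of
#' bin values.
#'
#' @param reads filtered read data.frame.
#' @param capture_regions normalized \code{interval_set} of capture regions.
#' @param layout \code{genome_layout}.
#' @return numeric vector of mean per-bp coverage parallel to the regions.
#' @export
ontarget_mean_doc <- function(reads, capture_regions, layout) {
  if (nrow(capture_regions) == 0)
    stop("empty capture region set")
  out <- numeric(nrow(capture_regions))
  for (chr in unique(capture_regions$chrom)) {
    rows <- which(capture_regions$chrom == chr)
    clen <- chrom_length(layout, chr)
    rd <- reads[reads$chrom == chr, , drop = FALSE]
    cov <- IRanges::coverage(IRanges::IRanges(rd$start + 1, rd$end),
                             width = clen)
    v <- IRanges::Views(cov, start = capture_regions$start[rows] + 1,
                        end = capture_regions$end[rows])
    out[rows] <- IRanges::viewMeans(v)
  }
  out
}
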