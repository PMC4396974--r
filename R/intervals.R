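#' Interval sets
#'
#' Plain-table container for genomic intervals (capture regions, peaks,
#' blacklists, mappability tracks). Coordinates are 0-based half-open, the
#' BED convention. Normalization sorts intervals and merges overlapping or
#' abutting ones per chromosome.
#'
#' @param chrom,start,end parallel vectors defining the intervals.
#' @param score optional numeric score per interval (kept through sorting,
#'   dropped by merging).
#' @param layout optional \code{genome_layout}; when given, intervals are
#'   validated against chromosome bounds.
#' @return data.frame of class \code{interval_set} with columns
#'   \code{chrom,start,end} (and \code{score} if supplied), sorted by
#'   chromosome then start.
#' @export
interval_set <- function(chrom = character(), start = numeric(),
                         end = numeric(), score = NULL, layout = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(chrom) == 1 && length(start) > 1)
    chrom <- rep(chrom, length(start))
  if (length(chrom) != length(start) || length(start) != length(end))
    stop("chrom, start, end must be parallel")
  if (any(start < 0) || any(end <= start))
    stop("intervals must satisfy 0 <= start < end")
  if (!is.null(layout)) {
    len <- chrom_length(layout, chrom)
    if (any(end > len))
      stop("interval beyond chromosome end on ",
           paste(unique(chrom[end > len]), collapse = ", "))
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (!is.null(score)) out$score <- as.numeric(score)
  o <- order(match(chrom, unique(chrom)), start, end)
  if (!is.null(layout)) o <- order(match(chrom, layout$chrom), start, end)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interval_set", "data.frame")
  out
}

#' Normalize an interval set
#'
#' Sorts and merges overlapping or abutting intervals within each chromosome,
#' so the result is non-overlapping and sorted. Scores are dropped.
#'
#' @param x an \code{interval_set} (or any data.frame with
#'   \code{chrom,start,end}).
#' @return normalized \code{interval_set}.
#' @export
normalize_intervals <- function(x) {
  if (nrow(x) == 0) return(interval_set())
  gr <- GenomicRanges::reduce(as_granges(x))
  interval_set(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1L,
               GenomicRanges::end(gr))
}

# data.frame (0-based half-open) -> GRanges (1-based closed)
as_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1, end = x$end))
}

granges_to_intervals <- function(gr, score = NULL) {
  interval_set(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1L,
               GenomicRanges::end(gr), score = score)
}

#' Read intervals from a BED file
#'
#' BED3/BED6, 0-based half-open, read through rtracklayer.
#'
#' @param path BED file path.
#' @param layout optional \code{genome_layout} for validation.
#' @return \code{interval_set} (with \code{score} when the file has one).
#' @export
read_bed <- function(path, layout = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  score <- if ("score" %in% names(S4Vectors::mcols(gr)))
    S4Vectors::mcols(gr)$score else NULL
  out <- interval_set(as.character(GenomicRanges::seqnames(gr)),
                      GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                      score = score, layout = layout)
  out
}

#' Write intervals to a BED file
#'
#' @param x \code{interval_set}; a \code{score} column, if present, is written
#'   to the BED score field.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- as.data.frame(x)
  has_score <- "score" %in% names(df)
  cols <- data.frame(chrom = df$chrom,
                     start = format(df$start, scientific = FALSE, trim = TRUE),
                     end = format(df$end, scientific = FALSE, trim = TRUE))
  if (has_score) {
    cols$name <- if ("name" %in% names(df)) df$name else
      paste0("region_", seq_len(nrow(df)))
    cols$score <- format(df$score, trim = TRUE)
  }
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Per-bin intersection length (bp) between a normalized interval set and a
# bin grid. Returns a vector parallel to the rows of `bins`.
intersect_bp_per_bin <- function(intervals, bins) {
  out <- numeric(nrow(bins))
  if (nrow(intervals) == 0) return(out)
  bgr <- as_granges(bins)
  igr <- as_granges(intervals)
  hits <- GenomicRanges::findOverlaps(bgr, igr)
  if (length(hits) == 0) return(out)
  ov <- IRanges::pintersect(bgr[S4Vectors::queryHits(hits)],
                            igr[S4Vectors::subjectHits(hits)])
  w <- GenomicRanges::width(ov)
  agg <- rowsum(w, S4Vectors::queryHits(hits))
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# Logical: does each row of `x` overlap any interval in `y` by >= 1 bp?
overlaps_any <- function(x, y) {
  if (nrow(x) == 0) return(logical(0))
  if (nrow(y) == 0) return(rep(FALSE, nrow(x)))
  IRanges::overlapsAny(as_granges(x), as_granges(y))
}
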