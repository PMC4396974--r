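#' Diff-based MAD noise estimate
#'
#' Robust per-bin noise estimate from lag-1 differences of consecutive
#' non-missing values in genomic order:
#' \code{1.4826 * median(|d - median(d)|) / sqrt(2)}. The sqrt(2) divisor
#' converts the spread of differences of two independent bins back to the
#' per-bin standard deviation, so the value is comparable to a profile's
#' bin-level sd. Insensitive to (piecewise-)constant copy-number level, so
#' it measures technical noise, not biology.
#'
#' @param values per-bin log2 values in genomic order; NAs are dropped
#'   before differencing.
#' @return the MAD estimate (0 for constant input or a constant-step ramp).
#' @export
mad_diff <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 3) stop("need at least 3 non-missing values")
  d <- diff(v)
  1.4826 * stats::median(abs(d - stats::median(d))) / sqrt(2)
}

#' Signal-to-noise ratio of a segmented region
#'
#' SNR = |segmentation value| / MAD, where the segmentation value is the
#' mean of the segment overlapping the query region the most.
#'
#' @param segments \code{segment_set}.
#' @param mad positive noise estimate (from [mad_diff()]).
#' @param region one-row data.frame or list with \code{chrom,start,end}.
#' @return the SNR.
#' @export
signal_to_noise <- function(segments, mad, region) {
  if (!is.numeric(mad) || mad <= 0) stop("mad must be positive")
  s <- segments[segments$chrom == region$chrom, , drop = FALSE]
  if (nrow(s) == 0) stop("no segment overlaps the region")
  ov <- pmin(s$end, region$end) - pmax(s$start, region$start)
  if (all(ov <= 0)) stop("no segment overlaps the region")
  abs(s$mean[which.max(ov)]) / mad
}

#' Array pseudo counts on a bin grid
#'
#' Projects array probe intensities onto genomic bins so array and
#' sequencing profiles can be compared on one grid. \code{nearest}: each
#' bin takes the intensity of the probe closest to the bin center (ties go
#' to the lower coordinate). \code{mean}: each bin takes the average
#' intensity of the probes inside it, missing when there is none.
#'
#' @param probes data.frame with \code{chrom}, \code{position} (bp) and
#'   \code{intensity} (log2 scale), sorted or not.
#' @param bins \code{bin_grid}.
#' @param mode \code{"nearest"} or \code{"mean"}.
#' @return numeric vector of pseudo counts parallel to the bins.
#' @export
array_pseudocounts <- function(probes, bins, mode = c("nearest", "mean")) {
  mode <- match.arg(mode)
  if (is.null(probes) || nrow(probes) == 0) stop("empty probe set")
  out <- rep(NA_real_, nrow(bins))
  for (chr in unique(bins$chrom)) {
    rows <- which(bins$chrom == chr)
    p <- probes[probes$chrom == chr, , drop = FALSE]
    if (nrow(p) == 0) next
    p <- p[order(p$position), , drop = FALSE]
    if (mode == "nearest") {
      centers <- (bins$start[rows] + bins$end[rows]) / 2
      for (b in seq_along(rows)) {
        dist <- abs(p$position - centers[b])
        out[rows[b]] <- p$intensity[which.min(dist)]  # first min = lower coord
      }
    } else {
      idx <- findInterval(p$position, bins$start[rows])
      ok <- idx >= 1 & p$position < bins$end[rows][pmax(idx, 1)]
      if (any(ok)) {
        agg <- tapply(p$intensity[ok], idx[ok], mean)
        out[rows[as.integer(names(agg))]] <- as.numeric(agg)
      }
    }
  }
  out
}

#' Weighted concordance of two segment sets
#'
#' Intersects two segmentations, and over the overlapping regions computes
#' the length-weighted Euclidean distance
#' \eqn{\sqrt{\sum_r w_r (a_r - b_r)^2 / \sum_r w_r}} and the
#' length-weighted Pearson correlation of the paired segment means (lengths
#' as frequency weights).
#'
#' @param a,b \code{segment_set}s on the same layout.
#' @return list of class \code{concordance_result}: \code{weighted_euclidean},
#'   \code{weighted_pearson}, \code{total_weight} (bp), \code{n_regions}.
#' @export
segment_concordance <- function(a, b) {
  ga <- as_granges(a)
  gb <- as_granges(b)
  hits <- GenomicRanges::findOverlaps(ga, gb)
  if (length(hits) == 0) stop("segment sets share no overlapping region")
  ov <- IRanges::pintersect(ga[S4Vectors::queryHits(hits)],
                            gb[S4Vectors::subjectHits(hits)])
  w <- as.numeric(GenomicRanges::width(ov))
  am <- a$mean[S4Vectors::queryHits(hits)]
  bm <- b$mean[S4Vectors::subjectHits(hits)]
  W <- sum(w)
  eu <- sqrt(sum(w * (am - bm)^2) / W)
  ma <- sum(w * am) / W
  mb <- sum(w * bm) / W
  cov_ab <- sum(w * (am - ma) * (bm - mb)) / W
  va <- sum(w * (am - ma)^2) / W
  vb <- sum(w * (bm - mb)^2) / W
  pear <- if (va > 0 && vb > 0) cov_ab / sqrt(va * vb) else NA_real_
  structure(list(weighted_euclidean = eu, weighted_pearson = pear,
                 total_weight = W, n_regions = length(w)),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "segment concordance over %d regions (%s bp):\n  weighted Euclidean distance %.4f, weighted Pearson r %.4f\n",
    x$n_regions, format(x$total_weight, big.mark = ","),
    x$weighted_euclidean, x$weighted_pearson))
  invisible(x)
}

#' Random-placement overlap simulation
#'
#' Tests whether a set of query intervals overlaps an annotation more than
#' expected by chance: each simulation re-places the query intervals
#' (keeping their length distribution) uniformly at random on the genome —
#' chromosomes chosen proportionally to placeable length — and records the
#' fraction of intervals overlapping the annotation by at least 1 bp. The
#' empirical p-value uses the +1 correction, so it is never exactly zero.
#'
#' @param query \code{interval_set} whose overlap is tested.
#' @param annotation \code{interval_set} to overlap against.
#' @param layout \code{genome_layout}.
#' @param n_sim number of simulations.
#' @param seed RNG seed.
#' @return list with \code{observed} (fraction of query intervals
#'   overlapping), \code{simulated} (vector of length \code{n_sim}) and
#'   \code{p} = (1 + #\{sims >= observed\}) / (1 + n_sim).
#' @export
random_placement_overlap <- function(query, annotation, layout,
                                     n_sim = 10000, seed = 1) {
  stopifnot(n_sim >= 1)
  if (nrow(query) == 0) stop("empty query set")
  widths <- query$end - query$start
  if (any(widths > max(layout$length)))
    stop("query interval longer than every chromosome")
  ann <- normalize_intervals(annotation)
  observed <- if (nrow(ann) == 0) 0 else
    mean(overlaps_any(query, ann))
  set.seed(seed)
  nq <- length(widths)
  total <- n_sim * nq
  wrep <- rep(widths, times = n_sim)
  chrom_idx <- integer(total)
  starts <- numeric(total)
  # placements drawn per distinct width (chromosome weights depend on it)
  for (w in unique(widths)) {
    sel <- which(wrep == w)
    place <- pmax(layout$length - w + 1, 0)
    if (all(place == 0)) stop("query interval longer than every chromosome")
    ci <- sample.int(nrow(layout), length(sel), replace = TRUE, prob = place)
    chrom_idx[sel] <- ci
    starts[sel] <- floor(stats::runif(length(sel), 0, place[ci]))
  }
  if (nrow(ann) == 0) {
    sims <- numeric(n_sim)
  } else {
    hit <- overlaps_any(data.frame(chrom = layout$chrom[chrom_idx],
                                   start = starts, end = starts + wrep),
                        ann)
    sims <- as.numeric(rowsum(as.numeric(hit),
                              rep(seq_len(n_sim), each = nq))[, 1]) / nq
  }
  list(observed = observed, simulated = sims,
       p = (1 + sum(sims >= observed)) / (1 + n_sim))
}
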