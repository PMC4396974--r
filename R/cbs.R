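#' Segmentation configuration
#'
#' Parameters of the permutation-based circular binary segmentation: a split
#' is accepted when the permutation p-value of the best arc falls below
#' \code{alpha}. The permutation reference distribution makes the test exact
#' at the configured resolution; \code{n_permutations} trades precision for
#' speed. An optional undo pass merges adjacent segments whose mean
#' difference is small relative to the profile's diff-based noise estimate.
#'
#' @param alpha significance level for accepting a split.
#' @param n_permutations permutations per tested split.
#' @param min_width minimum number of bins in the arc and in every non-empty
#'   flanking piece.
#' @param undo_sd merge adjacent segments with |mean difference| below
#'   \code{undo_sd} times the MAD-based scale estimate; 0 disables.
#' @param seed RNG seed used for the permutations (set once per
#'   [cbs_segment()] call); NULL leaves the RNG state alone.
#' @return list of class \code{segmentation_config}.
#' @export
segmentation_config <- function(alpha = 0.01, n_permutations = 10000,
                                min_width = 2, undo_sd = 0, seed = NULL) {
  stopifnot(alpha > 0, alpha < 1, n_permutations >= 100, min_width >= 1,
            undo_sd >= 0)
  structure(list(alpha = alpha, n_permutations = n_permutations,
                 min_width = min_width, undo_sd = undo_sd, seed = seed),
            class = "segmentation_config")
}

#' Best circular-arc split of a segment
#'
#' Finds the circular arc maximizing the pooled-variance two-sample t-like
#' statistic between the values inside and outside the arc, and computes a
#' permutation p-value (fraction of seeded random permutations whose own
#' maximum statistic reaches the observed one). Ties in the statistic are
#' broken toward the shorter arc, then the smaller start index, so the
#' result is deterministic.
#'
#' @param values ordered numeric values of one segment.
#' @param cfg \code{segmentation_config}.
#' @return list with \code{split} (logical: p below alpha), \code{arc_start}
#'   and \code{arc_end} (1-based inclusive positions of the arc),
#'   \code{statistic} and \code{p}; or \code{list(split = FALSE)} when the
#'   segment is too short to test.
#' @export
best_split <- function(values, cfg = segmentation_config()) {
  n <- length(values)
  if (n < 2 * cfg$min_width)
    return(list(split = FALSE, reason = "too short"))
  bs <- cpp_max_arc(as.numeric(values), as.integer(cfg$min_width))
  if (!isTRUE(bs$found))
    return(list(split = FALSE, reason = "no admissible arc"))
  pp <- cpp_perm_pvalue(as.numeric(values), bs$statistic,
                        as.integer(cfg$n_permutations),
                        as.integer(cfg$min_width), cfg$alpha)
  list(split = pp$p < cfg$alpha, arc_start = bs$i + 1L, arc_end = bs$j,
       statistic = bs$statistic, p = pp$p)
}

# recursive splitting of vals[lo..hi]; returns list of c(lo, hi)
cbs_recurse <- function(vals, lo, hi, cfg) {
  n <- hi - lo + 1L
  if (n >= 2 * cfg$min_width) {
    bs <- best_split(vals[lo:hi], cfg)
    if (isTRUE(bs$split)) {
      cuts <- c(bs$arc_start - 1L, bs$arc_end)
      cuts <- cuts[cuts > 0 & cuts < n]
      if (length(cuts)) {
        bounds <- c(lo - 1L, lo - 1L + cuts, hi)
        out <- list()
        for (b in seq_len(length(bounds) - 1L))
          out <- c(out, cbs_recurse(vals, bounds[b] + 1L, bounds[b + 1L], cfg))
        return(out)
      }
    }
  }
  list(c(lo, hi))
}

#' Circular binary segmentation of a per-bin profile
#'
#' Recursively applies [best_split()] within each chromosome over the usable,
#' non-missing bins; an accepted arc introduces up to two change points.
#' Segment means are arithmetic means of member-bin values; genomic
#' coordinates span from the start of the first member bin to the end of the
#' last, including skipped unusable bins in between. Deterministic for fixed
#' seed and input.
#'
#' @param profile data.frame with columns \code{chrom,start,end,log2} and
#'   optionally \code{usable}.
#' @param cfg \code{segmentation_config}.
#' @param layout optional \code{genome_layout} fixing chromosome order
#'   (defaults to order of appearance).
#' @return data.frame of class \code{segment_set}: columns
#'   \code{chrom,start,end,n_bins,mean}.
#' @export
cbs_segment <- function(profile, cfg = segmentation_config(), layout = NULL) {
  if (is.null(profile) || nrow(profile) == 0) stop("empty profile")
  usable <- if (!is.null(profile$usable)) profile$usable else
    rep(TRUE, nrow(profile))
  usable <- usable & !is.na(profile$log2)
  if (!any(usable)) stop("no usable bins to segment")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  chroms <- if (!is.null(layout)) intersect(layout$chrom, profile$chrom)
    else unique(profile$chrom)
  segs <- list()
  for (chr in chroms) {
    rows <- which(profile$chrom == chr & usable)
    if (length(rows) == 0) next
    vals <- profile$log2[rows]
    pieces <- cbs_recurse(vals, 1L, length(vals), cfg)
    if (cfg$undo_sd > 0 && length(pieces) > 1)
      pieces <- undo_small_splits(vals, pieces, cfg$undo_sd)
    for (pc in pieces) {
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = chr,
        start = profile$start[rows[pc[1]]],
        end = profile$end[rows[pc[2]]],
        n_bins = pc[2] - pc[1] + 1L,
        mean = mean(vals[pc[1]:pc[2]]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  class(out) <- c("segment_set", "data.frame")
  out
}

# merge adjacent pieces whose mean difference is below undo_sd * noise scale
undo_small_splits <- function(vals, pieces, undo_sd) {
  scale <- tryCatch(mad_diff(vals), error = function(e) stats::sd(vals))
  if (!is.finite(scale) || scale <= 0) return(pieces)
  repeat {
    if (length(pieces) < 2) break
    means <- vapply(pieces, function(p) mean(vals[p[1]:p[2]]), numeric(1))
    gaps <- abs(diff(means))
    w <- which.min(gaps)
    if (gaps[w] >= undo_sd * scale) break
    pieces[[w]] <- c(pieces[[w]][1], pieces[[w + 1]][2])
    pieces[[w + 1]] <- NULL
  }
  pieces
}

# per-bin fitted value: mean of the segment containing the bin (by midpoint)
fitted_from_segments <- function(profile, segments) {
  out <- rep(NA_real_, nrow(profile))
  if (is.null(segments) || nrow(segments) == 0) return(out)
  mid <- (profile$start + profile$end) / 2
  for (chr in unique(segments$chrom)) {
    s <- segments[segments$chrom == chr, , drop = FALSE]
    rows <- which(profile$chrom == chr)
    i <- findInterval(mid[rows], s$start)
    ok <- i >= 1 & i <= nrow(s)
    ok[ok] <- mid[rows][ok] < s$end[i[ok]]
    out[rows[ok]] <- s$mean[i[ok]]
  }
  out
}

#' Write segments as a SEG file
#'
#' IGV-dialect SEG: tab-separated with 1-based inclusive start positions
#' (internal coordinates are 0-based half-open).
#'
#' @param segments \code{segment_set}.
#' @param path output path.
#' @param sample sample identifier for the first column.
#' @return \code{path}, invisibly.
#' @export
write_seg <- function(segments, path, sample = "sample") {
  df <- data.frame(ID = sample, chrom = segments$chrom,
                   loc.start = format(segments$start + 1, scientific = FALSE,
                                      trim = TRUE),
                   loc.end = format(segments$end, scientific = FALSE,
                                    trim = TRUE),
                   num.mark = segments$n_bins,
                   seg.mean = round(segments$mean, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SEG file
#'
#' @param path SEG file (as written by [write_seg()] or IGV-compatible).
#' @return \code{segment_set} data.frame.
#' @export
read_seg <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(df[[2]]),
                    start = as.numeric(df[[3]]) - 1,
                    end = as.numeric(df[[4]]),
                    n_bins = as.integer(df[[5]]),
                    mean = as.numeric(df[[6]]),
                    stringsAsFactors = FALSE)
  class(out) <- c("segment_set", "data.frame")
  out
}
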