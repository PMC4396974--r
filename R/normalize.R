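#' Bin filter configuration
#'
#' Rules that flag bins as unusable before normalization: low mappability,
#' overlap with an exclusion (blacklist) list of known germline copy-number
#' variation, and zero/missing compensated counts.
#'
#' @param min_mappability minimum mean mappability for a usable bin.
#' @param blacklist_overlap_max maximum tolerated blacklist overlap as a
#'   fraction of the bin (default 0: any overlap excludes).
#' @param require_nonzero_doc exclude bins with zero or missing compensated
#'   counts instead of offsetting them.
#' @return list of class \code{bin_filter_config}.
#' @export
bin_filter_config <- function(min_mappability = 0.2,
                              blacklist_overlap_max = 0,
                              require_nonzero_doc = TRUE) {
  stopifnot(min_mappability >= 0, min_mappability <= 1,
            blacklist_overlap_max >= 0, blacklist_overlap_max <= 1)
  structure(list(min_mappability = min_mappability,
                 blacklist_overlap_max = blacklist_overlap_max,
                 require_nonzero_doc = isTRUE(require_nonzero_doc)),
            class = "bin_filter_config")
}

#' Loess correction configuration
#'
#' @param span loess span (fraction of points in each local fit).
#' @param degree local polynomial degree, 1 or 2.
#' @param covariate_order order in which the corrections are applied.
#' @return list of class \code{loess_config}.
#' @export
loess_config <- function(span = 0.75, degree = 2,
                         covariate_order = c("gc", "mappability")) {
  stopifnot(span > 0, span <= 1, degree %in% c(1, 2))
  structure(list(span = span, degree = degree,
                 covariate_order = covariate_order),
            class = "loess_config")
}

#' GC fraction per bin
#'
#' (G+C)/(A+C+G+T) over each bin, case-insensitive; N and other ambiguity
#' codes are excluded from the denominator. A bin with fewer than 10%
#' unambiguous bases is returned missing.
#'
#' @param genome_fasta path to an indexed FASTA (indexed on the fly if
#'   needed).
#' @param bins \code{bin_grid}.
#' @return numeric vector of GC fractions parallel to the bins.
#' @export
gc_fraction_per_bin <- function(genome_fasta, bins) {
  if (!file.exists(paste0(genome_fasta, ".fai")))
    Rsamtools::indexFa(genome_fasta)
  fa <- Rsamtools::FaFile(genome_fasta)
  idx <- Rsamtools::scanFaIndex(fa)
  have <- as.character(GenomicRanges::seqnames(idx))
  miss <- setdiff(unique(bins$chrom), have)
  if (length(miss))
    stop("chromosome absent from FASTA: ", paste(miss, collapse = ", "))
  gr <- as_granges(bins)
  seqs <- Rsamtools::scanFa(fa, gr)
  freq <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
  acgt <- rowSums(freq)
  gc <- (freq[, "G"] + freq[, "C"]) / acgt
  gc[acgt < 0.1 * bins$length] <- NA_real_
  unname(gc)
}

#' Mean mappability per bin
#'
#' Length-weighted mean of a per-interval mappability track (bedGraph-style
#' \code{chrom,start,end,score} with values in [0,1]) over each bin; bases
#' absent from the track count as 0.
#'
#' @param track \code{interval_set} with a \code{score} column, or a path to
#'   a 4-column bedGraph-like file.
#' @param bins \code{bin_grid}.
#' @return numeric vector of mean mappability per bin.
#' @export
mappability_per_bin <- function(track, bins) {
  if (is.character(track)) {
    tab <- utils::read.table(track, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    track <- interval_set(tab[[1]], tab[[2]], tab[[3]], score = tab[[4]])
  }
  if (!"score" %in% names(track)) stop("mappability track needs a score column")
  if (any(track$score < 0 | track$score > 1))
    stop("mappability values must lie in [0,1]")
  out <- numeric(nrow(bins))
  if (nrow(track) == 0) return(out)
  bgr <- as_granges(bins)
  tgr <- as_granges(track)
  hits <- GenomicRanges::findOverlaps(bgr, tgr)
  if (length(hits)) {
    ov <- IRanges::pintersect(bgr[S4Vectors::queryHits(hits)],
                              tgr[S4Vectors::subjectHits(hits)])
    contrib <- GenomicRanges::width(ov) *
      track$score[S4Vectors::subjectHits(hits)]
    agg <- rowsum(contrib, S4Vectors::queryHits(hits))
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out / bins$length
}

#' Correct bin values for a covariate with loess
#'
#' Fits a local regression m(c) of the values on the covariate over usable
#' pairs and returns \code{values * median(values) / m(c)}, i.e. a
#' multiplicative correction rescaled so the median is preserved. The fit
#' uses the robust (symmetric, Tukey biweight) loess family and is performed
#' on the log2 scale, so bins sitting on true copy-number gains and losses
#' are symmetric outliers that do not drag the technical-bias curve toward
#' themselves. Applied once per covariate (GC content, then mappability, by
#' default order in the pipeline). Bins with a missing covariate stay
#' missing.
#'
#' @param values positive per-bin values (compensated counts or a previous
#'   correction's output).
#' @param covariate per-bin covariate (GC fraction or mappability).
#' @param cfg \code{loess_config}.
#' @return corrected values, same length, NA propagated.
#' @export
loess_correct <- function(values, covariate, cfg = loess_config()) {
  usable <- !is.na(values) & !is.na(covariate) & values > 0
  if (sum(usable) < 30)
    stop("fewer than 30 usable (value, covariate) pairs; ",
         "use larger bins or skip this correction")
  med <- stats::median(values[usable])
  # fit on the log2 scale: gains and losses are then symmetric deviations,
  # so the robust weights treat both alike and the curve tracks the
  # copy-neutral majority
  fit <- stats::loess(v ~ c,
                      data = data.frame(v = log2(values[usable]),
                                        c = covariate[usable]),
                      span = cfg$span, degree = cfg$degree,
                      family = "symmetric",
                      control = stats::loess.control(surface = "direct",
                                                     iterations = 6))
  out <- rep(NA_real_, length(values))
  pred <- 2^stats::predict(fit, newdata = data.frame(c = covariate[usable]))
  corr <- values[usable] * med / pred
  corr[!is.finite(corr) | pred <= 0] <- NA_real_
  out[usable] <- corr
  # bins with a value but missing covariate stay missing; zero-value bins
  # keep their zero (nothing to correct)
  zero <- !is.na(values) & !is.na(covariate) & values == 0
  out[zero] <- 0
  out
}

#' Flag usable bins
#'
#' Applies the mappability threshold, blacklist exclusion and zero-count
#' rules to a coverage profile and fills its \code{usable} column.
#'
#' @param profile per-bin data.frame with at least
#'   \code{chrom,start,end,length,comp_doc,mappability}.
#' @param blacklist \code{interval_set} of excluded regions (may be empty).
#' @param cfg \code{bin_filter_config}.
#' @return the profile with a logical \code{usable} column set.
#' @export
apply_bin_filters <- function(profile, blacklist = interval_set(),
                              cfg = bin_filter_config()) {
  usable <- rep(TRUE, nrow(profile))
  if (!is.null(profile$mappability))
    usable <- usable & (is.na(profile$mappability) |
                          profile$mappability >= cfg$min_mappability)
  if (nrow(blacklist) > 0) {
    bl <- normalize_intervals(blacklist)
    frac <- intersect_bp_per_bin(bl, profile) / profile$length
    usable <- usable & frac <= cfg$blacklist_overlap_max
  }
  if (cfg$require_nonzero_doc)
    usable <- usable & !is.na(profile$comp_doc) & profile$comp_doc > 0
  profile$usable <- usable
  profile
}

#' Median normalization and log2 transform
#'
#' Centres the log2-transformed corrected values at the median of the usable
#' autosomal bins (the median is taken on the log scale, so the usable
#' autosomal median of the output is exactly 0 for even bin counts too).
#' Restricting to autosomes keeps sex-chromosome copy state from shifting
#' the baseline. Missing values propagate.
#'
#' @param values per-bin corrected values.
#' @param usable logical usable flags.
#' @param chrom per-bin chromosome names.
#' @param layout \code{genome_layout}.
#' @return per-bin log2 values (NA where the input is missing or
#'   non-positive).
#' @export
median_normalize_log2 <- function(values, usable, chrom, layout) {
  auto <- is_autosome(layout, chrom)
  sel <- usable & auto & !is.na(values) & values > 0
  if (!any(sel)) stop("no usable autosomal bins with positive values")
  m <- stats::median(log2(values[sel]))  # log-scale median: exact for even n
  out <- rep(NA_real_, length(values))
  pos <- !is.na(values) & values > 0
  out[pos] <- log2(values[pos]) - m
  out
}

#' Relative log2 ratio against a reference
#'
#' Bin-wise subtraction of the reference profile from the sample profile,
#' yielding relative copy-number ratios. Missing on either side propagates;
#' a bin is usable only when usable in both.
#'
#' @param sample_log2,reference_log2 per-bin log2 vectors on the same grid.
#' @param sample_usable,reference_usable usable flags (optional).
#' @return list with \code{log2} and \code{usable}.
#' @export
relative_log2 <- function(sample_log2, reference_log2,
                          sample_usable = NULL, reference_usable = NULL) {
  if (length(sample_log2) != length(reference_log2))
    stop("sample and reference are not on the same bin grid")
  rel <- sample_log2 - reference_log2
  usable <- if (is.null(sample_usable) || is.null(reference_usable))
    !is.na(rel) else sample_usable & reference_usable & !is.na(rel)
  list(log2 = rel, usable = usable)
}
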