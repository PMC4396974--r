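#' Read filter configuration
#'
#' Filters applied to alignment records on ingest: minimum mapping quality,
#' proper-pair requirement, duplicate removal and mitochondrial exclusion.
#' Defaults reproduce the workflow's filter (mapping quality at least 37,
#' properly paired reads only).
#'
#' @param min_mapq minimum Phred-scaled mapping quality to retain a read.
#' @param require_proper_pair drop reads not flagged as proper pairs
#'   (SAM FLAG 0x2).
#' @param drop_duplicates drop reads flagged as PCR/optical duplicates.
#' @param drop_mitochondrial drop reads on mitochondrial chromosomes.
#' @return list of class \code{read_filter_config}.
#' @export
read_filter_config <- function(min_mapq = 37, require_proper_pair = TRUE,
                               drop_duplicates = TRUE,
                               drop_mitochondrial = TRUE) {
  stopifnot(min_mapq >= 0)
  structure(list(min_mapq = min_mapq,
                 require_proper_pair = isTRUE(require_proper_pair),
                 drop_duplicates = isTRUE(drop_duplicates),
                 drop_mitochondrial = isTRUE(drop_mitochondrial)),
            class = "read_filter_config")
}

# Resolve a SAM or BAM path to an indexed BAM. SAM input is converted (and
# thereby sorted and indexed) into tempdir(); BAM input must already have a
# .bai index next to it.
resolve_alignment_file <- function(path) {
  if (!file.exists(path)) stop("no such alignment file: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- file.path(tempdir(),
                      paste0(tools::file_path_sans_ext(basename(path)), "_",
                             substr(tools::md5sum(path), 1, 8)))
    bam <- paste0(dest, ".bam")
    if (!file.exists(bam))
      bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                              indexDestination = TRUE)
    return(bam)
  }
  idx <- c(paste0(path, ".bai"), sub("\\.bam$", ".bai", path))
  if (!any(file.exists(idx)))
    stop("missing BAM index (.bai) for ", path,
         "; the alignment file must be coordinate-sorted and indexed")
  path
}

# Raw primary records with mapq/flag fields, chromosome names resolved
# against the layout. Internal workhorse for load_filtered_reads and
# classify_reads.
scan_primary_records <- function(alignment_path, layout,
                                 include_unmapped = FALSE) {
  bam <- resolve_alignment_file(alignment_path)
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isUnmappedQuery = if (include_unmapped) NA else FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = c("mapq", "flag"))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  chrom_file <- as.character(GenomicAlignments::seqnames(ga))
  map <- resolve_chrom_names(unique(chrom_file), layout)
  mito_names <- attr(layout, "mitochondrial")
  bad <- names(map)[is.na(map) & !(names(map) %in% mito_names) &
                      !(sub("^chr", "", names(map)) %in% mito_names)]
  if (length(bad))
    stop("chromosome present in alignment file but absent from layout: ",
         paste(bad, collapse = ", "))
  chrom <- unname(map[chrom_file])
  mapq <- S4Vectors::mcols(ga)$mapq
  fl <- S4Vectors::mcols(ga)$flag
  data.frame(chrom = ifelse(is.na(chrom), chrom_file, chrom),
             start = GenomicAlignments::start(ga) - 1L,
             end = GenomicAlignments::end(ga),
             strand = as.character(GenomicAlignments::strand(ga)),
             mapq = ifelse(is.na(mapq), 255L, mapq),
             proper_pair = bitwAnd(fl, 2L) > 0L,
             duplicate = bitwAnd(fl, 1024L) > 0L,
             unmapped = bitwAnd(fl, 4L) > 0L,
             mito = chrom_file %in% mito_names |
               sub("^chr", "", chrom_file) %in% mito_names |
               is_mitochondrial(layout, ifelse(is.na(chrom), chrom_file, chrom)),
             stringsAsFactors = FALSE)
}

#' Load quality-filtered reads from an alignment file
#'
#' Reads primary alignment records from a coordinate-sorted, indexed BAM (or
#' a SAM file, which is converted on the fly), and applies the read filters:
#' mapped, non-duplicate, properly paired, mapping quality at least
#' \code{cfg$min_mapq}, non-mitochondrial. Secondary and supplementary
#' alignments are always excluded. Chromosome names are resolved against the
#' layout, tolerating a bare "chr" prefix difference; any other mismatch is
#' an error naming the chromosome.
#'
#' @param alignment_path SAM/BAM path.
#' @param layout \code{genome_layout}.
#' @param cfg \code{read_filter_config}.
#' @return data.frame of reads with columns
#'   \code{chrom,start,end,strand,mapq,proper_pair,duplicate}
#'   (0-based half-open), in coordinate order.
#' @export
load_filtered_reads <- function(alignment_path, layout,
                                cfg = read_filter_config()) {
  rec <- scan_primary_records(alignment_path, layout, include_unmapped = FALSE)
  keep <- rec$mapq >= cfg$min_mapq
  if (cfg$require_proper_pair) keep <- keep & rec$proper_pair
  if (cfg$drop_duplicates) keep <- keep & !rec$duplicate
  if (cfg$drop_mitochondrial) keep <- keep & !rec$mito
  rec <- rec[keep & rec$chrom %in% layout$chrom, , drop = FALSE]
  rec <- rec[order(match(rec$chrom, layout$chrom), rec$start), , drop = FALSE]
  rownames(rec) <- NULL
  rec[, c("chrom", "start", "end", "strand", "mapq", "proper_pair",
          "duplicate")]
}

#' Classify alignment records into QC categories
#'
#' Counts every primary record in the file into exactly one of four
#' mutually exclusive categories, assigned in order: \code{low_quality}
#' (unmapped, duplicate, mapping quality below threshold, or not properly
#' paired), \code{mitochondrial}, \code{in_peaks} (alignment overlaps a peak
#' by at least 1 bp), and \code{remaining}. The counts sum to the number of
#' primary records.
#'
#' @param alignment_path SAM/BAM path.
#' @param peaks \code{interval_set} of peak regions (may be empty).
#' @param layout \code{genome_layout}.
#' @param cfg \code{read_filter_config}.
#' @return named numeric vector with elements \code{low_quality},
#'   \code{mitochondrial}, \code{in_peaks}, \code{remaining}, and attribute
#'   \code{total}.
#' @export
classify_reads <- function(alignment_path, peaks = interval_set(),
                           layout, cfg = read_filter_config()) {
  rec <- scan_primary_records(alignment_path, layout, include_unmapped = TRUE)
  low <- rec$unmapped | rec$mapq < cfg$min_mapq
  if (cfg$require_proper_pair) low <- low | !rec$proper_pair
  if (cfg$drop_duplicates) low <- low | rec$duplicate
  mito <- !low & rec$mito
  rest <- !low & !mito
  inpk <- rep(FALSE, nrow(rec))
  if (any(rest) && nrow(peaks) > 0)
    inpk[rest] <- overlaps_any(rec[rest, c("chrom", "start", "end")], peaks)
  counts <- c(low_quality = sum(low), mitochondrial = sum(mito),
              in_peaks = sum(inpk), remaining = sum(rest & !inpk))
  attr(counts, "total") <- nrow(rec)
  counts
}
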