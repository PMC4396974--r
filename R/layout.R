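#' Genome layout
#'
#' A genome layout is the ordered coordinate universe shared by every
#' container in the package: chromosome names, their lengths in bp, and which
#' chromosomes are mitochondrial or sex chromosomes. All internal coordinates
#' are 0-based half-open.
#'
#' @param chromosomes character vector of chromosome names, in the order they
#'   should be processed and reported.
#' @param lengths integer vector of chromosome lengths (bp), parallel to
#'   \code{chromosomes}.
#' @param mitochondrial names treated as mitochondrial (excluded from
#'   analysis by default).
#' @param sex names treated as sex chromosomes (binned and reported, but
#'   excluded from the normalization median).
#' @return An object of class \code{genome_layout}: a data.frame with columns
#'   \code{chrom} and \code{length}, plus attributes for the special
#'   chromosome sets.
#' @export
genome_layout <- function(chromosomes, lengths,
                          mitochondrial = c("chrM", "MT", "M"),
                          sex = c("chrX", "chrY", "X", "Y")) {
  chromosomes <- as.character(chromosomes)
  lengths <- as.numeric(lengths)
  if (length(chromosomes) != length(lengths))
    stop("chromosomes and lengths must have the same length")
  if (anyDuplicated(chromosomes))
    stop("duplicated chromosome names: ",
         paste(unique(chromosomes[duplicated(chromosomes)]), collapse = ", "))
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("all chromosome lengths must be positive")
  out <- data.frame(chrom = chromosomes, length = lengths,
                    stringsAsFactors = FALSE)
  attr(out, "mitochondrial") <- mitochondrial
  attr(out, "sex") <- sex
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' Read a genome layout from a file
#'
#' Accepts a samtools \code{.fai} index, a two-column chromosome-sizes TSV
#' (name, length), or an indexed FASTA file (indexed on the fly when the
#' \code{.fai} is absent).
#'
#' @param path file path.
#' @param ... passed to [genome_layout()].
#' @return A \code{genome_layout}.
#' @export
read_genome_layout <- function(path, ...) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && startsWith(first, ">")) {
    fai <- paste0(path, ".fai")
    if (!file.exists(fai)) Rsamtools::indexFa(path)
    idx <- Rsamtools::scanFaIndex(path)
    return(genome_layout(as.character(GenomicRanges::seqnames(idx)),
                         GenomicRanges::width(idx), ...))
  }
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expected at least two tab-separated columns in ", path)
  genome_layout(tab[[1]], as.numeric(tab[[2]]), ...)
}

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) stop("chromosome not in layout: ",
                     paste(chrom[is.na(i)], collapse = ", "))
  layout$length[i]
}

is_mitochondrial <- function(layout, chrom) {
  chrom %in% attr(layout, "mitochondrial")
}

is_autosome <- function(layout, chrom) {
  !(chrom %in% attr(layout, "mitochondrial")) & !(chrom %in% attr(layout, "sex"))
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", nrow(x), "chromosomes,",
      format(sum(x$length), big.mark = ","), "bp\n")
  print.data.frame(x, ...)
  invisible(x)
}

# Map chromosome names found in a file onto layout names, resolving only a
# "chr" prefix difference. Returns a named character vector (file name ->
# layout name); unresolvable names map to NA.
resolve_chrom_names <- function(names_in_file, layout) {
  target <- layout$chrom
  out <- ifelse(names_in_file %in% target, names_in_file, NA_character_)
  miss <- is.na(out)
  if (any(miss)) {
    stripped <- sub("^chr", "", names_in_file[miss])
    alt <- ifelse(stripped %in% target, stripped, paste0("chr", stripped))
    out[miss] <- ifelse(alt %in% target, alt, NA_character_)
  }
  names(out) <- names_in_file
  out
}
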