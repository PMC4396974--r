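# Small hand-built fixtures shared across test files. Everything is
# generated in code; SAM text is the only alignment format written.

tiny_layout <- function() {
  genome_layout(c("chr1", "chr2", "chrM"), c(100000, 80000, 16000))
}

# Write a SAM file from a read table. Columns: chrom, pos (0-based), mapq,
# and optionally flag (default 99 = paired, proper, mate-reversed, first in
# pair) and rlen.
write_test_sam <- function(reads, layout, path = tempfile(fileext = ".sam")) {
  flag <- if (!is.null(reads$flag)) reads$flag else rep(99L, nrow(reads))
  rlen <- if (!is.null(reads$rlen)) reads$rlen else rep(100L, nrow(reads))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", layout$chrom,
                      as.integer(layout$length)))
  rec <- sprintf("r%04d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
                 seq_len(nrow(reads)), flag, reads$chrom,
                 as.integer(reads$pos + 1), as.integer(reads$mapq), rlen)
  writeLines(c(header, rec), path)
  path
}

# read table in the shape load_filtered_reads() returns
reads_df <- function(chrom, start, end = start + 100, strand = "+",
                     mapq = 60L, proper_pair = TRUE, duplicate = FALSE) {
  data.frame(chrom = chrom, start = start, end = end,
             strand = rep_len(strand, length(start)),
             mapq = rep_len(mapq, length(start)),
             proper_pair = rep_len(proper_pair, length(start)),
             duplicate = rep_len(duplicate, length(start)),
             stringsAsFactors = FALSE)
}

# brute-force reference for the max-arc search in cbs: enumerate every
# admissible circular arc of x and return the argmax under the same
# tie-break (shorter arc, then smaller start)
brute_force_max_arc <- function(x, min_width = 2) {
  n <- length(x)
  best <- NULL
  for (i in 0:(n - 1)) {
    for (j in (i + 1):n) {
      k <- j - i
      if (k < min_width || n - k < min_width) next
      if (i > 0 && i < min_width) next
      if (j < n && n - j < min_width) next
      inside <- x[(i + 1):j]
      outside <- x[setdiff(seq_len(n), (i + 1):j)]
      m1 <- mean(inside); m2 <- mean(outside)
      ss <- sum((inside - m1)^2) + sum((outside - m2)^2)
      s2 <- ss / (n - 2)
      denom <- s2 * (1 / k + 1 / (n - k))
      T <- if (denom <= 1e-300) {
        if (abs(m1 - m2) > 1e-12) 1e12 else 0
      } else abs(m1 - m2) / sqrt(denom)
      tol <- if (is.null(best)) 0 else 1e-10 * max(1, best$statistic)
      if (is.null(best) || T > best$statistic + tol ||
          (T >= best$statistic - tol &&
           (k < best$j - best$i ||
            (k == best$j - best$i && i < best$i))))
        best <- list(i = i, j = j,
                     statistic = max(T, if (is.null(best)) T else
                       best$statistic))
    }
  }
  best
}
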