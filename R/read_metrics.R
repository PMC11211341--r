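# Per-library alignment statistics: counts, mapping rate, read-length
# distribution, and the sequencing-error profile derived from CIGAR + NM.

#' Mapping statistics for a library
#'
#' Counts all records, computes the mapped fraction, and summarises the
#' length distribution of mapped reads (sequence length including soft
#' clips, as a read-length histogram). The median is the 50th percentile of
#' mapped read lengths (mean of the middle two when even); with no mapped
#' reads it is reported as `NA`.
#'
#' @param records An [aln_records()] table of primary records.
#' @param bin_width Histogram bin width in nt (default 100).
#' @return A list of class `read_stats`: `total`, `mapped`, `mapping_rate`,
#'   `median_length`, `histogram` (data.frame bin_start, bin_end, count).
#' @export
mapping_stats <- function(records, bin_width = 100L) {
  if (nrow(records) == 0) stop("mapping_stats: no reads")
  lens <- nchar(records$seq[records$mapped])
  med <- if (length(lens)) unname(median(lens)) else NA_real_
  hist_df <- if (length(lens)) {
    b <- (max(lens) %/% bin_width) + 1L
    bin <- pmin(lens %/% bin_width, b - 1L)
    cnt <- tabulate(bin + 1L, nbins = b)
    data.frame(bin_start = (seq_len(b) - 1L) * bin_width,
               bin_end = seq_len(b) * bin_width, count = cnt)
  } else {
    data.frame(bin_start = integer(), bin_end = integer(), count = integer())
  }
  out <- list(total = nrow(records), mapped = sum(records$mapped),
              mapping_rate = sum(records$mapped) / nrow(records),
              median_length = med, histogram = hist_df)
  class(out) <- "read_stats"
  out
}

#' @export
print.read_stats <- function(x, ...) {
  cat(sprintf("read_stats: N=%d, mapped=%d (%.1f%%), median length=%s nt\n",
              x$total, x$mapped, 100 * x$mapping_rate,
              ifelse(is.na(x$median_length), "NA",
                     format(x$median_length))))
  invisible(x)
}

#' Per-read sequencing-error profile
#'
#' Splits the edit distance into mismatches and indels using the CIGAR:
#' inserted/deleted base counts come from I/D operations, mismatches are
#' `NM - inserted - deleted`. Rates are per alignment column, where columns
#' = aligned reference bases (M) + inserted bases (I) + deleted bases (D);
#' soft clips are excluded.
#'
#' @param records An [aln_records()] table; only mapped rows with an NM tag
#'   are profiled.
#' @return data.frame with one row per mapped read: qname, mismatches,
#'   insertions, deletions, columns, mismatch_rate, insertion_rate,
#'   deletion_rate, total_rate.
#' @export
error_profile <- function(records) {
  m <- records[records$mapped, , drop = FALSE]
  if (any(is.na(m$nm)))
    stop("error_profile: mapped records without an NM tag")
  n <- nrow(m)
  ins <- del <- mbases <- integer(n)
  for (i in seq_len(n)) {
    ops <- cigar_ops(m$cigar[i])
    ins[i] <- sum(ops$len[ops$op == "I"])
    del[i] <- sum(ops$len[ops$op == "D"])
    mbases[i] <- sum(ops$len[ops$op %in% c("M", "=", "X")])
  }
  mism <- m$nm - ins - del
  if (any(mism < 0))
    stop("error_profile: NM tag smaller than indel bases for read ",
         m$qname[which(mism < 0)[1]])
  cols <- mbases + ins + del
  data.frame(qname = m$qname, mismatches = mism, insertions = ins,
             deletions = del, columns = cols,
             mismatch_rate = mism / cols, insertion_rate = ins / cols,
             deletion_rate = del / cols,
             total_rate = (mism + ins + del) / cols)
}

#' Library-level aggregate error rates
#'
#' Pools mismatch/insertion/deletion counts over all mapped reads and
#' divides by pooled alignment columns.
#'
#' @param records An [aln_records()] table.
#' @return Named numeric vector: mismatch_rate, insertion_rate,
#'   deletion_rate, total_rate.
#' @export
library_error_profile <- function(records) {
  per <- error_profile(records)
  cols <- sum(per$columns)
  if (cols == 0)
    return(c(mismatch_rate = NA_real_, insertion_rate = NA_real_,
             deletion_rate = NA_real_, total_rate = NA_real_))
  c(mismatch_rate = sum(per$mismatches) / cols,
    insertion_rate = sum(per$insertions) / cols,
    deletion_rate = sum(per$deletions) / cols,
    total_rate = sum(per$mismatches + per$insertions + per$deletions) / cols)
}
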