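# In-memory container for primary long-read alignments: a plain data.frame
# with one row per read, SAM-style 1-based closed coordinates, and the soft
# clip sequences split out so downstream callers never re-parse the CIGAR.

#' Construct an alignment record table
#'
#' Builds the per-read alignment table used throughout the package. Each row
#' is one primary alignment (or unmapped read). Coordinates are 1-based
#' closed, as in SAM and GRanges. `seq` is stored in reference orientation;
#' for minus-strand alignments the poly(A) tail of the cDNA therefore appears
#' as a leading T-run soft clip.
#'
#' @param qname Read names (unique).
#' @param mapped Logical; FALSE rows carry NA coordinates/CIGAR.
#' @param chrom,start,end,strand Alignment coordinates (NA when unmapped).
#' @param cigar CIGAR strings with soft clips retained (NA when unmapped).
#' @param seq Read sequence in reference orientation, including clipped bases.
#' @param nm Edit-distance tag (mismatches + inserted + deleted bases).
#' @return A data.frame of class `aln_records` with the above columns plus
#'   `clip_left`/`clip_right` (soft-clip sequences, `""` when absent).
#' @export
aln_records <- function(qname, mapped, chrom, start, end, strand, cigar,
                        seq, nm) {
  df <- data.frame(
    qname = as.character(qname), mapped = as.logical(mapped),
    chrom = as.character(chrom), start = as.integer(start),
    end = as.integer(end), strand = as.character(strand),
    cigar = as.character(cigar), seq = as.character(seq),
    nm = as.integer(nm), stringsAsFactors = FALSE
  )
  clips <- split_clips(df$cigar, df$seq, df$mapped)
  df$clip_left <- clips$left
  df$clip_right <- clips$right
  class(df) <- c("aln_records", "data.frame")
  validate_records(df)
  df
}

split_clips <- function(cigar, seq, mapped) {
  left <- character(length(cigar))
  right <- character(length(cigar))
  for (i in seq_along(cigar)) {
    if (!mapped[i]) next
    cl <- cigar_clip_lens(cigar[i])
    n <- nchar(seq[i])
    if (cl[1] > 0) left[i] <- substr(seq[i], 1L, cl[1])
    if (cl[2] > 0) right[i] <- substr(seq[i], n - cl[2] + 1L, n)
  }
  list(left = left, right = right)
}

#' Validate alignment record invariants
#'
#' Checks the structural invariants of an `aln_records` table: unique names,
#' `end >= start` and a non-empty CIGAR for mapped rows, soft clips only at
#' CIGAR termini, and query-consumed CIGAR length equal to the stored
#' sequence length.
#'
#' @param records An `aln_records` data.frame.
#' @return The input, invisibly; errors on violation.
#' @export
validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  if (anyDuplicated(records$qname))
    stop("duplicate read names in records")
  m <- which(records$mapped)
  if (length(m)) {
    if (any(is.na(records$chrom[m])) || any(is.na(records$cigar[m])))
      stop("mapped records must carry chrom and CIGAR")
    if (any(records$end[m] < records$start[m]))
      stop("mapped records must satisfy end >= start")
    if (!all(records$strand[m] %in% c("+", "-")))
      stop("mapped records must have strand '+' or '-'")
    for (i in m) {
      qlen <- cigar_query_len(records$cigar[i])
      if (qlen != nchar(records$seq[i]))
        stop("CIGAR query length != sequence length for read ",
             records$qname[i])
      rlen <- cigar_ref_len(records$cigar[i])
      if (rlen != records$end[i] - records$start[i] + 1L)
        stop("CIGAR reference length != end - start + 1 for read ",
             records$qname[i])
      cigar_clip_lens(records$cigar[i]) # errors on interior clips
    }
  }
  invisible(records)
}

# 5' genomic position of a mapped read (alignment start for +, end for -),
# ignoring soft-clipped bases whose genomic origin is unknown.
read_five_prime <- function(records) {
  ifelse(records$strand == "+", records$start, records$end)
}

# 3' genomic position (cleavage side): end for +, start for -.
read_three_prime <- function(records) {
  ifelse(records$strand == "+", records$end, records$start)
}

# Spliced flag: >=1 reference skip of length >= min_intron.
is_spliced <- function(records, min_intron = 40L) {
  vapply(seq_len(nrow(records)), function(i) {
    if (!records$mapped[i]) return(NA)
    ops <- cigar_ops(records$cigar[i])
    any(ops$op == "N" & ops$len >= min_intron)
  }, logical(1))
}
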