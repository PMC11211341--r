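# CIGAR helpers. The simulator constructs CIGARs op-by-op, so the package
# carries its own small parser; GenomicAlignments is used in the test suite
# as an independent cross-check of the same geometry.

QUERY_OPS <- c("M", "I", "S", "=", "X")
REF_OPS   <- c("M", "D", "N", "=", "X")

#' Parse a CIGAR string into operations
#'
#' @param cigar A single CIGAR string (e.g. `"5S10M100N20M"`).
#' @return A data.frame with columns `len` (integer) and `op` (character),
#'   one row per operation, in order. `"*"` or `NA` yields zero rows.
#' @examples
#' cigar_ops("5S10M2I10M")
#' @export
cigar_ops <- function(cigar) {
  if (length(cigar) != 1L)
    stop("cigar_ops() expects a single CIGAR string")
  if (is.na(cigar) || cigar == "*")
    return(data.frame(len = integer(), op = character()))
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar))
    stop("malformed CIGAR: ", cigar)
  nc <- nchar(toks)
  structure(
    list(len = as.integer(substr(toks, 1L, nc - 1L)),
         op = substr(toks, nc, nc)),
    class = "data.frame", row.names = seq_along(toks)
  )
}

#' Query and reference lengths consumed by a CIGAR
#'
#' `cigar_query_len()` counts bases of the stored read sequence consumed
#' (M/I/S/=/X); `cigar_ref_len()` counts reference bases consumed
#' (M/D/N/=/X).
#'
#' @param cigar CIGAR string.
#' @return Integer length.
#' @export
cigar_query_len <- function(cigar) {
  ops <- cigar_ops(cigar)
  sum(ops$len[ops$op %in% QUERY_OPS])
}

#' @rdname cigar_query_len
#' @export
cigar_ref_len <- function(cigar) {
  ops <- cigar_ops(cigar)
  sum(ops$len[ops$op %in% REF_OPS])
}

#' Soft-clip lengths at the CIGAR termini
#'
#' @param cigar CIGAR string.
#' @return Integer vector `c(left, right)` of soft-clipped base counts.
#' @export
cigar_clip_lens <- function(cigar) {
  ops <- cigar_ops(cigar)
  n <- nrow(ops)
  left <- if (n > 0 && ops$op[1] == "S") ops$len[1] else 0L
  right <- if (n > 1 && ops$op[n] == "S") ops$len[n] else 0L
  if (n == 1 && ops$op[1] == "S")
    stop("CIGAR consists only of a soft clip: ", cigar)
  if (any(ops$op[-c(1L, n)] == "S"))
    stop("soft clip in CIGAR interior: ", cigar)
  c(left = left, right = right)
}

# Reference intervals (1-based closed) covered by M/=/X operations,
# merged when reference-adjacent. Used for per-base coverage labelling.
cigar_m_ranges <- function(cigar, pos) {
  ops <- cigar_ops(cigar)
  ref_at <- pos
  starts <- integer()
  ends <- integer()
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      starts <- c(starts, ref_at)
      ends <- c(ends, ref_at + len - 1L)
    }
    if (op %in% REF_OPS) ref_at <- ref_at + len
  }
  if (length(starts) == 0L)
    return(IRanges::IRanges())
  IRanges::reduce(IRanges::IRanges(start = starts, end = ends))
}

# Counts of inserted and deleted bases in a CIGAR.
cigar_indel_bases <- function(cigar) {
  ops <- cigar_ops(cigar)
  c(ins = sum(ops$len[ops$op == "I"]),
    del = sum(ops$len[ops$op == "D"]))
}

# Collapse a per-token op sequence into a CIGAR string.
ops_to_cigar <- function(lens, ops) {
  keep <- lens > 0L
  lens <- lens[keep]; ops <- ops[keep]
  if (length(ops) == 0L) return("*")
  r <- rle(paste0(ops))
  # merge equal adjacent ops while summing lengths
  out_ops <- r$values
  idx <- rep.int(seq_along(r$lengths), r$lengths)
  out_lens <- as.integer(rowsum(as.numeric(lens), idx))
  paste0(out_lens, out_ops, collapse = "")
}
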