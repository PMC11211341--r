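# Read-level transcript completeness. 3' support comes from an unmapped
# poly(A) tail in the soft clip on the read's 3' side; 5' support from
# proximity of the aligned 5' end to a same-strand CAGE cluster. The two
# flags define four categories: unsupported, three_only, five_only,
# five_three. Tail calls can be validated by the canonical polyadenylation
# motif upstream of the inferred cleavage site.

CATEGORY_LEVELS <- c("unsupported", "three_only", "five_only", "five_three")

#' Call a poly(A) tail from soft-clipped bases
#'
#' For `+` alignments the right soft clip is scanned from its 5' side for an
#' adenine-rich prefix; for `-` alignments the left soft clip is scanned
#' from its 3' side (i.e. reversed) for a thymine-rich prefix, since the
#' stored sequence is in reference orientation. The tail length is the
#' longest scanned prefix whose base fraction is at least `min_frac`
#' (scanning is capped at `scan_window` clipped nt); a tail is called
#' present when that length reaches `min_len`.
#'
#' @param records An [aln_records()] table (mapped rows are processed;
#'   unmapped rows return an absent call).
#' @param min_len Minimum tail length to call presence (default 10).
#' @param min_frac Minimum A (or T) fraction in the prefix (default 0.8).
#' @param scan_window Maximum clipped nt scanned (default 60).
#' @return data.frame: qname, polya (flag), tail_length, clip_side,
#'   clip_fraction (base fraction at the called length; NA when no clip).
#' @export
call_polya_tail <- function(records, min_len = 10L, min_frac = 0.8,
                            scan_window = 60L) {
  stopifnot(min_len > 0, min_frac > 0, scan_window > 0)
  n <- nrow(records)
  polya <- logical(n); tl <- integer(n)
  side <- character(n); frac <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!records$mapped[i]) { side[i] <- NA_character_; next }
    if (records$strand[i] == "+") {
      clip <- records$clip_right[i]; base <- "A"; side[i] <- "right"
    } else {
      # reverse so scanning starts at the tail-proximal end of the clip
      clip <- reverse_chars(records$clip_left[i]); base <- "T"
      side[i] <- "left"
    }
    res <- scan_tail_prefix(clip, base, min_frac, scan_window)
    tl[i] <- res$len
    frac[i] <- res$frac
    polya[i] <- res$len >= min_len
  }
  data.frame(qname = records$qname, polya = polya, tail_length = tl,
             clip_side = side, clip_fraction = frac)
}

reverse_chars <- function(x) {
  if (is.na(x) || nchar(x) < 2) return(x)
  paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
}

# Longest prefix (up to `cap` nt) of `clip` whose `base` fraction is
# >= min_frac; returns length 0 with NA fraction when no prefix qualifies.
scan_tail_prefix <- function(clip, base, min_frac, cap) {
  if (is.na(clip) || nchar(clip) == 0) return(list(len = 0L, frac = NA_real_))
  chars <- strsplit(substr(clip, 1L, cap), "", fixed = TRUE)[[1]]
  hits <- cumsum(chars == base)
  fr <- hits / seq_along(chars)
  ok <- which(fr >= min_frac)
  if (length(ok) == 0) return(list(len = 0L, frac = NA_real_))
  len <- max(ok)
  list(len = len, frac = fr[len])
}

#' CAGE support for read 5' ends
#'
#' The read 5' end (alignment start for `+`, alignment end for `-`) is
#' supported when it lies inside a same-strand CAGE cluster or within
#' `window` bp of its nearest edge. The signed distance to the nearest
#' same-strand cluster is reported for auditing (0 inside; positive when the
#' 5' end is to the right of the cluster in genomic coordinates).
#'
#' @param records An [aln_records()] table.
#' @param cage GRanges of CAGE clusters with +/- strands.
#' @param window Distance tolerance in bp (>= 0, default 50).
#' @return data.frame: qname, cage (flag), cage_distance (NA when no
#'   same-strand cluster exists on the chromosome).
#' @export
call_cage_support <- function(records, cage, window = 50L) {
  stopifnot(window >= 0)
  n <- nrow(records)
  supported <- logical(n)
  dist <- rep(NA_real_, n)
  m <- which(records$mapped)
  if (length(m) && length(cage)) {
    p5 <- read_five_prime(records[m, , drop = FALSE])
    pts <- GenomicRanges::GRanges(records$chrom[m],
                                  IRanges::IRanges(p5, p5),
                                  strand = records$strand[m])
    hit <- GenomicRanges::distanceToNearest(pts, cage, ignore.strand = FALSE)
    qh <- S4Vectors::queryHits(hit)
    # signed arithmetic distance to the nearest cluster edge: 0 inside,
    # negative upstream (left) of the cluster, positive downstream
    cl <- cage[S4Vectors::subjectHits(hit)]
    d <- ifelse(p5[qh] < BiocGenerics::start(cl),
                p5[qh] - BiocGenerics::start(cl),
                ifelse(p5[qh] > BiocGenerics::end(cl),
                       p5[qh] - BiocGenerics::end(cl), 0))
    dist[m[qh]] <- d
    supported[m[qh]] <- abs(d) <= window
  }
  data.frame(qname = records$qname, cage = supported, cage_distance = dist)
}

#' Classify reads into the four completeness categories
#'
#' Combines [call_polya_tail()] and [call_cage_support()] per mapped primary
#' read and assigns exactly one category: both flags -> `five_three`, tail
#' only -> `three_only`, CAGE only -> `five_only`, neither ->
#' `unsupported`. The spliced flag is TRUE when the CIGAR contains a
#' reference skip of at least `min_intron` bp. Reads on `exclude_chroms`
#' (e.g. spike-in contigs, where no CAGE truth exists) and unmapped reads
#' are dropped.
#'
#' @param records An [aln_records()] table.
#' @param cage GRanges of CAGE clusters.
#' @param cage_window,polya_min_len,polya_min_frac,polya_scan,min_intron
#'   Thresholds (see the individual callers).
#' @param exclude_chroms Chromosome names to drop (default none).
#' @return data.frame of class `completeness`: qname, chrom, strand,
#'   read_length, spliced, polya, tail_length, cage, cage_distance,
#'   category (factor with the four levels).
#' @export
classify_completeness <- function(records, cage, cage_window = 50L,
                                  polya_min_len = 10L, polya_min_frac = 0.8,
                                  polya_scan = 60L, min_intron = 40L,
                                  exclude_chroms = character()) {
  keep <- records$mapped & !(records$chrom %in% exclude_chroms)
  r <- records[keep, , drop = FALSE]
  if (nrow(r) == 0) {
    out <- data.frame(qname = character(), chrom = character(),
                      strand = character(), read_length = integer(),
                      spliced = logical(), polya = logical(),
                      tail_length = integer(), cage = logical(),
                      cage_distance = numeric(),
                      category = factor(character(),
                                        levels = CATEGORY_LEVELS))
    class(out) <- c("completeness", "data.frame")
    return(out)
  }
  pa <- call_polya_tail(r, polya_min_len, polya_min_frac, polya_scan)
  cg <- call_cage_support(r, cage, cage_window)
  category <- factor(ifelse(cg$cage & pa$polya, "five_three",
                     ifelse(pa$polya, "three_only",
                     ifelse(cg$cage, "five_only", "unsupported"))),
                     levels = CATEGORY_LEVELS)
  out <- data.frame(
    qname = r$qname, chrom = r$chrom, strand = r$strand,
    read_length = nchar(r$seq), spliced = is_spliced(r, min_intron),
    polya = pa$polya, tail_length = pa$tail_length,
    cage = cg$cage, cage_distance = cg$cage_distance,
    category = category
  )
  class(out) <- c("completeness", "data.frame")
  out
}

#' Stratified completeness summary
#'
#' Per-category fractions for all, spliced and unspliced reads, plus the
#' spliced-read percentage.
#'
#' @param comp A [classify_completeness()] result.
#' @return List: `n`, `spliced_percent`, and `fractions` (data.frame with
#'   stratum, category, n, fraction).
#' @export
completeness_summary <- function(comp) {
  strata <- list(all = rep(TRUE, nrow(comp)), spliced = comp$spliced,
                 unspliced = !comp$spliced)
  frac <- do.call(rbind, lapply(names(strata), function(s) {
    sub <- comp[strata[[s]], , drop = FALSE]
    tab <- table(sub$category)
    data.frame(stratum = s, category = names(tab), n = as.integer(tab),
               fraction = if (nrow(sub)) as.numeric(tab) / nrow(sub)
                          else NA_real_)
  }))
  list(n = nrow(comp),
       spliced_percent = if (nrow(comp)) 100 * mean(comp$spliced)
                         else NA_real_,
       fractions = frac)
}

#' Validate poly(A) calls by polyadenylation-motif proximity
#'
#' For each read with a positive tail call, scans the genomic interval
#' `search_interval` nt upstream of the inferred cleavage site (the aligned
#' 3' end) for any of the motifs, on the read's strand (minus-strand reads
#' are scanned via the reverse complement on the plus strand). The flag is
#' TRUE when a motif 3' edge falls inside the interval.
#'
#' @param records An [aln_records()] table (typically restricted to reads
#'   with `polya == TRUE`).
#' @param genome Named DNAStringSet.
#' @param motifs Character vector of motifs (default canonical `AATAAA`).
#' @param search_interval `c(min_up, max_up)` nt upstream of cleavage
#'   (default `c(10, 40)`).
#' @return Logical vector, one per record (NA for unmapped rows).
#' @export
validate_polya_motif <- function(records, genome, motifs = "AATAAA",
                                 search_interval = c(10L, 40L)) {
  stopifnot(length(search_interval) == 2,
            search_interval[1] <= search_interval[2])
  min_up <- search_interval[1]; max_up <- search_interval[2]
  chars <- as.character(genome)
  out <- rep(NA, nrow(records))
  for (i in seq_len(nrow(records))) {
    if (!records$mapped[i]) next
    s <- chars[[records$chrom[i]]]
    found <- FALSE
    for (motif in motifs) {
      ml <- nchar(motif)
      if (records$strand[i] == "+") {
        cleave <- records$end[i]
        lo <- cleave - max_up - ml + 1L; hi <- cleave - min_up
        if (hi < 1) next
        if (lo < 1) lo <- 1L # window clipped at the chromosome edge
        win <- substr(s, lo, hi)
        hits <- find_motif(win, motif)
        # motif 3' edge at win offset e maps to distance cleave - (lo+e-1)
        found <- any((cleave - (lo + hits + ml - 2L)) >= min_up &
                     (cleave - (lo + hits + ml - 2L)) <= max_up)
      } else {
        cleave <- records$start[i]
        rc <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(motif)))
        lo <- cleave + min_up; hi <- cleave + max_up + ml - 1L
        if (lo > nchar(s)) next
        if (hi > nchar(s)) hi <- nchar(s)
        win <- substr(s, lo, hi)
        hits <- find_motif(win, rc)
        # on -, the motif 3' edge (transcript sense) is its leftmost base
        found <- any((lo + hits - 1L - cleave) >= min_up &
                     (lo + hits - 1L - cleave) <= max_up)
      }
      if (found) break
    }
    out[i] <- found
  }
  out
}

# All start offsets (1-based) of `motif` in `s`, allowing overlaps.
find_motif <- function(s, motif) {
  hits <- integer()
  from <- 1L
  repeat {
    p <- regexpr(motif, substr(s, from, nchar(s)), fixed = TRUE)
    if (p == -1) break
    hits <- c(hits, from + p - 1L)
    from <- from + p
  }
  hits
}

#' Completeness category fractions by read-length bin
#'
#' @param comp A [classify_completeness()] result.
#' @param bin_edges Strictly increasing numeric vector of bin edges; reads
#'   outside `[min, max)` are dropped.
#' @return data.frame: bin_start, bin_end, n, and one fraction column per
#'   category (NA for empty bins). Fractions in occupied bins sum to 1.
#' @export
support_by_length <- function(comp, bin_edges) {
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  nb <- length(bin_edges) - 1L
  bin <- cut(comp$read_length, bin_edges, right = FALSE, labels = FALSE)
  out <- data.frame(bin_start = bin_edges[-length(bin_edges)],
                    bin_end = bin_edges[-1],
                    n = as.integer(tabulate(bin, nbins = nb)))
  for (cat in CATEGORY_LEVELS) out[[cat]] <- NA_real_
  for (b in seq_len(nb)) {
    sub <- comp[!is.na(bin) & bin == b, , drop = FALSE]
    if (nrow(sub) == 0) next
    tab <- table(sub$category)
    out[b, CATEGORY_LEVELS] <- as.numeric(tab[CATEGORY_LEVELS]) / nrow(sub)
  }
  out
}
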