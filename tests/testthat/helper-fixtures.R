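# Shared fixtures (memoised: the heavy simulations run once per session)
# and the independent oracles used against the implementation.

.fix <- new.env(parent = emptyenv())

fix_bundle <- function() {
  if (is.null(.fix$bundle))
    .fix$bundle <- build_reference(sim_config(), seed = 101L)
  .fix$bundle
}

# default CapTrap-like library: errors, truncation, contamination on
fix_lib_default <- function() {
  if (is.null(.fix$lib_default))
    .fix$lib_default <- simulate_library(fix_bundle(), protocol_profile(),
                                         10000L, seed = 202L)
  .fix$lib_default
}

# noise-free library: no sequencing errors, no TSS jitter, nothing unmapped;
# windows left at defaults so classifier and truth share the same geometry
clean_profile <- function(...) {
  protocol_profile(mismatch_rate = 0, insertion_rate = 0, deletion_rate = 0,
                   tss_jitter_sd = 0, unmapped_fraction = 0, ...)
}

fix_lib_clean <- function() {
  if (is.null(.fix$lib_clean))
    .fix$lib_clean <- simulate_library(fix_bundle(), clean_profile(),
                                       10000L, seed = 303L)
  .fix$lib_clean
}

spike_chroms <- function(bundle = fix_bundle()) unique(bundle$design$chrom)

# Expected completeness category from simulator truth under the default
# calling thresholds (tail >= min_len gives 3' support; a 5'-complete read
# whose TSS carries a CAGE cluster gives 5' support).
truth_category <- function(truth, min_len = 10L) {
  five <- truth$five_complete & truth$cage_at_tss
  three <- truth$tail_length >= min_len
  ifelse(five & three, "five_three",
         ifelse(three, "three_only",
                ifelse(five, "five_only", "unsupported")))
}

# --- independent oracles ----------------------------------------------------

# poly(A) prefix-scan oracle: enumerate every prefix of the clip and apply
# the length/fraction rule literally.
oracle_polya <- function(clip, base, min_len, min_frac, cap) {
  if (is.na(clip) || nchar(clip) == 0)
    return(list(present = FALSE, len = 0L))
  chars <- strsplit(clip, "", fixed = TRUE)[[1]]
  chars <- chars[seq_len(min(length(chars), cap))]
  best <- 0L
  for (L in seq_along(chars)) {
    if (mean(chars[seq_len(L)] == base) >= min_frac) best <- L
  }
  list(present = best >= min_len, len = best)
}

# closed-form least-squares oracle for the log-log fit
oracle_ols <- function(x, y) {
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ic <- mean(y) - sl * mean(x)
  c(slope = sl, intercept = ic)
}

# base-walk CIGAR oracle: advance one operation at a time, recording which
# reference bases are consumed and where skips of >= min_intron fall.
oracle_read_chain <- function(cigar, pos, min_intron) {
  ops <- cigar_ops(cigar)
  covered <- integer() # ref positions consumed by M/D/=/X or short N
  at <- pos
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "D", "=", "X") ||
        (op == "N" && len < min_intron)) {
      covered <- c(covered, at:(at + len - 1L))
      at <- at + len
    } else if (op == "N") {
      at <- at + len
    }
  }
  covered <- sort(unique(covered))
  brk <- which(diff(covered) > 1)
  starts <- covered[c(1L, brk + 1L)]
  ends <- covered[c(brk, length(covered))]
  data.frame(start = starts, end = ends)
}

# per-base genome labelling oracle for the coverage partition
oracle_partition <- function(records, bundle) {
  ann <- bundle$annotation
  main_chroms <- setdiff(names(bundle$genome), spike_chroms(bundle))
  labels <- lapply(setNames(main_chroms, main_chroms), function(chr) {
    n <- Biostrings::width(bundle$genome)[names(bundle$genome) == chr]
    lab <- rep(3L, n) # intergenic
    gn <- ann$genes[as.character(GenomicRanges::seqnames(ann$genes)) == chr]
    for (k in seq_along(gn))
      lab[BiocGenerics::start(gn)[k]:BiocGenerics::end(gn)[k]] <- 2L
    ex <- ann$exons[as.character(GenomicRanges::seqnames(ann$exons)) == chr]
    for (k in seq_along(ex))
      lab[BiocGenerics::start(ex)[k]:BiocGenerics::end(ex)[k]] <- 1L
    lab
  })
  tallies <- c(0, 0, 0)
  m <- which(records$mapped & records$chrom %in% main_chroms)
  for (i in m) {
    r <- cigar_ops(records$cigar[i])
    at <- records$start[i]
    for (j in seq_len(nrow(r))) {
      if (r$op[j] %in% c("M", "=", "X")) {
        seg <- labels[[records$chrom[i]]][at:(at + r$len[j] - 1L)]
        tallies <- tallies + tabulate(seg, 3L)
      }
      if (r$op[j] %in% c("M", "D", "N", "=", "X")) at <- at + r$len[j]
    }
  }
  setNames(tallies / sum(tallies), c("exonic", "intronic", "intergenic"))
}

# small hand-built record tables for unit examples
make_record <- function(qname = "r1", chrom = "chr1", start = 101L,
                        cigar = "100M", strand = "+", nm = 0L,
                        seq = NULL, mapped = TRUE) {
  if (is.null(seq))
    seq <- strrep("A", if (mapped) cigar_query_len(cigar) else 100L)
  aln_records(qname, mapped, if (mapped) chrom else NA,
              if (mapped) start else NA,
              if (mapped) start + cigar_ref_len(cigar) - 1L else NA,
              if (mapped) strand else NA, if (mapped) cigar else NA,
              seq, if (mapped) nm else NA)
}

bind_records <- function(...) {
  dfs <- list(...)
  out <- do.call(rbind, lapply(dfs, as.data.frame))
  class(out) <- c("aln_records", "data.frame")
  out
}

random_clip <- function(len, a_bias) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c(a_bias, rep((1 - a_bias) / 3, 3))), collapse = "")
}

category_levels <- function() c("unsupported", "three_only", "five_only",
                                "five_three")

reverse_string <- function(x) {
  if (nchar(x) < 2) return(x)
  paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
}

subset_main_annotation <- function(bundle = fix_bundle()) {
  ex <- bundle$annotation$exons
  keep <- !(as.character(GenomicRanges::seqnames(ex)) %in%
              spike_chroms(bundle))
  gene_annotation(ex[keep])
}

# CIGAR spelling a perfect spliced alignment over an exon table
mk_spliced_cigar <- function(ex) {
  w <- ex$end - ex$start + 1L
  parts <- character()
  for (i in seq_len(nrow(ex))) {
    parts <- c(parts, paste0(w[i], "M"))
    if (i < nrow(ex))
      parts <- c(parts, paste0(ex$start[i + 1] - ex$end[i] - 1L, "N"))
  }
  paste(parts, collapse = "")
}
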