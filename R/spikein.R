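# Spike-in sensitivity and quantitation: per-control read counts, detection
# rates, log-log concentration-response regression, detection limit, molar
# to molecule-count and copies-per-cell conversions, and intron-chain based
# reconstruction classes for multi-isoform (SIRV-style) controls.

AVOGADRO <- 6.02214e23

#' Count primary mapped reads per spike-in control
#'
#' Single-isoform (ERCC-style) controls are counted per contig. For
#' multi-isoform (SIRV-style) controls each read is attributed to the
#' isoform with the best [compare_to_reference()] class (`full_match` beats
#' `partial_overlap`; ties broken by exonic overlap, then id); reads
#' matching no isoform are unattributed. With `attribute_sirv = FALSE`,
#' SIRV counts are per gene/contig instead.
#'
#' @param records An [aln_records()] table.
#' @param design Spike-in design table (see [read_design()]).
#' @param ann A [gene_annotation()] carrying the SIRV transcript models
#'   (required when `attribute_sirv = TRUE` and SIRV rows exist).
#' @param attribute_sirv Attribute SIRV reads to isoforms (default TRUE).
#' @param end_window,min_intron Passed to the isoform comparison.
#' @return data.frame: id, class, count.
#' @export
count_spikein_reads <- function(records, design, ann = NULL,
                                attribute_sirv = TRUE, end_window = 50L,
                                min_intron = 40L) {
  if (is.null(design) || nrow(design) == 0) stop("empty spike-in design")
  known <- unique(design$chrom)
  missing_contigs <- setdiff(known, unique(records$chrom[records$mapped]))
  if (length(missing_contigs) == length(known) && nrow(records) > 0)
    warning("no reads on any spike-in contig")
  counts <- setNames(integer(nrow(design)), design$id)
  m <- records[records$mapped & records$chrom %in% known, , drop = FALSE]
  ercc <- design[design$class == "ERCC", , drop = FALSE]
  if (nrow(ercc)) {
    tab <- table(m$chrom[m$chrom %in% ercc$chrom])
    counts[names(tab)] <- as.integer(tab)
  }
  sirv <- design[design$class == "SIRV", , drop = FALSE]
  if (nrow(sirv)) {
    sm <- m[m$chrom %in% sirv$chrom, , drop = FALSE]
    if (!attribute_sirv || is.null(ann)) {
      if (attribute_sirv && is.null(ann))
        stop("isoform attribution needs the annotation with SIRV models")
      tab <- table(sm$chrom)
      for (g in unique(sirv$chrom)) {
        ids <- sirv$id[sirv$chrom == g]
        counts[ids[1]] <- if (g %in% names(tab)) as.integer(tab[[g]]) else 0L
      }
    } else if (nrow(sm)) {
      attr_tab <- attribute_sirv_reads(sm, sirv, ann, end_window, min_intron)
      tab <- table(attr_tab$id[!is.na(attr_tab$id)])
      counts[names(tab)] <- as.integer(tab)
    }
  }
  data.frame(id = design$id, class = design$class,
             count = unname(counts[design$id]))
}

# Best-matching isoform per read on SIRV contigs.
attribute_sirv_reads <- function(sm, sirv, ann, end_window, min_intron) {
  models <- lapply(setNames(sirv$id, sirv$id), function(tid)
    transcript_exon_table(ann, tid))
  out_id <- rep(NA_character_, nrow(sm))
  out_class <- rep("none", nrow(sm))
  for (i in seq_len(nrow(sm))) {
    chain <- read_to_transcript_model(sm$cigar[i], sm$start[i], min_intron)
    cand <- sirv[sirv$chrom == sm$chrom[i], , drop = FALSE]
    best_rank <- 3L; best_ov <- -1; best_id <- NA_character_
    for (j in seq_len(nrow(cand))) {
      cls <- compare_to_reference(chain, models[[cand$id[j]]], end_window)
      rank <- match(cls, c("full_match", "partial_overlap", "none"))
      ovl <- exonic_overlap_bp(chain, models[[cand$id[j]]])
      if (rank < best_rank || (rank == best_rank && ovl > best_ov)) {
        best_rank <- rank; best_ov <- ovl; best_id <- cand$id[j]
      }
    }
    if (best_rank < 3L) {
      out_id[i] <- best_id
      out_class[i] <- c("full_match", "partial_overlap")[best_rank]
    }
  }
  data.frame(qname = sm$qname, id = out_id, match_class = out_class)
}

exonic_overlap_bp <- function(a, b) {
  ra <- IRanges::IRanges(a$start, a$end)
  rb <- IRanges::IRanges(b$start, b$end)
  sum(IRanges::width(IRanges::intersect(ra, rb)))
}

#' Fraction of controls detected per class
#'
#' @param counts A [count_spikein_reads()] result.
#' @param min_reads Detection threshold (>= 1, default 1).
#' @return Named numeric vector of detected fractions per class.
#' @export
detection_rate <- function(counts, min_reads = 1L) {
  if (nrow(counts) == 0) stop("empty spike-in counts")
  if (min_reads < 1) stop("min_reads must be >= 1")
  vapply(split(counts$count, counts$class),
         function(x) mean(x >= min_reads), numeric(1))
}

#' Log-log concentration-response regression
#'
#' Ordinary least squares of log10(read count) on log10(concentration in
#' attomol/ul) over controls with count > 0 (zero counts are excluded:
#' log of zero is undefined; a pseudo-count mode is available).
#'
#' @param counts A [count_spikein_reads()] result.
#' @param design The matching design table.
#' @param class Spike-in class to fit (default `"ERCC"`).
#' @param pseudo_count Added to all counts before the log when > 0
#'   (default 0 = excluded zeros).
#' @return List: `slope`, `intercept`, `correlation`, `n_points`, `fit`
#'   (the `lm` object).
#' @export
fit_concentration_response <- function(counts, design, class = "ERCC",
                                       pseudo_count = 0) {
  d <- merge(counts[counts$class == class, , drop = FALSE],
             design[, c("id", "concentration_attomol_ul")], by = "id")
  if (pseudo_count > 0) d$count <- d$count + pseudo_count
  d <- d[d$count > 0, , drop = FALSE]
  if (nrow(d) < 3)
    stop("degenerate fit: fewer than 3 controls with positive counts")
  x <- log10(d$concentration_attomol_ul)
  y <- log10(d$count)
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       correlation = cor(x, y), n_points = nrow(d), fit = fit)
}

#' Detection limit from the concentration ladder
#'
#' The smallest design concentration `c*` such that every control with
#' concentration >= `c*` has at least `min_reads` reads; `NA` when nothing
#' qualifies.
#'
#' @param counts A [count_spikein_reads()] result.
#' @param design The matching design table.
#' @param class Spike-in class (default `"ERCC"`).
#' @param min_reads Detection threshold (default 1).
#' @return Concentration in attomol/ul, or NA.
#' @export
estimate_detection_limit <- function(counts, design, class = "ERCC",
                                     min_reads = 1L) {
  d <- merge(counts[counts$class == class, , drop = FALSE],
             design[, c("id", "concentration_attomol_ul")], by = "id")
  if (nrow(d) == 0) stop("no controls of class ", class)
  concs <- sort(unique(d$concentration_attomol_ul), decreasing = TRUE)
  limit <- NA_real_
  for (conc in concs) { # walk whole rungs down the ladder
    rung <- d$count[d$concentration_attomol_ul == conc]
    if (!all(rung >= min_reads)) break
    limit <- conc
  }
  limit
}

#' Convert a molar concentration to a molecule count
#'
#' molecules = concentration x (1/dilution) x volume x 1e-18 x Avogadro,
#' with the concentration in attomol/ul and the volume in ul.
#'
#' @param concentration_attomol_ul Concentration (attomol/ul).
#' @param dilution Dilution factor (default 100, i.e. a 1:100 dilution).
#' @param volume_ul Volume added (ul, default 4).
#' @return Number of molecules.
#' @export
amount_to_molecules <- function(concentration_attomol_ul, dilution = 100,
                                volume_ul = 4) {
  if (any(c(concentration_attomol_ul, dilution, volume_ul) < 0))
    stop("amount_to_molecules: negative input")
  concentration_attomol_ul / dilution * volume_ul * 1e-18 * AVOGADRO
}

#' Convert a molecule count to copies per cell
#'
#' copies = molecules / (total_rna_ug x 1e6 / per_cell_pg), i.e. molecules
#' divided by the number of cell equivalents in the RNA input.
#'
#' @param molecules Number of molecules.
#' @param total_rna_ug Total RNA mass the spike-ins were added to (ug,
#'   default 4).
#' @param per_cell_pg Assumed RNA content of a single cell (pg, default 5).
#' @return Copies per cell.
#' @export
molecules_per_cell <- function(molecules, total_rna_ug = 4, per_cell_pg = 5) {
  if (total_rna_ug <= 0 || per_cell_pg <= 0)
    stop("molecules_per_cell: masses must be positive")
  molecules / (total_rna_ug * 1e6 / per_cell_pg)
}

#' Per-read transcript model from a CIGAR
#'
#' Merges M/D (and short reference skips below `min_intron`, treated as
#' deletions) into exons; reference skips of at least `min_intron` bp
#' become introns.
#'
#' @param cigar CIGAR string.
#' @param pos 1-based alignment start.
#' @param min_intron Minimum reference skip kept as an intron (default 40).
#' @return data.frame of exons (start, end), 1-based closed, ascending.
#' @export
read_to_transcript_model <- function(cigar, pos, min_intron = 40L) {
  ops <- cigar_ops(cigar)
  ref_at <- pos
  ex_start <- pos; starts <- integer(); ends <- integer()
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "D", "=", "X")) {
      ref_at <- ref_at + len
    } else if (op == "N") {
      if (len >= min_intron) {
        if (ref_at > ex_start) { # skip empty exons from adjacent skips
          starts <- c(starts, ex_start); ends <- c(ends, ref_at - 1L)
        }
        ex_start <- ref_at + len
      }
      ref_at <- ref_at + len
    }
  }
  if (ref_at > ex_start) {
    starts <- c(starts, ex_start); ends <- c(ends, ref_at - 1L)
  }
  data.frame(start = starts, end = ends)
}

#' Compare a read chain to a reference transcript model
#'
#' `full_match` requires an identical intron chain and both termini within
#' `end_window` bp of the reference termini (for single-exon references:
#' both chains unspliced, overlapping, ends within the window);
#' `partial_overlap` requires at least 1 bp of exonic overlap; otherwise
#' `none`.
#'
#' @param query Exon chain data.frame (start, end) from
#'   [read_to_transcript_model()].
#' @param reference Exon chain data.frame of the reference transcript.
#' @param end_window Terminus tolerance in bp (default 50).
#' @return One of `"full_match"`, `"partial_overlap"`, `"none"`.
#' @export
compare_to_reference <- function(query, reference, end_window = 50L) {
  ovl <- exonic_overlap_bp(query, reference)
  qi <- intron_chain(query); ri <- intron_chain(reference)
  chains_equal <- nrow(qi) == nrow(ri) &&
    (nrow(qi) == 0 || (all(qi$start == ri$start) && all(qi$end == ri$end)))
  ends_ok <- abs(query$start[1] - reference$start[1]) <= end_window &&
    abs(query$end[nrow(query)] - reference$end[nrow(reference)]) <= end_window
  if (chains_equal && ends_ok && ovl > 0) return("full_match")
  if (ovl > 0) return("partial_overlap")
  "none"
}

#' Reconstruction level per multi-isoform control
#'
#' Each SIRV transcript is `end_to_end` when at least one read on its
#' contig gives a `full_match`, else `partial` when at least one read gives
#' `partial_overlap`, else `absent`. A length-stratified summary of levels
#' is included.
#'
#' @param records An [aln_records()] table.
#' @param design Design table (SIRV rows used).
#' @param ann A [gene_annotation()] with the SIRV transcript models.
#' @param end_window,min_intron Comparison thresholds.
#' @param length_bins Bin edges (nt) for the length summary.
#' @return List of class `sirv_detection`: `levels` (data.frame id, length,
#'   level, supporting_reads), `level_counts`, `by_length` (data.frame).
#' @export
classify_sirv_levels <- function(records, design, ann, end_window = 50L,
                                 min_intron = 40L,
                                 length_bins = c(0, 500, 1000, 1500, 2500)) {
  sirv <- design[design$class == "SIRV", , drop = FALSE]
  if (nrow(sirv) == 0) stop("design contains no SIRV rows")
  sm <- records[records$mapped & records$chrom %in% sirv$chrom, ,
                drop = FALSE]
  models <- lapply(setNames(sirv$id, sirv$id), function(tid)
    transcript_exon_table(ann, tid))
  chains <- lapply(seq_len(nrow(sm)), function(i)
    read_to_transcript_model(sm$cigar[i], sm$start[i], min_intron))
  level <- character(nrow(sirv)); support <- integer(nrow(sirv))
  for (j in seq_len(nrow(sirv))) {
    onctg <- which(sm$chrom == sirv$chrom[j])
    cls <- vapply(onctg, function(i)
      compare_to_reference(chains[[i]], models[[sirv$id[j]]], end_window),
      character(1))
    support[j] <- sum(cls != "none")
    level[j] <- if (any(cls == "full_match")) "end_to_end"
                else if (any(cls == "partial_overlap")) "partial"
                else "absent"
  }
  levels_df <- data.frame(id = sirv$id, length = sirv$length,
                          level = factor(level, levels = c("end_to_end",
                                                           "partial",
                                                           "absent")),
                          supporting_reads = support)
  bin <- cut(levels_df$length, length_bins, right = FALSE)
  by_len <- as.data.frame(table(length_bin = bin, level = levels_df$level))
  out <- list(levels = levels_df,
              level_counts = table(levels_df$level),
              by_length = by_len)
  class(out) <- "sirv_detection"
  out
}
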