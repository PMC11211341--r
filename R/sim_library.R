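# Protocol-biased long-read simulator. Emits primary alignments directly
# (no aligner involved): read geometry is derived from transcript exon
# chains, 5' truncation and poly(A) tails follow the protocol profile, and
# sequencing errors are injected as mismatches and 1-bp indels with the
# edit-distance tag kept consistent. Every read gets a ground-truth row.

#' Simulate a long-read library over a reference bundle
#'
#' Draws reads from the bundle's transcripts (log-normal gene expression),
#' spike-in controls (read counts proportional to concentration times the
#' capped-vs-uncapped capture ratio) and contamination classes (rRNA,
#' intronic, intergenic), applies the protocol's 5' completeness/truncation
#' model, appends poly(A) tails as soft-clipped A-runs on the 3' side in
#' reference orientation (trailing A-clip for `+` alignments, leading T-clip
#' for `-`), and injects sequencing errors. A configured fraction of reads
#' is emitted unmapped.
#'
#' @param bundle A [build_reference()] bundle.
#' @param profile A [protocol_profile()].
#' @param n_reads Number of reads (>= 0).
#' @param seed Integer seed; the same seed reproduces the library exactly.
#' @return A list with `records` (an [aln_records()] table) and `truth`
#'   (data.frame: qname, source_id, source_class, biotype, five_complete,
#'   cage_at_tss, tail_length, mismatches, insertions, deletions, spliced,
#'   mapped).
#' @export
simulate_library <- function(bundle, profile = protocol_profile(),
                             n_reads, seed = 42L) {
  stopifnot(is(bundle, "ref_bundle"))
  validate_profile(profile)
  if (n_reads < 0) stop("n_reads must be >= 0")
  if (n_reads == 0) {
    rec <- aln_records(character(), logical(), character(), integer(),
                       integer(), character(), character(), character(),
                       integer())
    return(list(records = rec, truth = empty_truth()))
  }
  with_seed(seed, simulate_library_impl(bundle, profile, as.integer(n_reads)))
}

empty_truth <- function() {
  data.frame(qname = character(), source_id = character(),
             source_class = character(), biotype = character(),
             five_complete = logical(), cage_at_tss = logical(),
             tail_length = integer(), mismatches = integer(),
             insertions = integer(), deletions = integer(),
             spliced = logical(), mapped = logical())
}

simulate_library_impl <- function(bundle, prof, n_reads) {
  ann <- bundle$annotation
  tx <- ann$transcripts
  design <- bundle$design
  genome_chars <- as.character(bundle$genome)

  # source class mixture
  spike_f <- prof$spikein_base_fraction *
    if (isTRUE(prof$spikein_capped)) prof$spikein_capture_ratio else 1
  if (is.null(design) || nrow(design) == 0) spike_f <- 0
  probs <- c(spike = spike_f, rRNA = prof$rRNA_fraction,
             intronic = prof$intronic_fraction,
             intergenic = prof$intergenic_fraction)
  probs <- c(probs, tx = max(0, 1 - sum(probs)))
  src_class <- sample(names(probs), n_reads, replace = TRUE, prob = probs)

  # expression weights for main-genome, non-rRNA transcripts
  main_tx <- tx[tx$spike_class == "none" & tx$biotype != "rRNA", ,
                drop = FALSE]
  gene_w <- rlnorm(length(unique(main_tx$gene_id)), 0, 1.5)
  names(gene_w) <- unique(main_tx$gene_id)
  tx_w <- gene_w[main_tx$gene_id] / table(main_tx$gene_id)[main_tx$gene_id]
  rrna_tx <- tx[tx$spike_class == "none" & tx$biotype == "rRNA", ,
                drop = FALSE]
  intronic_pool <- main_tx[main_tx$n_exons > 1, , drop = FALSE]
  gaps <- intergenic_gaps(bundle)

  exon_cache <- new.env(parent = emptyenv())
  get_exons <- function(tid) {
    if (is.null(exon_cache[[tid]]))
      exon_cache[[tid]] <- transcript_exon_table(ann, tid)
    exon_cache[[tid]]
  }

  unmapped <- runif(n_reads) < prof$unmapped_fraction
  rows <- vector("list", n_reads)
  trows <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    qname <- sprintf("read%06d", i)
    g <- switch(src_class[i],
      tx = draw_tx_read(main_tx, tx_w, get_exons, prof),
      spike = draw_spike_read(tx, design, get_exons, prof),
      rRNA = draw_rrna_read(rrna_tx, get_exons),
      intronic = draw_intronic_read(intronic_pool, get_exons),
      intergenic = draw_intergenic_read(gaps)
    )
    tail_len <- g$tail_length
    if (unmapped[i]) {
      n <- sample(200:800, 1)
      rows[[i]] <- list(
        qname = qname, mapped = FALSE, chrom = NA_character_,
        start = NA_integer_, end = NA_integer_, strand = NA_character_,
        cigar = NA_character_, seq = random_dna(n), nm = NA_integer_
      )
      trows[[i]] <- list(
        qname = qname, source_id = g$source_id,
        source_class = g$source_class, biotype = g$biotype,
        five_complete = g$five_complete, cage_at_tss = g$cage_at_tss,
        tail_length = as.integer(tail_len), mismatches = NA_integer_,
        insertions = NA_integer_, deletions = NA_integer_,
        spliced = NA, mapped = FALSE
      )
      next
    }
    a <- sum(g$blocks$end - g$blocks$start + 1)
    mm_n <- rbinom(1, a, prof$mismatch_rate)
    del_n <- rbinom(1, a, prof$deletion_rate)
    ins_n <- rbinom(1, a, prof$insertion_rate)
    # keep error positions strictly interior and disjoint
    avail <- max(0L, a - 2L)
    if (mm_n + del_n > avail) {
      mm_n <- min(mm_n, avail)
      del_n <- min(del_n, avail - mm_n)
    }
    ins_n <- min(ins_n, avail)
    aln <- build_read_aln(genome_chars[[g$chrom]], g$blocks, g$strand,
                          mm_n, ins_n, del_n, tail_len)
    rows[[i]] <- list(
      qname = qname, mapped = TRUE, chrom = g$chrom,
      start = as.integer(g$blocks$start[1]),
      end = as.integer(g$blocks$end[length(g$blocks$end)]),
      strand = g$strand, cigar = aln$cigar, seq = aln$seq,
      nm = as.integer(aln$nm)
    )
    trows[[i]] <- list(
      qname = qname, source_id = g$source_id, source_class = g$source_class,
      biotype = g$biotype, five_complete = g$five_complete,
      cage_at_tss = g$cage_at_tss, tail_length = as.integer(tail_len),
      mismatches = as.integer(mm_n), insertions = as.integer(ins_n),
      deletions = as.integer(del_n),
      spliced = length(g$blocks$start) > 1, mapped = TRUE
    )
  }
  fld <- function(lst, name, mode)
    vapply(lst, function(x) as.vector(x[[name]], mode = mode), vector(mode, 1))
  records <- aln_records(
    fld(rows, "qname", "character"), fld(rows, "mapped", "logical"),
    fld(rows, "chrom", "character"), fld(rows, "start", "integer"),
    fld(rows, "end", "integer"), fld(rows, "strand", "character"),
    fld(rows, "cigar", "character"), fld(rows, "seq", "character"),
    fld(rows, "nm", "integer")
  )
  truth <- data.frame(
    qname = fld(trows, "qname", "character"),
    source_id = fld(trows, "source_id", "character"),
    source_class = fld(trows, "source_class", "character"),
    biotype = fld(trows, "biotype", "character"),
    five_complete = fld(trows, "five_complete", "logical"),
    cage_at_tss = fld(trows, "cage_at_tss", "logical"),
    tail_length = fld(trows, "tail_length", "integer"),
    mismatches = fld(trows, "mismatches", "integer"),
    insertions = fld(trows, "insertions", "integer"),
    deletions = fld(trows, "deletions", "integer"),
    spliced = fld(trows, "spliced", "logical"),
    mapped = fld(trows, "mapped", "logical")
  )
  list(records = records, truth = truth)
}

draw_tail <- function(prof) {
  if (is.infinite(prof$polya_disp)) as.integer(round(prof$polya_mean))
  else rnbinom(1, size = prof$polya_disp, mu = prof$polya_mean)
}

# Transcript interval [p, q] (1-based transcript coords, 5'->3') mapped to
# ascending genomic blocks via the exon chain.
tx_to_blocks <- function(exon_tab, strand, p, q) {
  lens <- exon_tab$end - exon_tab$start + 1
  ord <- if (strand == "+") seq_len(nrow(exon_tab)) else rev(seq_len(nrow(exon_tab)))
  offs <- cumsum(c(0, lens[ord]))
  starts <- ends <- integer()
  for (k in seq_along(ord)) {
    lo <- max(p, offs[k] + 1); hi <- min(q, offs[k + 1])
    if (lo > hi) next
    e <- ord[k]
    if (strand == "+") {
      gs <- exon_tab$start[e] + (lo - offs[k] - 1)
      ge <- exon_tab$start[e] + (hi - offs[k] - 1)
    } else {
      ge <- exon_tab$end[e] - (lo - offs[k] - 1)
      gs <- exon_tab$end[e] - (hi - offs[k] - 1)
    }
    starts <- c(starts, gs); ends <- c(ends, ge)
  }
  o <- order(starts)
  list(start = starts[o], end = ends[o])
}

# 5' start position (transcript coords) under the profile's completeness /
# truncation model. `force_intron_at` (transcript position of the start of
# the last exon) restricts truncated starts so the read keeps >= 1 intron;
# NA disables the restriction.
draw_tx_start <- function(prof, L, force_intron_at = NA) {
  complete <- runif(1) < prof$p_cap5
  if (complete) {
    p <- 1 + max(0, round(rnorm(1, 0, prof$tss_jitter_sd)))
    return(list(p = min(p, max(1, L - 99)), complete = TRUE))
  }
  p_min <- prof$min_trunc_offset + 1
  p_max <- if (is.na(force_intron_at)) L - 99 else force_intron_at - 10
  if (p_max < p_min) {
    p <- max(2, p_max)
    if (p < 2) return(list(p = 1, complete = TRUE))
    return(list(p = p, complete = FALSE))
  }
  p <- if (prof$truncation_model == "exp3") {
    max(p_min, min(p_max, L - 99 - round(rexp(1, 1 / prof$trunc_exp_scale))))
  } else {
    sample(p_min:p_max, 1)
  }
  list(p = p, complete = FALSE)
}

draw_tx_read <- function(main_tx, tx_w, get_exons, prof) {
  j <- sample(nrow(main_tx), 1, prob = tx_w)
  t1 <- main_tx[j, ]
  ex <- get_exons(t1$transcript_id)
  L <- sum(ex$end - ex$start + 1)
  lens_txorder <- if (t1$strand == "+") ex$end - ex$start + 1 else
    rev(ex$end - ex$start + 1)
  le_len <- lens_txorder[length(lens_txorder)]
  unspliced <- nrow(ex) > 1 && runif(1) < prof$unspliced_fraction
  if (unspliced) {
    p_min <- L - le_len + 1
    p_max <- max(p_min, L - 99)
    p <- if (p_max > p_min) sample(p_min:p_max, 1) else p_min
    st <- list(p = p, complete = FALSE)
  } else if (nrow(ex) > 1) {
    st <- draw_tx_start(prof, L, force_intron_at = L - le_len + 1)
  } else {
    st <- draw_tx_start(prof, L)
  }
  list(chrom = t1$chrom, strand = t1$strand,
       blocks = tx_to_blocks(ex, t1$strand, st$p, L),
       source_id = t1$transcript_id, source_class = "transcript",
       biotype = t1$biotype, five_complete = st$complete,
       cage_at_tss = isTRUE(t1$cage_at_tss), tail_length = draw_tail(prof))
}

draw_spike_read <- function(tx, design, get_exons, prof) {
  j <- sample(nrow(design), 1, prob = design$concentration_attomol_ul)
  d1 <- design[j, ]
  t1 <- tx[tx$transcript_id == d1$id, ]
  ex <- get_exons(d1$id)
  L <- sum(ex$end - ex$start + 1)
  st <- draw_tx_start(prof, L)
  list(chrom = d1$chrom, strand = d1$strand,
       blocks = tx_to_blocks(ex, d1$strand, st$p, L),
       source_id = d1$id, source_class = d1$class, biotype = "other",
       five_complete = st$complete, cage_at_tss = FALSE,
       tail_length = draw_tail(prof))
}

draw_rrna_read <- function(rrna_tx, get_exons) {
  if (nrow(rrna_tx) == 0)
    stop("profile requests rRNA reads but the bundle has no rRNA genes")
  t1 <- rrna_tx[sample(nrow(rrna_tx), 1), ]
  ex <- get_exons(t1$transcript_id)
  len <- ex$end[1] - ex$start[1] + 1
  rl <- sample(100:min(600, len), 1)
  s <- ex$start[1] + sample(0:(len - rl), 1)
  list(chrom = t1$chrom, strand = sample(c("+", "-"), 1),
       blocks = list(start = s, end = s + rl - 1),
       source_id = t1$gene_id, source_class = "rRNA", biotype = "rRNA",
       five_complete = FALSE, cage_at_tss = FALSE, tail_length = 0L)
}

draw_intronic_read <- function(intronic_pool, get_exons) {
  if (nrow(intronic_pool) == 0)
    stop("profile requests intronic reads but no multi-exon genes exist")
  t1 <- intronic_pool[sample(nrow(intronic_pool), 1), ]
  ex <- get_exons(t1$transcript_id)
  intr <- intron_chain(ex)
  k <- sample(nrow(intr), 1)
  ilen <- intr$end[k] - intr$start[k] + 1
  rl <- sample(100:max(100, min(500, ilen - 2)), 1)
  s <- intr$start[k] + sample(0:max(0, ilen - rl), 1)
  list(chrom = t1$chrom, strand = sample(c("+", "-"), 1),
       blocks = list(start = s, end = s + rl - 1),
       source_id = t1$gene_id, source_class = "intronic",
       biotype = "intronic", five_complete = FALSE, cage_at_tss = FALSE,
       tail_length = 0L)
}

# Gene-free intervals on main chromosomes, with a 100-bp buffer around gene
# spans so contamination reads stay clear of annotation and CAGE windows.
intergenic_gaps <- function(bundle) {
  main_chroms <- setdiff(names(bundle$genome), bundle$design$chrom)
  lens <- setNames(Biostrings::width(bundle$genome), names(bundle$genome))
  gn <- bundle$annotation$genes
  gn <- gn[as.character(GenomicRanges::seqnames(gn)) %in% main_chroms]
  padded <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(gn),
    IRanges::IRanges(pmax(1, BiocGenerics::start(gn) - 100),
                     BiocGenerics::end(gn) + 100)
  )
  out <- list()
  for (chr in main_chroms) {
    chr_gaps <- IRanges::gaps(
      IRanges::reduce(IRanges::ranges(
        padded[as.character(GenomicRanges::seqnames(padded)) == chr])),
      start = 1, end = lens[[chr]]
    )
    chr_gaps <- chr_gaps[IRanges::width(chr_gaps) >= 600]
    if (length(chr_gaps))
      out[[chr]] <- data.frame(chrom = chr,
                               start = BiocGenerics::start(chr_gaps),
                               end = BiocGenerics::end(chr_gaps))
  }
  do.call(rbind, out)
}

draw_intergenic_read <- function(gaps) {
  if (is.null(gaps) || nrow(gaps) == 0)
    stop("no intergenic space available for contamination reads")
  k <- sample(nrow(gaps), 1, prob = gaps$end - gaps$start + 1)
  glen <- gaps$end[k] - gaps$start[k] + 1
  rl <- sample(100:min(500, glen - 100), 1)
  s <- gaps$start[k] + sample(0:(glen - rl), 1)
  list(chrom = gaps$chrom[k], strand = sample(c("+", "-"), 1),
       blocks = list(start = s, end = s + rl - 1),
       source_id = sprintf("%s:%d-%d", gaps$chrom[k], s, s + rl - 1),
       source_class = "intergenic", biotype = "intergenic",
       five_complete = FALSE, cage_at_tss = FALSE, tail_length = 0L)
}

OTHER_BASES <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                    G = c("A", "C", "T"), T = c("A", "C", "G"),
                    N = c("A", "C", "G", "T"))

# Assemble CIGAR, sequence (reference orientation) and NM tag for one read:
# genomic blocks joined by N gaps, `mm_n` mismatches, `ins_n`/`del_n` 1-bp
# indels at interior positions, and the poly(A) tail soft-clipped on the 3'
# reference side (right A-run for +, left T-run for -).
build_read_aln <- function(chrom_seq, blocks, strand, mm_n, ins_n, del_n,
                           tail_len) {
  widths <- blocks$end - blocks$start + 1
  a <- sum(widths)
  nb <- length(blocks$start)
  ref_chars <- unlist(strsplit(vapply(seq_len(nb), function(b)
    substr(chrom_seq, blocks$start[b], blocks$end[b]), character(1)), "",
    fixed = TRUE), use.names = FALSE)

  if (mm_n + ins_n + del_n == 0) {
    cig_lens <- integer(); cig_ops <- character()
    for (b in seq_len(nb)) {
      if (b > 1) {
        cig_lens <- c(cig_lens, blocks$start[b] - blocks$end[b - 1] - 1L)
        cig_ops <- c(cig_ops, "N")
      }
      cig_lens <- c(cig_lens, widths[b]); cig_ops <- c(cig_ops, "M")
    }
    seq <- paste(ref_chars, collapse = "")
    nm <- 0L
  } else {
    interior <- 2:(a - 1)
    md <- sample(interior, mm_n + del_n)
    mm_pos <- if (mm_n > 0) md[seq_len(mm_n)] else integer()
    del_pos <- if (del_n > 0) md[mm_n + seq_len(del_n)] else integer()
    ins_pos <- if (ins_n > 0) sample(interior, ins_n) else integer()

    for (p in mm_pos)
      ref_chars[p] <- sample(OTHER_BASES[[ref_chars[p]]], 1)
    # token stream along aligned reference bases; insertions sit after their
    # anchor base, deletions drop the query base but keep the ref column
    ops <- rep("M", a)
    ops[del_pos] <- "D"
    ins_flag <- logical(a)
    ins_flag[ins_pos] <- TRUE
    ins_char <- rep(NA_character_, a)
    ins_char[ins_pos] <- sample(c("A", "C", "G", "T"), length(ins_pos),
                                replace = TRUE)
    block_of <- rep(seq_len(nb), widths)
    tok_ops_all <- vector("list", nb)
    tok_lens_all <- vector("list", nb)
    seq_parts <- character(nb)
    for (b in seq_len(nb)) {
      idx <- which(block_of == b)
      # interleave each aligned column with its optional insertion token
      interl_op <- as.vector(rbind(ops[idx],
                                   ifelse(ins_flag[idx], "I",
                                          NA_character_)))
      interl_op <- interl_op[!is.na(interl_op)]
      interl_seq <- as.vector(rbind(
        ifelse(ops[idx] == "M", ref_chars[idx], NA_character_),
        ins_char[idx]))
      seq_parts[b] <- paste(interl_seq[!is.na(interl_seq)], collapse = "")
      if (b > 1) {
        tok_ops_all[[b]] <- c("N", interl_op)
        tok_lens_all[[b]] <- c(blocks$start[b] - blocks$end[b - 1] - 1L,
                               rep(1L, length(interl_op)))
      } else {
        tok_ops_all[[b]] <- interl_op
        tok_lens_all[[b]] <- rep(1L, length(interl_op))
      }
    }
    cig_lens <- unlist(tok_lens_all)
    cig_ops <- unlist(tok_ops_all)
    seq <- paste(seq_parts, collapse = "")
    nm <- mm_n + ins_n + del_n
  }

  if (tail_len > 0) {
    if (strand == "+") {
      cig_lens <- c(cig_lens, tail_len); cig_ops <- c(cig_ops, "S")
      seq <- paste0(seq, strrep("A", tail_len))
    } else {
      cig_lens <- c(tail_len, cig_lens); cig_ops <- c("S", cig_ops)
      seq <- paste0(strrep("T", tail_len), seq)
    }
  }
  list(cigar = ops_to_cigar(cig_lens, cig_ops), seq = seq, nm = nm)
}
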