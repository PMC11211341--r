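# Reference-bundle builder: a toy genome with multi-exon genes per biotype,
# CAGE clusters at a configurable fraction of TSSs, planted polyadenylation
# motifs upstream of transcript 3' ends, and dedicated spike-in contigs
# (single-exon ERCC-style ladder plus overlapping SIRV-style isoform
# modules), mirroring the composition of a combined genome + spike-in
# mapping reference at desk scale.

# Evaluate `code` under a fixed RNG seed without clobbering the caller's
# RNG stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

POLYA_MOTIF <- "AATAAA"

#' Build the toy reference bundle
#'
#' Deterministically (for a fixed seed) generates a genome, gene annotation,
#' CAGE clusters and spike-in design table. Every gene has at least one
#' transcript; ERCC-style controls are single-exon on dedicated contigs with
#' a log-spaced concentration ladder spanning at least five orders of
#' magnitude; SIRV-style controls are overlapping multi-isoform modules on
#' dedicated contigs. A canonical polyadenylation motif is planted upstream
#' of a configured fraction of main-genome transcript 3' ends (and scrubbed
#' elsewhere in the search window, so the planted fraction is exact truth).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the same seed reproduces the bundle exactly.
#' @return A list of class `ref_bundle`: `genome` (named
#'   [Biostrings::DNAStringSet]), `annotation` ([gene_annotation()] covering
#'   genes and spike-ins), `cage` (GRanges), `design` (data.frame: id, class,
#'   concentration_attomol_ul, length, chrom, strand, gene_id), and `config`.
#' @export
build_reference <- function(config = sim_config(), seed = 42L) {
  validate_sim_config(config)
  with_seed(seed, {
    main <- build_main_genome(config)
    spikes <- build_spike_contigs(config)

    exons <- suppressWarnings(c(main$exons, spikes$exons))
    tx_meta <- rbind(main$tx_meta, spikes$tx_meta)
    ann <- gene_annotation(exons, tx_meta = tx_meta)

    genome_chars <- c(main$genome, spikes$genome)
    # scrub/plant polyadenylation motifs at main-genome cleavage sites
    genome_chars <- plant_motifs(genome_chars, ann, config)
    tx_truth <- attr(genome_chars, "tx_truth")
    genome <- Biostrings::DNAStringSet(unlist(genome_chars))

    cage <- build_cage(ann, config)
    cage_truth <- attr(cage, "cage_at_tss")
    attr(cage, "cage_at_tss") <- NULL

    # fold simulation truth (planted motifs, CAGE presence at the TSS) into
    # the transcript table; spike-in transcripts get FALSE for both
    tx <- ann$transcripts
    tx$motif_planted <-
      tx_truth$motif_planted[match(tx$transcript_id, tx_truth$transcript_id)]
    tx$motif_offset <-
      tx_truth$motif_offset[match(tx$transcript_id, tx_truth$transcript_id)]
    tx$cage_at_tss <-
      cage_truth$cage_at_tss[match(tx$transcript_id,
                                   cage_truth$transcript_id)]
    tx$cage_at_tss[is.na(tx$cage_at_tss)] <- FALSE
    tx$motif_planted[is.na(tx$motif_planted)] <- FALSE
    ann$transcripts <- tx

    design <- spikes$design
    bundle <- list(genome = genome, annotation = ann, cage = cage,
                   design = design, config = config)
    class(bundle) <- "ref_bundle"
    bundle
  })
}

#' @export
print.ref_bundle <- function(x, ...) {
  cat("ref_bundle:", length(x$genome), "sequences (",
      sum(Biostrings::width(x$genome)), "bp ),",
      nrow(x$annotation$transcripts), "transcripts,",
      length(x$cage), "CAGE clusters,", nrow(x$design), "spike-ins\n")
  invisible(x)
}

build_main_genome <- function(cfg) {
  gpb <- cfg$genes_per_biotype[cfg$genes_per_biotype > 0]
  biotypes <- rep(names(gpb), gpb)
  n_genes <- length(biotypes)
  chrom_of <- rep(seq_len(cfg$chrom_n), length.out = n_genes)
  cursor <- integer(cfg$chrom_n) # last used position per chromosome

  ex_start <- ex_end <- integer(); ex_tx <- ex_gene <- ex_bt <- character()
  ex_chr <- character(); ex_strand <- character()
  meta <- list()
  for (i in seq_len(n_genes)) {
    bt <- biotypes[i]
    chr <- chrom_of[i]
    gap <- sample(cfg$intergene_gap_range[1]:cfg$intergene_gap_range[2], 1)
    gstart <- cursor[chr] + gap
    strand <- sample(c("+", "-"), 1)
    if (bt == "rRNA") {
      lens <- sample(500:1500, 1)
      introns <- integer()
    } else {
      n_ex <- sample(cfg$exon_n_range[1]:cfg$exon_n_range[2], 1)
      lens <- sample(cfg$exon_len_range[1]:cfg$exon_len_range[2], n_ex,
                     replace = TRUE)
      introns <- sample(cfg$intron_len_range[1]:cfg$intron_len_range[2],
                        n_ex - 1, replace = TRUE)
    }
    starts <- gstart + cumsum(c(0, lens[-length(lens)] + introns))
    ends <- starts + lens - 1
    gid <- sprintf("G%04d", i)
    for (k in seq_len(max(1L, cfg$transcripts_per_gene))) {
      keep <- seq_along(lens)
      if (k > 1 && length(lens) >= 3) # extra isoforms skip one internal exon
        keep <- setdiff(keep, 1 + (k - 1) %% (length(lens) - 2))
      tid <- sprintf("%s.T%d", gid, k)
      ex_start <- c(ex_start, starts[keep]); ex_end <- c(ex_end, ends[keep])
      ex_tx <- c(ex_tx, rep(tid, length(keep)))
      ex_gene <- c(ex_gene, rep(gid, length(keep)))
      ex_bt <- c(ex_bt, rep(bt, length(keep)))
      ex_chr <- c(ex_chr, rep(paste0("chr", chr), length(keep)))
      ex_strand <- c(ex_strand, rep(strand, length(keep)))
      meta[[tid]] <- data.frame(transcript_id = tid, spike_class = "none")
    }
    cursor[chr] <- max(ends)
  }
  chrom_len <- cursor + sample(cfg$intergene_gap_range[1]:
                                 cfg$intergene_gap_range[2], cfg$chrom_n,
                               replace = TRUE)
  genome <- lapply(chrom_len, random_dna)
  names(genome) <- paste0("chr", seq_len(cfg$chrom_n))
  exons <- GenomicRanges::GRanges(
    ex_chr, IRanges::IRanges(ex_start, ex_end), strand = ex_strand
  )
  S4Vectors::mcols(exons)$transcript_id <- ex_tx
  S4Vectors::mcols(exons)$gene_id <- ex_gene
  S4Vectors::mcols(exons)$biotype <- ex_bt
  list(genome = genome, exons = exons, tx_meta = do.call(rbind, meta))
}

build_spike_contigs <- function(cfg) {
  genome <- list()
  ex_start <- ex_end <- integer(); ex_tx <- ex_gene <- ex_bt <- character()
  ex_chr <- character(); ex_strand <- character()
  design <- list()

  if (cfg$ercc_n > 0) {
    lens <- sample(cfg$ercc_len_range[1]:cfg$ercc_len_range[2], cfg$ercc_n,
                   replace = TRUE)
    conc <- 10^seq(cfg$conc_log10_range[1], cfg$conc_log10_range[2],
                   length.out = cfg$ercc_n)
    conc <- sample(conc) # decorrelate concentration from id/length order
    for (i in seq_len(cfg$ercc_n)) {
      id <- sprintf("ERCC-%05d", i)
      genome[[id]] <- random_dna(lens[i] + 20L)
      ex_start <- c(ex_start, 11L); ex_end <- c(ex_end, 10L + lens[i])
      ex_tx <- c(ex_tx, id); ex_gene <- c(ex_gene, id)
      ex_bt <- c(ex_bt, "other"); ex_chr <- c(ex_chr, id)
      ex_strand <- c(ex_strand, "+")
      design[[id]] <- data.frame(
        id = id, class = "ERCC", concentration_attomol_ul = conc[i],
        length = lens[i], chrom = id, strand = "+", gene_id = id
      )
    }
  }

  if (cfg$sirv_n > 0) {
    per_gene <- rep(cfg$sirv_n %/% cfg$sirv_gene_n, cfg$sirv_gene_n)
    extra <- cfg$sirv_n %% cfg$sirv_gene_n
    if (extra > 0) per_gene[seq_len(extra)] <- per_gene[seq_len(extra)] + 1L
    for (g in seq_len(cfg$sirv_gene_n)) {
      chrom <- paste0("SIRV", g)
      strand <- sample(c("+", "-"), 1)
      n_master <- 8L
      mlens <- sample(150:400, n_master, replace = TRUE)
      milens <- sample(300:600, n_master - 1, replace = TRUE)
      mstart <- 200L + cumsum(c(0L, mlens[-n_master] + milens))
      mend <- mstart + mlens - 1L
      genome[[chrom]] <- random_dna(max(mend) + 200L)
      gid <- chrom
      for (k in seq_len(per_gene[g])) {
        tid <- sprintf("SIRV%d%02d", g, k)
        i0 <- sample(1:2, 1); j0 <- sample((n_master - 1):n_master, 1)
        keep <- i0:j0
        if (length(keep) > 2) {
          mid <- keep[-c(1, length(keep))]
          keep <- sort(c(keep[1], mid[runif(length(mid)) < 0.85],
                         keep[length(keep)]))
        }
        design[[tid]] <- data.frame(
          id = tid, class = "SIRV",
          concentration_attomol_ul = sample(cfg$sirv_conc_levels, 1),
          length = sum(mlens[keep]), chrom = chrom, strand = strand,
          gene_id = gid
        )
        ex_start <- c(ex_start, mstart[keep]); ex_end <- c(ex_end, mend[keep])
        ex_tx <- c(ex_tx, rep(tid, length(keep)))
        ex_gene <- c(ex_gene, rep(gid, length(keep)))
        ex_bt <- c(ex_bt, rep("other", length(keep)))
        ex_chr <- c(ex_chr, rep(chrom, length(keep)))
        ex_strand <- c(ex_strand, rep(strand, length(keep)))
      }
    }
  }

  exons <- GenomicRanges::GRanges(
    ex_chr, IRanges::IRanges(ex_start, ex_end), strand = ex_strand
  )
  S4Vectors::mcols(exons)$transcript_id <- ex_tx
  S4Vectors::mcols(exons)$gene_id <- ex_gene
  S4Vectors::mcols(exons)$biotype <- ex_bt
  design <- do.call(rbind, design)
  rownames(design) <- NULL
  tx_meta <- if (length(ex_tx)) {
    data.frame(transcript_id = unique(ex_tx), spike_class = "spike")
  } else {
    data.frame(transcript_id = character(), spike_class = character())
  }
  if (!is.null(design)) {
    tx_meta$spike_class <-
      design$class[match(tx_meta$transcript_id, design$id)]
  }
  list(genome = genome, exons = exons, tx_meta = tx_meta, design = design)
}

# Scrub the motif search window upstream of every main-genome cleavage site
# (so chance occurrences cannot blur the planted fraction), then plant the
# canonical motif for a configured fraction of transcripts. Records
# motif_planted / motif_offset in the transcript table.
plant_motifs <- function(genome_chars, ann, cfg) {
  tx <- ann$transcripts
  main <- tx[tx$spike_class == "none", , drop = FALSE]
  planted <- runif(nrow(main)) < cfg$motif_fraction
  offs <- sample(cfg$motif_offset_range[1]:cfg$motif_offset_range[2],
                 nrow(main), replace = TRUE)
  motif <- POLYA_MOTIF
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  ml <- nchar(motif)
  for (i in seq_len(nrow(main))) {
    chr <- main$chrom[i]
    s <- genome_chars[[chr]]
    tes <- main$tes[i]
    if (main$strand[i] == "+") {
      win <- c(max(1, tes - 50), tes - 5)
      scrub <- paste(sample(c("C", "G"), win[2] - win[1] + 1, replace = TRUE),
                     collapse = "")
      substr(s, win[1], win[2]) <- scrub
      if (planted[i]) { # 3' edge of the motif `offs` nt upstream of cleavage
        p2 <- tes - offs[i]
        substr(s, p2 - ml + 1, p2) <- motif
      }
    } else {
      win <- c(tes + 5, min(nchar(s), tes + 50))
      scrub <- paste(sample(c("C", "G"), win[2] - win[1] + 1, replace = TRUE),
                     collapse = "")
      substr(s, win[1], win[2]) <- scrub
      if (planted[i]) {
        p1 <- tes + offs[i]
        substr(s, p1, p1 + ml - 1) <- rc
      }
    }
    genome_chars[[chr]] <- s
  }
  ann$transcripts$motif_planted <-
    ifelse(ann$transcripts$spike_class == "none",
           planted[match(ann$transcripts$transcript_id, main$transcript_id)],
           FALSE)
  ann$transcripts$motif_offset <-
    ifelse(ann$transcripts$motif_planted,
           offs[match(ann$transcripts$transcript_id, main$transcript_id)],
           NA_integer_)
  # plant_motifs mutates the annotation truth columns as a side product;
  # propagate via attribute so build_reference can pick them up
  attr(genome_chars, "tx_truth") <-
    ann$transcripts[, c("transcript_id", "motif_planted", "motif_offset")]
  genome_chars
}

build_cage <- function(ann, cfg) {
  tx <- ann$transcripts
  main <- tx[tx$spike_class == "none", , drop = FALSE]
  has <- runif(nrow(main)) < cfg$cage_fraction
  hw <- cfg$cage_halfwidth
  gr <- GenomicRanges::GRanges(
    main$chrom[has],
    IRanges::IRanges(pmax(1, main$tss[has] - hw), main$tss[has] + hw),
    strand = main$strand[has]
  )
  gr <- BiocGenerics::unique(gr)
  attr(gr, "cage_at_tss") <-
    data.frame(transcript_id = main$transcript_id, cage_at_tss = has)
  gr
}
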