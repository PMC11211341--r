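# Gene/transcript annotation container: strand-aware exon chains with
# biotypes, held as GRanges plus a transcript metadata table. GTF IO goes
# through rtracklayer; coordinates are 1-based closed throughout.

#' Construct a gene annotation object
#'
#' @param exons A `GRanges` of exons with metadata columns `transcript_id`,
#'   `gene_id` and `biotype`. Exons of a transcript must be non-overlapping
#'   and on one chromosome/strand.
#' @param tx_meta Optional data.frame of per-transcript metadata (simulation
#'   truth such as `cage_at_tss`, `motif_planted`, `motif_offset`); merged by
#'   `transcript_id`.
#' @return A list of class `gene_annotation` with elements `exons` (GRanges),
#'   `transcripts` (data.frame: transcript_id, gene_id, chrom, strand,
#'   biotype, tss, tes, spliced_len, n_exons, plus any `tx_meta` columns) and
#'   `genes` (GRanges of gene spans with `gene_id`, `biotype`).
#' @export
gene_annotation <- function(exons, tx_meta = NULL) {
  stopifnot(is(exons, "GRanges"),
            all(c("transcript_id", "gene_id", "biotype") %in%
                  colnames(S4Vectors::mcols(exons))))
  ex <- BiocGenerics::sort(exons)
  sp <- S4Vectors::split(ex, S4Vectors::mcols(ex)$transcript_id)
  if (any(vapply(sp, function(g)
        length(GenomicRanges::reduce(g)) != length(g), logical(1))))
    stop("overlapping exons within a transcript")
  tx <- data.frame(
    transcript_id = names(sp),
    gene_id = vapply(sp, function(g)
      S4Vectors::mcols(g)$gene_id[1], character(1)),
    chrom = vapply(sp, function(g)
      as.character(GenomicRanges::seqnames(g)[1]), character(1)),
    strand = vapply(sp, function(g)
      as.character(BiocGenerics::strand(g)[1]), character(1)),
    biotype = vapply(sp, function(g)
      S4Vectors::mcols(g)$biotype[1], character(1)),
    tss = vapply(sp, function(g) {
      if (as.character(BiocGenerics::strand(g)[1]) == "+")
        min(BiocGenerics::start(g)) else max(BiocGenerics::end(g))
    }, numeric(1)),
    tes = vapply(sp, function(g) {
      if (as.character(BiocGenerics::strand(g)[1]) == "+")
        max(BiocGenerics::end(g)) else min(BiocGenerics::start(g))
    }, numeric(1)),
    spliced_len = vapply(sp, function(g)
      sum(BiocGenerics::width(g)), numeric(1)),
    n_exons = vapply(sp, length, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (!is.null(tx_meta))
    tx <- merge(tx, tx_meta, by = "transcript_id", all.x = TRUE, sort = FALSE)
  tx <- tx[order(tx$transcript_id), , drop = FALSE]
  rownames(tx) <- NULL
  gsp <- BiocGenerics::unlist(range(
    S4Vectors::split(ex, S4Vectors::mcols(ex)$gene_id)))
  genes <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(gsp), IRanges::ranges(gsp),
    strand = BiocGenerics::strand(gsp)
  )
  S4Vectors::mcols(genes)$gene_id <- names(gsp)
  bt <- tx$biotype[match(names(gsp), tx$gene_id)]
  S4Vectors::mcols(genes)$biotype <- bt
  names(genes) <- NULL
  out <- list(exons = ex, transcripts = tx, genes = genes)
  class(out) <- "gene_annotation"
  out
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", nrow(x$transcripts), "transcripts,",
      length(x$genes), "genes,", length(x$exons), "exons\n")
  cat("biotypes:", paste(sort(unique(x$transcripts$biotype)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Exon table of one transcript
#'
#' @param ann A `gene_annotation`.
#' @param transcript_id Transcript identifier.
#' @return data.frame (start, end), 1-based closed, ascending — the form
#'   [compare_to_reference()] consumes.
#' @export
transcript_exon_table <- function(ann, transcript_id) {
  g <- ann$exons[S4Vectors::mcols(ann$exons)$transcript_id == transcript_id]
  data.frame(start = BiocGenerics::start(g), end = BiocGenerics::end(g))
}

# Intron chain of an exon table: data.frame(start, end), possibly 0 rows.
intron_chain <- function(exon_tab) {
  n <- nrow(exon_tab)
  if (n < 2) return(data.frame(start = numeric(), end = numeric()))
  data.frame(start = exon_tab$end[-n] + 1, end = exon_tab$start[-1] - 1)
}

#' Write an annotation as GENCODE-dialect GTF
#'
#' Emits gene, transcript and exon rows with `gene_id`, `transcript_id` and
#' `gene_type` attributes (1-based closed coordinates).
#'
#' @param ann A `gene_annotation`.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(ann, path) {
  ex <- ann$exons
  gr_ex <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(ex), IRanges::ranges(ex),
    strand = BiocGenerics::strand(ex),
    type = "exon",
    gene_id = S4Vectors::mcols(ex)$gene_id,
    transcript_id = S4Vectors::mcols(ex)$transcript_id,
    gene_type = S4Vectors::mcols(ex)$biotype
  )
  tx <- ann$transcripts
  gr_tx <- GenomicRanges::GRanges(
    tx$chrom,
    IRanges::IRanges(pmin(tx$tss, tx$tes), pmax(tx$tss, tx$tes)),
    strand = tx$strand, type = "transcript",
    gene_id = tx$gene_id, transcript_id = tx$transcript_id,
    gene_type = tx$biotype
  )
  gn <- ann$genes
  gr_gn <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(gn), IRanges::ranges(gn),
    strand = BiocGenerics::strand(gn),
    type = "gene",
    gene_id = S4Vectors::mcols(gn)$gene_id,
    transcript_id = NA_character_,
    gene_type = S4Vectors::mcols(gn)$biotype
  )
  gr <- BiocGenerics::sort(c(gr_gn, gr_tx, gr_ex), ignore.strand = TRUE)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a GENCODE-dialect GTF into a gene annotation
#'
#' Only exon rows are used; `gene_type` (or `gene_biotype`) supplies the
#' biotype label.
#'
#' @param path GTF path.
#' @return A `gene_annotation`.
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  m <- S4Vectors::mcols(gr)
  ex <- gr[m$type == "exon"]
  bt_col <- intersect(c("gene_type", "gene_biotype"),
                      colnames(S4Vectors::mcols(ex)))[1]
  if (is.na(bt_col))
    stop("GTF lacks a gene_type/gene_biotype attribute: ", path)
  out <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(ex), IRanges::ranges(ex),
    strand = BiocGenerics::strand(ex)
  )
  S4Vectors::mcols(out)$transcript_id <- S4Vectors::mcols(ex)$transcript_id
  S4Vectors::mcols(out)$gene_id <- S4Vectors::mcols(ex)$gene_id
  S4Vectors::mcols(out)$biotype <- S4Vectors::mcols(ex)[[bt_col]]
  gene_annotation(out)
}
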