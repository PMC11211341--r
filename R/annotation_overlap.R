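# Read-vs-annotation statistics: biotype assignment by largest exonic
# overlap with a fixed tie-break precedence, per-base coverage partition
# into exonic/intronic/intergenic space, transcriptional-diversity
# statistics, and scaled gene-body meta-coverage profiles. Overlaps are
# strand-blind (antisense artifact reads still count towards the locus);
# UTRs are part of the exonic space.

BIOTYPE_PRECEDENCE <- c("rRNA", "protein_coding", "lncRNA", "pseudogene",
                        "miscRNA", "other")

#' Precompute overlap indexes for an annotation
#'
#' @param ann A [gene_annotation()].
#' @return List of class `annotation_index`: `exons_by_gene` (GRangesList of
#'   reduced exons), `exonic` (reduced GRanges over all genes), `gene_spans`
#'   (GRanges), `intronic` (gene spans minus exonic space), `gene_meta`
#'   (data.frame gene_id, biotype).
#' @export
annotation_index <- function(ann) {
  ex <- ann$exons
  by_gene <- GenomicRanges::reduce(
    S4Vectors::split(unstrand(ex), S4Vectors::mcols(ex)$gene_id))
  exonic <- GenomicRanges::reduce(unstrand(ex))
  spans <- unstrand(ann$genes)
  intronic <- GenomicRanges::setdiff(GenomicRanges::reduce(spans), exonic)
  idx <- list(
    exons_by_gene = by_gene,
    exonic = exonic,
    gene_spans = spans,
    intronic = intronic,
    gene_meta = data.frame(
      gene_id = S4Vectors::mcols(ann$genes)$gene_id,
      biotype = S4Vectors::mcols(ann$genes)$biotype
    )
  )
  class(idx) <- "annotation_index"
  idx
}

unstrand <- function(gr) {
  BiocGenerics::strand(gr) <- "*"
  gr
}

# Aligned (M) reference blocks of every mapped record as one GRanges with a
# `read` index column.
aligned_blocks <- function(records) {
  m <- which(records$mapped)
  if (length(m) == 0)
    return(GenomicRanges::GRanges(read = integer()))
  starts <- vector("list", length(m))
  ends <- vector("list", length(m))
  for (k in seq_along(m)) {
    i <- m[k]
    r <- cigar_m_ranges(records$cigar[i], records$start[i])
    starts[[k]] <- BiocGenerics::start(r)
    ends[[k]] <- BiocGenerics::end(r)
  }
  nblk <- lengths(starts)
  gr <- GenomicRanges::GRanges(
    rep(records$chrom[m], nblk),
    IRanges::IRanges(unlist(starts), unlist(ends))
  )
  S4Vectors::mcols(gr)$read <- rep(m, nblk)
  gr
}

#' Assign each read to a gene and biotype label
#'
#' A read overlapping at least `min_exonic_bp` of exonic sequence of one or
#' more genes is labelled with the biotype of the gene with the largest
#' exonic overlap (ties broken by the precedence rRNA > protein_coding >
#' lncRNA > pseudogene > miscRNA > other, then by gene id). Reads inside a
#' gene span without exonic overlap are `intronic`; the rest are
#' `intergenic`. The biotype `other` is reported as `other_genic`.
#'
#' @param records An [aln_records()] table.
#' @param idx An [annotation_index()].
#' @param min_exonic_bp Minimum exonic overlap to count as genic (default 1).
#' @return data.frame: qname, gene_id (NA for non-genic reads), label.
#' @export
assign_read_biotype <- function(records, idx, min_exonic_bp = 1L) {
  m <- which(records$mapped)
  gene_id <- rep(NA_character_, nrow(records))
  label <- rep(NA_character_, nrow(records))
  if (length(m) == 0)
    return(data.frame(qname = records$qname, gene_id = gene_id,
                      label = label)[integer(), ])
  blocks <- aligned_blocks(records)
  flat <- BiocGenerics::unlist(idx$exons_by_gene) # reduced exons, names = gene ids
  ov <- GenomicRanges::findOverlaps(blocks, flat, ignore.strand = TRUE)
  if (length(ov)) {
    q <- blocks[S4Vectors::queryHits(ov)]
    s <- flat[S4Vectors::subjectHits(ov)]
    ovw <- pmin(BiocGenerics::end(q), BiocGenerics::end(s)) -
      pmax(BiocGenerics::start(q), BiocGenerics::start(s)) + 1
    df <- data.frame(read = S4Vectors::mcols(q)$read,
                     gene = names(s), w = ovw)
    agg <- stats::aggregate(w ~ read + gene, df, sum)
    agg <- agg[agg$w >= min_exonic_bp, , drop = FALSE]
    if (nrow(agg)) {
      bt <- idx$gene_meta$biotype[match(agg$gene, idx$gene_meta$gene_id)]
      prec <- match(bt, BIOTYPE_PRECEDENCE)
      ord <- order(agg$read, -agg$w, prec, agg$gene)
      agg <- agg[ord, , drop = FALSE]
      best <- agg[!duplicated(agg$read), , drop = FALSE]
      gene_id[best$read] <- best$gene
      chosen_bt <- idx$gene_meta$biotype[match(best$gene,
                                               idx$gene_meta$gene_id)]
      label[best$read] <- ifelse(chosen_bt == "other", "other_genic",
                                 chosen_bt)
    }
  }
  # non-genic mapped reads: intronic when inside any gene span
  open <- m[is.na(label[m])]
  if (length(open)) {
    pts <- GenomicRanges::GRanges(records$chrom[open],
                                  IRanges::IRanges(records$start[open],
                                                   records$end[open]))
    inside <- IRanges::overlapsAny(pts, idx$gene_spans,
                                         ignore.strand = TRUE)
    label[open] <- ifelse(inside, "intronic", "intergenic")
  }
  data.frame(qname = records$qname[m], gene_id = gene_id[m],
             label = label[m])
}

#' Partition aligned nucleotides into exonic/intronic/intergenic space
#'
#' Every aligned base (M operations) is labelled exonic if it falls inside
#' any annotated exon, else intronic if inside any gene span, else
#' intergenic; fractions are over all aligned bases of mapped reads.
#'
#' @param records An [aln_records()] table.
#' @param idx An [annotation_index()].
#' @return Named numeric vector (exonic, intronic, intergenic) summing to 1.
#' @export
coverage_partition <- function(records, idx) {
  blocks <- aligned_blocks(records)
  total <- sum(BiocGenerics::width(blocks))
  if (total == 0)
    return(c(exonic = NA_real_, intronic = NA_real_, intergenic = NA_real_))
  exonic <- overlap_bases(blocks, idx$exonic)
  intronic <- overlap_bases(blocks, idx$intronic)
  c(exonic = exonic / total, intronic = intronic / total,
    intergenic = (total - exonic - intronic) / total)
}

# Bases of `blocks` (per-read, multiplicity counted) inside the disjoint
# range set `set`.
overlap_bases <- function(blocks, set) {
  ov <- GenomicRanges::findOverlaps(blocks, set, ignore.strand = TRUE)
  if (length(ov) == 0) return(0)
  q <- blocks[S4Vectors::queryHits(ov)]
  s <- set[S4Vectors::subjectHits(ov)]
  sum(pmin(BiocGenerics::end(q), BiocGenerics::end(s)) -
        pmax(BiocGenerics::start(q), BiocGenerics::start(s)) + 1)
}

#' Transcriptional-diversity statistics
#'
#' Counts reads per gene (assignment by largest exonic overlap via
#' [assign_read_biotype()]), the cumulative read fraction over genes sorted
#' by decreasing count, and the share of reads on the top `top_k` genes.
#' Reads not assigned to any gene are excluded.
#'
#' @param records An [aln_records()] table.
#' @param idx An [annotation_index()].
#' @param top_k Number of top genes for the headline share (default 10).
#' @return List of class `diversity_result`: `gene_counts` (data.frame
#'   gene_id, count, sorted decreasing), `cumulative_fraction`,
#'   `top_share`, `n_assigned`.
#' @export
diversity_stats <- function(records, idx, top_k = 10L) {
  if (top_k <= 0) stop("top_k must be positive")
  calls <- assign_read_biotype(records, idx)
  assigned <- calls[!is.na(calls$gene_id), , drop = FALSE]
  tab <- sort(table(assigned$gene_id), decreasing = TRUE)
  counts <- data.frame(gene_id = names(tab), count = as.integer(tab))
  cum <- if (nrow(counts)) cumsum(counts$count) / sum(counts$count)
         else numeric()
  out <- list(
    gene_counts = counts,
    cumulative_fraction = cum,
    top_share = if (nrow(counts))
      sum(head(counts$count, top_k)) / sum(counts$count) else NA_real_,
    n_assigned = nrow(assigned)
  )
  class(out) <- "diversity_result"
  out
}

#' Scaled gene-body meta-coverage profile
#'
#' Per eligible gene (span >= `n_bins` bp and non-zero coverage), base
#' coverage over the gene span is averaged within `n_bins` equal-width
#' bins, the bin vector is flipped for minus-strand genes (bin 1 = 5' end)
#' and normalised by its own mean; the profile is the across-gene mean per
#' bin with a 95% confidence band (1.96 x across-gene standard error).
#'
#' @param records An [aln_records()] table.
#' @param ann A [gene_annotation()] (gene spans and strands are used).
#' @param n_bins Number of bins (>= 2, default 100).
#' @return List of class `meta_profile`: `n_bins`, `n_genes`, `mean`
#'   (length `n_bins`), `ci_halfwidth`.
#' @export
metagene_profile <- function(records, ann, n_bins = 100L) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  blocks <- aligned_blocks(records)
  cov <- GenomicRanges::coverage(blocks)
  genes <- ann$genes
  mat <- NULL
  for (k in seq_along(genes)) {
    chr <- as.character(GenomicRanges::seqnames(genes)[k])
    gs <- BiocGenerics::start(genes)[k]; ge <- BiocGenerics::end(genes)[k]
    glen <- ge - gs + 1
    if (glen < n_bins) next
    if (!chr %in% names(cov)) next
    rl <- cov[[chr]]
    ge_c <- min(ge, length(rl))
    v <- if (gs <= ge_c)
      as.numeric(S4Vectors::window(rl, gs, ge_c)) else numeric(0)
    if (length(v) < glen) v <- c(v, numeric(glen - length(v)))
    if (sum(v) == 0) next
    if (as.character(BiocGenerics::strand(genes)[k]) == "-") v <- rev(v)
    bin_idx <- floor((seq_len(glen) - 1) * n_bins / glen) + 1
    binned <- as.numeric(tapply(v, bin_idx, mean))
    binned <- binned / mean(binned)
    mat <- rbind(mat, binned)
  }
  if (is.null(mat)) stop("metagene_profile: no eligible genes with coverage")
  mu <- colMeans(mat)
  se <- if (nrow(mat) > 1) apply(mat, 2, sd) / sqrt(nrow(mat))
        else numeric(n_bins)
  out <- list(n_bins = as.integer(n_bins), n_genes = nrow(mat),
              mean = unname(mu), ci_halfwidth = unname(1.96 * se))
  class(out) <- "meta_profile"
  out
}
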