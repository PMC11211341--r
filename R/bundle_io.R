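# File-format boundary of the package. Genome as FASTA (Biostrings),
# annotation as GENCODE-dialect GTF (rtracklayer), CAGE clusters as BED6
# (rtracklayer), alignments as coordinate-sorted SAM, design/truth as TSV.
# SAM records constructed in memory are emitted as text directly; reading
# goes through Rsamtools (asBam + scanBam) so the records seen downstream
# are exactly what htslib parses.

#' Write a simulated bundle to disk
#'
#' @param bundle A [build_reference()] bundle.
#' @param records An [aln_records()] table (may be empty).
#' @param truth The matching truth table (may be empty).
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of file paths (genome, annotation, cage,
#'   alignments, design, truth), invisibly.
#' @export
write_bundle <- function(bundle, records, truth, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- c(
    genome = file.path(out_dir, "genome.fa"),
    annotation = file.path(out_dir, "annotation.gtf"),
    cage = file.path(out_dir, "cage.bed"),
    alignments = file.path(out_dir, "alignments.sam"),
    design = file.path(out_dir, "design.tsv"),
    truth = file.path(out_dir, "truth.tsv")
  )
  Biostrings::writeXStringSet(bundle$genome, paths["genome"], width = 60L)
  write_annotation_gtf(bundle$annotation, paths["annotation"])
  write_cage_bed(bundle$cage, paths["cage"])
  write_sam(records, bundle$genome, paths["alignments"])
  utils::write.table(bundle$design, paths["design"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read a bundle directory written by [write_bundle()]
#'
#' @param dir Directory containing `genome.fa`, `annotation.gtf`,
#'   `cage.bed`, `alignments.sam`, `design.tsv`, `truth.tsv`.
#' @return A list with `genome`, `annotation`, `cage`, `design`, `records`,
#'   `truth`.
#' @export
read_bundle <- function(dir) {
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  list(
    genome = genome,
    annotation = read_annotation_gtf(file.path(dir, "annotation.gtf")),
    cage = read_cage_bed(file.path(dir, "cage.bed")),
    design = utils::read.delim(file.path(dir, "design.tsv")),
    records = read_sam(file.path(dir, "alignments.sam")),
    truth = utils::read.delim(file.path(dir, "truth.tsv"))
  )
}

#' Write CAGE clusters as BED6
#'
#' @param cage GRanges of clusters (strand `+`/`-`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cage_bed <- function(cage, path) {
  gr <- cage
  S4Vectors::mcols(gr)$name <- sprintf("cage_%05d", seq_along(gr))
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read CAGE clusters from a BED6 file
#'
#' @param path BED path (0-based half-open on disk; returned as 1-based
#'   GRanges).
#' @return GRanges with strand.
#' @export
read_cage_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (any(!as.character(BiocGenerics::strand(gr)) %in% c("+", "-")))
    stop("CAGE BED must carry +/- strands: ", path)
  gr
}

#' Write alignment records as coordinate-sorted SAM
#'
#' Emits primary records with soft clips retained and the `NM` tag set;
#' unmapped reads get flag 4. MAPQ is fixed at 60 and qualities are omitted.
#'
#' @param records An [aln_records()] table.
#' @param genome Named DNAStringSet (or named integer lengths) defining the
#'   `@SQ` header lines.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, genome, path) {
  lens <- if (is(genome, "DNAStringSet"))
    setNames(Biostrings::width(genome), names(genome)) else genome
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lens), as.integer(lens)))
  m <- records[records$mapped, , drop = FALSE]
  u <- records[!records$mapped, , drop = FALSE]
  m <- m[order(match(m$chrom, names(lens)), m$start), , drop = FALSE]
  body <- character()
  if (nrow(m))
    body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                    m$qname, ifelse(m$strand == "-", 16L, 0L), m$chrom,
                    m$start, m$cigar, m$seq, m$nm)
  if (nrow(u))
    body <- c(body, sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*",
                            u$qname, u$seq))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read primary alignments from a SAM/BAM file
#'
#' Parses through Rsamtools (SAM is converted to a temporary BAM first).
#' Secondary and supplementary alignments are dropped with a message; the
#' `NM` tag is required for mapped reads used by [error_profile()].
#'
#' @param path SAM or BAM path.
#' @return An [aln_records()] table.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("no such alignment file: ", path)
  bam <- if (grepl("\\.bam$", path)) path
  else Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                        indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "cigar", "seq"),
    tag = "NM"
  )
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- x$flag
  sec <- bitwAnd(flag, 256L) > 0 | bitwAnd(flag, 2048L) > 0
  if (any(sec))
    message("dropping ", sum(sec), " secondary/supplementary alignments")
  keep <- !sec
  mapped <- bitwAnd(flag[keep], 4L) == 0
  cig <- x$cigar[keep]
  ref_len <- vapply(seq_along(cig), function(i)
    if (mapped[i]) cigar_ref_len(cig[i]) else NA_integer_, integer(1))
  aln_records(
    qname = x$qname[keep], mapped = mapped,
    chrom = ifelse(mapped, as.character(x$rname[keep]), NA),
    start = ifelse(mapped, x$pos[keep], NA),
    end = ifelse(mapped, x$pos[keep] + ref_len - 1L, NA),
    strand = ifelse(mapped, as.character(x$strand[keep]), NA),
    cigar = ifelse(mapped, cig, NA),
    seq = as.character(x$seq)[keep],
    nm = x$tag$NM[keep]
  )
}

#' Read a spike-in design table
#'
#' @param path TSV with columns id, class, concentration_attomol_ul, length,
#'   chrom, strand, gene_id.
#' @return data.frame.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path)
  need <- c("id", "class", "concentration_attomol_ul", "length", "chrom")
  miss <- setdiff(need, colnames(d))
  if (length(miss))
    stop("design table lacks columns: ", paste(miss, collapse = ", "))
  if (any(d$concentration_attomol_ul <= 0))
    stop("design concentrations must be > 0")
  d
}
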