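# End-to-end orchestration over one library. run_pipeline() only sequences
# the per-module operations — every number in the report is recomputable by
# calling the owning function directly. Reports serialize to JSON with TSV
# sidecars; compare_libraries() lines up headline metrics across libraries
# prepared with identical thresholds.

REPORT_SCHEMA_VERSION <- "1.0"

#' Build a pipeline run configuration
#'
#' Inputs may be file paths (FASTA/GTF/BED/SAM/TSV) or the in-memory
#' objects the rest of the package produces. All analysis thresholds are
#' gathered here so cross-library comparisons can verify comparability.
#'
#' @param alignments [aln_records()] table or SAM/BAM path.
#' @param genome Named DNAStringSet or FASTA path.
#' @param annotation [gene_annotation()] or GTF path.
#' @param cage GRanges or BED6 path.
#' @param design Design data.frame or TSV path (NULL to skip spike-in
#'   analysis).
#' @param cage_window,polya_min_len,polya_min_frac,polya_scan,motifs,
#'   motif_window,min_intron,end_window,min_reads,n_bins,top_k Analysis
#'   thresholds; defaults as documented in the individual modules.
#' @return List of class `run_config`.
#' @export
run_config <- function(alignments, genome, annotation, cage, design = NULL,
                       cage_window = 50L, polya_min_len = 10L,
                       polya_min_frac = 0.8, polya_scan = 60L,
                       motifs = "AATAAA", motif_window = c(10L, 40L),
                       min_intron = 40L, end_window = 50L, min_reads = 1L,
                       n_bins = 100L, top_k = 10L) {
  thresholds <- list(cage_window = cage_window,
                     polya_min_len = polya_min_len,
                     polya_min_frac = polya_min_frac,
                     polya_scan = polya_scan, motifs = motifs,
                     motif_window = motif_window, min_intron = min_intron,
                     end_window = end_window, min_reads = min_reads,
                     n_bins = n_bins, top_k = top_k)
  bad <- vapply(thresholds[c("polya_min_len", "polya_min_frac",
                             "polya_scan", "min_intron", "end_window",
                             "min_reads", "n_bins", "top_k")],
                function(x) any(x <= 0), logical(1))
  bad["cage_window"] <- cage_window < 0
  if (any(bad))
    stop("invalid thresholds: ", paste(names(bad)[bad], collapse = ", "))
  cfg <- list(alignments = alignments, genome = genome,
              annotation = annotation, cage = cage, design = design,
              thresholds = thresholds)
  class(cfg) <- "run_config"
  cfg
}

load_inputs <- function(cfg) {
  genome <- if (is.character(cfg$genome)) {
    g <- Biostrings::readDNAStringSet(cfg$genome)
    names(g) <- sub("\\s.*$", "", names(g))
    g
  } else cfg$genome
  annotation <- if (is.character(cfg$annotation))
    read_annotation_gtf(cfg$annotation) else cfg$annotation
  cage <- if (is.character(cfg$cage)) read_cage_bed(cfg$cage) else cfg$cage
  design <- if (is.character(cfg$design)) read_design(cfg$design)
            else cfg$design
  records <- if (is.character(cfg$alignments)) read_sam(cfg$alignments)
             else cfg$alignments
  ann_chroms <- unique(as.character(
    GenomicRanges::seqnames(annotation$exons)))
  missing <- setdiff(ann_chroms, names(genome))
  if (length(missing))
    stop("annotation references chromosomes absent from the genome: ",
         paste(missing, collapse = ", "))
  if (!is.null(design)) {
    missing <- setdiff(unique(design$chrom), names(genome))
    if (length(missing))
      stop("design references contigs absent from the genome: ",
           paste(missing, collapse = ", "))
  }
  list(genome = genome, annotation = annotation, cage = cage,
       design = design, records = records)
}

#' Run the full per-library analysis
#'
#' Sequences [mapping_stats()], [library_error_profile()],
#' [classify_completeness()] (+ motif validation and length stratification),
#' [assign_read_biotype()], [coverage_partition()], [diversity_stats()],
#' [metagene_profile()] and — when a design is supplied — the spike-in
#' analyses, over genome (non-spike) and spike-in strata of the records.
#' Deterministic for fixed inputs.
#'
#' @param cfg A [run_config()].
#' @return List of class `library_report`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(is(cfg, "run_config"))
  th <- cfg$thresholds
  inp <- load_inputs(cfg)
  records <- inp$records
  spike_chroms <- if (!is.null(inp$design)) unique(inp$design$chrom)
                  else character()
  genome_rec <- records[!records$mapped |
                          !(records$chrom %in% spike_chroms), , drop = FALSE]
  main_ann <- subset_annotation(inp$annotation,
                               setdiff(unique(as.character(
                                 GenomicRanges::seqnames(inp$annotation$exons))),
                                 spike_chroms))
  idx <- annotation_index(main_ann)

  stats <- mapping_stats(records)
  errs <- library_error_profile(records)
  comp <- classify_completeness(records, inp$cage,
                                cage_window = th$cage_window,
                                polya_min_len = th$polya_min_len,
                                polya_min_frac = th$polya_min_frac,
                                polya_scan = th$polya_scan,
                                min_intron = th$min_intron,
                                exclude_chroms = spike_chroms)
  tails <- comp[comp$polya, , drop = FALSE]
  motif_flags <- if (nrow(tails)) {
    sub <- records[match(tails$qname, records$qname), , drop = FALSE]
    validate_polya_motif(sub, inp$genome, th$motifs, th$motif_window)
  } else logical()
  lenbins <- seq(0, 3600, by = 600)
  by_len <- support_by_length(comp, lenbins)
  biotype <- assign_read_biotype(genome_rec, idx)
  bt_frac <- if (nrow(biotype))
    table(factor(biotype$label,
                 levels = c(setdiff(BIOTYPE_PRECEDENCE, "other"),
                            "other_genic", "intronic",
                            "intergenic"))) / nrow(biotype)
  else NULL
  part <- coverage_partition(genome_rec, idx)
  divers <- diversity_stats(genome_rec, idx, top_k = th$top_k)
  meta <- metagene_profile(genome_rec, main_ann, n_bins = th$n_bins)

  spike <- NULL
  if (!is.null(inp$design)) {
    counts <- count_spikein_reads(records, inp$design, inp$annotation,
                                  end_window = th$end_window,
                                  min_intron = th$min_intron)
    limit <- estimate_detection_limit(counts, inp$design,
                                      min_reads = th$min_reads)
    molecules <- if (is.na(limit)) NA_real_ else amount_to_molecules(limit)
    fit <- tryCatch(fit_concentration_response(counts, inp$design),
                    error = function(e) NULL)
    sirv <- if (any(inp$design$class == "SIRV"))
      classify_sirv_levels(records, inp$design, inp$annotation,
                           end_window = th$end_window,
                           min_intron = th$min_intron)
    else NULL
    spike <- list(
      counts = counts,
      detection_rate = detection_rate(counts, th$min_reads),
      slope = if (!is.null(fit)) fit$slope else NA_real_,
      intercept = if (!is.null(fit)) fit$intercept else NA_real_,
      correlation = if (!is.null(fit)) fit$correlation else NA_real_,
      detection_limit_attomol_ul = limit,
      detection_limit_molecules = molecules,
      detection_limit_copies_per_cell =
        if (is.na(molecules)) NA_real_ else molecules_per_cell(molecules),
      sirv_levels = sirv
    )
  }

  report <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("flreadqc")),
    thresholds = th,
    read_stats = stats,
    error_rates = errs,
    completeness = completeness_summary(comp),
    completeness_records = comp,
    polya_motif_support = if (length(motif_flags))
      mean(motif_flags, na.rm = TRUE) else NA_real_,
    support_by_length = by_len,
    biotype_fractions = bt_frac,
    coverage_partition = part,
    diversity = divers,
    meta_profile = meta,
    spikein = spike
  )
  class(report) <- "library_report"
  report
}

# Restrict an annotation to a chromosome set.
subset_annotation <- function(ann, chroms) {
  keep <- as.character(GenomicRanges::seqnames(ann$exons)) %in% chroms
  ex <- ann$exons[keep]
  meta_cols <- setdiff(colnames(ann$transcripts),
                       c("gene_id", "chrom", "strand", "biotype", "tss",
                         "tes", "spliced_len", "n_exons"))
  gene_annotation(ex, tx_meta = ann$transcripts[, meta_cols, drop = FALSE])
}

#' @export
print.library_report <- function(x, ...) {
  cat("library_report (schema", x$schema_version, ")\n")
  print(x$read_stats)
  cat(sprintf("spliced reads: %.1f%%\n", x$completeness$spliced_percent))
  fr <- x$completeness$fractions
  ft <- fr$fraction[fr$stratum == "all" & fr$category == "five_three"]
  cat(sprintf("5'+3' supported (all reads): %.1f%%\n", 100 * ft))
  cat(sprintf("coverage: %.1f%% exonic, %.1f%% intronic, %.1f%% intergenic\n",
              100 * x$coverage_partition["exonic"],
              100 * x$coverage_partition["intronic"],
              100 * x$coverage_partition["intergenic"]))
  if (!is.null(x$spikein))
    cat(sprintf("spike-ins: slope %.2f, r %.2f, limit %.3g attomol/ul\n",
                x$spikein$slope, x$spikein$correlation,
                x$spikein$detection_limit_attomol_ul))
  invisible(x)
}

#' Serialize a library report
#'
#' Writes `report.json` (scalar metrics and thresholds) plus TSV sidecars
#' (per-read completeness, length stratification, biotype fractions,
#' per-gene counts, meta-profile, spike-in counts and SIRV levels).
#'
#' @param report A [run_pipeline()] result.
#' @param out_dir Output directory.
#' @return Named vector of written paths, invisibly.
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  fr <- report$completeness$fractions
  scalar <- list(
    schema_version = report$schema_version,
    package_version = report$package_version,
    thresholds = report$thresholds,
    total_reads = report$read_stats$total,
    mapped_reads = report$read_stats$mapped,
    mapping_rate = report$read_stats$mapping_rate,
    median_read_length = report$read_stats$median_length,
    error_rates = as.list(report$error_rates),
    spliced_percent = report$completeness$spliced_percent,
    category_fractions_all =
      setNames(as.list(fr$fraction[fr$stratum == "all"]),
               fr$category[fr$stratum == "all"]),
    polya_motif_support = report$polya_motif_support,
    coverage_partition = as.list(report$coverage_partition),
    top_gene_share = report$diversity$top_share,
    spikein = if (!is.null(report$spikein))
      report$spikein[c("detection_rate", "slope", "intercept",
                       "correlation", "detection_limit_attomol_ul",
                       "detection_limit_molecules",
                       "detection_limit_copies_per_cell")]
    else NULL
  )
  paths <- c(json = file.path(out_dir, "report.json"))
  jsonlite::write_json(scalar, paths["json"], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths["completeness"] <- tsv(report$completeness_records,
                               "completeness.tsv")
  paths["support_by_length"] <- tsv(report$support_by_length,
                                    "support_by_length.tsv")
  if (!is.null(report$biotype_fractions))
    paths["biotypes"] <- tsv(as.data.frame(report$biotype_fractions),
                             "biotype_fractions.tsv")
  paths["gene_counts"] <- tsv(report$diversity$gene_counts,
                              "gene_counts.tsv")
  paths["meta_profile"] <- tsv(
    data.frame(bin = seq_len(report$meta_profile$n_bins),
               mean = report$meta_profile$mean,
               ci_halfwidth = report$meta_profile$ci_halfwidth),
    "meta_profile.tsv")
  if (!is.null(report$spikein)) {
    paths["spikein_counts"] <- tsv(report$spikein$counts,
                                   "spikein_counts.tsv")
    if (!is.null(report$spikein$sirv_levels))
      paths["sirv_levels"] <- tsv(report$spikein$sirv_levels$levels,
                                  "sirv_levels.tsv")
  }
  invisible(paths)
}

#' Compare headline metrics across library reports
#'
#' Refuses to compare reports generated under different thresholds.
#'
#' @param reports Named list of >= 2 [run_pipeline()] results.
#' @return data.frame with one row per metric and one column per library.
#' @export
compare_libraries <- function(reports) {
  if (length(reports) < 2) stop("need at least two reports to compare")
  if (is.null(names(reports)))
    names(reports) <- paste0("library", seq_along(reports))
  th0 <- reports[[1]]$thresholds
  for (r in reports[-1])
    if (!identical(r$thresholds, th0))
      stop("reports are not comparable: analysis thresholds differ")
  metric_row <- function(rep) {
    fr <- rep$completeness$fractions
    fall <- function(cat) fr$fraction[fr$stratum == "all" &
                                        fr$category == cat]
    c(median_length = rep$read_stats$median_length,
      mapping_rate = rep$read_stats$mapping_rate,
      spliced_percent = rep$completeness$spliced_percent,
      unsupported = fall("unsupported"),
      three_only = fall("three_only"),
      five_only = fall("five_only"),
      five_three = fall("five_three"),
      intronic_coverage = unname(rep$coverage_partition["intronic"]),
      top_gene_share = rep$diversity$top_share,
      meta_profile_sd = sd(rep$meta_profile$mean),
      spikein_slope = if (!is.null(rep$spikein)) rep$spikein$slope
                      else NA_real_,
      detection_limit = if (!is.null(rep$spikein))
        rep$spikein$detection_limit_attomol_ul else NA_real_)
  }
  cols <- lapply(reports, metric_row)
  out <- data.frame(metric = names(cols[[1]]))
  for (nm in names(cols)) out[[nm]] <- unname(cols[[nm]])
  out
}
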