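# Configuration objects for the synthetic-data module. The defaults define
# the study conditions used throughout the test suite: a desk-scale genome
# with a handful of multi-exon genes per biotype, the full 92-control ERCC
# ladder spanning five orders of magnitude, and 69 SIRV isoforms in seven
# overlapping gene modules.

#' Simulation configuration for the toy reference bundle
#'
#' @param chrom_n Number of main-genome chromosomes (>= 1).
#' @param genes_per_biotype Named integer vector of gene counts per biotype.
#'   Names must come from `protein_coding, lncRNA, pseudogene, miscRNA,
#'   rRNA, other`. rRNA genes are single-exon; all others are multi-exon.
#' @param transcripts_per_gene Isoforms per main-genome gene.
#' @param exon_n_range,exon_len_range,intron_len_range Ranges (inclusive)
#'   for exon count, exon length (bp) and intron length (bp) of multi-exon
#'   genes.
#' @param intergene_gap_range Range of gaps between adjacent genes (bp).
#' @param ercc_n Number of single-exon ERCC-style controls (default 92).
#' @param sirv_n Total SIRV-style isoforms (default 69).
#' @param sirv_gene_n Number of SIRV gene modules / dedicated contigs.
#' @param ercc_len_range ERCC transcript length range (nt).
#' @param conc_log10_range log10 range (attomol/ul) of the ERCC
#'   concentration ladder; must span >= 5 orders of magnitude.
#' @param sirv_conc_levels Concentration levels (attomol/ul) sampled for
#'   SIRV isoforms.
#' @param cage_fraction Fraction of main-genome TSSs given a CAGE cluster.
#' @param cage_halfwidth Half-width (bp) of each CAGE cluster around its TSS.
#' @param motif_fraction Fraction of transcript 3' ends with a canonical
#'   polyadenylation motif planted upstream of the cleavage site.
#' @param motif_offset_range Range (nt upstream of cleavage, 3' edge of the
#'   motif) where planted motifs are placed.
#' @param min_intron Minimum intron length (bp); smaller reference skips are
#'   treated as deletions everywhere in the package.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chrom_n = 3L,
                       genes_per_biotype = c(protein_coding = 14L, lncRNA = 5L,
                                             pseudogene = 3L, miscRNA = 2L,
                                             rRNA = 2L, other = 1L),
                       transcripts_per_gene = 1L,
                       exon_n_range = c(3L, 6L),
                       exon_len_range = c(200L, 500L),
                       intron_len_range = c(300L, 800L),
                       intergene_gap_range = c(600L, 1200L),
                       ercc_n = 92L,
                       sirv_n = 69L,
                       sirv_gene_n = 7L,
                       ercc_len_range = c(250L, 2000L),
                       conc_log10_range = c(-1.5, 3.5),
                       sirv_conc_levels = c(37.5, 75, 150, 300),
                       cage_fraction = 0.8,
                       cage_halfwidth = 10L,
                       motif_fraction = 0.66,
                       motif_offset_range = c(15L, 35L),
                       min_intron = 40L) {
  cfg <- list(
    chrom_n = as.integer(chrom_n),
    genes_per_biotype = genes_per_biotype,
    transcripts_per_gene = as.integer(transcripts_per_gene),
    exon_n_range = as.integer(exon_n_range),
    exon_len_range = as.integer(exon_len_range),
    intron_len_range = as.integer(intron_len_range),
    intergene_gap_range = as.integer(intergene_gap_range),
    ercc_n = as.integer(ercc_n), sirv_n = as.integer(sirv_n),
    sirv_gene_n = as.integer(sirv_gene_n),
    ercc_len_range = as.integer(ercc_len_range),
    conc_log10_range = as.numeric(conc_log10_range),
    sirv_conc_levels = as.numeric(sirv_conc_levels),
    cage_fraction = cage_fraction, cage_halfwidth = as.integer(cage_halfwidth),
    motif_fraction = motif_fraction,
    motif_offset_range = as.integer(motif_offset_range),
    min_intron = as.integer(min_intron)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

BIOTYPES <- c("protein_coding", "lncRNA", "pseudogene", "miscRNA", "rRNA",
              "other")

validate_sim_config <- function(cfg) {
  if (cfg$chrom_n < 1L)
    stop("sim_config: chrom_n must be >= 1")
  gpb <- cfg$genes_per_biotype
  if (is.null(names(gpb)) || !all(names(gpb) %in% BIOTYPES))
    stop("sim_config: genes_per_biotype names must be in the biotype vocabulary")
  if (sum(gpb) < 1L || any(gpb < 0))
    stop("sim_config: need at least one gene and no negative counts")
  if (any(c(cfg$exon_len_range, cfg$intron_len_range,
            cfg$intergene_gap_range, cfg$ercc_len_range) <= 0))
    stop("sim_config: lengths must be positive")
  if (cfg$ercc_n < 0 || cfg$sirv_n < 0 || cfg$sirv_gene_n < 1)
    stop("sim_config: invalid spike-in counts")
  if (diff(cfg$conc_log10_range) < 5)
    stop("sim_config: concentration ladder must span >= 5 orders of magnitude")
  if (cfg$cage_fraction < 0 || cfg$cage_fraction > 1 ||
      cfg$motif_fraction < 0 || cfg$motif_fraction > 1)
    stop("sim_config: fractions must lie in [0, 1]")
  if (cfg$intron_len_range[1] < cfg$min_intron)
    stop("sim_config: introns must be at least min_intron long")
  invisible(cfg)
}

#' Protocol bias profile for the read simulator
#'
#' Captures the protocol-dependent phenomenology the simulator emulates:
#' the probability that a read's 5' end sits at the true TSS, the truncation
#' law for 5'-incomplete reads, the poly(A) tail length distribution, per-base
#' sequencing error rates, contamination fractions, and the capture advantage
#' of capped over uncapped spike-ins.
#'
#' Two presets are provided. `"captrap"` emulates a cap-trapping library:
#' high 5' completeness, mostly spliced reads, negligible rRNA and low error
#' rates. `"smarter"` emulates a template-switching library: strong 3' bias
#' (exponential truncation from the 3' end), many unspliced and
#' intronic/intergenic reads, and more rRNA.
#'
#' @param preset `"captrap"` (default) or `"smarter"`.
#' @param ... Named overrides of any profile field (see Details).
#' @return A list of class `protocol_profile` with fields: `p_cap5`,
#'   `tss_jitter_sd`, `truncation_model` (`"uniform"` or `"exp3"`),
#'   `trunc_exp_scale`, `min_trunc_offset`, `polya_mean`, `polya_disp`
#'   (Inf for a deterministic tail), `mismatch_rate`, `insertion_rate`,
#'   `deletion_rate`, `unspliced_fraction`, `rRNA_fraction`,
#'   `intronic_fraction`, `intergenic_fraction`, `unmapped_fraction`,
#'   `spikein_base_fraction`, `spikein_capture_ratio`, `spikein_capped`.
#' @export
protocol_profile <- function(preset = c("captrap", "smarter"), ...) {
  preset <- match.arg(preset)
  prof <- list(
    p_cap5 = 0.45, tss_jitter_sd = 5, truncation_model = "uniform",
    trunc_exp_scale = 600, min_trunc_offset = 120L,
    polya_mean = 20, polya_disp = 5,
    mismatch_rate = 0.02, insertion_rate = 0.005, deletion_rate = 0.01,
    unspliced_fraction = 0.12, rRNA_fraction = 0.005,
    intronic_fraction = 0.03, intergenic_fraction = 0.02,
    unmapped_fraction = 0.01,
    spikein_base_fraction = 0.001, spikein_capture_ratio = 40,
    spikein_capped = TRUE
  )
  if (preset == "smarter") {
    prof$p_cap5 <- 0.10
    prof$truncation_model <- "exp3"
    prof$unspliced_fraction <- 0.45
    prof$rRNA_fraction <- 0.05
    prof$intronic_fraction <- 0.18
    prof$intergenic_fraction <- 0.06
    prof$mismatch_rate <- 0.03
    prof$deletion_rate <- 0.015
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(prof))
  if (length(unknown))
    stop("unknown protocol_profile fields: ", paste(unknown, collapse = ", "))
  prof[names(dots)] <- dots
  class(prof) <- "protocol_profile"
  validate_profile(prof)
  prof
}

validate_profile <- function(prof) {
  probs <- c(prof$p_cap5, prof$unspliced_fraction, prof$rRNA_fraction,
             prof$intronic_fraction, prof$intergenic_fraction,
             prof$unmapped_fraction, prof$spikein_base_fraction)
  if (any(probs < 0 | probs > 1))
    stop("protocol_profile: probabilities must lie in [0, 1]")
  if (any(c(prof$mismatch_rate, prof$insertion_rate, prof$deletion_rate) < 0))
    stop("protocol_profile: error rates must be >= 0")
  contam <- prof$rRNA_fraction + prof$intronic_fraction +
    prof$intergenic_fraction +
    prof$spikein_base_fraction * prof$spikein_capture_ratio
  if (contam > 1)
    stop("protocol_profile: contamination + spike-in fractions exceed 1")
  if (!prof$truncation_model %in% c("uniform", "exp3"))
    stop("protocol_profile: truncation_model must be 'uniform' or 'exp3'")
  invisible(prof)
}
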