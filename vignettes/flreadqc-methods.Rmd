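---
title: "Methods: read-level completeness, spike-in calibration, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: read-level completeness, spike-in calibration, and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures behind `flreadqc`, the
defaults of every tunable parameter, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the
design was genuinely open. It states no empirical result beyond what the
test suite and `scripts/acceptance.R` themselves compute.

## 1. Read-level completeness

A mapped primary read is *3'-supported* when its soft clip on the 3' side
contains a poly(A) tail, and *5'-supported* when its aligned 5' end lies
near a same-strand CAGE cluster. The two binary flags define four
mutually exclusive categories (`unsupported`, `three_only`, `five_only`,
`five_three`), reported for all, spliced, and unspliced reads. A read is
*spliced* when its CIGAR contains a reference skip (`N`) of at least
`min_intron` bp; shorter skips are treated as deletions throughout the
package, including when per-read exon chains are built.

### Poly(A) tail calling

Sequences are stored in reference orientation, so the tail of a
`+`-strand alignment is a trailing A-run in the right soft clip and the
tail of a `-`-strand alignment is a leading T-run in the left soft clip
(scanned reversed, i.e. from its tail-proximal end). The call scans
prefixes of the clip: the tail length is the longest prefix whose A (or
T) fraction is at least `polya_min_frac`, with scanning capped at
`polya_scan` clipped nt; the tail is *present* when that length reaches
`polya_min_len`.

Defaults: `polya_min_len = 10` nt, `polya_min_frac = 0.8`,
`polya_scan = 60` nt. The fraction threshold tolerates basecalling
errors inside genuine tails while the 10-nt minimum rejects short
A-runs that arise by chance in random clips; the 60-nt cap keeps the
scan inside the region where a tail, if any, must start. The test suite
pins the caller to an independent brute-force oracle that enumerates
every prefix.

### CAGE support

The read 5' end is the alignment start for `+` and the alignment end for
`-`; soft-clipped 5' bases are ignored because their genomic origin is
unknown. Support requires a same-strand cluster whose edge is within
`cage_window` bp (default **±50 bp**) in arithmetic coordinate distance
— a 5' end 51 bp from the nearest edge is unsupported. The signed
distance (0 inside a cluster, negative upstream, positive downstream) is
reported per read so support calls can be audited: CAGE clusters
typically come from other samples, so absence of support does not prove
5' incompleteness.

Reads on spike-in contigs are excluded from CAGE-based classification —
no CAGE truth exists there — and are handled by the spike-in module.

### Polyadenylation-motif validation

For reads with a positive tail call, the genomic window
`motif_window = [10, 40]` nt upstream of the inferred cleavage site (the
aligned 3' end) is scanned for the canonical signal `AATAAA` on the
read's strand (reverse complement on the `+` strand for `-` reads). The
motif's 3' edge must fall inside the interval. The motif set is
extensible; only the canonical hexamer is on by default because variant
motifs trade specificity for sensitivity and the validation is meant as
a conservative cross-check of the tail caller. Windows are clipped at
chromosome bounds.

## 2. Annotation overlap

Biotype assignment uses aligned (`M`) blocks against exons, ignoring
strand (antisense artifacts still belong to the locus). A read with at
least `min_exonic_bp = 1` bp of exonic overlap takes the biotype of the
gene with the largest exonic overlap; exact ties break by the precedence
`rRNA > protein_coding > lncRNA > pseudogene > miscRNA > other`, with
rRNA first because rRNA depletion is the headline contrast between
cap-dependent and cap-independent protocols. Reads without exonic
overlap are `intronic` when inside a gene span, else `intergenic`. UTRs
count as exonic.

The coverage partition labels every aligned base — exonic if inside any
annotated exon, else intronic if inside any gene span, else intergenic —
and is tested against a per-base brute-force labelling of the whole toy
genome.

The gene-body meta-profile averages per-base coverage of each gene span
into `n_bins = 100` equal-width bins, flips minus-strand genes so bin 1
is the 5' end, normalises each gene's vector by its own mean (so highly
expressed genes do not dominate the aggregate — the figure-level
normalisation used by coverage tools is not specified, and per-gene-mean
scaling makes the flat-profile expectation exactly 1 in every bin), and
reports the across-gene mean with a 95% band (1.96 × across-gene
standard error). Genes shorter than `n_bins` bp or with zero coverage
are excluded.

## 3. Spike-in calibration

Single-isoform controls are counted per contig; multi-isoform controls
are attributed per read to the best-matching isoform. A per-read exon
chain is built from the CIGAR (`M`/`D` merged; `N ≥ min_intron` become
introns) and compared with each reference model: `full_match` requires
an identical intron chain and both termini within `end_window = 50` nt
of the reference termini (for single-exon references: both chains
unspliced, overlapping, ends within the window); `partial_overlap`
requires ≥ 1 bp exonic overlap. Per isoform, `end_to_end` means at least
one full match, `partial` at least one partial overlap, `absent`
otherwise. Per-read chains rather than an assembler feed this comparison
because they are deterministic, desk-scale, and exactly what the reads
support.

Detection uses `min_reads = 1`; the detection limit is the smallest
ladder concentration c\* such that *every* control at or above c\* is
detected, walking whole rungs (all controls sharing a concentration) down
the ladder. The concentration–response fit is ordinary least squares of
log10(count) on log10(attomol/µl) over controls with positive counts;
zero counts are excluded because their log is undefined (a pseudo-count
mode exists but is off by default, since it pulls the fit toward the
pseudo-count at the bottom of the ladder). This *detected-only*
estimator is consistent when depth puts most of the ladder above zero
expected counts; at very shallow depth zero-truncation attenuates the
slope, which the test suite documents by checking slope recovery at
depths where the majority of the ladder is detected.

Unit conversions: `molecules = c × (1/dilution) × volume × 10⁻¹⁸ × N_A`
with `N_A = 6.02214 × 10²³`, defaults `dilution = 100`, `volume = 4 µl`
(the volume-like quantity in the mix description is interpreted as 4 µl);
`copies/cell = molecules / (total_rna_ug × 10⁶ / per_cell_pg)` with
defaults 4 µg RNA and 5 pg per cell. The conversions are exposed as pure
functions and are linear in each argument; the composition is invariant
under simultaneous scaling of concentration and dilution.

## 4. The synthetic-data generator

The generator produces the study conditions under which every claim in
the test suite is evaluated. It emulates:

* a toy genome (3 chromosomes, auto-sized around the genes placed on
  them) with non-overlapping multi-exon genes per biotype (defaults: 14
  protein-coding, 5 lncRNA, 3 pseudogene, 2 miscRNA, 2 single-exon rRNA,
  1 other; 3–6 exons of 200–500 bp, introns 300–800 bp, intergenic gaps
  600–1200 bp);
* CAGE clusters (±10 bp around the TSS) at `cage_fraction = 0.8` of
  TSSs — the fraction is recorded per transcript as truth;
* the canonical polyadenylation motif planted with its 3' edge 15–35 nt
  upstream of `motif_fraction = 0.66` of main-genome cleavage sites; the
  whole search window is first scrubbed of chance occurrences (refilled
  with C/G), so the planted fraction is *exact* truth for the motif
  validator;
* dedicated spike-in contigs: 92 single-exon ERCC-style controls with a
  log-spaced ladder over `conc_log10_range = [-1.5, 3.5]` (five orders
  of magnitude, shuffled against id/length), and 69 SIRV-style isoforms
  in 7 overlapping modules drawn from 8 master exons per module. SIRV
  concentrations take four 2×-spaced levels (37.5–300 attomol/µl) so
  the two control classes contribute comparable molar totals, as in a
  1:1 mix;
* protocol bias via `protocol_profile()`: the probability `p_cap5` that
  a read starts at the TSS (default 0.45, jitter SD 5 bp downstream),
  5'-truncation for incomplete reads, negative-binomial poly(A) tails
  (mean 20 nt, dispersion 5; dispersion `Inf` gives deterministic
  tails), per-base mismatch/insertion/deletion rates (0.02/0.005/0.01),
  an unspliced-read knob (0.12), contamination fractions (rRNA 0.005,
  intronic 0.03, intergenic 0.02), an unmapped fraction (0.01), and a
  capped-vs-uncapped spike-in capture ratio of 40 applied to a base
  spike-in fraction of 0.001. A `"smarter"` preset flips the profile to
  a template-switching caricature: strong 3' bias, many unspliced and
  non-exonic reads, more rRNA.

Design choices worth calling out:

* **Truncation law.** No published truncation distribution exists for
  these protocols, so 5'-incomplete reads start uniformly at least
  `min_trunc_offset = 120` nt downstream of the TSS (degradation rarely
  nibbles just a few bases, and the offset keeps truncated starts
  outside any CAGE window so truth labels are unambiguous). An
  exponential-from-the-3'-end alternative (`truncation_model = "exp3"`,
  scale 600 nt) mimics the 3' bias of template-switching kits. Spliced
  truncated reads are constrained to retain at least one intron so the
  unspliced-read knob is the sole source of unspliced transcript reads.
* **Geometry is exact.** Records are emitted with
  CIGAR/sequence/extent consistency enforced at construction; `NM`
  equals injected mismatches plus indel bases; tails appear only as
  clips. The simulator writes SAM directly and reads it back through
  htslib (Rsamtools), so the on-disk dialect is externally validated.
* **What is not modelled:** platform-specific error structure
  (homopolymer errors, quality scores), RNA degradation beyond the
  truncation knob, internal priming artifacts, chimeric reads,
  multi-mapping, and real expression covariance. Passing tests
  demonstrate correctness of the measurement code under known truth,
  not protocol performance on real tissue.

## 5. Numerical choices and degenerate inputs

* Coordinates are 1-based closed (SAM/GRanges convention) everywhere in
  memory; BED 0-based conversion happens in rtracklayer on IO.
* Empty inputs: zero reads simulate to empty tables; empty record lists
  classify to empty results; `mapping_stats()` on no records, an empty
  spike-in design, fewer than three positive controls for the fit, and
  a meta-profile with no eligible genes are errors with explicit
  messages; an all-undetected ladder yields an `NA` detection limit.
* Ties: biotype precedence as above, then gene id; SIRV attribution
  prefers `full_match` over `partial_overlap`, then larger exonic
  overlap, then id.
* The median read length is the 50th percentile of mapped read lengths
  (mean of middle two); histogram bin width 100 nt.
* Error-rate denominators are alignment columns `M + I + D`; soft clips
  are excluded. Secondary/supplementary alignments are dropped at
  parse time with a message.
* Determinism: `build_reference()` and `simulate_library()` take
  explicit seeds and restore the caller's RNG state; the analysis
  pipeline is deterministic given its inputs.

## 6. Problem sizes

The shared test fixtures use one bundle (27 genes, 161 spike-ins,
~260 kb of sequence) and two 10,000-read libraries (default and
noise-free profiles); the stochastic recovery checks use 50 regression
seeds, 100 detection-limit seeds, 20 simulation seeds for the spike-in
goodness-of-fit, and 12,000-read libraries for the capped-vs-uncapped
contrast. `scripts/acceptance.R` simulates a 15,000-read library plus
two 20,000-read enrichment libraries. These sizes make every stochastic
band (3 binomial SEs, chi-square at α = 0.01) meaningful while keeping a
full run in minutes.

## 7. Known limitations

* CAGE-based 5' calls inherit the incompleteness of external cluster
  sets; treat category fractions as comparative, not absolute.
* The detected-only concentration fit is biased at depths where much of
  the ladder is unobserved; compare slopes only between libraries of
  similar spike-in depth.
* Biotype assignment resolves multi-gene overlap by largest exonic
  overlap with a fixed precedence; annotations with heavily nested or
  antisense loci may warrant an EM-style assignment, which is out of
  scope.
* The toy genome has well-separated genes; performance on overlapping
  real loci is not exercised by the synthetic benchmark.
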