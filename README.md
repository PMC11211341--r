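# flreadqc

Full-length read quality control for long-read RNA-seq.

## The problem

Long-read cDNA protocols differ sharply in how often a sequenced read
represents the *complete* RNA molecule, from the capped 5' end (the
transcription start site) to the polyadenylated 3' end. Benchmarking a
library preparation therefore needs read-level evidence for both termini:

* **3' support** — an unmapped poly(A) tail left in the soft-clipped bases
  at the read's 3' side (a trailing A-run for `+` alignments, a leading
  T-run for `-` alignments, since SAM stores sequences in reference
  orientation). Tail calls can be cross-checked against the canonical
  polyadenylation signal `AATAAA` located 10–40 nt upstream of the
  cleavage site.
* **5' support** — proximity of the aligned 5' end to an independently
  derived CAGE (Cap Analysis of Gene Expression) cluster on the same
  strand.

The two flags partition reads into four categories — *unsupported*,
*3'-only*, *5'-only*, and *5'+3'* (full-length) — reported separately for
spliced and unspliced reads. Around this core, the package computes the
standard per-library panel used in protocol benchmarks: mapping rate and
read-length distribution, per-base sequencing-error rates split into
mismatches and indels from the CIGAR + `NM` tag, read-to-biotype
assignment against a GENCODE-style annotation, exonic/intronic/intergenic
nucleotide coverage partition, transcriptional-diversity statistics
(top-10-gene read share), and scaled gene-body meta-coverage profiles
with confidence bands.

For absolute calibration the package analyses synthetic spike-in
controls: single-isoform ERCC-style ladders (detection rate, ordinary
least squares of log10 read count on log10 concentration in attomol/µl,
detection limit as the lowest fully-detected ladder rung) and
multi-isoform SIRV-style modules, where each per-read exon chain is
compared with the reference isoform models (`full_match` /
`partial_overlap` / `none` by intron-chain identity and terminus
windows), yielding per-isoform *end-to-end* / *partial* / *absent*
levels. Molar amounts convert to molecule counts via
`molecules = c × (1/dilution) × volume × 10⁻¹⁸ × N_A` and to copies per
cell via the cell-equivalents of the RNA input.

Because real benchmark libraries are large and external, the package
ships a first-class **synthetic-data module**: it builds a desk-scale
reference bundle (toy genome, multi-exon genes per biotype, CAGE clusters
at a configurable fraction of TSSs, planted polyadenylation motifs, the
92-control ERCC ladder spanning five orders of magnitude, and 69 SIRV
isoforms in seven overlapping modules) and simulates protocol-biased
alignments with a per-read truth table, so every stage of the pipeline is
verifiable end-to-end without downloads.

## Worked example

```r
library(flreadqc)

bundle <- build_reference(sim_config(), seed = 7)
lib    <- simulate_library(bundle, protocol_profile(), 5000, seed = 8)

cfg <- run_config(alignments = lib$records, genome = bundle$genome,
                  annotation = bundle$annotation, cage = bundle$cage,
                  design = bundle$design)
report <- run_pipeline(cfg)
print(report)
```

```
library_report (schema 1.0 )
read_stats: N=5000, mapped=4951 (99.0%), median length=1021 nt
spliced reads: 82.5%
5'+3' supported (all reads): 26.3%
coverage: 98.5% exonic, 0.9% intronic, 0.6% intergenic
spike-ins: slope 0.65, r 0.83, limit 418 attomol/ul
```

Reading the numbers: 99.0% of the 5 000 simulated reads map (the
simulator emitted ~1% unmapped); 82.5% of classified reads span at least
one intron; 26.3% carry both a poly(A) tail and CAGE support at the
defaults (±50 bp CAGE window, tail ≥ 10 nt at ≥ 80% adenine); coverage is
overwhelmingly exonic for this cap-trapping-like profile; and the ERCC
ladder at this shallow depth is detected only at its upper rungs, which
attenuates the detected-only log-log slope (0.65) and leaves the
detection limit at 418 attomol/µl. `write_report(report, dir)`
serialises the scalar panel as JSON with per-read and per-control TSV
sidecars, and `compare_libraries()` lines up the headline metrics across
libraries analysed under identical thresholds.

File-based inputs work the same way: `run_config()` accepts SAM/BAM,
FASTA, GTF, BED6 and TSV paths, parsed through Rsamtools, Biostrings and
rtracklayer; `write_bundle()`/`read_bundle()` round-trip a simulated
bundle through those formats.

## Scope notes

The package consumes alignments; it does not basecall or map reads (the
simulator emits alignment records directly). CAGE support from external
cluster sets is indicative rather than definitive — per-read signed
distances are reported so users can audit the calls. See the methods
vignette (`vignettes/flreadqc-methods.Rmd`) for the model, parameter
defaults and their rationale, and known limitations.
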