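# Biotype assignment, coverage partition, diversity, meta-profiles.

# tiny two-gene annotation for worked examples: an rRNA single-exon gene
# and a two-exon protein-coding gene, plus empty space
toy_annotation <- function() {
  ex <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(c(1001L, 5001L, 6001L), c(1500L, 5300L, 6300L)),
    strand = c("+", "+", "+")
  )
  S4Vectors::mcols(ex)$transcript_id <- c("R1.T1", "P1.T1", "P1.T1")
  S4Vectors::mcols(ex)$gene_id <- c("R1", "P1", "P1")
  S4Vectors::mcols(ex)$biotype <- c("rRNA", "protein_coding",
                                    "protein_coding")
  gene_annotation(ex)
}

test_that("biotype labels follow overlap and the precedence rule", {
  idx <- annotation_index(toy_annotation())
  inside_rrna <- make_record("a", start = 1101L, cigar = "100M")
  in_intron <- make_record("b", start = 5401L, cigar = "100M")
  in_desert <- make_record("c", start = 9001L, cigar = "100M")
  calls <- assign_read_biotype(bind_records(inside_rrna, in_intron,
                                            in_desert), idx)
  expect_equal(calls$label, c("rRNA", "intronic", "intergenic"))
  expect_equal(calls$gene_id, c("R1", NA, NA))

  # exact tie in exonic overlap: rRNA wins over protein_coding
  tie_ex <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(100L, 300L), c(249L, 449L)), strand = "+")
  S4Vectors::mcols(tie_ex)$transcript_id <- c("A.T1", "B.T1")
  S4Vectors::mcols(tie_ex)$gene_id <- c("A", "B")
  S4Vectors::mcols(tie_ex)$biotype <- c("protein_coding", "rRNA")
  tidx <- annotation_index(gene_annotation(tie_ex))
  spanning <- make_record("t", start = 200L, cigar = "50M50N50M")
  call <- assign_read_biotype(spanning, tidx)
  expect_equal(call$label, "rRNA")
})

test_that("library biotype fractions sum to one", {
  lib <- fix_lib_default()
  b <- fix_bundle()
  main <- lib$records[lib$records$mapped &
                        !lib$records$chrom %in% spike_chroms(), ]
  class(main) <- class(lib$records)
  idx <- annotation_index(subset_main_annotation(b))
  calls <- assign_read_biotype(main, idx)
  expect_equal(nrow(calls), nrow(main))
  expect_equal(sum(table(calls$label)) / nrow(calls), 1)
  # contamination truth maps onto the expected labels
  tr <- lib$truth[match(calls$qname, lib$truth$qname), ]
  expect_true(mean(calls$label[tr$source_class == "intergenic"] ==
                     "intergenic") > 0.95)
  expect_true(mean(calls$label[tr$source_class == "rRNA"] == "rRNA") > 0.95)
})

test_that("coverage partition matches worked examples", {
  idx <- annotation_index(toy_annotation())
  fully_exonic <- make_record("a", start = 1101L, cigar = "100M")
  expect_equal(unname(coverage_partition(fully_exonic, idx)), c(1, 0, 0))
  # 50 bases exonic, 50 intronic (exon ends at 5300)
  half <- make_record("b", start = 5251L, cigar = "100M")
  expect_equal(unname(coverage_partition(half, idx)), c(0.5, 0.5, 0))
})

test_that("coverage partition equals the per-base labelling oracle", {
  lib <- fix_lib_default()
  b <- fix_bundle()
  main <- lib$records[lib$records$mapped &
                        !lib$records$chrom %in% spike_chroms(), ]
  class(main) <- class(lib$records)
  idx <- annotation_index(subset_main_annotation(b))
  got <- coverage_partition(main, idx)
  want <- oracle_partition(main, b)
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(unname(sum(got)), 1, tolerance = 1e-9)
})

test_that("diversity statistics follow the definitions", {
  idx <- annotation_index(toy_annotation())
  ten_on_one <- do.call(bind_records, lapply(1:10, function(i)
    make_record(paste0("r", i), start = 1101L, cigar = "100M")))
  d <- diversity_stats(ten_on_one, idx)
  expect_equal(d$top_share, 1.0)
  expect_equal(d$cumulative_fraction[1], 1.0)
  expect_error(diversity_stats(ten_on_one, idx, top_k = 0), "positive")

  # uniform reads over 100 genes -> top-10 share 0.10
  ex <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(seq(1, by = 1000, length.out = 100),
                             width = 500), strand = "+")
  S4Vectors::mcols(ex)$transcript_id <- sprintf("U%03d.T1", 1:100)
  S4Vectors::mcols(ex)$gene_id <- sprintf("U%03d", 1:100)
  S4Vectors::mcols(ex)$biotype <- "protein_coding"
  uidx <- annotation_index(gene_annotation(ex))
  reads <- do.call(bind_records, lapply(1:100, function(i)
    make_record(paste0("u", i), start = (i - 1L) * 1000L + 101L,
                cigar = "100M")))
  expect_equal(diversity_stats(reads, uidx)$top_share, 0.10)
})

test_that("diversity matches a recount from the simulator truth", {
  lib <- fix_lib_default()
  b <- fix_bundle()
  main <- lib$records[lib$records$mapped &
                        !lib$records$chrom %in% spike_chroms(), ]
  class(main) <- class(lib$records)
  idx <- annotation_index(subset_main_annotation(b))
  d <- diversity_stats(main, idx)
  tr <- lib$truth
  tx <- b$annotation$transcripts
  genic <- tr$mapped & tr$source_class %in% c("transcript", "rRNA")
  src_gene <- ifelse(tr$source_class[genic] == "rRNA", tr$source_id[genic],
                     tx$gene_id[match(tr$source_id[genic],
                                      tx$transcript_id)])
  truth_counts <- sort(table(src_gene), decreasing = TRUE)
  truth_share <- sum(head(truth_counts, 10)) / sum(truth_counts)
  expect_equal(d$top_share, truth_share, tolerance = 0.02)
})

test_that("meta-profile is flat under uniform coverage and zero CI for
           identical genes", {
  ex <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1001L, 3001L), c(2000L, 4000L)),
    strand = c("+", "+"))
  S4Vectors::mcols(ex)$transcript_id <- c("A.T1", "B.T1")
  S4Vectors::mcols(ex)$gene_id <- c("A", "B")
  S4Vectors::mcols(ex)$biotype <- "protein_coding"
  ann <- gene_annotation(ex)
  reads <- bind_records(
    make_record("a", start = 1001L, cigar = "1000M"),
    make_record("b", start = 3001L, cigar = "1000M"))
  mp <- metagene_profile(reads, ann, n_bins = 50L)
  expect_equal(mp$n_genes, 2L)
  expect_lt(max(abs(mp$mean - 1)), 1e-9)
  expect_lt(max(mp$ci_halfwidth), 1e-9)
})

test_that("3'-confined coverage shows up only in the terminal bins", {
  # one + gene and one - gene, reads covering the 3' terminal 10%
  ex <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1001L, 5001L), c(2000L, 6000L)),
    strand = c("+", "-"))
  S4Vectors::mcols(ex)$transcript_id <- c("A.T1", "B.T1")
  S4Vectors::mcols(ex)$gene_id <- c("A", "B")
  S4Vectors::mcols(ex)$biotype <- "protein_coding"
  ann <- gene_annotation(ex)
  reads <- bind_records(
    make_record("a", start = 1901L, cigar = "100M"), # + gene: right end
    make_record("b", start = 5001L, cigar = "100M")) # - gene: left end
  mp <- metagene_profile(reads, ann, n_bins = 100L)
  expect_true(all(mp$mean[1:90] == 0))
  expect_true(all(mp$mean[91:100] > 0))
})

test_that("meta-profile is invariant to gene order and coverage scaling", {
  lib <- fix_lib_default()
  b <- fix_bundle()
  ann <- subset_main_annotation(b)
  main <- lib$records[lib$records$mapped &
                        !lib$records$chrom %in% spike_chroms(), ]
  class(main) <- class(lib$records)
  mp1 <- metagene_profile(main, ann, n_bins = 40L)
  # duplicating every read scales all coverages by 2: profile unchanged
  dup <- main
  dup$qname <- paste0(dup$qname, "_copy")
  both <- bind_records(main, dup)
  mp2 <- metagene_profile(both, ann, n_bins = 40L)
  expect_equal(mp1$mean, mp2$mean, tolerance = 1e-12)
  expect_error(metagene_profile(main[integer(), ], ann), "no eligible")
})
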