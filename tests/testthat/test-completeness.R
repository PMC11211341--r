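# Poly(A) calling, CAGE support, four-way completeness classification,
# motif validation and length stratification.

test_that("poly(A) calls follow the prefix rule on worked examples", {
  # + read with a clean 15-nt A tail in the right clip
  r <- aln_records("a", TRUE, "chr1", 101L, 200L, "+", "100M15S",
                   paste0(strrep("G", 100), strrep("A", 15)), 0L)
  call <- call_polya_tail(r)
  expect_true(call$polya)
  expect_equal(call$tail_length, 15L)
  expect_equal(call$clip_side, "right")

  # + read with a random right clip
  r2 <- aln_records("b", TRUE, "chr1", 101L, 200L, "+", "100M12S",
                    paste0(strrep("G", 100), "ACGTACGTACGT"), 0L)
  expect_false(call_polya_tail(r2)$polya)

  # - read: tail appears as a leading T-run (strand symmetry)
  r3 <- aln_records("c", TRUE, "chr1", 101L, 200L, "-", "12S100M",
                    paste0(strrep("T", 12), strrep("G", 100)), 0L)
  call3 <- call_polya_tail(r3)
  expect_true(call3$polya)
  expect_equal(call3$tail_length, 12L)
  expect_equal(call3$clip_side, "left")

  # no clip at all -> absent, not an error
  expect_false(call_polya_tail(make_record())$polya)
})

test_that("poly(A) caller matches the exhaustive prefix-scan oracle", {
  set.seed(42)
  n <- 1000
  params <- list(min_len = 10L, min_frac = 0.8, scan = 60L)
  for (i in seq_len(n)) {
    len <- sample(0:80, 1)
    bias <- sample(c(0.25, 0.6, 0.8, 0.9, 1.0), 1)
    clip <- if (len > 0) random_clip(len, bias) else ""
    strand <- sample(c("+", "-"), 1)
    if (strand == "+") {
      seq <- paste0(strrep("G", 50), clip)
      cig <- if (len > 0) sprintf("50M%dS", len) else "50M"
      r <- aln_records("x", TRUE, "chr1", 1L, 50L, "+", cig, seq, 0L)
      oracle <- oracle_polya(clip, "A", params$min_len, params$min_frac,
                             params$scan)
    } else {
      rc <- reverse_string(clip)
      seq <- paste0(rc, strrep("G", 50))
      cig <- if (len > 0) sprintf("%dS50M", len) else "50M"
      r <- aln_records("x", TRUE, "chr1", 1L, 50L, "-", cig, seq, 0L)
      oracle <- oracle_polya(clip, "T", params$min_len, params$min_frac,
                             params$scan)
    }
    got <- call_polya_tail(r, params$min_len, params$min_frac, params$scan)
    expect_identical(got$polya, oracle$present)
    expect_identical(got$tail_length, oracle$len)
  }
})

test_that("CAGE support is window-bounded and strand-aware", {
  cage <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000L, 1020L),
                                 strand = "+")
  at <- function(pos, strand = "+") {
    cig <- "100M"
    start <- if (strand == "+") pos else pos - 99L
    aln_records("x", TRUE, "chr1", start, start + 99L, strand, cig,
                strrep("A", 100), 0L)
  }
  # 5' end exactly at the cluster start
  expect_true(call_cage_support(at(1000L), cage)$cage)
  expect_equal(call_cage_support(at(1000L), cage)$cage_distance, 0)
  # 50 bp outside is still in, 51 bp is out
  expect_true(call_cage_support(at(1070L), cage, window = 50L)$cage)
  expect_false(call_cage_support(at(1071L), cage, window = 50L)$cage)
  expect_equal(call_cage_support(at(1071L), cage)$cage_distance, 51)
  # same coordinate, opposite strand -> unsupported
  expect_false(call_cage_support(at(1000L, "-"), cage)$cage)
})

test_that("categories are the deterministic function of the two flags", {
  cage <- GenomicRanges::GRanges("chr1", IRanges::IRanges(90L, 110L),
                                 strand = "+")
  tailseq <- paste0(strrep("G", 100), strrep("A", 15))
  both <- aln_records("a", TRUE, "chr1", 100L, 199L, "+", "100M15S",
                      tailseq, 0L)
  none <- aln_records("b", TRUE, "chr1", 5000L, 5099L, "+", "100M",
                      strrep("G", 100), 0L)
  tail_only <- aln_records("c", TRUE, "chr1", 5000L, 5099L, "+", "100M15S",
                           tailseq, 0L)
  cage_only <- aln_records("d", TRUE, "chr1", 100L, 199L, "+", "100M",
                           strrep("G", 100), 0L)
  comp <- classify_completeness(bind_records(both, none, tail_only,
                                             cage_only), cage)
  expect_equal(as.character(comp$category),
               c("five_three", "unsupported", "three_only", "five_only"))
  # empty input -> empty output
  expect_equal(nrow(classify_completeness(make_record()[integer(), ], cage)),
               0L)
})

test_that("classification is order-invariant and partitions every stratum", {
  lib <- fix_lib_default()
  b <- fix_bundle()
  comp <- classify_completeness(lib$records, b$cage,
                                exclude_chroms = spike_chroms())
  n_expected <- sum(lib$records$mapped &
                      !lib$records$chrom %in% spike_chroms())
  expect_equal(nrow(comp), n_expected)
  expect_equal(sum(table(comp$category)), n_expected)
  s <- completeness_summary(comp)
  for (st in c("all", "spliced", "unspliced")) {
    f <- s$fractions[s$fractions$stratum == st, ]
    expect_equal(sum(f$n), sum(switch(st, all = rep(TRUE, nrow(comp)),
                                      spliced = comp$spliced,
                                      unspliced = !comp$spliced)))
    if (sum(f$n) > 0) expect_equal(sum(f$fraction), 1)
  }
  set.seed(6)
  perm <- lib$records[sample(nrow(lib$records)), ]
  class(perm) <- class(lib$records)
  comp2 <- classify_completeness(perm, b$cage,
                                 exclude_chroms = spike_chroms())
  expect_equal(comp[order(comp$qname), ]$category,
               comp2[order(comp2$qname), ]$category)
})

test_that("noise-free classification recovers the truth categories", {
  lib <- fix_lib_clean()
  b <- fix_bundle()
  comp <- classify_completeness(lib$records, b$cage,
                                exclude_chroms = spike_chroms())
  tr <- lib$truth[match(comp$qname, lib$truth$qname), ]
  expected <- truth_category(tr)
  agree <- mean(as.character(comp$category) == expected)
  expect_gte(agree, 0.99)
})

test_that("motif validation finds planted signals and nothing else", {
  # genome with AATAAA ending 20 nt upstream of the cleavage site at 200
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("C", 174), "AATAAA", strrep("C", 140))))
  plus <- aln_records("a", TRUE, "chr1", 101L, 200L, "+", "100M",
                      strrep("G", 100), 0L)
  expect_true(validate_polya_motif(plus, g))
  # interval [10,40] excludes a motif 5 nt upstream
  g2 <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("C", 189), "AATAAA", strrep("C", 125))))
  expect_false(validate_polya_motif(plus, g2))
  # motif only on the opposite strand (literal AATAAA downstream of a -
  # read cleavage is TTTATT in transcript sense -> no support)
  minus <- aln_records("b", TRUE, "chr1", 101L, 200L, "-", "100M",
                       strrep("G", 100), 0L)
  expect_false(validate_polya_motif(minus, g))
  # the reverse complement at the right spot does support a - read
  g3 <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("C", 120), "TTTATT", strrep("C", 194))))
  expect_true(validate_polya_motif(minus, g3))
})

test_that("motif support equals the planted fraction on clean tails", {
  lib <- fix_lib_clean()
  b <- fix_bundle()
  tr <- lib$truth
  tx <- b$annotation$transcripts
  # complete transcriptome reads end exactly at annotated cleavage sites
  full <- tr$mapped & tr$source_class == "transcript" & tr$five_complete
  recs <- lib$records[lib$records$qname %in% tr$qname[full], ]
  flags <- validate_polya_motif(recs, b$genome)
  planted <- tx$motif_planted[match(tr$source_id[match(recs$qname,
                                                       tr$qname)],
                                    tx$transcript_id)]
  expect_identical(unname(flags), unname(planted))
})

test_that("support-by-length bins are well formed", {
  lib <- fix_lib_default()
  b <- fix_bundle()
  comp <- classify_completeness(lib$records, b$cage,
                                exclude_chroms = spike_chroms())
  tab <- support_by_length(comp, seq(0, 4000, by = 500))
  occupied <- tab$n > 0
  expect_true(all(abs(rowSums(tab[occupied, category_levels()]) - 1) < 1e-9))
  expect_true(all(is.na(tab[!occupied, "five_three"])))
  expect_error(support_by_length(comp, c(100, 50)), "increasing")
  # single occupied bin when all reads share one length/category
  one <- data.frame(read_length = rep(1000L, 5), spliced = TRUE,
                    category = factor(rep("five_three", 5),
                                      levels = category_levels()))
  t1 <- support_by_length(one, c(0, 600, 1200))
  expect_equal(t1$five_three, c(NA, 1))
})
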