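# Spike-in counting, detection, regression, limits, unit conversions and
# isoform reconstruction classes.

test_that("molar-to-molecule and per-cell conversions follow the formulas", {
  # 1 attomol undiluted in 1 ul is Avogadro x 1e-18 molecules
  expect_equal(amount_to_molecules(1, 1, 1), 602214, tolerance = 1e-6)
  expect_equal(amount_to_molecules(0, 100, 4), 0)
  expect_error(amount_to_molecules(-1, 100, 4), "negative")
  # 4 ug of RNA at 5 pg per cell is 800,000 cell equivalents
  expect_equal(molecules_per_cell(800000, 4, 5), 1.0)
  expect_equal(molecules_per_cell(0, 4, 5), 0)
  expect_error(molecules_per_cell(100, 0, 5), "positive")
  # linearity and scale invariance of the composition
  expect_equal(amount_to_molecules(2, 100, 4),
               2 * amount_to_molecules(1, 100, 4))
  expect_equal(
    molecules_per_cell(amount_to_molecules(3 * 0.05, 3 * 100, 4)),
    molecules_per_cell(amount_to_molecules(0.05, 100, 4)))
})

test_that("detection rate is the fraction of controls above threshold", {
  counts <- data.frame(id = sprintf("E%02d", 1:92), class = "ERCC",
                       count = c(rep(5L, 69), rep(0L, 23)))
  expect_equal(unname(detection_rate(counts)), 69 / 92)
  counts$count <- 1L
  expect_equal(unname(detection_rate(counts)), 1.0)
  counts$count <- 0L
  expect_equal(unname(detection_rate(counts)), 0.0)
  expect_error(detection_rate(counts[integer(), ]), "empty")
  expect_error(detection_rate(counts, min_reads = 0), ">= 1")
})

test_that("the log-log fit matches exact and degenerate cases", {
  design <- data.frame(id = paste0("E", 1:10), class = "ERCC",
                       concentration_attomol_ul = 10^seq(0, 3,
                                                         length.out = 10))
  counts <- data.frame(id = design$id, class = "ERCC",
                       count = 10 * design$concentration_attomol_ul)
  fit <- fit_concentration_response(counts, design)
  expect_equal(fit$slope, 1.0, tolerance = 1e-12)
  expect_equal(fit$intercept, 1.0, tolerance = 1e-12)
  expect_equal(fit$correlation, 1.0, tolerance = 1e-12)
  counts$count[3:10] <- 0L
  expect_error(fit_concentration_response(counts, design), "degenerate")
})

test_that("Poisson regression recovery holds across depths, vs the OLS
           oracle", {
  # the detected-only log-log fit is consistent once sequencing depth puts
  # most of the ladder above zero counts (as in real libraries that detect
  # the majority of the controls); slope recovery is checked at 5 depths
  conc <- 10^seq(-1.5, 3.5, length.out = 92) # 5-decade, 92-point ladder
  design <- data.frame(id = sprintf("E%02d", 1:92), class = "ERCC",
                       concentration_attomol_ul = conc)
  for (depth in c(50, 150, 500, 1500, 5000)) {
    slopes <- numeric(50)
    for (seed in 1:50) {
      set.seed(seed)
      counts <- data.frame(id = design$id, class = "ERCC",
                           count = rpois(92, lambda = depth * conc))
      fit <- fit_concentration_response(counts, design)
      pos <- counts$count > 0
      oracle <- oracle_ols(log10(conc[pos]), log10(counts$count[pos]))
      expect_lt(abs(fit$slope - oracle["slope"]), 1e-10)
      expect_lt(abs(fit$intercept - oracle["intercept"]), 1e-10)
      slopes[seed] <- fit$slope
    }
    expect_lt(abs(mean(slopes) - 1), 0.1)
  }
})

test_that("detection limit walks the ladder from the top", {
  design <- data.frame(id = paste0("E", 1:6), class = "ERCC",
                       concentration_attomol_ul = 10^(0:5))
  all_in <- data.frame(id = design$id, class = "ERCC", count = 2L)
  expect_equal(estimate_detection_limit(all_in, design), 1)
  only_top <- data.frame(id = design$id, class = "ERCC",
                         count = c(0L, 0L, 0L, 0L, 0L, 3L))
  expect_equal(estimate_detection_limit(only_top, design), 1e5)
  none <- data.frame(id = design$id, class = "ERCC", count = 0L)
  expect_true(is.na(estimate_detection_limit(none, design)))
  # a gap in the middle pushes the limit above it
  gap <- data.frame(id = design$id, class = "ERCC",
                    count = c(1L, 1L, 0L, 1L, 1L, 1L))
  expect_equal(estimate_detection_limit(gap, design), 1e3)
})

test_that("the detection-limit estimator finds the expected rung", {
  # 6 rungs, 10x apart, 4 controls each; expected counts cross 1 between
  # rung 3 (E=0.5) and rung 4 (E=5): the limit should land on rung 4
  rung_e <- c(0.005, 0.05, 0.5, 5, 50, 500)
  design <- data.frame(id = sprintf("S%02d", 1:24), class = "ERCC",
                       concentration_attomol_ul = rep(rung_e, each = 4))
  hits <- 0
  for (seed in 1:100) {
    set.seed(seed)
    counts <- data.frame(id = design$id, class = "ERCC",
                         count = rpois(24, design$concentration_attomol_ul))
    lim <- estimate_detection_limit(counts, design)
    if (!is.na(lim) && lim == 5) hits <- hits + 1
  }
  expect_gte(hits / 100, 0.9)
})

test_that("per-read transcript models match the base-walk oracle", {
  # worked examples
  ch <- read_to_transcript_model("50M100N50M", 1001L)
  expect_equal(ch$start, c(1001L, 1151L))
  expect_equal(ch$end, c(1050L, 1200L))
  expect_equal(read_to_transcript_model("100M", 501L),
               data.frame(start = 501L, end = 600L))
  # short skips below min_intron merge into the exon
  expect_equal(nrow(read_to_transcript_model("50M20N50M", 1L, 40L)), 1L)
  # random CIGARs vs the oracle
  set.seed(13)
  for (k in 1:100) {
    nops <- sample(3:9, 1)
    ops <- sample(c("M", "I", "D", "N"), nops, replace = TRUE,
                  prob = c(0.5, 0.15, 0.15, 0.2))
    ops[c(1, nops)] <- "M"
    lens <- ifelse(ops == "N", sample(10:200, nops, replace = TRUE),
                   sample(1:100, nops, replace = TRUE))
    cig <- paste0(lens, ops, collapse = "")
    got <- read_to_transcript_model(cig, 5000L, 40L)
    want <- oracle_read_chain(cig, 5000L, 40L)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("reference comparison distinguishes full, partial and none", {
  ref <- data.frame(start = c(100L, 500L, 900L),
                    end = c(200L, 600L, 1000L))
  # identical chain, ends within the window
  q1 <- data.frame(start = c(130L, 500L, 900L), end = c(200L, 600L, 980L))
  expect_equal(compare_to_reference(q1, ref, 50L), "full_match")
  # missing the first intron
  q2 <- data.frame(start = 520L, end = 980L)
  expect_equal(compare_to_reference(q2, ref, 50L), "partial_overlap")
  # disjoint
  q3 <- data.frame(start = 2000L, end = 2100L)
  expect_equal(compare_to_reference(q3, ref, 50L), "none")
  # ends outside the window demote to partial
  q4 <- data.frame(start = c(260L, 500L, 900L), end = c(200L, 600L, 1000L))
  q4 <- data.frame(start = c(100L, 500L, 900L), end = c(200L, 600L, 1060L))
  expect_equal(compare_to_reference(q4, ref, 50L), "partial_overlap")
  # single-exon reference: unspliced overlap with both ends in window
  ref1 <- data.frame(start = 100L, end = 1000L)
  expect_equal(compare_to_reference(data.frame(start = 120L, end = 1010L),
                                    ref1, 50L), "full_match")
  expect_equal(compare_to_reference(data.frame(start = 400L, end = 1000L),
                                    ref1, 50L), "partial_overlap")
})

test_that("spike-in counting attributes reads and warns on silence", {
  b <- fix_bundle()
  lib <- fix_lib_clean()
  counts <- count_spikein_reads(lib$records, b$design, b$annotation)
  expect_equal(nrow(counts), nrow(b$design))
  tr <- lib$truth
  spike_truth <- table(tr$source_id[tr$source_class == "ERCC" & tr$mapped])
  for (id in names(spike_truth))
    expect_equal(counts$count[counts$id == id],
                 as.integer(spike_truth[[id]]))
  # no reads at all on spike contigs -> zero counts and a warning
  main_only <- lib$records[lib$records$mapped &
                             !lib$records$chrom %in% spike_chroms(), ]
  class(main_only) <- class(lib$records)
  expect_warning(z <- count_spikein_reads(main_only, b$design,
                                          b$annotation), "no reads")
  expect_true(all(z$count == 0L))
})

test_that("SIRV levels partition the design and match worked examples", {
  b <- fix_bundle()
  sirv <- b$design[b$design$class == "SIRV", ]
  ann <- b$annotation
  # build one full-length read for the first SIRV isoform
  tid <- sirv$id[1]
  ex <- transcript_exon_table(ann, tid)
  cig <- mk_spliced_cigar(ex)
  qlen <- sum(ex$end - ex$start + 1L)
  full_read <- aln_records("full", TRUE, sirv$chrom[1], ex$start[1],
                           ex$end[nrow(ex)], sirv$strand[1], cig,
                           strrep("A", qlen), 0L)
  res <- classify_sirv_levels(full_read, b$design, ann)
  expect_equal(as.character(res$levels$level[res$levels$id == tid]),
               "end_to_end")
  # every level is one of the three classes and counts partition 69
  expect_equal(sum(res$level_counts), 69L)
  # a terminal-exon-only read is at best partial for multi-exon isoforms
  last <- ex[nrow(ex), ]
  part_read <- aln_records("part", TRUE, sirv$chrom[1], last$start,
                           last$end, sirv$strand[1],
                           paste0(last$end - last$start + 1L, "M"),
                           strrep("A", last$end - last$start + 1L), 0L)
  res2 <- classify_sirv_levels(part_read, b$design, ann)
  multi <- res2$levels$id %in%
    b$annotation$transcripts$transcript_id[
      b$annotation$transcripts$n_exons > 1]
  expect_false(any(res2$levels$level[multi] == "end_to_end"))
  # contigs without reads are entirely absent
  other <- res2$levels$id[!res2$levels$id %in%
                            sirv$id[sirv$chrom == sirv$chrom[1]]]
  expect_true(all(res2$levels$level[res2$levels$id %in% other] == "absent"))
})

test_that("clean-library SIRV levels equal a truth-model recount", {
  b <- fix_bundle()
  lib <- fix_lib_clean()
  res <- classify_sirv_levels(lib$records, b$design, b$annotation)
  # with p_cap5 < 1 truncated SIRV reads exist; recount expected levels
  # from the truth table plus reference models only (independent of the
  # per-read CIGAR walk): a complete read of isoform s realises s's model
  tr <- lib$truth
  sirv <- b$design[b$design$class == "SIRV", ]
  models <- lapply(setNames(sirv$id, sirv$id), function(tid)
    transcript_exon_table(b$annotation, tid))
  complete_src <- unique(tr$source_id[tr$mapped & tr$source_class == "SIRV" &
                                        tr$five_complete])
  any_src_by_chrom <- split(tr$source_id[tr$mapped &
                                           tr$source_class == "SIRV"],
                            sirv$chrom[match(tr$source_id[tr$mapped &
                                                            tr$source_class == "SIRV"],
                                             sirv$id)])
  for (j in seq_len(nrow(sirv))) {
    tid <- sirv$id[j]
    full_expected <- any(vapply(complete_src[complete_src %in%
                                               sirv$id[sirv$chrom == sirv$chrom[j]]],
                                function(s)
                                  compare_to_reference(models[[s]],
                                                       models[[tid]]) ==
                                  "full_match", logical(1)))
    lv <- as.character(res$levels$level[res$levels$id == tid])
    if (full_expected) expect_equal(lv, "end_to_end")
    srcs <- any_src_by_chrom[[sirv$chrom[j]]]
    if (is.null(srcs) || length(srcs) == 0)
      expect_equal(lv, "absent")
  }
})
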