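test_that("bedGraph tracks parse; gap queries average in zeros", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t100\t10", "chr1\t100\t200\t20", "chr1\t300\t400\t5"), f)
  tr <- read_bedgraph(f)
  expect_equal(nrow(tr), 3L)
  expect_equal(track_mean_depth(tr, "chr1", 0, 100), 10)
  # query spanning the 200-300 gap
  expect_equal(track_mean_depth(tr, "chr1", 150, 350),
               mean(per_base_depth_oracle(tr, "chr1", 150, 350)))

  empty <- withr::local_tempfile(fileext = ".bedgraph")
  file.create(empty)
  tr0 <- read_bedgraph(empty)
  expect_equal(nrow(tr0), 0L)
  expect_equal(track_mean_depth(tr0, "chr1", 0, 50), 0)

  bad <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t100\t10", "chr1\t50\t150\t20"), bad)
  expect_error(read_bedgraph(bad), "overlap")
})

test_that("flat coverage yields no promoter candidates at any threshold > 1", {
  gene <- make_toy_gene(sim_config(seed = 14))
  tx <- gene$transcripts$main
  span <- range(c(tx$exons$start, tx$exons$end))
  flat <- coverage_track(data.frame(contig = tx$exons$contig[1],
                                    start = span[1], end = span[2], depth = 10))
  cand <- score_intronic_windows(flat, tx)
  expect_equal(cand$fold_score, rep(10 / 11, nrow(cand)))
  for (thr in c(1.5, 2, 5, 10))
    expect_equal(nrow(call_promoter_candidates(cand, thr)), 0L)
})

test_that("an elevated upstream window is scored by plain fold arithmetic", {
  gene <- make_toy_gene(sim_config(seed = 14))
  tx <- gene$transcripts$main
  pe <- gene$promoter_exon
  contig <- tx$exons$contig[1]
  span <- range(c(tx$exons$start, tx$exons$end))
  ex <- tx$exons[tx$exons$index == pe, ]
  w <- 500L
  tr <- coverage_track(data.frame(
    contig = contig,
    start = c(span[1], ex$start - w, ex$start),
    end = c(ex$start - w, ex$start, span[2]),
    depth = c(10, 100, 10)))
  cand <- score_intronic_windows(tr, tx, window_size = w)
  row <- cand[cand$exon_index == pe, ]
  expect_equal(row$window_mean_depth, 100)
  expect_equal(row$background_depth, 10)
  expect_equal(row$fold_score, 100 / 11, tolerance = 1e-12)
  called <- call_promoter_candidates(cand, 5)
  expect_equal(called$exon_index, pe)
})

test_that("threshold sweeps are monotone: raising it never adds candidates", {
  gene <- make_toy_gene(sim_config(seed = 15))
  trk <- simulate_coverage_with_promoter(sim_config(seed = 15), gene)
  cand <- score_intronic_windows(trk, gene$transcripts$main)
  thr <- c(1.5, 2, 3, 5, 8, 12)
  ns <- vapply(thr, function(t) nrow(call_promoter_candidates(cand, t)), integer(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("promoter detection is strand-invariant", {
  cfg <- sim_config(seed = 16)
  gene <- make_toy_gene(cfg)
  trk <- simulate_coverage_with_promoter(cfg, gene)
  called <- call_promoter_candidates(score_intronic_windows(trk, gene$transcripts$main))
  expect_equal(called$exon_index, gene$promoter_exon)

  mir <- mirror_gene(gene)
  Lc <- nchar(gene$genome$sequences[[1]])
  mtrk <- coverage_track(data.frame(contig = trk$contig,
                                    start = Lc - trk$end, end = Lc - trk$start,
                                    depth = trk$depth))
  mcalled <- call_promoter_candidates(score_intronic_windows(mtrk, mir$transcripts$main))
  expect_equal(mcalled$exon_index, called$exon_index)
})

test_that("peak overlap is half-open and matches brute-force intersection", {
  gene <- make_toy_gene(sim_config(seed = 14))
  tx <- gene$transcripts$main
  span <- range(c(tx$exons$start, tx$exons$end))
  flat <- coverage_track(data.frame(contig = tx$exons$contig[1],
                                    start = span[1], end = span[2], depth = 10))
  cand <- score_intronic_windows(flat, tx)
  w1 <- cand[1, ]
  inside <- data.frame(contig = tx$exons$contig[1],
                       start = w1$window_start + 2L, end = w1$window_start + 10L)
  out <- annotate_with_peaks(cand, inside, "dnase")
  expect_true(out$peak_dnase[1])
  expect_false(any(out$peak_dnase[-1]))
  # abutting interval (peak end == window start) does not overlap
  abut <- data.frame(contig = tx$exons$contig[1],
                     start = w1$window_start - 50L, end = w1$window_start)
  out <- annotate_with_peaks(cand, abut, "h3k4me3")
  expect_false(out$peak_h3k4me3[1])
  # random peaks against O(n*m) brute force
  withr::with_seed(33, {
    for (i in 1:10) {
      pk <- data.frame(contig = tx$exons$contig[1],
                       start = sample(span[1]:span[2], 15))
      pk$end <- pk$start + sample(10:400, 15, replace = TRUE)
      got <- annotate_with_peaks(cand, pk, "p")$peak_p
      brute <- vapply(seq_len(nrow(cand)), function(j)
        any(cand$window_start[j] < pk$end & pk$start < cand$window_end[j]),
        logical(1))
      expect_equal(got, brute)
    }
  })
})

test_that("BED peaks round-trip through the reader", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t250\tpeak1\t900\t.", "chr1\t400\t500\tpeak2\t800\t."), f)
  pk <- read_peaks_bed(f)
  expect_equal(pk$start, c(100L, 400L))
  expect_equal(pk$end, c(250L, 500L))
})

test_that("the internal initiator search finds the planted in-frame ATG", {
  for (seed in c(3, 8, 21)) {
    gene <- make_toy_gene(sim_config(seed = seed))
    fs <- find_internal_start(gene$genome, gene$transcripts$main,
                              gene$promoter_exon, gene$tss_position)
    expect_true(fs$found)
    expect_equal(fs$atg_position, gene$atg_position)
    expect_equal(fs$aa_offset, gene$expected_aa_offset)
    # and on the mirrored minus-strand gene
    mir <- mirror_gene(gene)
    fsm <- find_internal_start(mir$genome, mir$transcripts$main,
                               mir$promoter_exon, mir$tss_position)
    expect_equal(fsm$aa_offset, fs$aa_offset)
    expect_equal(fsm$atg_position, mir$atg_position)
  }
})

test_that("out-of-frame ATGs upstream of the initiator are passed over", {
  gene <- make_toy_gene(sim_config(seed = 3))
  tx <- gene$transcripts$main
  pe <- gene$promoter_exon
  edge <- tx$exons$start[tx$exons$index == pe]
  p <- exon_phase(tx, pe)
  # plant a decoy ATG upstream of the real one, at an out-of-frame distance
  d_real <- edge - gene$atg_position
  d_decoy <- d_real + 7L                      # 7 shifts frame for any phase
  stopifnot((d_decoy %% 3L) != (d_real %% 3L))
  contig <- gene$genome$sequences[[1]]
  substr(contig, edge - d_decoy + 1L, edge - d_decoy + 3L) <- "ATG"
  g2 <- GenomeSequence(stats::setNames(contig, names(gene$genome$sequences)))
  fs <- find_internal_start(g2, tx, pe, gene$tss_position)
  expect_true(fs$found)
  expect_equal(fs$atg_position, gene$atg_position)  # decoy skipped

  expect_error(find_internal_start(gene$genome, tx, pe, edge + 5L),
               "precondition")
})
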