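test_that("FASTA reading loads, uppercases and indexes all records", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 description text", "acgt", ">chr2", "GGGTTTAA"), f)
  g <- read_genome_fasta(f)
  expect_setequal(contig_names(g), c("chr1", "chr2"))
  expect_equal(unname(contig_lengths(g)[c("chr1", "chr2")]), c(4L, 8L))
  expect_equal(genome_fetch(g, "chr1", 0, 4), "ACGT")
  expect_equal(genome_fetch(g, "chr2", 0, 8), "GGGTTTAA")

  empty <- withr::local_tempfile(fileext = ".fa")
  file.create(empty)
  expect_error(read_genome_fasta(empty), "line 1")
  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c("ACGT"), bad)
  expect_error(read_genome_fasta(bad), "line 1")
})

test_that("interval fetch respects bounds and strand", {
  g <- GenomeSequence(c(c1 = "AACCGGTTAA"))
  expect_equal(nchar(genome_fetch(g, "c1", 2, 7)), 5L)
  # reverse-strand fetch equals the Biostrings reverse complement
  fwd <- genome_fetch(g, "c1", 1, 9)
  expect_equal(genome_fetch(g, "c1", 1, 9, strand = "-"),
               as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd))))
  expect_error(genome_fetch(g, "c1", -1, 4), "out of bounds")
  expect_error(genome_fetch(g, "c1", 0, 11), "out of bounds")
  expect_error(genome_fetch(g, "nope", 0, 2), "unknown contig")
  expect_error(GenomeSequence(c(a = "ACGT", a = "GGCC")), "duplicate")
})

test_that("GFF coordinates convert 1-based inclusive to 0-based half-open", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tmRNA\t100\t150\t.\t+\t.\tID=tx1",
               "chr1\tsrc\texon\t100\t150\t.\t+\t.\tParent=tx1",
               "chr1\tsrc\tCDS\t100\t150\t.\t+\t0\tParent=tx1"), f)
  tx <- read_gene_models_gff(f)[["tx1"]]
  expect_equal(tx$exons$start, 99L)
  expect_equal(tx$exons$end, 150L)
  expect_equal(tx$exons$end - tx$exons$start, 51L)
})

test_that("GFF round trip preserves models; minus strand ranks right-to-left", {
  tg <- tiny_gene()
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models_gff3(list(tg$tx), f)
  back <- read_gene_models_gff(f)[["tiny-201"]]
  expect_equal(back$exons$start, tg$tx$exons$start)
  expect_equal(back$exons$end, tg$tx$exons$end)
  expect_equal(back$exons$index, 1:3)
  expect_equal(back$cds_start, tg$tx$cds_start)
  expect_equal(back$cds_end, tg$tx$cds_end)

  gene <- make_toy_gene(sim_config(seed = 2))
  mir <- mirror_gene(gene)
  fm <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models_gff3(list(mir$transcripts$main), fm)
  mtx <- read_gene_models_gff(fm)[[1]]
  expect_equal(mtx$strand, "-")
  # on the minus strand, exon 1 sits at the highest genomic coordinates
  expect_equal(order(mtx$exons$start, decreasing = TRUE), mtx$exons$index)
  expect_error(read_gene_models_gff(withr::local_tempfile(fileext = ".gff3")),
               "exist")
})

test_that("spliced CDS matches construction on both strands", {
  tg <- tiny_gene()
  expect_equal(spliced_cds(tg$tx, tg$genome), TINY_CDS)
  expect_equal(spliced_cds(tg$tx, tg$genome), spliced_cds_oracle(tg$tx, tg$genome))
  for (seed in 1:3) {
    gene <- make_toy_gene(sim_config(seed = seed))
    mir <- mirror_gene(gene)
    expect_identical(spliced_cds(mir$transcripts$main, mir$genome),
                     spliced_cds(gene$transcripts$main, gene$genome))
  }
})

test_that("translation follows the standard code and halts at the first stop", {
  expect_equal(translate_cds("ATGGAATAA"),
               list(protein = "ME", stopped = TRUE, stop_codon_index = 3L))
  expect_equal(translate_cds("ATGGAA"),
               list(protein = "ME", stopped = FALSE, stop_codon_index = NA_integer_))
  expect_equal(translate_cds("ATGGAATAAC")$protein, "ME")  # trailing base ignored
  expect_error(translate_cds(""), "empty")
  withr::with_seed(99, {
    for (i in 1:10) {
      s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
      got <- translate_cds(s)
      exp <- translate_oracle(s)
      expect_equal(got$protein, exp$protein)
      expect_equal(got$stopped, exp$stopped)
    }
  })
})

test_that("exon phases equal the cumulative coding-length oracle", {
  tg <- tiny_gene()
  expect_equal(exon_phase(tg$tx, 1), 0L)
  expect_equal(exon_phase(tg$tx, 2), 10L %% 3L)
  expect_equal(exon_phase(tg$tx, 3), 25L %% 3L)
  gene <- make_toy_gene(sim_config(seed = 4))
  tx <- gene$transcripts$main
  cum <- 0L
  for (k in seq_len(n_exons(tx))) {
    expect_equal(exon_phase(tx, k), cum %% 3L)
    cum <- cum + exon_coding_length(tx, k)
  }
  # phases are invariant under strand mirroring
  mir <- mirror_gene(gene)
  for (k in seq_len(n_exons(tx)))
    expect_equal(exon_phase(mir$transcripts$main, k), exon_phase(tx, k))
})

test_that("genomic/protein coordinate maps are mutually inverse over the CDS", {
  tg <- tiny_gene()
  cdspos <- cds_genomic_positions(tg$tx)
  expect_equal(genomic_to_protein(tg$tx, cdspos[1]), 1L)
  expect_equal(genomic_to_protein(tg$tx, cdspos[4]), 2L)
  for (i in seq_along(cdspos)) {
    aa <- genomic_to_protein(tg$tx, cdspos[i])
    expect_equal(aa, (i - 1L) %/% 3L + 1L)
    expect_true(cdspos[i] %in% protein_to_genomic(tg$tx, aa))
    expect_equal(coding_offset_oracle(tg$tx, cdspos[i]), i)
  }
  intronic <- tg$tx$exons$end[1] + 3L
  expect_error(genomic_to_protein(tg$tx, intronic), "out-of-CDS")
})

test_that("translated toy CDS length satisfies 3 * (protein + stop) = CDS", {
  for (seed in 1:5) {
    gene <- make_toy_gene(sim_config(seed = seed))
    tx <- gene$transcripts$main
    cds <- spliced_cds(tx, gene$genome)
    tr <- translate_cds(cds)
    expect_true(tr$stopped)
    expect_equal(3L * (nchar(tr$protein) + 1L), nchar(cds))
  }
})

test_that("orthologous projection interpolates and never extrapolates", {
  map <- data.frame(src_exon = 1:2,
                    src_aa_start = c(1L, 101L), src_aa_end = c(100L, 200L),
                    tgt_aa_start = c(1L, 201L), tgt_aa_end = c(100L, 300L))
  expect_equal(project_orthologous_aa(map, 50), 50L)       # identity interval
  m2 <- data.frame(src_exon = 1, src_aa_start = 1, src_aa_end = 100,
                   tgt_aa_start = 201, tgt_aa_end = 300)
  expect_equal(project_orthologous_aa(m2, 1), 201L)
  expect_equal(project_orthologous_aa(map, 150), 250L)
  expect_true(is.na(project_orthologous_aa(map, 500)))
  # monotone nondecreasing over a dense random map
  withr::with_seed(7, {
    n <- 20
    src_e <- sort(sample(1:10000, 2 * n)); dim(src_e) <- c(2, n)
    tgt_e <- sort(sample(1:20000, 2 * n)); dim(tgt_e) <- c(2, n)
    dm <- data.frame(src_exon = 1:n, src_aa_start = src_e[1, ],
                     src_aa_end = src_e[2, ], tgt_aa_start = tgt_e[1, ],
                     tgt_aa_end = tgt_e[2, ])
    covered <- unlist(lapply(seq_len(n), function(i) src_e[1, i]:src_e[2, i]))
    proj <- project_orthologous_aa(dm, covered)
    expect_true(all(diff(proj) >= 0))
  })
  bad <- data.frame(src_exon = 1:2, src_aa_start = c(1, 50), src_aa_end = c(100, 60),
                    tgt_aa_start = c(1, 50), tgt_aa_end = c(100, 60))
  expect_error(project_orthologous_aa(bad, 10), "overlap")
})

test_that("orthology maps read from TSV and validate", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("src_exon\tsrc_aa_start\tsrc_aa_end\ttgt_aa_start\ttgt_aa_end",
               "1\t1\t100\t1\t100", "2\t101\t200\t201\t300"), f)
  m <- read_orthology_map(f)
  expect_equal(nrow(m), 2L)
  expect_equal(project_orthologous_aa(m, 101), 201L)
})
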