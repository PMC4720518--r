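#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators. One seed fixes
#' every draw: identical configs give identical outputs. Defaults encode the
#' study conditions the analyses assume: junction depth 10,000; true
#' mutant:wild-type ratio 0.225 with 0.1% base error over 10,000 amplicon
#' reads; a 10-fold intronic read accumulation over background in a 500 bp
#' window; a 2:1 isoform abundance ratio; and cohorts mixing N-/C-terminal
#' truncations around the aa 14,760 boundary.
#'
#' @param seed Integer seed driving every draw.
#' @param n_exons Number of exons of the toy gene (>= 6).
#' @param exon_coding_range,intron_range Sampling ranges (bases).
#' @param utr5,utr3,flank Untranslated/flank lengths (bases).
#' @param promoter_exon Exon carrying the internal promoter in its upstream
#'   intron (default `n_exons - 3`).
#' @param tss_upstream TSS distance upstream of that exon (default 110 bp).
#' @param novex_exon Embed a minor-isoform exclusive terminal exon?
#' @param depth Expected reads per junction/region.
#' @param psi_true Per-exon true inclusion level(s) in [0,1].
#' @param nmd_ratio_true True mutant:wild-type transcript ratio.
#' @param nmd_n_reads Amplicon reads to simulate.
#' @param base_error_rate Per-base sequencing error rate.
#' @param background_depth,exon_depth_mult,promoter_fold,promoter_window
#'   Coverage model: intronic background, exon multiplier, promoter-window
#'   fold and width.
#' @param isoform_true_ratio,isoform_region_length Isoform count model.
#' @param cohorts data.frame with `label`, `n`, `trunc_rate`, `p_C`,
#'   `p_novex3` per cohort.
#' @param boundary_aa,protein_length Meta-transcript geometry for cohorts.
#' @return List of class `SimulationConfig`.
#' @export
sim_config <- function(seed = 1L, n_exons = 12L,
                       exon_coding_range = c(45L, 120L),
                       intron_range = c(300L, 600L),
                       utr5 = 30L, utr3 = 30L, flank = 200L,
                       promoter_exon = NULL, tss_upstream = 110L,
                       novex_exon = TRUE,
                       depth = 10000L, psi_true = NULL,
                       nmd_ratio_true = 0.225, nmd_n_reads = 10000L,
                       base_error_rate = 0.001,
                       background_depth = 10, exon_depth_mult = 10,
                       promoter_fold = 10, promoter_window = 500L,
                       isoform_true_ratio = 2.0, isoform_region_length = 100L,
                       cohorts = default_cohorts(),
                       boundary_aa = 14760L, protein_length = 35991L) {
  if (n_exons < 6L) stop("config error: need at least 6 exons")
  if (any(c(nmd_ratio_true / (1 + nmd_ratio_true), base_error_rate, psi_true) < 0 |
          c(nmd_ratio_true / (1 + nmd_ratio_true), base_error_rate, psi_true) > 1))
    stop("config error: fractions must be in [0,1]")
  if (is.null(promoter_exon)) promoter_exon <- n_exons - 3L
  if (promoter_exon < 2L || promoter_exon > n_exons - 1L)
    stop("config error: promoter exon must be internal")
  if (novex_exon && promoter_exon == 3L)
    stop("config error: promoter exon 3 collides with the Novex-role intron")
  structure(mget(names(formals(sim_config))), class = "SimulationConfig")
}

#' Default synthetic cohort structure
#'
#' Four cohorts echoing an end-stage DCM series (C-dominant truncations), an
#' unselected DCM series, pooled literature controls (balanced mix), and a
#' senior-athlete series whose truncations sit N-terminal or in the Novex-3
#' exon.
#' @return data.frame with `label`, `n`, `trunc_rate`, `p_C`, `p_novex3`.
#' @export
default_cohorts <- function() {
  data.frame(label = c("end_stage_DCM", "unselected_DCM", "CTL_lit", "senior_athletes"),
             n = c(250L, 400L, 1500L, 199L),
             trunc_rate = c(0.25, 0.15, 0.012, 0.015),
             p_C = c(30 / 31, 37 / 48, 18 / 38, 0),
             p_novex3 = c(0.02, 0.02, 0.05, 0.5),
             stringsAsFactors = FALSE)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# codons of the standard code that are not stops
non_stop_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# replace every ATG occurrence in a string (middle base -> C), repeatedly
strip_atg <- function(s) {
  repeat {
    i <- regexpr("ATG", s, fixed = TRUE)
    if (i < 0) return(s)
    substr(s, i + 1L, i + 1L) <- "C"
  }
}

#' Generate a miniature Titin-like gene
#'
#' Builds a random-sequence genome containing a multi-exon "mini-titin" on
#' the plus strand: a valid CDS (starts ATG, ends in a stop, length a
#' multiple of 3, no internal stop), GT..AG introns, a designated
#' internal-promoter intron whose last `tss_upstream` bases contain exactly
#' one ATG, planted in frame ~7 codons upstream of the chosen exon, and
#' (optionally) a minor-isoform terminal exon embedded in intron 2 playing
#' the Novex-3 role.
#'
#' @param config A [sim_config()].
#' @return List of class `ToyGene` with `genome`, `transcripts` (named list:
#'   `main`, and `novex` if requested), `promoter_exon`, `tss_position`,
#'   `atg_position`, `expected_aa_offset`, `config`.
#' @export
make_toy_gene <- function(config = sim_config()) {
  withr::with_seed(config$seed, make_toy_gene_impl(config))
}

make_toy_gene_impl <- function(config) {
  n <- config$n_exons
  L <- sample(seq(config$exon_coding_range[1], config$exon_coding_range[2]), n,
              replace = TRUE)
  if (any(L < 3L)) stop("config error: exon coding length below one codon")
  L[n] <- L[n] + (3L - sum(L) %% 3L) %% 3L
  total <- sum(L)
  ncod <- total %/% 3L
  codons <- c("ATG", sample(non_stop_codons(), ncod - 2L, replace = TRUE), "TAA")
  cds <- paste(codons, collapse = "")
  bnd <- cumsum(L)
  chunks <- substring(cds, c(1L, bnd[-n] + 1L), bnd)

  pe <- config$promoter_exon
  phase_pe <- sum(L[seq_len(pe - 1L)]) %% 3L
  ilen <- sample(seq(config$intron_range[1], config$intron_range[2]), n - 1L,
                 replace = TRUE)
  ilen[pe - 1L] <- max(config$promoter_window, config$tss_upstream) + 100L

  # Novex-role exon geometry (embedded in intron 2)
  novex <- NULL
  if (config$novex_exon) {
    r <- sum(L[1:2]) %% 3L                 # bases already in the straddle codon
    compl_len <- (3L - r) %% 3L
    nov_codons <- paste(c(sample(non_stop_codons(), 8L, replace = TRUE), "TAA"),
                        collapse = "")
    nov_coding_len <- compl_len + nchar(nov_codons)
    nov_utr <- 15L
    nov_len <- nov_coding_len + nov_utr
    ilen[2L] <- max(ilen[2L], 30L + nov_len + 30L)
  }

  # introns: GT ... AG
  introns <- vapply(ilen, function(l) {
    if (l < 10L) stop("config error: intron too short")
    paste0("GT", rand_dna(l - 4L), "AG")
  }, character(1))

  # sanitize the promoter intron's TSS window and plant the in-frame ATG
  pi_idx <- pe - 1L
  pintr <- introns[pi_idx]
  plen <- nchar(pintr)
  win0 <- plen - config$tss_upstream + 1L      # 1-based window start in intron
  window <- strip_atg(substr(pintr, win0, plen))
  d <- 21L + ((phase_pe - 21L) %% 3L)          # d == phase (mod 3), d in 21..23
  off_in_win <- config$tss_upstream - d + 1L   # 1-based position of the A
  substr(window, off_in_win, off_in_win + 2L) <- "ATG"
  substr(pintr, win0, plen) <- window
  introns[pi_idx] <- pintr

  # embed the novex exon sequence inside intron 2
  nov_rel <- NA_integer_
  if (config$novex_exon) {
    i2 <- introns[2L]
    repeat {
      straddle_tail <- substr(chunks[2L], nchar(chunks[2L]) - r + 1L, nchar(chunks[2L]))
      compl <- if (compl_len > 0L) rand_dna(compl_len) else ""
      straddle <- paste0(straddle_tail, compl)
      if (r == 0L || Biostrings::GENETIC_CODE[[straddle]] != "*") break
    }
    nov_seq <- paste0(compl, nov_codons, rand_dna(nov_utr))
    nov_rel <- 31L                              # 1-based offset inside intron 2
    substr(i2, nov_rel, nov_rel + nov_len - 1L) <- nov_seq
    introns[2L] <- i2
  }

  # assemble the contig and record coordinates (0-based half-open)
  exon_seqs <- chunks
  exon_seqs[1L] <- paste0(rand_dna(config$utr5), chunks[1L])
  exon_seqs[n] <- paste0(chunks[n], rand_dna(config$utr3))
  pos <- config$flank
  estart <- integer(n); eend <- integer(n)
  pieces <- rand_dna(config$flank)
  istart <- integer(n - 1L)
  for (k in seq_len(n)) {
    estart[k] <- pos
    eend[k] <- pos + nchar(exon_seqs[k])
    pieces <- c(pieces, exon_seqs[k])
    pos <- eend[k]
    if (k < n) {
      istart[k] <- pos
      pieces <- c(pieces, introns[k])
      pos <- pos + nchar(introns[k])
    }
  }
  pieces <- c(pieces, rand_dna(config$flank))
  contig <- paste(pieces, collapse = "")
  genome <- GenomeSequence(c(chrT = contig))

  cds_start <- estart[1L] + config$utr5
  cds_end <- estart[n] + L[n]
  main <- TranscriptModel("miniTTN-201", "+",
                          data.frame(contig = "chrT", start = estart, end = eend,
                                     index = seq_len(n)),
                          cds_start, cds_end)

  transcripts <- list(main = main)
  if (config$novex_exon) {
    nstart <- istart[2L] + nov_rel - 1L
    nend <- nstart + nov_len
    nov_tx <- TranscriptModel("miniTTN-novex", "+",
                              data.frame(contig = "chrT",
                                         start = c(estart[1:2], nstart),
                                         end = c(eend[1:2], nend),
                                         index = 1:3),
                              cds_start, nstart + nov_coding_len)
    transcripts$novex <- nov_tx
  }

  # post-conditions: both models translate cleanly end to end
  for (tx in transcripts) {
    tr <- translate_cds(spliced_cds(tx, genome))
    if (!tr$stopped || grepl("\\*", tr$protein))
      stop("internal error: toy gene CDS does not translate cleanly (", tx$id, ")")
  }

  tss <- estart[pe] - config$tss_upstream
  structure(list(genome = genome, transcripts = transcripts,
                 promoter_exon = pe, tss_position = tss,
                 atg_position = estart[pe] - d,
                 expected_aa_offset = d %/% 3L,
                 config = config),
            class = "ToyGene")
}

#' Mirror a toy gene onto the minus strand
#'
#' Reverse-complements the genome and re-expresses every transcript on the
#' minus strand at mirrored coordinates; transcript order, spliced CDS,
#' phases, and all downstream calls must be invariant under this operation.
#'
#' @param gene A `ToyGene`.
#' @return The mirrored `ToyGene`.
#' @export
mirror_gene <- function(gene) {
  ctg <- names(gene$genome$sequences)[1]
  Lc <- nchar(gene$genome$sequences[[1]])
  genome <- GenomeSequence(stats::setNames(revcomp(gene$genome$sequences[[1]]), ctg))
  flip_tx <- function(tx) {
    ex <- tx$exons
    TranscriptModel(tx$id, if (tx$strand == "+") "-" else "+",
                    data.frame(contig = ex$contig,
                               start = Lc - ex$end, end = Lc - ex$start,
                               index = ex$index),
                    Lc - tx$cds_end, Lc - tx$cds_start)
  }
  out <- gene
  out$genome <- genome
  out$transcripts <- lapply(gene$transcripts, flip_tx)
  out$tss_position <- Lc - 1L - gene$tss_position
  out$atg_position <- Lc - 1L - gene$atg_position
  out
}

#' Simulate exon-exon junction counts
#'
#' Generative model paired with the PSI estimator: with inclusion abundance
#' a = psi and exclusion abundance b = 1 - psi, the two inclusion junctions
#' draw I5, I3 ~ Poisson(depth * a) independently and the skip junction
#' draws X ~ Poisson(depth * b). An including transcript feeds both of its
#' inclusion junctions while a skipping transcript feeds the single skip
#' junction, which is why the estimator doubles X; under this model
#' PSI = (I5+I3)/(I5+I3+2X) converges to a/(a+b).
#'
#' @param config A [sim_config()]; `psi_true` and `depth` are used.
#' @param transcript Optional `TranscriptModel`. When given, terminal exons
#'   receive their single inclusion junction (the other absent) and cannot
#'   be skipped; when `NULL`, every `psi_true` entry is treated as an
#'   internal exon.
#' @return Junction count table (`exon_id`, `I5`, `I3`, `X`).
#' @export
simulate_junction_counts <- function(config, transcript = NULL) {
  psi <- config$psi_true
  if (is.null(psi)) psi <- 1
  depth <- config$depth
  withr::with_seed(config$seed, {
    if (is.null(transcript)) {
      nn <- length(psi)
      data.frame(exon_id = paste0("e", seq_len(nn)),
                 I5 = stats::rpois(nn, depth * psi),
                 I3 = stats::rpois(nn, depth * psi),
                 X = stats::rpois(nn, depth * (1 - psi)),
                 stringsAsFactors = FALSE)
    } else {
      nn <- n_exons(transcript)
      psi <- rep_len(psi, nn)
      I5 <- I3 <- X <- rep(NA_integer_, nn)
      for (k in seq_len(nn)) {
        if (k > 1L) I5[k] <- stats::rpois(1, depth * psi[k])
        if (k < nn) I3[k] <- stats::rpois(1, depth * psi[k])
        if (k > 1L && k < nn) X[k] <- stats::rpois(1, depth * (1 - psi[k]))
      }
      data.frame(exon_id = paste0("e", seq_len(nn)), I5 = I5, I3 = I3, X = X,
                 stringsAsFactors = FALSE)
    }
  })
}

#' Simulate a heterozygote amplicon read set
#'
#' Each read is drawn from the mutant allele with probability r/(1+r)
#' (r = true mutant:wild-type ratio) and copied from a ~100 bp amplicon with
#' a central SNV; independent per-base errors are applied at
#' `base_error_rate`. Truth labels are retained.
#'
#' @param config A [sim_config()]; uses `nmd_ratio_true`, `nmd_n_reads`,
#'   `base_error_rate`.
#' @return List with `reads`, `truth` (`"mutant"`/`"wildtype"`),
#'   `ref_window`, `alt_window` (21-mers centered on the variant),
#'   `amplicon_ref`, `amplicon_alt`.
#' @export
simulate_het_amplicon <- function(config) {
  withr::with_seed(config$seed, {
    alen <- 101L; center <- 51L
    ref <- rand_dna(alen)
    ref_base <- substr(ref, center, center)
    alt_base <- sample(setdiff(c("A", "C", "G", "T"), ref_base), 1L)
    alt <- ref; substr(alt, center, center) <- alt_base
    k <- 10L
    ref_window <- substr(ref, center - k, center + k)
    alt_window <- substr(alt, center - k, center + k)
    r <- config$nmd_ratio_true
    n <- config$nmd_n_reads
    is_mut <- stats::runif(n) < r / (1 + r)
    reads <- ifelse(is_mut, alt, ref)
    n_err <- stats::rbinom(n, alen, config$base_error_rate)
    for (i in which(n_err > 0L)) {
      pos <- sample.int(alen, n_err[i])
      s <- reads[i]
      for (p in pos) {
        substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(s, p, p)), 1L)
      }
      reads[i] <- s
    }
    list(reads = reads, truth = ifelse(is_mut, "mutant", "wildtype"),
         ref_window = ref_window, alt_window = alt_window,
         amplicon_ref = ref, amplicon_alt = alt)
  })
}

#' Simulate a coverage track with an internal-promoter signal
#'
#' Per-base Poisson depth across the gene: introns at the background rate,
#' exons at `background * exon_depth_mult`, and the designated window of the
#' upstream intron adjacent to the promoter exon's 5' edge at
#' `background * promoter_fold`.
#'
#' @param config A [sim_config()].
#' @param gene A `ToyGene` (its `main` transcript and `promoter_exon` are
#'   used).
#' @return A `CoverageTrack`.
#' @export
simulate_coverage_with_promoter <- function(config, gene) {
  tx <- gene$transcripts$main
  pe <- gene$promoter_exon
  ex <- tx$exons
  contig <- ex$contig[1]
  span0 <- min(ex$start); span1 <- max(ex$end)
  withr::with_seed(config$seed, {
    lambda <- rep(config$background_depth, span1 - span0)
    for (k in seq_len(nrow(ex))) {
      idx <- (ex$start[k] - span0 + 1L):(ex$end[k] - span0)
      lambda[idx] <- config$background_depth * config$exon_depth_mult
    }
    intr <- transcript_introns(tx)
    up <- intr[intr$intron_index == pe - 1L, ]
    w <- min(config$promoter_window, up$end - up$start)
    pex <- ex[ex$index == pe, ]
    if (tx$strand == "+") { ws <- pex$start - w; we <- pex$start }
    else { ws <- pex$end; we <- pex$end + w }
    lambda[(ws - span0 + 1L):(we - span0)] <-
      config$background_depth * config$promoter_fold
    depth <- stats::rpois(length(lambda), lambda)
    runs <- rle(depth)
    ends <- span0 + cumsum(runs$lengths)
    starts <- c(span0, ends[-length(ends)])
    coverage_track(data.frame(contig = contig, start = starts, end = ends,
                              depth = runs$values))
  })
}

#' Simulate isoform-specific region counts
#'
#' Poisson read counts over two equal-information isoform-specific regions
#' at a true abundance ratio, the generative counterpart of
#' [isoform_ratio()].
#'
#' @param config A [sim_config()]; uses `isoform_true_ratio`, `depth`,
#'   `isoform_region_length`.
#' @return List with `count_a`, `length_a`, `count_b`, `length_b`,
#'   `true_ratio`.
#' @export
simulate_isoform_counts <- function(config) {
  withr::with_seed(config$seed, {
    list(count_a = stats::rpois(1, config$depth * config$isoform_true_ratio),
         length_a = config$isoform_region_length,
         count_b = stats::rpois(1, config$depth),
         length_b = config$isoform_region_length,
         true_ratio = config$isoform_true_ratio)
  })
}

#' Simulate a cohort truncation table
#'
#' Subjects carry a truncating variant with their cohort's rate; carriers
#' fall in the Novex-3 exon with probability `p_novex3`, otherwise C-terminal
#' to the boundary with probability `p_C`, with amino-acid positions drawn
#' uniformly within the chosen side.
#'
#' @param config A [sim_config()]; uses `cohorts`, `boundary_aa`,
#'   `protein_length`.
#' @return Cohort variant table (`subject_id`, `cohort_label`, `aa_position`,
#'   `novex3`, `truncating`); carriers only.
#' @export
simulate_cohort_variants <- function(config) {
  co <- config$cohorts
  if (any(co$trunc_rate < 0 | co$trunc_rate > 1 | co$p_C < 0 | co$p_C > 1 |
          co$p_novex3 < 0 | co$p_novex3 > 1))
    stop("config error: probabilities must be in [0,1]")
  b <- config$boundary_aa; P <- config$protein_length
  withr::with_seed(config$seed, {
    rows <- lapply(seq_len(nrow(co)), function(i) {
      carrier <- which(stats::runif(co$n[i]) < co$trunc_rate[i])
      if (length(carrier) == 0L) return(NULL)
      nv <- stats::runif(length(carrier)) < co$p_novex3[i]
      cside <- stats::runif(length(carrier)) < co$p_C[i]
      aa <- integer(length(carrier))
      aa[nv] <- sample(4000:6000, sum(nv), replace = TRUE)       # Novex-3 span
      aa[!nv & cside] <- sample(b:P, sum(!nv & cside), replace = TRUE)
      aa[!nv & !cside] <- sample(seq_len(b - 1L), sum(!nv & !cside),
                                 replace = TRUE)
      data.frame(subject_id = sprintf("%s_%04d", co$label[i], carrier),
                 cohort_label = co$label[i], aa_position = aa,
                 novex3 = nv, truncating = TRUE, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(subject_id = character(0), cohort_label = character(0),
                        aa_position = integer(0), novex3 = logical(0),
                        truncating = logical(0), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

# ---- fixture writers -------------------------------------------------------

#' Write a genome to FASTA
#' @param genome A `GenomeSequence`.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write transcript models to GFF3
#' @param transcripts List of `TranscriptModel` objects.
#' @param path Output path.
#' @export
write_gene_models_gff3 <- function(transcripts, path) {
  lines <- "##gff-version 3"
  for (tx in transcripts) {
    ex <- tx$exons
    contig <- ex$contig[1]
    lines <- c(lines, paste(contig, "cronoscan", "mRNA",
                            min(ex$start) + 1L, max(ex$end), ".", tx$strand, ".",
                            paste0("ID=", tx$id), sep = "\t"))
    for (i in seq_len(nrow(ex))) {
      lines <- c(lines, paste(contig, "cronoscan", "exon",
                              ex$start[i] + 1L, ex$end[i], ".", tx$strand, ".",
                              paste0("Parent=", tx$id), sep = "\t"))
      sp <- coding_span(tx, ex$index[i])
      if (!is.null(sp))
        lines <- c(lines, paste(contig, "cronoscan", "CDS",
                                sp[1] + 1L, sp[2], ".", tx$strand, "0",
                                paste0("Parent=", tx$id), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a junction count table to TSV
#' @param table Junction count table.
#' @param path Output path.
#' @export
write_junction_table <- function(table, path) {
  tb <- table
  for (col in c("I5", "I3", "X"))
    tb[[col]] <- ifelse(is.na(tb[[col]]), ".", as.character(tb[[col]]))
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a coverage track to bedGraph
#' @param track A `CoverageTrack`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  utils::write.table(track[, c("contig", "start", "end", "depth")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a cohort variant table to TSV
#' @param table Cohort variant table.
#' @param path Output path.
#' @export
write_cohort_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write synthetic junction-spanning reads as SAM
#'
#' Emits one spliced alignment (`aMbNcM` CIGAR) per requested read: for each
#' intron, `incl_counts[k]` reads spanning the exon k / exon k+1 junction;
#' for each internal exon, `skip_counts[k]` reads whose gap spans the exon.
#' Anchors are 10 bases each side, with sequence taken from the genome.
#' Plus-strand transcripts only (the toy gene is plus-strand; mirrored
#' models are exercised at the junction-table level).
#'
#' @param path Output SAM path.
#' @param transcript A plus-strand `TranscriptModel`.
#' @param genome A `GenomeSequence`.
#' @param incl_counts Integer vector, one per intron.
#' @param skip_counts Integer vector, one per exon (internal entries used).
#' @return `path`, invisibly.
#' @export
write_junction_sam <- function(path, transcript, genome, incl_counts,
                               skip_counts = integer(n_exons(transcript))) {
  stopifnot(transcript$strand == "+")
  ex <- transcript$exons
  contig <- ex$contig[1]
  clen <- nchar(genome$sequences[[contig]])
  anchor <- 10L
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", contig, clen))
  emit <- function(gap_start, gap_end, tag, count) {
    if (count <= 0L) return(character(0))
    pos1 <- gap_start - anchor + 1L          # 1-based alignment start
    cig <- sprintf("%dM%dN%dM", anchor, gap_end - gap_start, anchor)
    seq <- paste0(genome_fetch(genome, contig, gap_start - anchor, gap_start),
                  genome_fetch(genome, contig, gap_end, gap_end + anchor))
    sprintf("%s_%d\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
            tag, seq_len(count), contig, pos1, cig, seq)
  }
  intr <- transcript_introns(transcript)
  for (k in seq_len(nrow(intr)))
    lines <- c(lines, emit(intr$start[k], intr$end[k], paste0("incl", k),
                           incl_counts[k]))
  ne <- n_exons(transcript)
  if (ne >= 3L) for (k in 2:(ne - 1L)) {
    a <- ex[ex$index == k - 1L, ]; b <- ex[ex$index == k + 1L, ]
    lines <- c(lines, emit(a$end, b$start, paste0("skip", k), skip_counts[k]))
  }
  writeLines(lines, path)
  invisible(path)
}
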