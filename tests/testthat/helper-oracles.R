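# Hand-built three-exon gene with a fully known CDS, plus independent
# oracle implementations used to cross-check the package's own paths.

# CDS = ATG AAA CCC GGG TTT AAC CCA GGA TTG AAG TAA -> protein MKPGFNPGLK
TINY_CHUNKS <- c("ATGAAACCCG", "GGTTTAACCCAGGAT", "TGAAGTAA")
TINY_CDS <- paste(TINY_CHUNKS, collapse = "")
TINY_PROTEIN <- "MKPGFNPGLK"

# Assemble a plus-strand gene from coding chunks and explicit intron
# sequences; coordinates are derived by accumulation, nothing hard-coded.
gene_with_introns <- function(introns = c(paste0("GT", strrep("ACTC", 4), "AG"),
                                          paste0("GT", strrep("TGAC", 4), "AG")),
                              chunks = TINY_CHUNKS,
                              utr5 = "GTTCA", utr3 = "CTTAG",
                              flank = "ACGTACGTAC") {
  exon_seqs <- chunks
  exon_seqs[1] <- paste0(utr5, chunks[1])
  n <- length(chunks)
  exon_seqs[n] <- paste0(chunks[n], utr3)
  pieces <- flank
  pos <- nchar(flank)
  estart <- eend <- integer(n)
  for (k in seq_len(n)) {
    estart[k] <- pos
    eend[k] <- pos + nchar(exon_seqs[k])
    pieces <- c(pieces, exon_seqs[k])
    pos <- eend[k]
    if (k < n) {
      pieces <- c(pieces, introns[k])
      pos <- pos + nchar(introns[k])
    }
  }
  pieces <- c(pieces, flank)
  genome <- GenomeSequence(c(chr1 = paste(pieces, collapse = "")))
  tx <- TranscriptModel("tiny-201", "+",
                        data.frame(contig = "chr1", start = estart, end = eend,
                                   index = seq_len(n)),
                        estart[1] + nchar(utr5),
                        estart[n] + nchar(chunks[n]))
  list(genome = genome, tx = tx, cds = paste(chunks, collapse = ""))
}

tiny_gene <- function() gene_with_introns()

# independent translation oracle (Biostrings translate, halt at first stop)
translate_oracle <- function(s) {
  n <- (nchar(s) %/% 3L) * 3L
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(substr(s, 1, n)),
                                           if.fuzzy.codon = "X"))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) list(protein = substr(aa, 1, stop_at - 1), stopped = TRUE,
                        stop_codon_index = as.integer(stop_at))
  else list(protein = aa, stopped = FALSE, stop_codon_index = NA_integer_)
}

# CDS offset (1-based) of a genomic position, by direct accumulation over the
# plus-strand exon table -- independent of cds_genomic_positions()
coding_offset_oracle <- function(tx, pos0) {
  stopifnot(tx$strand == "+")
  off <- 0L
  for (k in seq_len(nrow(tx$exons))) {
    ex <- tx$exons[tx$exons$index == k, ]
    s <- max(ex$start, tx$cds_start); e <- min(ex$end, tx$cds_end)
    if (s >= e) next
    if (pos0 >= s && pos0 < e) return(off + (pos0 - s) + 1L)
    off <- off + (e - s)
  }
  NA_integer_
}

# spliced CDS by direct substring over the contig (plus strand)
spliced_cds_oracle <- function(tx, genome) {
  stopifnot(tx$strand == "+")
  contig <- genome$sequences[[tx$exons$contig[1]]]
  out <- ""
  for (k in seq_len(nrow(tx$exons))) {
    ex <- tx$exons[tx$exons$index == k, ]
    s <- max(ex$start, tx$cds_start); e <- min(ex$end, tx$cds_end)
    if (s < e) out <- paste0(out, substr(contig, s + 1L, e))
  }
  out
}

# expected frameshift/nonsense description by the stated counting rule,
# from reference and mutant translations
protein_change_oracle <- function(ref_tr, mut_tr) {
  rp <- strsplit(ref_tr$protein, "")[[1]]
  mp <- strsplit(mut_tr$protein, "")[[1]]
  nmin <- min(length(rp), length(mp))
  div <- which(rp[seq_len(nmin)] != mp[seq_len(nmin)])
  i <- if (length(div)) div[1] else nmin + 1L
  if (i > length(rp) && i > length(mp)) return(NA_character_)
  if (i > length(mp)) {
    if (!mut_tr$stopped) return(NA_character_)
    return(sprintf("p.%s%dX", rp[i], i))
  }
  if (!mut_tr$stopped) return(sprintf("p.%s%d%sfsX?", rp[i], i, mp[i]))
  sprintf("p.%s%d%sfsX%d", rp[i], i, mp[i], length(mp) - i + 2L)
}

# brute-force protospacer enumeration: every 23-mer window on both strands
# ending in GG, by a plain double loop
brute_pam_scan <- function(seqstr, region_start = 0L) {
  out <- list()
  L <- nchar(seqstr)
  rc <- revcomp(seqstr)
  if (L >= 23L) {
    for (i in 0:(L - 23L)) {
      w <- substr(seqstr, i + 1L, i + 23L)
      if (substr(w, 22L, 23L) == "GG")
        out[[length(out) + 1L]] <- data.frame(protospacer = substr(w, 1, 20),
                                              pam = substr(w, 21, 23),
                                              strand = "+",
                                              position = region_start + i)
      w2 <- substr(rc, i + 1L, i + 23L)
      if (substr(w2, 22L, 23L) == "GG")
        out[[length(out) + 1L]] <- data.frame(protospacer = substr(w2, 1, 20),
                                              pam = substr(w2, 21, 23),
                                              strand = "-",
                                              position = region_start + (L - 23L - i))
    }
  }
  if (!length(out))
    return(data.frame(protospacer = character(0), pam = character(0),
                      strand = character(0), position = integer(0)))
  df <- do.call(rbind, out)
  df[order(df$position, df$strand), ]
}

# naive exact-match count of a pattern on both strands (overlaps allowed)
brute_match_count <- function(site, genome) {
  total <- 0L
  for (seq in genome$sequences) {
    for (pat in c(site, revcomp(site))) {
      L <- nchar(seq); k <- nchar(pat)
      if (L >= k) for (i in 1:(L - k + 1L))
        if (substr(seq, i, i + k - 1L) == pat) total <- total + 1L
    }
  }
  total
}

# per-base expansion of a coverage track over [start, end)
per_base_depth_oracle <- function(track, contig, start, end) {
  d <- numeric(end - start)
  s <- track[track$contig == contig, , drop = FALSE]
  for (i in seq_len(nrow(s))) {
    a <- max(s$start[i], start); b <- min(s$end[i], end)
    if (a < b) d[(a - start + 1L):(b - start)] <- s$depth[i]
  }
  d
}
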