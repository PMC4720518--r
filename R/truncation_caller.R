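#' Consequence call constructor
#'
#' @param category One of `NONSENSE`, `FRAMESHIFT`, `ACCEPTOR_SKIP_FRAMESHIFT`,
#'   `ACCEPTOR_SKIP_INFRAME`, `DONOR_RETENTION_PTC`,
#'   `DONOR_RETENTION_READTHROUGH`, `OTHER`.
#' @param aa_position First affected amino acid (1-based), or `NA`.
#' @param protein_change HGVS-like protein change string, or `NA`.
#' @param detail Free-text detail.
#' @return Object of class `ConsequenceCall`; `truncating` is derived from
#'   the category (never set independently).
#' @export
ConsequenceCall <- function(category, aa_position = NA_integer_,
                            protein_change = NA_character_, detail = "") {
  cats <- c("NONSENSE", "FRAMESHIFT", "ACCEPTOR_SKIP_FRAMESHIFT",
            "ACCEPTOR_SKIP_INFRAME", "DONOR_RETENTION_PTC",
            "DONOR_RETENTION_READTHROUGH", "OTHER")
  category <- match.arg(category, cats)
  truncating <- category %in% c("NONSENSE", "FRAMESHIFT",
                                "ACCEPTOR_SKIP_FRAMESHIFT",
                                "DONOR_RETENTION_PTC")
  structure(list(category = category, truncating = truncating,
                 aa_position = as.integer(aa_position),
                 protein_change = protein_change, detail = detail),
            class = "ConsequenceCall")
}

#' @export
print.ConsequenceCall <- function(x, ...) {
  cat(x$category, if (x$truncating) "[truncating]" else "[non-truncating]",
      if (!is.na(x$protein_change)) x$protein_change else "", "\n")
  invisible(x)
}

#' Normalize a variant's alleles
#'
#' Trims the shared suffix, then the shared prefix (keeping at least one base
#' in each allele, VCF anchor style), adjusting `pos` accordingly. VCF allows
#' several encodings of one indel; classification operates on the trimmed
#' form.
#'
#' @param pos 1-based position of the first ref base.
#' @param ref,alt Allele strings.
#' @return List with normalized `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(pos, ref, alt) {
  if (!nzchar(ref) || !nzchar(alt)) stop("alleles must be non-empty")
  # shared suffix
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  # shared prefix (keep a one-base anchor)
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref)); alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' HGVS-like protein change string
#'
#' Frameshift renders `p.{ref}{pos}{new}fsX{k}` where `pos` is the first
#' divergent residue, `new` the mutant residue there, and `k` the 1-based
#' offset of the new stop counted from `pos` (the stop itself is position
#' `k`). A pure nonsense change renders `p.{ref}{pos}X`. A frameshift with
#' no stop before the end of the mutant reading renders `fsX?`.
#'
#' @param ref_protein Reference protein string.
#' @param mutant_protein Mutant protein string (stop excluded).
#' @param mutant_stopped Did mutant translation reach a stop codon?
#' @return The change string, or `NA` if the proteins are identical.
#' @export
hgvs_p_string <- function(ref_protein, mutant_protein, mutant_stopped = TRUE) {
  rp <- strsplit(ref_protein, "")[[1]]
  mp <- strsplit(mutant_protein, "")[[1]]
  nmin <- min(length(rp), length(mp))
  div <- which(rp[seq_len(nmin)] != mp[seq_len(nmin)])
  i <- if (length(div)) div[1] else nmin + 1L
  if (i > length(rp) && i > length(mp)) return(NA_character_)  # identical
  if (i > length(mp)) {
    # mutant is a proper prefix of ref: residue i replaced by a stop
    if (!mutant_stopped) return(NA_character_)
    return(sprintf("p.%s%dX", rp[i], i))
  }
  new_aa <- mp[i]
  if (!mutant_stopped)
    return(sprintf("p.%s%d%sfsX?", rp[i], i, new_aa))
  k <- length(mp) - i + 2L  # stop codon sits one past the last mutant residue
  sprintf("p.%s%d%sfsX%d", rp[i], i, new_aa, k)
}

#' Consequence of a splice-acceptor variant: exon skipping
#'
#' A canonical acceptor (-1/-2) variant is modelled as skipping the exon.
#' The verdict is purely phase-based: skipping changes the downstream reading
#' frame iff the exon's coding length is not a multiple of 3.
#'
#' @param transcript A `TranscriptModel`.
#' @param exon_index 1-based transcript-order index of the skipped exon
#'   (must be internal and coding).
#' @param genome Optional `GenomeSequence`; when supplied, the frameshift
#'   protein change is computed by re-translating the exon-deleted CDS.
#' @return A [ConsequenceCall()].
#' @export
acceptor_skip_consequence <- function(transcript, exon_index, genome = NULL) {
  ne <- n_exons(transcript)
  if (exon_index <= 1L || exon_index >= ne)
    stop("not-applicable: exon ", exon_index,
         " is terminal; no skip model for first/last exons")
  L <- exon_coding_length(transcript, exon_index)
  if (L == 0L)
    stop("not-applicable: exon ", exon_index, " is non-coding")
  aa_pos <- {
    sp <- coding_span(transcript, exon_index)
    first_base <- if (transcript$strand == "+") sp[1] else sp[2] - 1L
    genomic_to_protein(transcript, first_base)
  }
  if (L %% 3L == 0L) {
    detail <- sprintf("exon %d coding length %d in frame; phase-based rule: non-truncating",
                      exon_index, L)
    if (!is.null(genome)) {
      mut <- skip_exon_cds(transcript, exon_index, genome)
      tr <- translate_cds(mut)
      ref_tr <- translate_cds(spliced_cds(transcript, genome))
      if (tr$stopped && nchar(tr$protein) < nchar(ref_tr$protein) - L %/% 3L)
        detail <- paste0(detail, "; note: novel junction stop on re-translation")
    }
    return(ConsequenceCall("ACCEPTOR_SKIP_INFRAME", aa_pos, NA_character_, detail))
  }
  pc <- NA_character_
  if (!is.null(genome)) {
    ref_tr <- translate_cds(spliced_cds(transcript, genome))
    mut_tr <- translate_cds(skip_exon_cds(transcript, exon_index, genome))
    pc <- hgvs_p_string(ref_tr$protein, mut_tr$protein, mut_tr$stopped)
  }
  ConsequenceCall("ACCEPTOR_SKIP_FRAMESHIFT", aa_pos, pc,
                  sprintf("exon %d coding length %d shifts frame", exon_index, L))
}

# spliced CDS with one exon's coding segment removed
skip_exon_cds <- function(transcript, exon_index, genome) {
  segs <- character(0)
  for (i in seq_len(n_exons(transcript))) {
    if (i == exon_index) next
    sp <- coding_span(transcript, i)
    if (is.null(sp)) next
    segs <- c(segs, list(c(sp[1], sp[2])))
  }
  pieces <- vapply(segs, function(sp)
    genome_fetch(genome, transcript$exons$contig[1], sp[1], sp[2]), character(1))
  # segs were appended in transcript order (genomic order differs on "-")
  if (transcript$strand == "+") paste(pieces, collapse = "")
  else revcomp(paste(rev(pieces), collapse = ""))
}

#' Consequence of a splice-donor variant: intron retention
#'
#' A canonical donor (+1/+2) variant is modelled as read-through of the
#' intron. The retained-intron CDS is translated in silico from the canonical
#' start: a stop before the canonical stop position is a premature
#' termination codon (truncating); a stop-free in-frame intron reading is a
#' read-through (in-frame insertion, non-truncating).
#'
#' @param transcript A `TranscriptModel`.
#' @param intron_index 1-based intron index (intron k lies between transcript
#'   exons k and k+1; both must be coding).
#' @param genome A `GenomeSequence`.
#' @return A [ConsequenceCall()].
#' @export
donor_retention_consequence <- function(transcript, intron_index, genome) {
  ne <- n_exons(transcript)
  if (intron_index < 1L || intron_index > ne - 1L)
    stop("input error: intron index ", intron_index, " out of range")
  if (exon_coding_length(transcript, intron_index) == 0L ||
      exon_coding_length(transcript, intron_index + 1L) == 0L)
    stop("not-applicable: intron ", intron_index, " not flanked by coding exons")
  intr <- transcript_introns(transcript)
  iv <- intr[intr$intron_index == intron_index, ]
  intron_seq <- genome_fetch(genome, transcript$exons$contig[1], iv$start, iv$end,
                             strand = transcript$strand)
  intron_len <- nchar(intron_seq)

  # retained CDS: coding segments of exons 1..k, intron, exons k+1..n
  pieces <- character(0)
  for (i in seq_len(ne)) {
    sp <- coding_span(transcript, i)
    if (!is.null(sp))
      pieces <- c(pieces, genome_fetch(genome, transcript$exons$contig[1],
                                       sp[1], sp[2],
                                       strand = transcript$strand))
    if (i == intron_index) pieces <- c(pieces, intron_seq)
  }
  # pieces are already transcript-oriented strings, in transcript order
  retained <- paste(pieces, collapse = "")

  ref_tr <- translate_cds(spliced_cds(transcript, genome))
  mut_tr <- translate_cds(retained)
  canonical_stop_codon <- nchar(retained) %/% 3L
  readthrough <- intron_len %% 3L == 0L && mut_tr$stopped &&
    mut_tr$stop_codon_index == canonical_stop_codon
  aa_div <- {
    rp <- ref_tr$protein; mp <- mut_tr$protein
    nmin <- min(nchar(rp), nchar(mp))
    d <- which(strsplit(rp, "")[[1]][seq_len(nmin)] !=
               strsplit(mp, "")[[1]][seq_len(nmin)])
    if (length(d)) d[1] else nmin + 1L
  }
  if (readthrough) {
    ConsequenceCall("DONOR_RETENTION_READTHROUGH", aa_div, NA_character_,
                    sprintf("intron %d (%d nt) read through in frame, %d residues inserted",
                            intron_index, intron_len, intron_len %/% 3L))
  } else {
    pc <- hgvs_p_string(ref_tr$protein, mut_tr$protein, mut_tr$stopped)
    ConsequenceCall("DONOR_RETENTION_PTC", aa_div, pc,
                    sprintf("intron %d (%d nt) retention introduces a premature stop",
                            intron_index, intron_len))
  }
}

# Locate the splice-site dinucleotides in genomic coordinates, per intron.
# Returns a data.frame with transcript-order intron_index and the two donor
# (+1/+2) and two acceptor (-1/-2) genomic positions (0-based).
splice_site_positions <- function(transcript) {
  intr <- transcript_introns(transcript)
  if (nrow(intr) == 0L) return(cbind(intr, donor1 = integer(0)))
  plus <- transcript$strand == "+"
  data.frame(intron_index = intr$intron_index,
             donor1 = if (plus) intr$start else intr$end - 1L,
             donor2 = if (plus) intr$start + 1L else intr$end - 2L,
             acceptor1 = if (plus) intr$end - 1L else intr$start,
             acceptor2 = if (plus) intr$end - 2L else intr$start + 1L)
}

#' Classify a variant's truncation consequence
#'
#' Dispatch follows the rules used for Titin truncation calling: a coding
#' SNV creating a stop is `NONSENSE`; a coding indel whose length difference
#' is not a multiple of 3 is `FRAMESHIFT` (protein change by re-translation);
#' a variant at the intronic -1/-2 positions of a splice acceptor is modelled
#' as exon skipping (truncating only if the skipped exon's coding length
#' changes codon phase); a variant at +1/+2 of a donor is modelled as intron
#' retention (truncating only if in-silico translation of the retained
#' intron hits a premature stop). Everything else is `OTHER`, non-truncating.
#' Variants touching both a splice dinucleotide and exonic bases are
#' classified by the splice model (tie-break recorded in `detail`).
#'
#' @param variant List or one-row data.frame with `contig`, `pos` (1-based),
#'   `ref`, `alt`.
#' @param transcript A `TranscriptModel`.
#' @param genome A `GenomeSequence`.
#' @return A [ConsequenceCall()].
#' @export
classify_variant <- function(variant, transcript, genome) {
  pos1 <- as.integer(variant$pos); ref <- toupper(variant$ref); alt <- toupper(variant$alt)
  contig <- as.character(variant$contig)
  obs <- genome_fetch(genome, contig, pos1 - 1L, pos1 - 1L + nchar(ref))
  if (obs != ref)
    stop("input error: ref allele '", ref, "' does not match genome '", obs,
         "' at ", contig, ":", pos1)
  nv <- normalize_variant(pos1, ref, alt)
  pos0 <- nv$pos - 1L                       # 0-based first affected base
  span <- seq.int(pos0, pos0 + nchar(nv$ref) - 1L)

  ex <- transcript$exons
  tx_start <- min(ex$start); tx_end <- max(ex$end)
  if (pos0 >= tx_end || max(span) < tx_start)
    stop("not-applicable: variant outside transcript span")

  ss <- splice_site_positions(transcript)
  if (nrow(ss)) {
    hit_d <- ss$intron_index[ss$donor1 %in% span | ss$donor2 %in% span]
    hit_a <- ss$intron_index[ss$acceptor1 %in% span | ss$acceptor2 %in% span]
    if (length(hit_d)) {
      call <- donor_retention_consequence(transcript, hit_d[1], genome)
      call$detail <- paste0(call$detail, "; splice interpretation takes precedence")
      return(call)
    }
    if (length(hit_a)) {
      call <- acceptor_skip_consequence(transcript, hit_a[1] + 1L, genome)
      call$detail <- paste0(call$detail, "; splice interpretation takes precedence")
      return(call)
    }
  }

  cdspos <- cds_genomic_positions(transcript)
  in_cds <- span %in% cdspos
  if (!all(in_cds))
    return(ConsequenceCall("OTHER", detail = if (any(in_cds))
      "partially non-coding; not classified as coding change" else
      "non-coding (UTR/intronic, non-canonical splice)"))

  cds <- spliced_cds(transcript, genome)
  if (transcript$strand == "+") {
    off <- match(pos0, cdspos)
    mut_cds <- paste0(substr(cds, 1L, off - 1L), nv$alt,
                      substr(cds, off + nchar(nv$ref), nchar(cds)))
  } else {
    # the genomic ref block appears reverse-complemented in the CDS, starting
    # at the CDS offset of its genomically-last base
    off <- match(pos0 + nchar(nv$ref) - 1L, cdspos)
    mut_cds <- paste0(substr(cds, 1L, off - 1L), revcomp(nv$alt),
                      substr(cds, off + nchar(nv$ref), nchar(cds)))
  }
  ref_tr <- translate_cds(cds)
  mut_tr <- translate_cds(mut_cds)
  len_diff <- abs(nchar(nv$alt) - nchar(nv$ref))

  if (len_diff == 0L) {
    if (identical(ref_tr$protein, mut_tr$protein))
      return(ConsequenceCall("OTHER", detail = "synonymous"))
    if (mut_tr$stopped && nchar(mut_tr$protein) < nchar(ref_tr$protein) &&
        startsWith(ref_tr$protein, mut_tr$protein)) {
      aa <- nchar(mut_tr$protein) + 1L
      pc <- sprintf("p.%s%dX", substr(ref_tr$protein, aa, aa), aa)
      return(ConsequenceCall("NONSENSE", aa, pc, "substitution creates stop codon"))
    }
    rp <- strsplit(ref_tr$protein, "")[[1]]; mp <- strsplit(mut_tr$protein, "")[[1]]
    nmin <- min(length(rp), length(mp))
    aa <- which(rp[seq_len(nmin)] != mp[seq_len(nmin)])[1]
    pc <- sprintf("p.%s%d%s", rp[aa], aa, mp[aa])
    return(ConsequenceCall("OTHER", aa, pc, "missense"))
  }
  if (len_diff %% 3L != 0L) {
    pc <- hgvs_p_string(ref_tr$protein, mut_tr$protein, mut_tr$stopped)
    aa <- if (!is.na(pc)) as.integer(sub("^p\\.[A-Z*](\\d+).*$", "\\1", pc)) else NA_integer_
    return(ConsequenceCall("FRAMESHIFT", aa, pc,
                           sprintf("coding indel, length change %d", len_diff)))
  }
  ConsequenceCall("OTHER", detail = sprintf(
    "in-frame coding indel (length change %d); phase-preserving, non-truncating by rule",
    len_diff))
}

#' Read variants from a VCF file
#'
#' Multi-allelic records are expanded to one row per alternate allele.
#'
#' @param path Path to a VCF file.
#' @return data.frame with `contig`, `pos` (1-based), `id`, `ref`, `alt`.
#' @export
read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(fx)), function(i) {
    alts <- strsplit(fx$ALT[i], ",", fixed = TRUE)[[1]]
    data.frame(contig = fx$CHROM[i], pos = as.integer(fx$POS[i]),
               id = fx$ID[i], ref = fx$REF[i], alt = alts,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify every variant in a table against one transcript
#'
#' @param variants data.frame as returned by [read_variants_vcf()].
#' @param transcript A `TranscriptModel`.
#' @param genome A `GenomeSequence`.
#' @return data.frame with `id`, `category`, `truncating`, `aa_position`,
#'   `protein_change`, `detail`.
#' @export
classify_variants <- function(variants, transcript, genome) {
  res <- lapply(seq_len(nrow(variants)), function(i) {
    call <- classify_variant(variants[i, ], transcript, genome)
    data.frame(id = if ("id" %in% names(variants)) variants$id[i] else NA_character_,
               category = call$category, truncating = call$truncating,
               aa_position = call$aa_position,
               protein_change = call$protein_change,
               detail = call$detail, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
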