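#' Genome sequence container
#'
#' Holds a set of named contig sequences as uppercase nucleotide strings.
#' All internal coordinates in this package are 0-based half-open; file
#' formats (GFF, VCF, FASTA indexing) are converted at the I/O boundary.
#'
#' @param sequences Named character vector of nucleotide sequences.
#' @return An object of class `GenomeSequence`.
#' @export
GenomeSequence <- function(sequences) {
  if (!is.character(sequences) || length(sequences) == 0L)
    stop("sequences must be a non-empty named character vector")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("every contig must be named")
  if (anyDuplicated(names(sequences)))
    stop("duplicate contig names: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]), collapse = ", "))
  structure(list(sequences = toupper(sequences)), class = "GenomeSequence")
}

#' @export
print.GenomeSequence <- function(x, ...) {
  cat("GenomeSequence with", length(x$sequences), "contig(s):\n")
  for (nm in names(x$sequences))
    cat("  ", nm, ": ", nchar(x$sequences[[nm]]), " bp\n", sep = "")
  invisible(x)
}

#' Contig names and lengths
#' @param genome A `GenomeSequence`.
#' @return Character vector of contig names / named integer vector of lengths.
#' @export
contig_names <- function(genome) names(genome$sequences)

#' @rdname contig_names
#' @export
contig_lengths <- function(genome) vapply(genome$sequences, nchar, integer(1))

#' Fetch an interval of genomic sequence
#'
#' @param genome A `GenomeSequence`.
#' @param contig Contig name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` (forward) or `"-"` (reverse complement returned).
#' @return Nucleotide string of length `end - start`.
#' @export
genome_fetch <- function(genome, contig, start, end, strand = "+") {
  stopifnot(inherits(genome, "GenomeSequence"))
  if (!contig %in% names(genome$sequences)) stop("unknown contig: ", contig)
  seq <- genome$sequences[[contig]]
  if (start < 0 || end > nchar(seq) || start > end)
    stop(sprintf("interval [%d,%d) out of bounds for contig %s (length %d)",
                 start, end, contig, nchar(seq)))
  s <- substr(seq, start + 1L, end)
  if (strand == "-") s <- revcomp(s) else if (strand != "+") stop("strand must be '+' or '-'")
  s
}

#' Reverse complement of a nucleotide string
#' @param s Nucleotide string.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(s) {
  if (nchar(s) == 0L) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Read a genome FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A [GenomeSequence()]; sequences uppercased, names truncated at the
#'   first whitespace.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L)
    stop("parse error at line 1: empty FASTA file: ", path)
  if (!startsWith(first, ">"))
    stop("parse error at line 1: expected FASTA header ('>'), got: ", first)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no records in FASTA file: ", path)
  nms <- sub("\\s.*$", "", names(ss))
  GenomeSequence(stats::setNames(as.character(ss), nms))
}

#' Transcript model
#'
#' Strand-aware exon/CDS structure. `exons` is a data.frame with columns
#' `contig`, `start`, `end` (0-based half-open genomic) and `index` (1-based
#' rank in transcript 5'->3' order). `cds_start`/`cds_end` are the genomic
#' bounds (0-based half-open) of the coding region, strand-independent.
#'
#' @param id Transcript identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons Exon data.frame as described above, ordered by `index`.
#' @param cds_start,cds_end Genomic CDS bounds (0-based half-open).
#' @return An object of class `TranscriptModel`.
#' @export
TranscriptModel <- function(id, strand, exons, cds_start, cds_end) {
  stopifnot(strand %in% c("+", "-"),
            is.data.frame(exons),
            all(c("contig", "start", "end", "index") %in% names(exons)))
  exons <- exons[order(exons$index), , drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) == 0L) stop("transcript ", id, " has zero exons")
  if (any(exons$start >= exons$end))
    stop("transcript ", id, ": exon with start >= end")
  g <- exons[order(exons$start), ]
  if (nrow(g) > 1L && any(g$start[-1L] < g$end[-nrow(g)]))
    stop("transcript ", id, ": overlapping exons")
  # transcript order must match genomic order on the strand
  expect_gen <- if (strand == "+") order(exons$start) else order(-exons$start)
  if (!identical(exons$index[expect_gen], sort(exons$index)))
    stop("transcript ", id, ": exon index order inconsistent with strand")
  if (cds_start >= cds_end)
    stop("transcript ", id, ": cds_start must be < cds_end")
  in_exon <- function(p) any(exons$start <= p & p < exons$end)
  if (!in_exon(cds_start) || !in_exon(cds_end - 1L))
    stop("transcript ", id, ": CDS boundary outside exons")
  structure(list(id = id, strand = strand, exons = exons,
                 cds_start = as.integer(cds_start), cds_end = as.integer(cds_end)),
            class = "TranscriptModel")
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat("TranscriptModel", x$id, "(", x$strand, "strand ),",
      nrow(x$exons), "exons, CDS", x$cds_start, "-", x$cds_end, "\n")
  invisible(x)
}

#' Number of exons of a transcript
#' @param transcript A `TranscriptModel`.
#' @export
n_exons <- function(transcript) nrow(transcript$exons)

# Coding overlap of exon i (transcript index), as genomic 0-based half-open
# bounds, or NULL if the exon is fully non-coding.
coding_span <- function(transcript, exon_index) {
  ex <- transcript$exons[transcript$exons$index == exon_index, ]
  if (nrow(ex) != 1L) stop("no exon with index ", exon_index)
  s <- max(ex$start, transcript$cds_start)
  e <- min(ex$end, transcript$cds_end)
  if (s >= e) return(NULL)
  c(s, e)
}

#' Coding length of one exon
#'
#' @param transcript A `TranscriptModel`.
#' @param exon_index 1-based transcript-order exon index.
#' @return Number of coding bases in that exon (0 for UTR-only exons).
#' @export
exon_coding_length <- function(transcript, exon_index) {
  sp <- coding_span(transcript, exon_index)
  if (is.null(sp)) 0L else as.integer(sp[2] - sp[1])
}

#' Introns of a transcript
#'
#' @param transcript A `TranscriptModel`.
#' @return data.frame with `intron_index` (1-based, intron k lies between
#'   transcript exons k and k+1), `start`, `end` (genomic 0-based half-open).
#' @export
transcript_introns <- function(transcript) {
  ex <- transcript$exons
  n <- nrow(ex)
  if (n < 2L)
    return(data.frame(intron_index = integer(0), start = integer(0), end = integer(0)))
  res <- lapply(seq_len(n - 1L), function(k) {
    a <- ex[ex$index == k, ]
    b <- ex[ex$index == k + 1L, ]
    data.frame(intron_index = k,
               start = min(a$end, b$end),
               end = max(a$start, b$start))
  })
  do.call(rbind, res)
}

#' Read gene models from GFF3/GTF
#'
#' Parses exon and CDS features grouped by transcript. 1-based inclusive file
#' coordinates become internal 0-based half-open. Exons are ranked in
#' transcription order (right-to-left on the minus strand).
#'
#' @param path Path to a GFF3 or GTF file (format detected from extension).
#' @return Named list of [TranscriptModel()] objects.
#' @export
read_gene_models_gff <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  fmt <- if (grepl("\\.gtf$", path, ignore.case = TRUE)) "gtf" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  md <- S4Vectors::mcols(gr)
  txid <- if (!is.null(md$transcript_id)) {
    as.character(md$transcript_id)
  } else if (!is.null(md$Parent)) {
    vapply(as.list(md$Parent), function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  } else stop("no transcript_id or Parent attribute in ", path)
  type <- as.character(md$type)
  keep <- type %in% c("exon", "CDS") & !is.na(txid)
  gr <- gr[keep]; txid <- txid[keep]; type <- type[keep]
  if (length(gr) == 0L) stop("no exon/CDS features in ", path)
  out <- list()
  for (tid in unique(txid)) {
    sel <- txid == tid
    g <- gr[sel]; ty <- type[sel]
    exg <- g[ty == "exon"]
    cdg <- g[ty == "CDS"]
    if (length(exg) == 0L)
      stop("model error: transcript ", tid, " has zero exons")
    strand <- as.character(BiocGenerics::strand(exg))[1]
    if (!strand %in% c("+", "-"))
      stop("model error: transcript ", tid, " has no strand")
    st <- BiocGenerics::start(exg) - 1L  # to 0-based half-open
    en <- BiocGenerics::end(exg)
    ord <- if (strand == "+") order(st) else order(-st)
    exons <- data.frame(contig = as.character(GenomicRanges::seqnames(exg))[ord],
                        start = st[ord], end = en[ord],
                        index = seq_along(st))
    if (length(cdg) == 0L)
      stop("model error: transcript ", tid, " has no CDS features")
    cs <- min(BiocGenerics::start(cdg)) - 1L
    ce <- max(BiocGenerics::end(cdg))
    in_exon <- function(p) any(exons$start <= p & p < exons$end)
    if (!in_exon(cs) || !in_exon(ce - 1L))
      stop("model error: transcript ", tid, ": CDS outside exons")
    out[[tid]] <- TranscriptModel(tid, strand, exons, cs, ce)
  }
  out
}

#' Spliced coding sequence of a transcript
#'
#' Concatenates the coding segment of every exon in transcript orientation;
#' minus-strand output is reverse-complemented so the result always begins at
#' the initiator codon.
#'
#' @param transcript A `TranscriptModel`.
#' @param genome A `GenomeSequence`.
#' @return Nucleotide string (the CDS, 5'->3').
#' @export
spliced_cds <- function(transcript, genome) {
  segs <- character(0)  # forward-strand pieces, collected in transcript order
  for (i in seq_len(n_exons(transcript))) {
    sp <- coding_span(transcript, i)
    if (is.null(sp)) next
    segs <- c(segs, genome_fetch(genome, transcript$exons$contig[1], sp[1], sp[2]))
  }
  if (length(segs) == 0L) stop("model error: transcript has no coding sequence")
  if (transcript$strand == "+") {
    paste(segs, collapse = "")
  } else {
    # transcript order is descending genomic; reassemble ascending, then
    # reverse-complement the whole CDS
    revcomp(paste(rev(segs), collapse = ""))
  }
}

#' Translate a coding sequence
#'
#' Standard genetic code; translation halts at the first stop codon. Codons
#' containing ambiguous bases translate to `X`. A trailing partial codon is
#' ignored.
#'
#' @param seq Nucleotide string, length >= 3.
#' @return List with `protein` (string, stop excluded), `stopped` (logical)
#'   and `stop_codon_index` (1-based codon index of the stop, or `NA`).
#' @export
translate_cds <- function(seq) {
  if (is.null(seq) || !nzchar(seq)) stop("empty sequence")
  if (nchar(seq) < 3L) stop("sequence shorter than one codon")
  seq <- toupper(seq)
  n_codon <- nchar(seq) %/% 3L
  starts <- 3L * (seq_len(n_codon) - 1L) + 1L
  codons <- substring(seq, starts, starts + 2L)
  aas <- unname(Biostrings::GENETIC_CODE[codons])
  aas[is.na(aas)] <- "X"
  stop_at <- which(aas == "*")
  if (length(stop_at)) {
    k <- stop_at[1]
    list(protein = paste(aas[seq_len(k - 1L)], collapse = ""),
         stopped = TRUE, stop_codon_index = k)
  } else {
    list(protein = paste(aas, collapse = ""), stopped = FALSE,
         stop_codon_index = NA_integer_)
  }
}

#' Codon phase of an exon
#'
#' Phase = (number of coding bases 5' of the exon) mod 3. Exons whose coding
#' length is a multiple of 3 can be skipped without changing downstream phase.
#'
#' @param transcript A `TranscriptModel`.
#' @param exon_index 1-based transcript-order exon index.
#' @return 0, 1 or 2; `NA` for a fully non-coding exon.
#' @export
exon_phase <- function(transcript, exon_index) {
  if (exon_coding_length(transcript, exon_index) == 0L) return(NA_integer_)
  before <- 0L
  for (i in seq_len(exon_index - 1L))
    before <- before + exon_coding_length(transcript, i)
  before %% 3L
}

#' Genomic positions of all CDS bases, in transcript order
#'
#' Serves as the exact coordinate map between the spliced CDS and the genome
#' (element k is the genomic 0-based position of CDS base k).
#'
#' @param transcript A `TranscriptModel`.
#' @return Integer vector of genomic 0-based positions.
#' @export
cds_genomic_positions <- function(transcript) {
  pos <- integer(0)
  for (i in seq_len(n_exons(transcript))) {
    sp <- coding_span(transcript, i)
    if (is.null(sp)) next
    p <- seq.int(sp[1], sp[2] - 1L)
    if (transcript$strand == "-") p <- rev(p)
    pos <- c(pos, p)
  }
  pos
}

#' Map a genomic position to a protein residue
#'
#' @param transcript A `TranscriptModel`.
#' @param genomic_position 0-based genomic position within a coding exon.
#' @return 1-based amino-acid index.
#' @export
genomic_to_protein <- function(transcript, genomic_position) {
  cdspos <- cds_genomic_positions(transcript)
  off <- match(genomic_position, cdspos)
  if (is.na(off))
    stop("out-of-CDS: position ", genomic_position,
         " is not within a coding exon of ", transcript$id)
  as.integer((off - 1L) %/% 3L + 1L)
}

#' Map a protein residue to its genomic codon positions
#'
#' Inverse of [genomic_to_protein()]: returns the three genomic positions of
#' the codon encoding residue `aa`, in transcript order.
#'
#' @param transcript A `TranscriptModel`.
#' @param aa 1-based amino-acid index.
#' @return Integer vector of three genomic 0-based positions.
#' @export
protein_to_genomic <- function(transcript, aa) {
  cdspos <- cds_genomic_positions(transcript)
  i <- 3L * (aa - 1L) + 1L
  if (aa < 1L || i + 2L > length(cdspos))
    stop("aa index ", aa, " outside the protein of ", transcript$id)
  cdspos[i:(i + 2L)]
}

#' Read an exon-level orthology interval map
#'
#' Five tab-separated columns: source exon index, source aa start/end, target
#' aa start/end. Used to project amino-acid positions onto another species'
#' meta-transcript coordinate system.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `src_exon`, `src_aa_start`, `src_aa_end`,
#'   `tgt_aa_start`, `tgt_aa_end`, validated monotone and non-overlapping.
#' @export
read_orthology_map <- function(path) {
  m <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("src_exon", "src_aa_start", "src_aa_end", "tgt_aa_start", "tgt_aa_end")
  if (!all(need %in% names(m)))
    stop("orthology map must have columns: ", paste(need, collapse = ", "))
  validate_orthology_map(m)
}

#' @rdname read_orthology_map
#' @param map Orthology map data.frame (see [read_orthology_map()]).
#' @export
validate_orthology_map <- function(map) {
  m <- map[order(map$src_aa_start), , drop = FALSE]
  if (any(m$src_aa_start > m$src_aa_end) || any(m$tgt_aa_start > m$tgt_aa_end))
    stop("orthology map: interval with start > end")
  if (nrow(m) > 1L) {
    if (any(m$src_aa_start[-1L] <= m$src_aa_end[-nrow(m)]))
      stop("orthology map: overlapping source intervals")
    if (any(diff(m$tgt_aa_start) <= 0) || any(m$tgt_aa_start[-1L] <= m$tgt_aa_end[-nrow(m)]))
      stop("orthology map: target intervals not monotone increasing")
  }
  rownames(m) <- NULL
  m
}

#' Project an amino-acid position through an orthology map
#'
#' Linear interpolation within the containing interval, rounded to the
#' nearest integer. Positions outside every interval return `NA` rather than
#' being extrapolated.
#'
#' @param map Orthology map (see [read_orthology_map()]).
#' @param aa 1-based amino-acid position(s) in source coordinates.
#' @return Integer vector of target positions (`NA` where unmapped).
#' @export
project_orthologous_aa <- function(map, aa) {
  map <- validate_orthology_map(map)
  vapply(aa, function(a) {
    row <- map[map$src_aa_start <= a & a <= map$src_aa_end, , drop = FALSE]
    if (nrow(row) == 0L) return(NA_integer_)
    r <- row[1, ]
    if (r$src_aa_end == r$src_aa_start) return(as.integer(r$tgt_aa_start))
    frac <- (a - r$src_aa_start) / (r$src_aa_end - r$src_aa_start)
    as.integer(round(r$tgt_aa_start + frac * (r$tgt_aa_end - r$tgt_aa_start)))
  }, integer(1))
}
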