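#' Scan a region for CRISPR/Cas9 protospacer+PAM sites
#'
#' Every 23-mer window on either strand whose final two bases are `GG`
#' (i.e. a 20-nt protospacer followed by an NGG PAM) yields a candidate.
#' Overlapping candidates are all reported. Minus-strand candidates are
#' reported with the genomic forward-strand start of their 23-mer window.
#'
#' @param genome A `GenomeSequence`.
#' @param contig Contig name.
#' @param start,end 0-based half-open region to scan.
#' @return data.frame with `protospacer` (20-mer), `pam` (3-mer), `strand`,
#'   `position` (genomic 0-based start of the 23-mer), `gg_start`
#'   (protospacer begins `GG`, preferred for T7 transcription).
#' @export
scan_protospacers <- function(genome, contig, start, end) {
  empty <- data.frame(protospacer = character(0), pam = character(0),
                      strand = character(0), position = integer(0),
                      gg_start = logical(0), stringsAsFactors = FALSE)
  L <- end - start
  if (L < 23L) return(empty)
  fwd <- genome_fetch(genome, contig, start, end)
  scan_one <- function(s) {
    n <- nchar(s) - 22L
    i <- seq_len(n)                         # 1-based window starts
    sites <- substring(s, i, i + 22L)
    keep <- substring(sites, 22L, 23L) == "GG"
    list(offset = i[keep] - 1L, site = sites[keep])
  }
  p <- scan_one(fwd)
  m <- scan_one(revcomp(fwd))
  res <- list()
  if (length(p$offset))
    res[[1]] <- data.frame(protospacer = substring(p$site, 1L, 20L),
                           pam = substring(p$site, 21L, 23L),
                           strand = "+", position = as.integer(start + p$offset),
                           stringsAsFactors = FALSE)
  if (length(m$offset))
    res[[2]] <- data.frame(protospacer = substring(m$site, 1L, 20L),
                           pam = substring(m$site, 21L, 23L),
                           strand = "-",
                           position = as.integer(start + (L - 23L - m$offset)),
                           stringsAsFactors = FALSE)
  out <- do.call(rbind, res)
  if (is.null(out)) return(empty)
  out$gg_start <- substring(out$protospacer, 1L, 2L) == "GG"
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count exact genome matches of a guide site
#'
#' Exact 23-mer (protospacer + PAM) string matching over both strands of
#' every contig; overlapping occurrences all count. No mismatch-tolerant
#' off-target scoring is attempted -- uniqueness means a single exact match.
#'
#' @param site The 23-mer (protospacer followed by PAM), or a candidate row
#'   from [scan_protospacers()].
#' @param genome A `GenomeSequence`.
#' @return Integer match count.
#' @export
count_genome_matches <- function(site, genome) {
  if (is.list(site) || is.data.frame(site))
    site <- paste0(site$protospacer, site$pam)
  site <- toupper(site)
  if (nchar(site) != 23L) stop("site must be a 23-mer")
  pat <- Biostrings::DNAString(site)
  rcp <- Biostrings::reverseComplement(pat)
  total <- 0L
  for (seq in genome$sequences) {
    subj <- Biostrings::DNAString(seq)
    total <- total + Biostrings::countPattern(pat, subj) +
      Biostrings::countPattern(rcp, subj)
  }
  total
}

#' Annotate candidates with genome match counts
#'
#' @param candidates Output of [scan_protospacers()].
#' @param genome A `GenomeSequence`.
#' @return `candidates` with a `genome_matches` column.
#' @export
add_genome_matches <- function(candidates, genome) {
  candidates$genome_matches <- vapply(seq_len(nrow(candidates)), function(i)
    count_genome_matches(paste0(candidates$protospacer[i], candidates$pam[i]),
                         genome), integer(1))
  candidates
}

#' Rank guide candidates
#'
#' Order: unique genome matches first, then 5'-GG protospacers (T7
#' transcription initiates efficiently on GG), then ascending genomic
#' position; ties broken by strand (`+` before `-`). The sort is stable.
#'
#' @param candidates Candidates with a `genome_matches` column
#'   (see [add_genome_matches()]).
#' @return Re-ordered data.frame with a `rank` column.
#' @export
rank_guides <- function(candidates) {
  if (!"genome_matches" %in% names(candidates))
    stop("candidates must carry genome_matches; see add_genome_matches()")
  o <- order(candidates$genome_matches != 1L,   # unique first
             !candidates$gg_start,              # GG-start first
             candidates$position,
             candidates$strand != "+")
  out <- candidates[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
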