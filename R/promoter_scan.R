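#' Read a bedGraph coverage track
#'
#' @param path 4-column bedGraph file. Gaps between intervals are depth 0.
#' @return data.frame of class `CoverageTrack` with `contig`, `start`, `end`
#'   (0-based half-open, sorted) and `depth`.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^(track|#)", lines)]
  if (length(lines) == 0L)
    return(coverage_track(data.frame(contig = character(0), start = integer(0),
                                     end = integer(0), depth = numeric(0))))
  gr <- rtracklayer::import(path, format = "bedGraph")
  tr <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr),
                   depth = as.numeric(gr$score))
  coverage_track(tr)
}

#' Coverage track constructor/validator
#'
#' @param tr data.frame with `contig`, `start`, `end`, `depth`.
#' @return Sorted, validated `CoverageTrack`.
#' @export
coverage_track <- function(tr) {
  stopifnot(all(c("contig", "start", "end", "depth") %in% names(tr)))
  if (any(tr$depth < 0)) stop("depths must be >= 0")
  tr <- tr[order(tr$contig, tr$start), , drop = FALSE]
  for (ct in unique(tr$contig)) {
    s <- tr[tr$contig == ct, ]
    if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)]))
      stop("parse error: overlapping intervals in coverage track on ", ct)
  }
  rownames(tr) <- NULL
  structure(tr, class = c("CoverageTrack", "data.frame"))
}

#' Mean per-base depth over an interval
#'
#' Bases not covered by any track interval count as depth 0.
#'
#' @param track A `CoverageTrack`.
#' @param contig Contig name.
#' @param start,end 0-based half-open interval.
#' @return Mean depth (numeric).
#' @export
track_mean_depth <- function(track, contig, start, end) {
  if (end <= start) stop("empty interval")
  s <- track[track$contig == contig, , drop = FALSE]
  if (nrow(s) == 0L) return(0)
  ov_start <- pmax(s$start, start); ov_end <- pmin(s$end, end)
  w <- pmax(0L, ov_end - ov_start)
  sum(w * s$depth) / (end - start)
}

# Weighted median of per-base depth over a set of intervals (gaps = depth 0),
# computed from run lengths without per-base expansion.
track_median_depth <- function(track, contig, starts, ends) {
  vals <- numeric(0); wts <- numeric(0)
  s <- track[track$contig == contig, , drop = FALSE]
  for (i in seq_along(starts)) {
    a <- starts[i]; b <- ends[i]
    if (b <= a) next
    ov_start <- pmax(s$start, a); ov_end <- pmin(s$end, b)
    keep <- ov_end > ov_start
    covered <- sum(ov_end[keep] - ov_start[keep])
    vals <- c(vals, s$depth[keep]); wts <- c(wts, (ov_end - ov_start)[keep])
    gap <- (b - a) - covered
    if (gap > 0) { vals <- c(vals, 0); wts <- c(wts, gap) }
  }
  if (length(vals) == 0L) return(0)
  o <- order(vals)
  vals <- vals[o]; wts <- wts[o]
  cw <- cumsum(wts); n <- sum(wts)
  # exact median of the per-base expansion (weights are base counts)
  if (n %% 2 == 1) {
    vals[which(cw >= (n + 1) / 2)[1]]
  } else {
    lo <- vals[which(cw >= n / 2)[1]]
    hi <- vals[which(cw >= n / 2 + 1)[1]]
    (lo + hi) / 2
  }
}

#' Score upstream-intron windows for promoter-like read accumulation
#'
#' For each internal exon, the scored window is the `window_size` bases of
#' the upstream intron adjacent to the exon's 5' (acceptor) edge in
#' transcript orientation -- on minus-strand genes this lies at higher
#' genomic coordinates. The fold score compares the window's mean depth to
#' the median per-base depth over all introns of the gene (pseudocount on the
#' background absorbs empty tracks).
#'
#' @param track A `CoverageTrack`.
#' @param transcript A `TranscriptModel`.
#' @param window_size Window width in bases (default 500; truncated with a
#'   flag when the intron is shorter).
#' @param pseudocount Added to the background before dividing (default 1).
#' @return data.frame of class `PromoterCandidate` with one row per internal
#'   exon: `exon_index`, `window_start`, `window_end`, `window_mean_depth`,
#'   `background_depth`, `fold_score`, `truncated`.
#' @export
score_intronic_windows <- function(track, transcript, window_size = 500L,
                                   pseudocount = 1) {
  if (window_size < 1L) stop("window_size must be >= 1")
  ne <- n_exons(transcript)
  if (ne < 3L) stop("need at least 3 exons to scan internal exons")
  contig <- transcript$exons$contig[1]
  intr <- transcript_introns(transcript)
  background <- track_median_depth(track, contig, intr$start, intr$end)

  rows <- lapply(2:(ne - 1L), function(k) {
    up <- intr[intr$intron_index == k - 1L, ]     # upstream intron of exon k
    ilen <- up$end - up$start
    w <- min(window_size, ilen)
    ex <- transcript$exons[transcript$exons$index == k, ]
    if (transcript$strand == "+") {
      ws <- ex$start - w; we <- ex$start
    } else {
      ws <- ex$end; we <- ex$end + w
    }
    md <- track_mean_depth(track, contig, ws, we)
    data.frame(exon_index = k, window_start = ws, window_end = we,
               window_mean_depth = md, background_depth = background,
               fold_score = md / (background + pseudocount),
               truncated = w < window_size)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("PromoterCandidate", "data.frame"))
}

#' Call promoter candidates above a fold threshold
#'
#' @param candidates Output of [score_intronic_windows()].
#' @param fold_threshold Minimum fold score (default 5; must be > 1).
#' @return Called subset with a `called` column, sorted by descending fold
#'   score.
#' @export
call_promoter_candidates <- function(candidates, fold_threshold = 5) {
  if (fold_threshold <= 1) stop("fold_threshold must be > 1")
  if (nrow(candidates) == 0L) {
    candidates$called <- logical(0)
    return(candidates)
  }
  candidates$called <- candidates$fold_score >= fold_threshold
  out <- candidates[candidates$called, , drop = FALSE]
  out <- out[order(-out$fold_score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a BED peak file
#'
#' @param path BED file of peak intervals.
#' @return data.frame with `contig`, `start`, `end` (0-based half-open).
#' @export
read_peaks_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr))
}

#' Annotate promoter candidates with epigenomic peak overlap
#'
#' Adds a logical column `peak_<label>`: `TRUE` iff the candidate window
#' intersects any peak interval (half-open intersection, so an abutting
#' interval with `end == start` does not overlap).
#'
#' @param candidates Candidate data.frame (see [score_intronic_windows()]).
#' @param peaks Peak data.frame (see [read_peaks_bed()]).
#' @param label Peak-set label used in the new column name.
#' @param contig Contig of the candidate windows (default: peaks' contigs are
#'   matched against this name).
#' @return `candidates` with the added overlap column.
#' @export
annotate_with_peaks <- function(candidates, peaks, label, contig = NULL) {
  col <- paste0("peak_", label)
  if (nrow(candidates) == 0L) { candidates[[col]] <- logical(0); return(candidates) }
  if (is.null(contig)) contig <- peaks$contig[1]
  pk <- peaks[peaks$contig == contig, , drop = FALSE]
  if (nrow(pk) == 0L) { candidates[[col]] <- FALSE; return(candidates) }
  q <- IRanges::IRanges(start = candidates$window_start + 1L,
                        end = candidates$window_end)      # 1-based closed
  s <- IRanges::IRanges(start = pk$start + 1L, end = pk$end)
  candidates[[col]] <- IRanges::overlapsAny(q, s)
  candidates
}

#' Find the in-frame internal initiator ATG upstream of an exon
#'
#' Scans the transcript-orientation sequence from an internal transcription
#' start site toward the exon and reports the first ATG whose reading frame
#' runs in-frame into the exon, i.e. whose distance d to the exon's 5' edge
#' satisfies d mod 3 == exon phase. `aa_offset` counts the complete codons
#' between the ATG (inclusive) and the exon start (exclusive).
#'
#' @param genome A `GenomeSequence`.
#' @param transcript A `TranscriptModel`.
#' @param exon_index 1-based transcript-order index of the downstream exon.
#' @param tss_position Genomic 0-based position of the TSS, within the
#'   upstream intron.
#' @return List with `found`, `atg_position` (genomic 0-based position of the
#'   A), `aa_offset`, `in_frame`.
#' @export
find_internal_start <- function(genome, transcript, exon_index, tss_position) {
  if (exon_index < 2L) stop("exon must have an upstream intron")
  intr <- transcript_introns(transcript)
  up <- intr[intr$intron_index == exon_index - 1L, ]
  ex <- transcript$exons[transcript$exons$index == exon_index, ]
  contig <- ex$contig
  plus <- transcript$strand == "+"
  edge <- if (plus) ex$start else ex$end          # exon 5' edge (genomic)
  in_intron <- tss_position >= up$start && tss_position < up$end
  downstream_of_exon <- if (plus) tss_position >= edge else tss_position < edge
  if (downstream_of_exon || !in_intron)
    stop("precondition error: TSS must lie within the upstream intron")
  s <- if (plus) genome_fetch(genome, contig, tss_position, edge)
       else genome_fetch(genome, contig, edge, tss_position + 1L, strand = "-")
  Lseq <- nchar(s)
  p <- exon_phase(transcript, exon_index)
  if (is.na(p)) stop("exon ", exon_index, " is non-coding; no phase")
  if (Lseq >= 3L) for (i in 0:(Lseq - 3L)) {
    if (substr(s, i + 1L, i + 3L) != "ATG") next
    d <- Lseq - i
    if (d %% 3L == p) {
      atg <- if (plus) tss_position + i else tss_position - i
      return(list(found = TRUE, atg_position = atg,
                  aa_offset = d %/% 3L, in_frame = TRUE))
    }
  }
  list(found = FALSE, atg_position = NA_integer_, aa_offset = NA_integer_,
       in_frame = FALSE)
}
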