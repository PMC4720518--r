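#' Read an exon-exon junction count table
#'
#' TSV with columns `exon_id`, `I5` (reads on the upstream-exon to exon
#' junction), `I3` (reads on the exon to downstream-exon junction) and `X`
#' (reads on junctions skipping the exon). `"."` encodes a junction that does
#' not exist (e.g. the missing inclusion junction of a terminal exon) and is
#' kept distinct from an observed zero.
#'
#' @param path Path to the TSV file.
#' @return data.frame with integer columns `I5`, `I3`, `X` (`NA` = absent).
#' @export
read_junction_table <- function(path) {
  tb <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("exon_id", "I5", "I3", "X")
  if (!all(need %in% names(tb)))
    stop("junction table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tb$exon_id))
    stop("duplicate exon_id: ",
         paste(unique(tb$exon_id[duplicated(tb$exon_id)]), collapse = ", "))
  parse_count <- function(col) {
    vapply(seq_along(tb[[col]]), function(i) {
      v <- tb[[col]][i]
      if (v == ".") return(NA_integer_)
      if (!grepl("^[0-9]+$", v))
        stop("parse error at row ", i, ", column ", col,
             ": counts must be non-negative integers or '.', got '", v, "'")
      as.integer(v)
    }, integer(1))
  }
  data.frame(exon_id = tb$exon_id,
             I5 = parse_count("I5"), I3 = parse_count("I3"),
             X = parse_count("X"), stringsAsFactors = FALSE)
}

#' Percent-spliced-in estimate for one exon
#'
#' PSI = (I5 + I3) / (I5 + I3 + 2X). One skipping event removes both
#' inclusion junctions, hence the factor 2 on the exclusion count. Terminal
#' exons carry a single inclusion junction (the other recorded as absent) and
#' use PSI = I / (I + 2X). Estimates whose junction-read denominator falls
#' below `min_denominator` are no-calls (`pass = FALSE`, `psi = NA`).
#'
#' @param I5,I3,X Junction read counts (`NA` = junction absent).
#' @param min_denominator Read-sufficiency cutoff on the denominator
#'   (default 15).
#' @return List of class `PsiEstimate` with `psi`, `denominator`, `pass`.
#' @export
estimate_psi <- function(I5, I3, X, min_denominator = 15L) {
  counts <- c(I5 = I5, I3 = I3, X = X)
  if (any(!is.na(counts) & counts < 0)) stop("counts must be >= 0")
  if (all(is.na(counts)))
    return(structure(list(psi = NA_real_, denominator = 0L, pass = FALSE),
                     class = "PsiEstimate"))
  inc <- sum(c(I5, I3), na.rm = TRUE)
  have_inclusion <- !is.na(I5) || !is.na(I3)
  x <- if (is.na(X)) 0L else X
  denom <- as.integer(inc + 2L * x)
  pass <- have_inclusion && denom >= min_denominator && denom > 0L
  structure(list(psi = if (pass) inc / denom else NA_real_,
                 denominator = denom, pass = pass),
            class = "PsiEstimate")
}

#' @export
print.PsiEstimate <- function(x, ...) {
  if (x$pass) cat(sprintf("PSI = %.3f (denominator %d)\n", x$psi, x$denominator))
  else cat(sprintf("PSI: no-call (denominator %d)\n", x$denominator))
  invisible(x)
}

#' PSI estimates for a whole junction table
#'
#' @param junctions Junction count table (see [read_junction_table()]).
#' @param min_denominator Read-sufficiency cutoff.
#' @return data.frame with `exon_id`, `I5`, `I3`, `X`, `denominator`, `psi`,
#'   `pass`.
#' @export
psi_table <- function(junctions, min_denominator = 15L) {
  res <- lapply(seq_len(nrow(junctions)), function(i) {
    e <- estimate_psi(junctions$I5[i], junctions$I3[i], junctions$X[i],
                      min_denominator = min_denominator)
    data.frame(denominator = e$denominator, psi = e$psi, pass = e$pass)
  })
  cbind(junctions[, c("exon_id", "I5", "I3", "X")], do.call(rbind, res))
}

#' Median PSI across samples
#'
#' Median over passing estimates only; no-call (`NA`) if no sample passes.
#'
#' @param psi Numeric vector of per-sample PSI values (`NA` for no-calls).
#' @param pass Logical vector of the same length (default: `!is.na(psi)`).
#' @return Median PSI or `NA`.
#' @export
median_psi <- function(psi, pass = !is.na(psi)) {
  keep <- pass & !is.na(psi)
  if (!any(keep)) return(NA_real_)
  stats::median(psi[keep])
}

#' Count constitutive amino acids N-terminal to a boundary
#'
#' Sums the amino-acid lengths of exons whose median PSI strictly exceeds
#' `threshold` and whose span lies entirely N-terminal to `boundary_aa`.
#'
#' @param aa_start,aa_end 1-based inclusive amino-acid span of each exon.
#' @param psi Median PSI per exon (`NA` = no-call, never counted).
#' @param threshold PSI cutoff for "constitutive" (default 0.9, strict `>`).
#' @param boundary_aa Exons must end before this position to be counted.
#' @return Integer: total constitutive amino acids.
#' @export
count_constitutive_aa <- function(aa_start, aa_end, psi, threshold = 0.9,
                                  boundary_aa) {
  stopifnot(length(aa_start) == length(aa_end), length(psi) == length(aa_start))
  if (any(aa_start > aa_end)) stop("model error: aa_start > aa_end")
  o <- order(aa_start)
  if (length(o) > 1L && any(aa_start[o][-1L] <= aa_end[o][-length(o)]))
    stop("model error: overlapping exon amino-acid spans")
  keep <- !is.na(psi) & psi > threshold & aa_end < boundary_aa
  sum(as.integer(aa_end[keep] - aa_start[keep] + 1L))
}

#' Count junction reads from spliced alignments
#'
#' Reads a SAM file of spliced alignments (`N` CIGAR operations), matches
#' each alignment gap against the transcript's annotated introns and tallies
#' inclusion and exclusion junction support per exon. A gap equal to an
#' annotated intron supports inclusion of both flanking exons (I3 of the
#' upstream exon, I5 of the downstream exon); a gap spanning exactly from the
#' end of exon k-1 to the start of exon k+1 supports exclusion (X) of exon k.
#' Gaps matching neither are ignored and tallied in the `discarded`
#' attribute.
#'
#' @param sam_path Path to a SAM file.
#' @param transcript A `TranscriptModel`.
#' @return Junction count table (`exon_id` = `e<index>`; absent junctions of
#'   terminal exons are `NA`) with attribute `discarded`.
#' @export
count_junctions_from_alignments <- function(sam_path, transcript) {
  bam <- Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  ga <- GenomicAlignments::readGAlignments(bam)
  jx <- unlist(GenomicAlignments::junctions(ga))  # introns, 1-based closed

  ne <- n_exons(transcript)
  ex <- transcript$exons
  # genomic-order exon table with transcript indices
  g <- ex[order(ex$start), ]
  counts <- data.frame(exon_id = paste0("e", seq_len(ne)),
                       I5 = rep(0L, ne), I3 = rep(0L, ne), X = rep(0L, ne),
                       stringsAsFactors = FALSE)
  # annotated introns keyed by (start, end) in 0-based half-open coords
  intr <- transcript_introns(transcript)
  discarded <- 0L
  if (length(jx)) {
    js <- BiocGenerics::start(jx) - 1L  # 0-based half-open gap
    je <- BiocGenerics::end(jx)
    for (r in seq_along(js)) {
      hit <- which(intr$start == js[r] & intr$end == je[r])
      if (length(hit) == 1L) {
        k <- intr$intron_index[hit]  # between transcript exons k and k+1
        counts$I3[k] <- counts$I3[k] + 1L
        counts$I5[k + 1L] <- counts$I5[k + 1L] + 1L
        next
      }
      # skip gap: from end of exon k-1 to start of exon k+1 (transcript order)
      skip <- NA_integer_
      if (ne >= 3L) for (k in 2:(ne - 1L)) {
        a <- ex[ex$index == k - 1L, ]; b <- ex[ex$index == k + 1L, ]
        gs <- min(a$end, b$end); ge <- max(a$start, b$start)
        if (js[r] == gs && je[r] == ge) { skip <- k; break }
      }
      if (!is.na(skip)) counts$X[skip] <- counts$X[skip] + 1L
      else discarded <- discarded + 1L
    }
  }
  # terminal exons: the missing inclusion junction is absent, not zero;
  # terminal exons cannot be skipped
  counts$I5[1L] <- NA_integer_
  counts$I3[ne] <- NA_integer_
  counts$X[c(1L, ne)] <- NA_integer_
  attr(counts, "discarded") <- discarded
  counts
}
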