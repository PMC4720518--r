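#' Assign amplicon reads to alleles by discriminating windows
#'
#' A read containing the exact reference window is wild-type, one containing
#' the exact alternate window is mutant; reads matching neither or both are
#' ambiguous and excluded from ratio estimation. Windows are the sequence
#' context of length 2k+1 centered on the variant (default k = 10): adequate
#' for ~100 bp amplicons without realignment.
#'
#' @param reads Character vector of read sequences.
#' @param ref_window,alt_window Discriminating window sequences (must differ).
#' @return Object of class `AllelicCounts` with `mutant_reads`,
#'   `wildtype_reads`, `ambiguous_reads`.
#' @export
assign_reads <- function(reads, ref_window, alt_window) {
  if (identical(toupper(ref_window), toupper(alt_window)))
    stop("configuration error: ref and alt windows are identical")
  reads <- toupper(reads)
  has_ref <- grepl(toupper(ref_window), reads, fixed = TRUE)
  has_alt <- grepl(toupper(alt_window), reads, fixed = TRUE)
  wt <- sum(has_ref & !has_alt)
  mut <- sum(has_alt & !has_ref)
  structure(list(mutant_reads = mut, wildtype_reads = wt,
                 ambiguous_reads = length(reads) - wt - mut),
            class = "AllelicCounts")
}

#' Read amplicon reads from FASTQ or plain text
#'
#' @param path FASTQ file (extension `.fq`/`.fastq`) or one read per line.
#' @return Character vector of read sequences.
#' @export
read_amplicon_reads <- function(path) {
  if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) {
    as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
  } else {
    r <- readLines(path, warn = FALSE)
    r[nzchar(r)]
  }
}

#' Estimate nonsense-mediated decay from allelic imbalance
#'
#' In a heterozygote, both alleles are transcribed equally; the ratio of
#' mutant to wild-type reads therefore measures how much mutant transcript
#' survives decay. The 95% interval is a Wilson score interval on
#' p = mut/(mut+wt), transformed to the ratio scale p/(1-p).
#'
#' @param counts An `AllelicCounts` (see [assign_reads()]), or a list with
#'   `mutant_reads` and `wildtype_reads`.
#' @param min_reads Low-coverage floor on classified reads (default 100;
#'   targeted assays typically use 600-10,000).
#' @return Object of class `NmdEstimate` with `ratio`, `percent_of_wildtype`,
#'   `percent_degraded`, `ci_low`, `ci_high`, `n_classified`, `low_coverage`.
#' @export
estimate_nmd <- function(counts, min_reads = 100L) {
  mut <- counts$mutant_reads; wt <- counts$wildtype_reads
  if (wt == 0L) stop("undefined ratio: zero wild-type reads")
  n <- mut + wt
  low <- n < min_reads
  if (low) warning("low coverage: ", n, " classified reads < floor ", min_reads)
  ratio <- mut / wt
  ci <- stats::prop.test(mut, n, correct = FALSE)$conf.int  # Wilson score
  r_ci <- ci / (1 - ci)
  structure(list(ratio = ratio,
                 percent_of_wildtype = 100 * ratio,
                 percent_degraded = 100 - 100 * ratio,
                 ci_low = r_ci[1], ci_high = r_ci[2],
                 n_classified = n, low_coverage = low),
            class = "NmdEstimate")
}

#' @export
print.NmdEstimate <- function(x, ...) {
  cat(sprintf("mutant:wild-type ratio %.3f (95%% CI %.3f-%.3f), %.1f%% degraded, n=%d\n",
              x$ratio, x$ci_low, x$ci_high, x$percent_degraded, x$n_classified))
  invisible(x)
}

#' Length-normalized isoform abundance ratio
#'
#' Compares two transcript classes (e.g. the internal-promoter Cronos isoform
#' vs full-length) from reads mapping to isoform-specific regions, correcting
#' for region length.
#'
#' @param count_a,count_b Read counts over the two isoform-specific regions.
#' @param length_a,length_b Region lengths (nt).
#' @return `(count_a/length_a) / (count_b/length_b)`.
#' @export
isoform_ratio <- function(count_a, length_a, count_b, length_b) {
  if (length_a <= 0 || length_b <= 0) stop("region lengths must be > 0")
  if (count_a < 0 || count_b < 0) stop("counts must be >= 0")
  if (count_b == 0) stop("undefined ratio: zero reads in denominator region")
  (count_a / length_a) / (count_b / length_b)
}

#' Pool allelic counts across replicates
#'
#' @param ... `AllelicCounts` objects.
#' @param method `"sum"` (default) pools reads before ratio estimation.
#' @return A pooled `AllelicCounts`.
#' @export
pool_allelic_counts <- function(..., method = c("sum")) {
  method <- match.arg(method)
  reps <- list(...)
  structure(list(
    mutant_reads = sum(vapply(reps, `[[`, numeric(1), "mutant_reads")),
    wildtype_reads = sum(vapply(reps, `[[`, numeric(1), "wildtype_reads")),
    ambiguous_reads = sum(vapply(reps, `[[`, numeric(1), "ambiguous_reads"))),
    class = "AllelicCounts")
}
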