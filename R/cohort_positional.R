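#' Classify a truncation position relative to the Cronos promoter boundary
#'
#' Positions at or beyond the boundary (inclusive, "from aa 14,760 onwards")
#' are C-terminal; positions before it are N-terminal. Variants in the
#' Novex-3-exclusive terminal exon are excluded from positional ratios.
#'
#' @param aa_position 1-based amino-acid position(s) on the meta-transcript.
#' @param boundary_aa Boundary position (default 14760, the human
#'   meta-transcript position of the internal Cronos promoter region).
#' @param novex3 Logical flag(s): variant lies in the Novex-3 exon.
#' @return Character vector in `{"N", "C", "NOVEX3_EXCLUDED"}`.
#' @export
classify_relative_to_cronos <- function(aa_position, boundary_aa = 14760L,
                                        novex3 = FALSE) {
  if (boundary_aa < 1L) stop("boundary_aa must be >= 1")
  if (any(aa_position <= 0L)) stop("input error: aa_position must be >= 1")
  n <- max(length(aa_position), length(novex3))
  aa_position <- rep_len(aa_position, n); novex3 <- rep_len(novex3, n)
  ifelse(novex3, "NOVEX3_EXCLUDED",
         ifelse(aa_position >= boundary_aa, "C", "N"))
}

#' Summarize truncation positions per cohort
#'
#' Counts truncating variants C-terminal and N-terminal to the boundary per
#' cohort, excluding (but tallying) Novex-3 variants, and formats the C:N
#' ratio text.
#'
#' @param table data.frame with `subject_id`, `cohort_label`, `aa_position`,
#'   `novex3` (logical), `truncating` (logical).
#' @param boundary_aa Boundary position (default 14760).
#' @return data.frame with one row per cohort: `cohort_label`, `n_C`, `n_N`,
#'   `n_novex3_excluded`, `ratio_text` ("C:N").
#' @export
summarize_cohorts <- function(table, boundary_aa = 14760L) {
  if (nrow(table) == 0L) stop("empty cohort table")
  tr <- table[table$truncating, , drop = FALSE]
  labs <- unique(table$cohort_label)
  rows <- lapply(labs, function(lb) {
    s <- tr[tr$cohort_label == lb, , drop = FALSE]
    cls <- if (nrow(s)) classify_relative_to_cronos(s$aa_position, boundary_aa,
                                                    s$novex3) else character(0)
    nC <- sum(cls == "C"); nN <- sum(cls == "N")
    data.frame(cohort_label = lb, n_C = nC, n_N = nN,
               n_novex3_excluded = sum(cls == "NOVEX3_EXCLUDED"),
               ratio_text = sprintf("%d:%d", nC, nN),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pooled two-proportion z-test
#'
#' Difference-in-proportions test with pooled variance; two-sided p from the
#' normal distribution. No continuity correction by default (exposed as a
#' flag). When both groups have zero (or all) successes the pooled variance
#' vanishes and the degenerate convention z = 0, p = 1 applies.
#'
#' @param x1,n1 Successes and size of group 1.
#' @param x2,n2 Successes and size of group 2.
#' @param correct Apply the Yates-style continuity correction (default FALSE).
#' @return Object of class `ProportionTestResult` with `p1`, `p2`, `z`,
#'   `p_value`.
#' @export
two_proportion_test <- function(x1, n1, x2, n2, correct = FALSE) {
  if (n1 <= 0 || n2 <= 0) stop("input error: group sizes must be > 0")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2)
    stop("input error: need 0 <= x <= n in both groups")
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  if (se == 0) {
    z <- 0; p <- 1
  } else {
    d <- p1 - p2
    if (correct) {
      cc <- min(abs(d), 0.5 * (1 / n1 + 1 / n2))
      d <- sign(d) * (abs(d) - cc)
    }
    z <- d / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(p1 = p1, p2 = p2, z = z, p_value = p),
            class = "ProportionTestResult")
}

#' @export
print.ProportionTestResult <- function(x, ...) {
  cat(sprintf("two-proportion test: p1=%.4f p2=%.4f z=%.3f p=%.4g\n",
              x$p1, x$p2, x$z, x$p_value))
  invisible(x)
}

#' Fold ratio of two proportions
#'
#' @param p1,p2 Proportions (p2 > 0).
#' @return `p1 / p2`.
#' @export
fold_ratio <- function(p1, p2) {
  if (p2 <= 0) stop("undefined fold: p2 must be > 0")
  p1 / p2
}

#' Read a cohort variant table
#'
#' @param path TSV with columns `subject_id`, `cohort_label`, `aa_position`,
#'   `novex3`, `truncating`.
#' @return Typed data.frame.
#' @export
read_cohort_table <- function(path) {
  tb <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("subject_id", "cohort_label", "aa_position", "novex3", "truncating")
  if (!all(need %in% names(tb)))
    stop("cohort table must have columns: ", paste(need, collapse = ", "))
  tb$aa_position <- as.integer(tb$aa_position)
  tb$novex3 <- as.logical(tb$novex3)
  tb$truncating <- as.logical(tb$truncating)
  tb
}
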