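#' Reciprocal overlap fractions of two interval sets
#'
#' An interval counts as overlapped when it shares at least one base pair
#' with any interval of the other set; fractions are interval-count based
#' ("share of binding sites"), not base-pair based. Two sets are called
#' reciprocally overlapping when each set has at least `threshold` of its
#' intervals overlapped (boundary inclusive).
#'
#' @param a,b Tidy interval tibbles (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @param threshold Reciprocal-overlap threshold (default 0.10).
#' @return Tibble with one row: `fraction_a`, `fraction_b`,
#'   `reciprocal_pass`.
#' @export
overlap_fractions <- function(a, b, threshold = 0.10) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    warn("empty interval set; overlap fractions defined as 0")
    return(tibble(fraction_a = 0, fraction_b = 0, reciprocal_pass = FALSE))
  }
  check_intervals(a, "a"); check_intervals(b, "b")
  ga <- as_granges(a); gb <- as_granges(b)
  fa <- mean(IRanges::overlapsAny(ga, gb))
  fb <- mean(IRanges::overlapsAny(gb, ga))
  tibble(
    fraction_a = fa, fraction_b = fb,
    reciprocal_pass = fa >= threshold && fb >= threshold
  )
}

#' Fisher exact test on interval-set co-occurrence
#'
#' Builds a 2x2 contingency table from two interval sets the way the
#' bedtools `fisher` utility does, estimating the "neither" cell from the
#' genome length and the mean interval size (an explicit approximation of
#' an otherwise unpublished internal): n11 = intervals of A overlapping B,
#' n12 = A not overlapping, n21 = B not overlapping, and
#' n22 = max(0, genome_size / mean_interval_length - n11 - n12 - n21).
#' The two-sided p-value is the exact hypergeometric test on that table.
#'
#' @param a,b Tidy interval tibbles.
#' @param genome_size Genome length in bases (must exceed the total
#'   covered length).
#' @return Tibble with one row: the four cells, `odds_ratio`, `p_value`.
#' @export
interval_fisher <- function(a, b, genome_size) {
  check_intervals(a, "a"); check_intervals(b, "b")
  ga <- as_granges(a); gb <- as_granges(b)
  covered <- sum(IRanges::width(GenomicRanges::reduce(c(ga, gb))))
  if (genome_size <= covered) {
    abort("genome_size must exceed the total covered length")
  }
  n11 <- sum(IRanges::overlapsAny(ga, gb))
  n12 <- nrow(a) - n11
  n21 <- nrow(b) - sum(IRanges::overlapsAny(gb, ga))
  mean_len <- mean(c(a$end - a$start, b$end - b$start))
  n22 <- max(0, round(genome_size / mean_len) - n11 - n12 - n21)
  tab <- matrix(c(n11, n12, n21, n22), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warn("degenerate contingency table (zero margin); p = 1")
    return(tibble(n11 = n11, n12 = n12, n21 = n21, n22 = n22,
                  odds_ratio = NA_real_, p_value = 1))
  }
  ft <- fisher.test(tab, alternative = "two.sided")
  tibble(n11 = n11, n12 = n12, n21 = n21, n22 = n22,
         odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' TSS windows from transcription start sites
#'
#' Expands single-base TSS positions into the +/- `pad` windows used for
#' annotation: `[tss - pad, tss + pad + 1)` half-open, covering the TSS
#' base itself. Strand is ignored.
#'
#' @param tss Tibble with `chrom` and `pos` (0-based TSS base).
#' @param pad Padding in bases (default 2500).
#' @return Tidy interval tibble.
#' @export
tss_windows <- function(tss, pad = 2500) {
  tibble(
    chrom = tss$chrom,
    start = pmax(0L, as.integer(tss$pos - pad)),
    end = as.integer(tss$pos + pad + 1L)
  )
}

#' Fraction of peaks falling in TE and TSS tracks
#'
#' Computes, independently, the fraction of peaks sharing at least one
#' base pair with the transposable-element track and with the TSS-window
#' track; a peak may count in both.
#'
#' @param peaks Tidy interval tibble of ChIP peaks.
#' @param te_track Transposable-element interval tibble.
#' @param tss_track TSS-window interval tibble (see [tss_windows()]).
#' @return Tibble with one row: `fraction_te`, `fraction_tss`.
#' @export
annotate_peaks <- function(peaks, te_track, tss_track) {
  if (nrow(peaks) == 0) {
    warn("empty peak set; fractions defined as 0")
    return(tibble(fraction_te = 0, fraction_tss = 0))
  }
  check_intervals(peaks, "peaks")
  gp <- as_granges(peaks)
  frac_in <- function(track) {
    if (nrow(track) == 0) return(0)
    mean(IRanges::overlapsAny(gp, as_granges(track)))
  }
  tibble(fraction_te = frac_in(te_track), fraction_tss = frac_in(tss_track))
}

#' Filter peaks by peak-caller score
#'
#' Keeps peaks whose score is strictly greater than `min_score`
#' (default 80, the MACS-score cut used for ChIP peak sets).
#'
#' @param peaks Tidy interval tibble with a `score` column.
#' @param min_score Score threshold (strict `>`).
#' @return Filtered peak tibble.
#' @export
filter_peaks <- function(peaks, min_score = 80) {
  if (nrow(peaks) == 0) return(peaks)
  if (!("score" %in% names(peaks)) || anyNA(peaks$score)) {
    abort("peaks must carry a complete `score` column")
  }
  peaks[peaks$score > min_score, , drop = FALSE]
}
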