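#' Select variants within +/- 1 kb of each gene's canonical transcript
#'
#' Keeps a variant when it lies on the same chromosome as its gene's
#' transcript and within the window spanning the transcript plus `pad`
#' bases on each side.
#'
#' @param variants Variant tibble (see [read_variant_table()]); `pos` is
#'   1-based.
#' @param exons Exon tibble with `gene_id`, `chrom`, `strand`, `start`,
#'   `end` (0-based half-open) and `coverage`.
#' @param pad Window padding in bases (default 1000).
#' @return Filtered variant tibble.
#' @export
select_region_variants <- function(variants, exons, pad = 1000) {
  if (nrow(variants) == 0) return(variants)
  span <- exons |>
    group_by(.data$gene_id) |>
    summarise(chrom = first(.data$chrom),
              tx_start = min(.data$start), tx_end = max(.data$end),
              .groups = "drop")
  v <- left_join(variants, span, by = "gene_id", suffix = c("", ".tx"))
  pos0 <- v$pos - 1L
  keep <- !is.na(v$tx_start) & v$chrom == v$chrom.tx &
    pos0 >= v$tx_start - pad & pos0 < v$tx_end + pad
  variants[keep, , drop = FALSE]
}

#' Keep variants passing quality filters
#'
#' @param variants Variant tibble.
#' @return Variants whose `filter_status` is exactly `"PASS"`.
#' @export
filter_pass <- function(variants) {
  variants[variants$filter_status == "PASS", , drop = FALSE]
}

#' Split multiallelic records and left-normalize simple indels
#'
#' One output record per ALT allele. Each (ref, alt) pair is reduced to
#' its minimal representation by trimming the shared suffix and then the
#' shared prefix (advancing `pos` accordingly), the usual normalization
#' applied before annotation.
#'
#' @param raw Tibble of raw records; `alt` may contain comma-separated
#'   alleles.
#' @return Variant tibble with exactly one ALT allele per record.
#' @export
split_multiallelic <- function(raw) {
  if (nrow(raw) == 0) return(raw)
  out <- raw |>
    mutate(alt = strsplit(.data$alt, ",", fixed = TRUE)) |>
    unnest("alt")
  norm <- pmap(list(out$pos, out$ref, out$alt), normalize_allele)
  out$pos <- vapply(norm, `[[`, 0L, "pos")
  out$ref <- vapply(norm, `[[`, "", "ref")
  out$alt <- vapply(norm, `[[`, "", "alt")
  out
}

normalize_allele <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  # shared suffix first, then shared prefix
  while (length(r) > 1 && length(a) > 1 && tail(r, 1) == tail(a, 1)) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

#' Coverage filter on transcripts and exons
#'
#' Drops transcripts whose length-weighted average per-base coverage is
#' not strictly greater than `min_coverage` (default 20x), then, within
#' kept transcripts, drops individual exons with average coverage strictly
#' below `min_coverage`. The coding length is recomputed over the kept
#' exons.
#'
#' @param exons Exon tibble (`gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `coverage`).
#' @param min_coverage Coverage threshold (default 20).
#' @return Filtered exon tibble.
#' @export
coverage_filter <- function(exons, min_coverage = 20) {
  tx <- exons |>
    group_by(.data$gene_id) |>
    summarise(
      avg_cov = sum(.data$coverage * (.data$end - .data$start)) /
        sum(.data$end - .data$start),
      .groups = "drop"
    )
  keep_tx <- tx$gene_id[tx$avg_cov > min_coverage]
  exons[exons$gene_id %in% keep_tx & exons$coverage >= min_coverage, ,
        drop = FALSE]
}

# 1-based CDS coordinate of a genomic position within a gene's kept exons,
# strand-aware; NA when the position falls outside the exons
cds_position <- function(pos, gene, exons) {
  e <- exons[exons$gene_id == gene, , drop = FALSE]
  if (nrow(e) == 0) return(NA_integer_)
  e <- arrange(e, .data$start)
  pos0 <- pos - 1L
  hit <- which(pos0 >= e$start & pos0 < e$end)
  if (length(hit) == 0) return(NA_integer_)
  before <- if (hit > 1) sum(e$end[seq_len(hit - 1)] - e$start[seq_len(hit - 1)]) else 0L
  cds_fwd <- before + (pos0 - e$start[hit]) + 1L
  if (first(e$strand) == "-") {
    total <- sum(e$end - e$start)
    return(as.integer(total - cds_fwd + 1L))
  }
  as.integer(cds_fwd)
}

#' Extract high-confidence loss-of-function variants
#'
#' Keeps variants annotated as LoF with high confidence that fall inside
#' the (coverage-filtered) exons and within the first `1 - tail_frac` of
#' the coding sequence; LoF calls in the last 5% of the canonical
#' transcript are removed, as are low-confidence or flagged calls.
#'
#' @param variants Variant tibble.
#' @param exons Exon tibble after [coverage_filter()].
#' @param tail_frac Terminal CDS fraction to exclude (default 0.05).
#' @return Filtered variant tibble with an added `cds_pos` column.
#' @export
extract_lof <- function(variants, exons, tail_frac = 0.05) {
  v <- variants[variants$consequence == "lof" &
                  variants$lof_confidence == "high", , drop = FALSE]
  if (nrow(v) == 0) { v$cds_pos <- integer(0); return(v) }
  cds_len <- exons |>
    group_by(.data$gene_id) |>
    summarise(cds_length = sum(.data$end - .data$start), .groups = "drop")
  v$cds_pos <- vapply(seq_len(nrow(v)), function(i) {
    cds_position(v$pos[i], v$gene_id[i], exons)
  }, 0L)
  v <- left_join(v, cds_len, by = "gene_id")
  keep <- !is.na(v$cds_pos) & v$cds_pos <= (1 - tail_frac) * v$cds_length
  v[keep, setdiff(names(v), "cds_length"), drop = FALSE]
}

#' Gene-level loss-of-function constraint Z-scores
#'
#' Per-gene LoF counts are normalized by coding length and converted to a
#' standard score across the analyzed gene set (population standard
#' deviation: the gene set is the whole population of interest). High Z
#' means more LoF variation per coding base, i.e. less constraint.
#'
#' @param lof_variants Variant tibble after [extract_lof()].
#' @param exons Exon tibble after [coverage_filter()]; defines the gene
#'   set and coding lengths.
#' @return Tibble with `gene_id`, `lof_count`, `cds_length`, `rate`, `z`.
#' @export
z_scores <- function(lof_variants, exons) {
  genes <- exons |>
    group_by(.data$gene_id) |>
    summarise(cds_length = sum(.data$end - .data$start), .groups = "drop")
  counts <- lof_variants |> count(.data$gene_id, name = "lof_count")
  out <- genes |>
    left_join(counts, by = "gene_id") |>
    mutate(lof_count = coalesce(.data$lof_count, 0L),
           rate = .data$lof_count / .data$cds_length)
  mu <- mean(out$rate)
  sigma <- sqrt(mean((out$rate - mu)^2))
  if (sigma == 0) {
    warn("zero variance in LoF rates; all z-scores set to 0")
    out$z <- 0
  } else {
    out$z <- (out$rate - mu) / sigma
  }
  out[, c("gene_id", "lof_count", "cds_length", "rate", "z")]
}

#' Full loss-of-function constraint cascade
#'
#' Applies the fixed stage order - region selection, PASS filter,
#' multiallelic split/normalization, coverage filter, LoF extraction,
#' Z-scores - and reports per-stage attrition.
#'
#' @param raw_variants Raw variant tibble (possibly multiallelic).
#' @param exons Exon tibble with coverage.
#' @param pad,min_coverage,tail_frac Stage parameters (defaults 1000, 20,
#'   0.05).
#' @return List with `constraints` (tibble from [z_scores()]), `attrition`
#'   (tibble `stage`, `n_variants`) and `exons_kept`.
#' @export
lof_constraint <- function(raw_variants, exons, pad = 1000,
                           min_coverage = 20, tail_frac = 0.05) {
  att <- list(tibble(stage = "input", n_variants = nrow(raw_variants)))
  v <- select_region_variants(raw_variants, exons, pad = pad)
  att <- c(att, list(tibble(stage = "region", n_variants = nrow(v))))
  v <- filter_pass(v)
  att <- c(att, list(tibble(stage = "pass", n_variants = nrow(v))))
  v <- split_multiallelic(v)
  att <- c(att, list(tibble(stage = "split", n_variants = nrow(v))))
  ex <- coverage_filter(exons, min_coverage = min_coverage)
  v <- extract_lof(v, ex, tail_frac = tail_frac)
  att <- c(att, list(tibble(stage = "lof", n_variants = nrow(v))))
  list(
    constraints = z_scores(v, ex),
    attrition = bind_rows(att),
    exons_kept = ex
  )
}
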