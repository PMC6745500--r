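# genomic (1-based) position of a 1-based CDS coordinate; inverse of
# cds_position() for exons sorted by start
genomic_from_cds <- function(cds_pos, e, strand) {
  total <- sum(e$end - e$start)
  fwd <- if (strand == "-") total - cds_pos + 1L else cds_pos
  cum <- cumsum(e$end - e$start)
  idx <- which(fwd <= cum)[1]
  before <- if (idx > 1) cum[idx - 1] else 0L
  as.integer(e$start[idx] + (fwd - before - 1L) + 1L)
}

#' Simulate gene models, exon coverage and LoF variant tables
#'
#' Builds synthetic canonical transcripts (multi-exon, stranded) with
#' per-exon mean coverage, then plants variants with known fate at every
#' stage of the loss-of-function constraint cascade: true high-confidence
#' LoF variants Poisson-distributed with a length-proportional rate
#' (inflated by `outlier_multiplier` for designated outlier genes) and
#' placed only where they survive all filters; plus known numbers of
#' variants outside the +/- 1 kb window, non-PASS variants, multiallelic
#' records, LoF calls in the last 5% of the CDS, low-confidence LoF calls
#' and non-LoF background variants.
#'
#' @param n_genes Number of genes (default 60).
#' @param length_range CDS length range in bases (default 900-3000).
#' @param lof_rate_per_base Expected LoF variants per coding base
#'   (default 0.005).
#' @param n_outliers,outlier_multiplier Genes with an inflated LoF rate
#'   (defaults 3 and 5).
#' @param coverage_mean,coverage_sd Per-exon coverage distribution for
#'   well-covered exons (defaults 30 and 4).
#' @param n_low_tx,n_low_exons Transcripts fully below the 20x coverage
#'   bar, and additional single low-coverage exons inside kept transcripts
#'   (defaults 2 and 3).
#' @param n_outside,n_nonpass,n_multiallelic,n_last5,n_lowconf,n_other
#'   Planted counts for each off-path category (defaults 10, 15, 5, 10,
#'   10, 20).
#' @param seed Mandatory RNG seed.
#' @return List with `exons` (tibble `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `coverage`), `variants` (raw variant tibble, possibly
#'   multiallelic) and `truth`.
#' @export
gen_gene_set <- function(n_genes = 60, length_range = c(900, 3000),
                         lof_rate_per_base = 0.005, n_outliers = 3,
                         outlier_multiplier = 5, coverage_mean = 30,
                         coverage_sd = 4, n_low_tx = 2, n_low_exons = 3,
                         n_outside = 10, n_nonpass = 15, n_multiallelic = 5,
                         n_last5 = 10, n_lowconf = 10, n_other = 20,
                         seed) {
  if (missing(seed)) abort("`seed` is mandatory")
  set.seed(seed)
  genes <- sprintf("gene%03d", seq_len(n_genes))
  strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  outliers <- sample(genes, n_outliers)
  low_tx <- sample(setdiff(genes, outliers), n_low_tx)

  exon_rows <- list()
  for (i in seq_len(n_genes)) {
    L <- sample(seq(length_range[1], length_range[2]), 1)
    n_ex <- sample(3:6, 1)
    cuts <- sort(sample(seq(100, L - 100), n_ex - 1))
    lens <- diff(c(0, cuts, L))
    offset <- (i - 1) * 50000
    starts <- offset + cumsum(c(0, head(lens, -1) + 1000))
    cov <- pmax(rnorm(n_ex, coverage_mean, coverage_sd), 21)
    if (genes[i] %in% low_tx) cov <- rep(12, n_ex)
    exon_rows[[i]] <- tibble(
      gene_id = genes[i], chrom = "chr1", strand = strands[i],
      start = as.integer(starts), end = as.integer(starts + lens),
      coverage = cov
    )
  }
  exons <- bind_rows(exon_rows)

  # plant single low-coverage exons where the transcript average stays > 20
  kept_genes <- setdiff(genes, low_tx)
  candidates <- sample(kept_genes)
  planted_low <- 0
  for (g in candidates) {
    if (planted_low >= n_low_exons) break
    idx <- which(exons$gene_id == g)
    j <- sample(idx, 1)
    old <- exons$coverage[j]
    exons$coverage[j] <- 15
    w <- exons$end[idx] - exons$start[idx]
    if (sum(exons$coverage[idx] * w) / sum(w) > 20) {
      planted_low <- planted_low + 1
    } else {
      exons$coverage[j] <- old
    }
  }

  # the generator's own view of the coverage cascade (weighted mean > 20,
  # then exon coverage >= 20), used to place true variants where they survive
  tx_cov <- exons |>
    group_by(.data$gene_id) |>
    summarise(avg = sum(.data$coverage * (.data$end - .data$start)) /
                sum(.data$end - .data$start), .groups = "drop")
  covered_genes <- tx_cov$gene_id[tx_cov$avg > 20]
  kept_exons <- exons[exons$gene_id %in% covered_genes &
                        exons$coverage >= 20, , drop = FALSE]

  mk_variant <- function(gene, pos, filter = "PASS", csq = "lof",
                         conf = "high", alt = "T") {
    tibble(chrom = "chr1", pos = as.integer(pos), ref = "A", alt = alt,
           filter_status = filter, gene_id = gene, consequence = csq,
           lof_confidence = conf)
  }
  place_in_cds <- function(gene, cds_lo, cds_hi, n) {
    e <- arrange(kept_exons[kept_exons$gene_id == gene, ], .data$start)
    strand <- first(e$strand)
    cds <- sample(seq(cds_lo, cds_hi), n, replace = TRUE)
    vapply(cds, genomic_from_cds, 0L, e = e, strand = strand)
  }
  cds_len <- kept_exons |>
    group_by(.data$gene_id) |>
    summarise(len = sum(.data$end - .data$start), .groups = "drop")
  len_of <- setNames(cds_len$len, cds_len$gene_id)

  vars <- list()
  true_lof <- setNames(rep(0L, n_genes), genes)
  for (g in covered_genes) {
    mult <- if (g %in% outliers) outlier_multiplier else 1
    n <- rpois(1, lof_rate_per_base * len_of[g] * mult)
    true_lof[g] <- n
    if (n > 0) {
      pos <- place_in_cds(g, 1, floor(0.95 * len_of[g]), n)
      vars[[length(vars) + 1]] <- mk_variant(g, pos)
    }
  }
  pick_gene <- function(n) sample(covered_genes, n, replace = TRUE)

  g_out <- pick_gene(n_outside)
  span <- exons |>
    group_by(.data$gene_id) |>
    summarise(tx_end = max(.data$end), .groups = "drop")
  tx_end <- setNames(span$tx_end, span$gene_id)
  vars[[length(vars) + 1]] <- mk_variant(g_out, tx_end[g_out] + 1000 + 100)

  g_np <- pick_gene(n_nonpass)
  vars[[length(vars) + 1]] <- mk_variant(
    g_np, vapply(g_np, function(g) place_in_cds(g, 1, floor(0.9 * len_of[g]), 1), 0L),
    filter = "RF"
  )
  g_ma <- pick_gene(n_multiallelic)
  vars[[length(vars) + 1]] <- mk_variant(
    g_ma, vapply(g_ma, function(g) place_in_cds(g, 1, floor(0.9 * len_of[g]), 1), 0L),
    csq = "other", conf = "na", alt = "T,G"
  )
  g_l5 <- pick_gene(n_last5)
  vars[[length(vars) + 1]] <- mk_variant(
    g_l5, vapply(g_l5, function(g) {
      place_in_cds(g, floor(0.95 * len_of[g]) + 1, len_of[g], 1)
    }, 0L)
  )
  g_lc <- pick_gene(n_lowconf)
  vars[[length(vars) + 1]] <- mk_variant(
    g_lc, vapply(g_lc, function(g) place_in_cds(g, 1, floor(0.9 * len_of[g]), 1), 0L),
    conf = "low"
  )
  g_ot <- pick_gene(n_other)
  vars[[length(vars) + 1]] <- mk_variant(
    g_ot, vapply(g_ot, function(g) place_in_cds(g, 1, floor(0.9 * len_of[g]), 1), 0L),
    csq = "other", conf = "na"
  )
  variants <- bind_rows(vars)

  list(
    exons = exons,
    variants = variants,
    truth = list(
      genes = tibble(
        gene_id = genes, strand = strands,
        covered = genes %in% covered_genes,
        outlier = genes %in% outliers,
        cds_length_covered = unname(len_of[genes]),
        true_lof = unname(true_lof)
      ),
      planted = list(
        n_outside = n_outside, n_nonpass = n_nonpass,
        n_multiallelic = n_multiallelic, n_last5 = n_last5,
        n_lowconf = n_lowconf, n_other = n_other,
        low_coverage_tx = low_tx, n_low_exons = planted_low
      )
    )
  )
}

#' Simulate two interval sets with a controlled reciprocal overlap
#'
#' Deterministically places `n_a` disjoint intervals and a second set in
#' which `round(target * n_b)` intervals overlap the first set while the
#' rest fall in the gaps, so the achieved per-set overlapped fractions
#' equal the rounded target (within 1/(2n)). A target of 1 yields
#' identical sets; a target of 0 yields disjoint sets.
#'
#' @param n_a,n_b Interval counts (defaults 200 each; at least 25 so the
#'   rounding error stays within 0.02).
#' @param reciprocal_overlap_target Desired overlapped fraction in `[0, 1]`.
#' @param width Interval width in bases (default 500).
#' @param seed RNG seed (layout is deterministic; kept for API uniformity).
#' @return List with interval tibbles `a` and `b` and `truth` (achieved
#'   fractions).
#' @export
gen_interval_sets <- function(n_a = 200, n_b = 200,
                              reciprocal_overlap_target, width = 500,
                              seed) {
  if (missing(seed)) abort("`seed` is mandatory")
  t <- reciprocal_overlap_target
  if (t < 0 || t > 1) abort("target must be in [0, 1]")
  if (n_a < 25 || n_b < 25) abort("need >= 25 intervals per set")
  set.seed(seed)
  gap <- 3 * width
  starts_a <- (seq_len(n_a) - 1) * (width + gap)
  a <- tibble(chrom = "chr1", start = as.integer(starts_a),
              end = as.integer(starts_a + width))
  ka <- round(t * n_a)
  kb <- round(t * n_b)
  b_rows <- list()
  if (kb >= ka) {
    if (ka > 0) {
      b_rows[[1]] <- a[seq_len(ka), ]
      extra <- kb - ka
      if (extra > 0) {
        # additional overlapping B intervals stacked inside the first A
        s <- rep(a$start[1], extra)
        b_rows[[2]] <- tibble(chrom = "chr1", start = as.integer(s + 1),
                              end = as.integer(s + width))
      }
    }
  } else if (ka > 0) {
    # one wide interval covering the surplus A intervals, then singles
    m <- ka - kb + 1
    b_rows[[1]] <- tibble(chrom = "chr1", start = a$start[1],
                          end = a$end[m])
    if (kb > 1) b_rows[[2]] <- a[seq(m + 1, ka), ]
  }
  n_free <- n_b - kb
  if (n_free > 0) {
    slots <- (seq_len(n_free) + n_a) * (width + gap) + width * 2
    b_rows[[length(b_rows) + 1]] <- tibble(
      chrom = "chr1", start = as.integer(slots),
      end = as.integer(slots + width)
    )
  }
  b <- arrange(bind_rows(b_rows), .data$chrom, .data$start, .data$end)
  list(
    a = a, b = b,
    truth = list(target = t, fraction_a = ka / n_a, fraction_b = kb / n_b)
  )
}
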