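exons_toy <- tibble::tibble(
  gene_id = "g1", chrom = "chr1", strand = "+",
  start = c(1000L, 3000L), end = c(2000L, 4000L),
  coverage = c(30, 30)
)

test_that("region selection keeps variants within 1 kb of the transcript", {
  mkv <- function(pos) tibble::tibble(
    chrom = "chr1", pos = as.integer(pos), ref = "A", alt = "T",
    filter_status = "PASS", gene_id = "g1", consequence = "lof",
    lof_confidence = "high"
  )
  # transcript spans [1000, 4000); window [0, 5000) half-open, pos is 1-based
  expect_equal(nrow(select_region_variants(mkv(1), exons_toy)), 1)     # pos0 = 0, inside
  expect_equal(nrow(select_region_variants(mkv(5000), exons_toy)), 1)  # pos0 = 4999, inside
  expect_equal(nrow(select_region_variants(mkv(5001), exons_toy)), 0)  # 1 bp outside
  expect_equal(nrow(select_region_variants(mkv(integer(0))[0, ], exons_toy)), 0)
})

test_that("the PASS filter is exact and case-sensitive", {
  v <- tibble::tibble(
    chrom = "chr1", pos = 1500L, ref = "A", alt = "T",
    filter_status = c("PASS", "RF", "pass"), gene_id = "g1",
    consequence = "lof", lof_confidence = "high"
  )
  expect_equal(filter_pass(v)$filter_status, "PASS")
})

test_that("multiallelic records split and normalize to minimal representation", {
  raw <- tibble::tibble(
    chrom = "chr1", pos = 100L, ref = "A", alt = "T,G",
    filter_status = "PASS", gene_id = "g1", consequence = "lof",
    lof_confidence = "high"
  )
  sp <- split_multiallelic(raw)
  expect_equal(nrow(sp), 2)
  expect_equal(sp$alt, c("T", "G"))

  bi <- dplyr::mutate(raw, alt = "T")
  expect_equal(split_multiallelic(bi), bi)

  # CTT -> CAT: shared suffix then prefix trimmed, position advanced
  indel <- dplyr::mutate(raw, ref = "CTT", alt = "CAT")
  norm <- split_multiallelic(indel)
  expect_equal(norm$pos, 101L)
  expect_equal(norm$ref, "T")
  expect_equal(norm$alt, "A")

  ins <- dplyr::mutate(raw, ref = "A", alt = "AT,ATT")
  ni <- split_multiallelic(ins)
  expect_equal(ni$ref, c("A", "A"))
  expect_equal(ni$alt, c("AT", "ATT"))
  expect_equal(ni$pos, c(100L, 100L))
})

test_that("coverage filtering applies both the transcript and the exon rule", {
  ex <- tibble::tibble(
    gene_id = c("g1", "g1", "g2", "g3"),
    chrom = "chr1", strand = "+",
    start = c(0L, 1000L, 5000L, 9000L),
    end = c(500L, 1500L, 5500L, 9500L),
    coverage = c(31, 19, 20, 25)
  )
  kept <- coverage_filter(ex)
  # g1 average (31+19)/2 = 25 > 20 -> kept, but its 19x exon is removed
  expect_equal(kept$gene_id, c("g1", "g3"))
  expect_equal(kept$coverage, c(31, 25))
  # g2 average exactly 20 -> dropped (strict >)
  expect_false("g2" %in% kept$gene_id)

  all_good <- dplyr::mutate(ex, coverage = 25)
  expect_equal(coverage_filter(all_good), all_good)
})

test_that("LoF extraction enforces confidence and the last-5% rule strand-aware", {
  mkv <- function(pos, conf = "high") tibble::tibble(
    chrom = "chr1", pos = as.integer(pos), ref = "A", alt = "T",
    filter_status = "PASS", gene_id = "g1", consequence = "lof",
    lof_confidence = conf
  )
  # cds_length = 2000; last 5% is cds_pos > 1900
  mid <- extract_lof(mkv(1500), exons_toy)        # cds_pos 500
  expect_equal(nrow(mid), 1)
  expect_equal(mid$cds_pos, 500L)
  late <- extract_lof(mkv(3950), exons_toy)       # cds_pos 1950 (0.975)
  expect_equal(nrow(late), 0)
  low <- extract_lof(mkv(1500, conf = "low"), exons_toy)
  expect_equal(nrow(low), 0)

  minus <- dplyr::mutate(exons_toy, strand = "-")
  early_minus <- extract_lof(mkv(3950), minus)    # cds_pos 51 on minus strand
  expect_equal(early_minus$cds_pos, 51L)
  late_minus <- extract_lof(mkv(1010), minus)     # cds_pos 1991
  expect_equal(nrow(late_minus), 0)
})

test_that("z-scores standardize length-normalized LoF rates", {
  ex <- tibble::tibble(
    gene_id = sprintf("g%d", 1:5), chrom = "chr1", strand = "+",
    start = 0L, end = c(1000L, 2000L, 1000L, 4000L, 2500L),
    coverage = 30
  )
  counts <- c(1L, 4L, 3L, 8L, 5L)
  v <- tibble::tibble(
    chrom = "chr1", pos = 10L, ref = "A", alt = "T",
    filter_status = "PASS",
    gene_id = rep(ex$gene_id, counts),
    consequence = "lof", lof_confidence = "high"
  )
  z <- z_scores(v, ex)
  rate <- counts / (ex$end - ex$start)
  brute <- (rate - mean(rate)) / sqrt(mean((rate - mean(rate))^2))
  expect_equal(z$z, brute)
  expect_equal(mean(z$z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z$z^2)), 1, tolerance = 1e-12)

  ex_eq <- dplyr::mutate(ex, end = 1000L)
  expect_warning(z0 <- z_scores(v[rep(1, 5), ] |>
                                  dplyr::mutate(gene_id = ex$gene_id),
                                ex_eq), "zero variance")
  expect_true(all(z0$z == 0))
})

test_that("the full cascade reproduces the synthetic truth stage by stage", {
  gs <- gen_gene_set(n_genes = 40, seed = 108)
  res <- lof_constraint(gs$variants, gs$exons)
  att <- setNames(res$attrition$n_variants, res$attrition$stage)
  pl <- gs$truth$planted
  n_true <- sum(gs$truth$genes$true_lof)

  expect_equal(att[["region"]], att[["input"]] - pl$n_outside)
  expect_equal(att[["pass"]], att[["region"]] - pl$n_nonpass)
  expect_equal(att[["split"]], att[["pass"]] + pl$n_multiallelic)
  expect_equal(att[["lof"]], n_true)
  expect_true(all(diff(unname(att[c("input", "region", "pass")])) <= 0))

  genes <- gs$truth$genes
  expect_equal(sort(res$constraints$gene_id),
               sort(genes$gene_id[genes$covered]))
  joined <- dplyr::inner_join(res$constraints, genes, by = "gene_id")
  expect_equal(joined$lof_count, joined$true_lof)
  # inflated-rate outliers sit in the upper tail of the constraint score
  expect_gt(min(joined$z[joined$outlier]), max(joined$z[!joined$outlier]))
  expect_equal(mean(res$constraints$z), 0, tolerance = 1e-10)
})
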