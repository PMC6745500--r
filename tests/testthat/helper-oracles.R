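# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (enumeration / direct formulas) and never call the
# package functions they check.

# exact two-sided Fisher p by full enumeration over all tables with the
# observed margins (probability-mass ordering)
oracle_fisher_p <- function(n11, n12, n21, n22) {
  r1 <- n11 + n12
  c1 <- n11 + n21
  n <- n11 + n12 + n21 + n22
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(ks, function(k) {
    exp(lchoose(c1, k) + lchoose(n - c1, r1 - k) - lchoose(n, r1))
  }, 0)
  p_obs <- probs[ks == n11]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
oracle_mw_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  combos <- utils::combn(length(pooled), na)
  u_obs <- u_stat(a, b)
  mu <- na * length(b) / 2
  us <- apply(combos, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# prefix-mean BFDR on a posterior vector, the definition spelled out
oracle_bfdr <- function(post) {
  ord <- order(post, decreasing = TRUE)
  out <- numeric(length(post))
  out[ord] <- cumsum(1 - post[ord]) / seq_along(ord)
  out
}

# random additive distance matrix: random topology + exponential branch
# lengths, distances read off the tree
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) stats::rexp(k, 10) + 0.05)
  as.matrix(ape::cophenetic.phylo(tr))
}

# tiny handcrafted count matrix: one bait, one control batch
toy_matrix <- function(bait_counts, ctrl_counts, prey = "preyA",
                       bait = "BAIT1", bait_self = 50) {
  nb <- length(bait_counts)
  nc <- length(ctrl_counts)
  counts <- rbind(c(bait_counts, ctrl_counts),
                  c(rep(bait_self, nb), rep(0, nc)))
  rownames(counts) <- c(prey, bait)
  colnames(counts) <- c(sprintf("b%d", seq_len(nb)), sprintf("c%d", seq_len(nc)))
  runs <- tibble::tibble(
    run_id = colnames(counts),
    bait_id = c(rep(bait, nb), rep("CONTROL", nc)),
    batch = "b1",
    bio_replicate = c(rep(1L, nb), seq_len(nc)),
    tech_replicate = c(seq_len(nb), rep(1L, nc)),
    control_kind = c(rep("none", nb), rep("gfp", nc))
  )
  count_matrix(counts, runs)
}

# interval sets realizing a prescribed bedtools-style 2x2 table
# (n11 A-intervals overlap B, n12 do not; n21 B-intervals do not overlap A;
# genome_size chosen so the estimated total slots give the wanted n22)
sets_for_table <- function(n11, n12, n21, n22, width = 100) {
  slot <- function(i) (i - 1) * 4 * width
  a_start <- vapply(seq_len(n11 + n12), slot, 0)
  a <- tibble::tibble(chrom = "chr1", start = a_start, end = a_start + width)
  b_over <- a[seq_len(n11), ]
  b_far <- vapply(seq_len(n21) + n11 + n12 + 5, slot, 0)
  b <- dplyr::bind_rows(b_over,
                        tibble::tibble(chrom = "chr1", start = b_far,
                                       end = b_far + width))
  genome_size <- width * (n11 + n12 + n21 + n22)
  list(a = a, b = b, genome_size = genome_size)
}
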