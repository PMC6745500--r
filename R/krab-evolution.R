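AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

# aligned sequence tibble (id, seq) -> character matrix, one row per sequence
seq_char_matrix <- function(seqs) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  lens <- nchar(seqs$seq)
  if (length(unique(lens)) > 1) {
    abort("sequences are not aligned: unequal lengths")
  }
  m <- do.call(rbind, strsplit(toupper(seqs$seq), ""))
  rownames(m) <- seqs$id
  m
}

#' Pairwise p-distance matrix of an aligned domain set
#'
#' The uncorrected distance used to build the KRAB A-box tree: for each
#' sequence pair, the fraction of mismatching columns among columns where
#' neither sequence has a gap (pairwise deletion).
#'
#' @param seqs Tibble with `id` and aligned `seq` (equal lengths, `-` gaps).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(seqs) {
  m <- seq_char_matrix(seqs)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) {
        abort(paste0("no comparable columns between '", rownames(m)[i],
                     "' and '", rownames(m)[j], "'"))
      }
      d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (Saitou-Nei Q-criterion) on uncorrected
#' distances. Negative branch-length estimates are clamped to zero with the
#' deficit transferred to the sibling branch (so the pair's total stays
#' equal to its distance), and ties in the Q-criterion are broken by the
#' lowest index pair, making the topology deterministic.
#'
#' @param d Symmetric distance matrix with zero diagonal and dimnames,
#'   n >= 2.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  if (!isSymmetric(unname(d))) abort("distance matrix must be symmetric")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  labels <- rownames(d)
  n <- nrow(d)
  if (n < 2) abort("need at least 2 taxa")
  node <- labels

  clamp_pair <- function(bi, bj) {
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    c(max(bi, 0), max(bj, 0))
  }
  fmt <- function(x) format(x, digits = 10, scientific = FALSE, trim = TRUE)

  while (n > 3) {
    r <- rowSums(d)
    best <- NULL; best_q <- Inf
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        q <- (n - 2) * d[i, j] - r[i] - r[j]
        if (q < best_q - 1e-12) { best_q <- q; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    b <- clamp_pair(bi, d[i, j] - bi)
    new_node <- paste0("(", node[i], ":", fmt(b[1]), ",",
                       node[j], ":", fmt(b[2]), ")")
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    node <- c(node[keep], new_node)
    rownames(d2) <- colnames(d2) <- seq_len(n - 1)
    d <- d2
    n <- n - 1
  }

  newick <- if (n == 2) {
    b <- d[1, 2] / 2
    paste0("(", node[1], ":", fmt(b), ",", node[2], ":", fmt(b), ");")
  } else {
    b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    b12 <- clamp_pair(b1, b2)
    b3 <- max(b3, 0)
    paste0("(", node[1], ":", fmt(b12[1]), ",", node[2], ":", fmt(b12[2]),
           ",", node[3], ":", fmt(b3), ");")
  }
  ape::read.tree(text = newick)
}

#' Column-wise consensus of aligned reference sequences
#'
#' Modal non-gap residue per column; ties broken by the alphabetically
#' first residue; all-gap columns yield a gap.
#'
#' @param seqs Tibble with `id`, aligned `seq`.
#' @return Single consensus string.
#' @export
consensus_sequence <- function(seqs) {
  if (nrow(seqs) == 0) abort("empty reference set")
  m <- seq_char_matrix(seqs)
  cons <- apply(m, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0) return("-")
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[tab == tab[1]][order(names(tab)[tab == tab[1]])][1]
  })
  paste(cons, collapse = "")
}

#' Classify KRAB A-boxes as standard (sK) or variant (vK)
#'
#' The variant-KRAB cluster is operationalized as a reproducible
#' distance-to-consensus rule: a domain is variant when its p-distance to
#' the consensus of the standard references exceeds `tau`. The default
#' `tau = 0.3` sits between the within-cluster divergence of standard
#' domains and the divergence of the variant cluster in the synthetic
#' calibration data.
#'
#' @param seqs Tibble with `id`, aligned `seq`.
#' @param sk_reference_ids Ids (subset of `seqs$id`) defining the standard
#'   KRAB references from which the consensus is built.
#' @param tau Distance threshold (strict `>` means variant).
#' @return Tibble with `id`, `dist_to_consensus`, `krab_class`.
#' @export
classify_krab <- function(seqs, sk_reference_ids, tau = 0.3) {
  refs <- seqs[seqs$id %in% sk_reference_ids, , drop = FALSE]
  if (nrow(refs) == 0) abort("empty sK reference set")
  cons <- consensus_sequence(refs)
  both <- bind_rows(tibble(id = ".consensus", seq = cons), seqs)
  m <- seq_char_matrix(both)
  cvec <- m[1, ]
  dist <- vapply(seq_len(nrow(m) - 1) + 1, function(i) {
    ok <- m[i, ] != "-" & cvec != "-"
    if (!any(ok)) abort(paste0("no comparable columns for '", m[i, 1], "'"))
    mean(m[i, ok] != cvec[ok])
  }, 0)
  tibble(
    id = seqs$id,
    dist_to_consensus = dist,
    krab_class = ifelse(dist > tau, "vK", "sK")
  )
}

#' Consensus logo: per-column residue probabilities and information content
#'
#' Observed residue frequencies per alignment column (gaps excluded from
#' the column counts), with information content measured in bits above a
#' uniform 1/20 background: IC = log2(20) - H(column). Columns that are
#' mostly gaps (> 50%) are dropped.
#'
#' @param seqs Tibble with `id`, aligned `seq`.
#' @return A `consensus_logo` object: `probabilities` tibble (`column`,
#'   `residue`, `prob`) and `information` tibble (`column`, `ic`).
#' @export
consensus_logo <- function(seqs) {
  m <- seq_char_matrix(seqs)
  gap_frac <- colMeans(m == "-")
  keep <- which(gap_frac <= 0.5)
  probs <- list(); ics <- numeric(length(keep))
  for (k in seq_along(keep)) {
    col <- m[, keep[k]]
    col <- col[col != "-"]
    tab <- table(factor(col, levels = AA20))
    p <- as.numeric(tab) / sum(tab)
    nz <- p > 0
    h <- -sum(p[nz] * log2(p[nz]))
    ics[k] <- log2(20) - h
    probs[[k]] <- tibble(column = k, residue = AA20[nz], prob = p[nz])
  }
  structure(
    list(
      probabilities = bind_rows(probs),
      information = tibble(column = seq_along(keep), ic = ics)
    ),
    class = "consensus_logo"
  )
}
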