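#' Subcellular-localization filter
#'
#' Discards edges where a nuclear-only bait pulled down a prey annotated as
#' exclusively cytoplasmic by its cellular-component classes. Preys without
#' annotation (absent from `prey_annotations` or carrying only the class
#' `"unknown"`) are kept, as are all edges of mixed nuclear/cytoplasmic
#' baits.
#'
#' @param edges Tibble with at least `bait_id` and `prey_id`.
#' @param bait_meta Tibble with `bait_id` and `localization`
#'   (`"nuclear"` or `"mixed"`).
#' @param prey_annotations Long tibble with `prey_id`, `cc_class` rows
#'   (classes among `"nuclear"`, `"cytoplasmic"`, `"other"`, `"unknown"`).
#' @return The edge tibble with conflicting edges removed.
#' @export
localization_filter <- function(edges, bait_meta, prey_annotations) {
  bad_loc <- setdiff(unique(bait_meta$localization), c("nuclear", "mixed"))
  if (length(bad_loc) > 0) {
    abort(paste0("unknown bait localization class: ", bad_loc[1]))
  }
  excl_cyto <- prey_annotations |>
    group_by(.data$prey_id) |>
    summarise(
      excl = all(.data$cc_class == "cytoplasmic") &&
        n() > 0 && !any(.data$cc_class == "unknown"),
      .groups = "drop"
    )
  e <- edges |>
    left_join(bait_meta[, c("bait_id", "localization")], by = "bait_id") |>
    left_join(excl_cyto, by = "prey_id") |>
    mutate(
      excl = coalesce(.data$excl, FALSE),
      drop = .data$localization %in% "nuclear" & .data$excl
    )
  edges[!e$drop, , drop = FALSE]
}

#' KAP1 recruitment strength (KAP1FC) of a bait
#'
#' KAP1FC is the log2 spectral-count fold change of the corepressor KAP1
#' (TRIM28) in a bait's purifications relative to controls. Baits at or
#' above the threshold (default 3) are classified as strong KAP1 binders;
#' below it, the interactome is not considered KAP1-associated.
#'
#' @param x A [count_matrix()].
#' @param bait Bait id.
#' @param kap1_id Prey id of KAP1 in the count matrix (default `"KAP1"`).
#' @param strong_threshold Strong/weak boundary on the log2 scale
#'   (default 3; the boundary itself is strong).
#' @param pseudocount,min_count Passed to [fold_change()].
#' @return Tibble with one row: `bait_id`, `kap1fc`, `class`
#'   (`"strong"`/`"weak"`).
#' @export
kap1_fc <- function(x, bait, kap1_id = "KAP1", strong_threshold = 3,
                    pseudocount = 0.5, min_count = 10) {
  if (!(kap1_id %in% x$preys)) {
    abort(paste0("KAP1 id '", kap1_id, "' absent from prey universe"))
  }
  fc <- fold_change(x, bait, prey = kap1_id,
                    pseudocount = pseudocount, min_count = min_count)
  kfc <- fc$log2_fc
  tibble(
    bait_id = bait, kap1fc = kfc,
    class = ifelse(kfc >= strong_threshold, "strong", "weak")
  )
}

#' Unique interactors per bait
#'
#' A prey is a unique interactor when it appears in exactly one bait's
#' final interactome. Reports the per-bait unique-prey count and flags
#' baits reaching `min_unique` (default 3) unique preys.
#'
#' @param edges Final interactome edge tibble (`bait_id`, `prey_id`).
#' @param min_unique Threshold for the flag (default 3).
#' @return List with `preys` (tibble `prey_id`, `bait_id`, `unique`) and
#'   `baits` (tibble `bait_id`, `n_unique`, `flagged`).
#' @export
unique_interactors <- function(edges, min_unique = 3) {
  deg <- edges |>
    distinct(.data$bait_id, .data$prey_id) |>
    add_count(.data$prey_id, name = "degree")
  preys <- deg |>
    mutate(unique = .data$degree == 1) |>
    select("prey_id", "bait_id", "unique")
  baits <- deg |>
    group_by(.data$bait_id) |>
    summarise(n_unique = sum(.data$degree == 1), .groups = "drop") |>
    mutate(flagged = .data$n_unique >= min_unique)
  list(preys = preys, baits = baits)
}

#' Shared interactors of genomically overlapping bait pairs vs random pairs
#'
#' For each bait pair binding overlapping genomic sites, counts the preys
#' shared by the two interactomes, then draws an equal number of random
#' non-overlapping bait pairs and compares the two count distributions by
#' a two-sided Mann-Whitney rank test (exact when both groups have at most
#' 20 pairs and no ties; normal approximation with tie correction
#' otherwise).
#'
#' @param edges Final interactome edge tibble.
#' @param overlap_pairs Tibble with `bait_a`, `bait_b` (genomically
#'   overlapping couples).
#' @param n_random Number of random couples (default `nrow(overlap_pairs)`),
#'   sampled without replacement from bait pairs not in `overlap_pairs`.
#' @param seed Mandatory RNG seed.
#' @return List with `observed` and `null` count tibbles and `p_value`.
#' @export
shared_partner_null <- function(edges, overlap_pairs, n_random = NULL,
                                seed) {
  if (missing(seed)) abort("`seed` is mandatory")
  if (is.null(n_random)) n_random <- nrow(overlap_pairs)
  prey_sets <- edges |>
    distinct(.data$bait_id, .data$prey_id) |>
    group_by(.data$bait_id) |>
    summarise(preys = list(.data$prey_id), .groups = "drop")
  sets <- setNames(prey_sets$preys, prey_sets$bait_id)
  shared <- function(a, b) {
    length(intersect(sets[[a]] %||% character(), sets[[b]] %||% character()))
  }
  observed <- overlap_pairs |>
    mutate(shared = map2(.data$bait_a, .data$bait_b, shared) |> unlist())

  baits <- sort(unique(edges$bait_id))
  all_pairs <- t(utils::combn(baits, 2))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  used <- key(overlap_pairs$bait_a, overlap_pairs$bait_b)
  eligible <- which(!(key(all_pairs[, 1], all_pairs[, 2]) %in% used))
  if (length(eligible) < n_random) {
    abort(paste0("only ", length(eligible),
                 " eligible non-overlapping pairs; ", n_random, " requested"))
  }
  set.seed(seed)
  pick <- sample(eligible, n_random)
  null <- tibble(bait_a = all_pairs[pick, 1], bait_b = all_pairs[pick, 2]) |>
    mutate(shared = map2(.data$bait_a, .data$bait_b, shared) |> unlist())

  exact <- nrow(observed) <= 20 && nrow(null) <= 20 &&
    !any(duplicated(c(observed$shared, null$shared)))
  p <- suppressWarnings(
    wilcox.test(observed$shared, null$shared,
                alternative = "two.sided", exact = exact)$p.value
  )
  list(observed = observed, null = null, p_value = p)
}

#' Pairwise Pearson correlation of bait interactome profiles
#'
#' Builds the bait x prey log2 fold-change profile matrix over the union
#' prey set (preys absent from a bait's edge list are imputed as
#' log2 fold change 0, i.e. no change) and computes all pairwise Pearson
#' correlations plus a hierarchical clustering order with correlation
#' distance (1 - r) and average linkage. Baits with zero-variance profiles
#' have undefined correlations and are excluded from clustering.
#'
#' @param edges Edge tibble with `bait_id`, `prey_id`, `log2_fc`
#'   (typically the final interactome).
#' @return A `kzfp_correlation` object: `correlation` matrix, clustering
#'   `order` (bait ids), and `dropped` (zero-variance baits).
#' @export
interactome_correlation <- function(edges) {
  prof <- edges |>
    distinct(.data$bait_id, .data$prey_id, .keep_all = TRUE) |>
    select("bait_id", "prey_id", "log2_fc") |>
    pivot_wider(names_from = "prey_id", values_from = "log2_fc",
                values_fill = 0)
  m <- as.matrix(prof[, -1, drop = FALSE])
  rownames(m) <- prof$bait_id
  v <- apply(m, 1, stats::var)
  dropped <- rownames(m)[v == 0 | is.na(v)]
  if (length(dropped) > 0) {
    warn(paste0("zero-variance profile(s) excluded from clustering: ",
                paste(dropped, collapse = ", ")))
  }
  keep <- setdiff(rownames(m), dropped)
  r <- suppressWarnings(cor(t(m), method = "pearson"))
  ord <- keep
  if (length(keep) > 2) {
    hc <- hclust(as.dist(1 - r[keep, keep]), method = "average")
    ord <- keep[hc$order]
  }
  structure(
    list(correlation = r, order = ord, dropped = dropped),
    class = "kzfp_correlation"
  )
}

#' Group KAP1FC values by the baits' TE-binding fraction
#'
#' Splits baits into low and high transposable-element binders at a cutoff
#' on the fraction of their ChIP peaks falling in TEs (default 0.40, low
#' is strictly below) and compares the two KAP1FC distributions with a
#' two-sided Mann-Whitney rank test. A pure regrouping: every bait with
#' peak data lands in exactly one group.
#'
#' @param kap1_calls Tibble of [kap1_fc()] rows.
#' @param te_fractions Tibble with `bait_id`, `fraction_te` (see
#'   [annotate_peaks()]); baits without peak data are dropped.
#' @param cutoff TE-fraction boundary (default 0.4).
#' @return List with `groups` (tibble `bait_id`, `kap1fc`, `te_group`) and
#'   `p_value`.
#' @export
kap1fc_by_te_fraction <- function(kap1_calls, te_fractions, cutoff = 0.4) {
  d <- inner_join(kap1_calls, te_fractions, by = "bait_id") |>
    mutate(te_group = ifelse(.data$fraction_te < cutoff, "low_te", "high_te"))
  p <- NA_real_
  if (n_distinct(d$te_group) == 2) {
    p <- suppressWarnings(
      wilcox.test(kap1fc ~ te_group, data = d,
                  alternative = "two.sided")$p.value
    )
  }
  list(groups = d[, c("bait_id", "kap1fc", "te_group")], p_value = p)
}

#' Export the final interactome as a weighted network
#'
#' Writes GEXF and node/edge TSVs via [write_network()]. Edge weights are
#' the average fold change over controls; bait nodes carry their KAP1FC
#' value and strong/weak class when `kap1_calls` is supplied, and their
#' KRAB class when `bait_meta` is supplied.
#'
#' @param edges Final interactome edge tibble (`bait_id`, `prey_id`,
#'   `avg_fc`).
#' @param prefix Output path prefix (see [write_network()]).
#' @param kap1_calls Optional tibble from [kap1_fc()] rows.
#' @param bait_meta Optional tibble with `bait_id`, `krab_class`.
#' @return File paths written, invisibly.
#' @export
export_network <- function(edges, prefix, kap1_calls = NULL,
                           bait_meta = NULL) {
  baits <- unique(edges$bait_id)
  preys <- setdiff(unique(edges$prey_id), baits)
  nodes <- bind_rows(
    tibble(id = baits, kind = "bait"),
    tibble(id = preys, kind = "prey")
  )
  nodes$kap1fc <- NA_real_
  nodes$class <- NA_character_
  if (!is.null(kap1_calls)) {
    i <- match(nodes$id, kap1_calls$bait_id)
    nodes$kap1fc <- kap1_calls$kap1fc[i]
    nodes$class <- kap1_calls$class[i]
  }
  if (!is.null(bait_meta) && "krab_class" %in% names(bait_meta)) {
    i <- match(nodes$id, bait_meta$bait_id)
    krab <- bait_meta$krab_class[i]
    nodes$class <- ifelse(is.na(nodes$class), krab, nodes$class)
  }
  net_edges <- tibble(
    source = edges$bait_id, target = edges$prey_id, weight = edges$avg_fc
  )
  write_network(nodes, net_edges, prefix)
}
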