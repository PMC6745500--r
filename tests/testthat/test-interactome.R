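bait_meta_toy <- tibble::tibble(
  bait_id = c("Bnuc", "Bmix"),
  localization = c("nuclear", "mixed")
)
ann_toy <- tibble::tibble(
  prey_id = c("cyto", "both", "both", "nuc"),
  cc_class = c("cytoplasmic", "nuclear", "cytoplasmic", "nuclear")
)

test_that("localization filter removes only nuclear-bait x exclusively-cytoplasmic edges", {
  edges <- tibble::tibble(
    bait_id = c("Bnuc", "Bmix", "Bnuc", "Bnuc"),
    prey_id = c("cyto", "cyto", "both", "unannotated")
  )
  out <- localization_filter(edges, bait_meta_toy, ann_toy)
  expect_equal(nrow(out), 3)
  expect_false(any(out$bait_id == "Bnuc" & out$prey_id == "cyto"))
  # mixed bait keeps the cytoplasmic prey; non-exclusive and unannotated kept
  expect_true(any(out$bait_id == "Bmix" & out$prey_id == "cyto"))
  expect_true(any(out$prey_id == "both"))
  expect_true(any(out$prey_id == "unannotated"))
})

test_that("localization and significance filters commute as per-edge predicates", {
  set.seed(41)
  edges <- tibble::tibble(
    bait_id = sample(c("Bnuc", "Bmix"), 40, replace = TRUE),
    prey_id = sample(c("cyto", "both", "nuc", "free"), 40, replace = TRUE),
    avg_fc = runif(40, 0.5, 10),
    bfdr = runif(40, 0, 0.05),
    qc_pass = TRUE
  )
  a <- localization_filter(call_significant(edges), bait_meta_toy, ann_toy)
  b <- call_significant(localization_filter(edges, bait_meta_toy, ann_toy))
  expect_equal(a, b)
})

test_that("every planted localization conflict is removed and nothing else", {
  sim <- gen_apms(apms_sim_config(n_baits = 15, n_preys = 150,
                                  n_controls = 8, seed = 51))
  loc <- gen_localization(sprintf("bait%03d", 1:15), sprintf("prey%04d", 1:150),
                          sim$truth$edges, conflict_rate = 0.2, seed = 52)
  truth <- sim$truth$edges
  kept <- localization_filter(truth, loc$bait_meta, loc$prey_annotations)
  removed <- dplyr::anti_join(truth, kept, by = c("bait_id", "prey_id"))
  expect_gt(nrow(loc$planted), 0)
  expect_equal(
    dplyr::arrange(removed[, c("bait_id", "prey_id")], bait_id, prey_id),
    dplyr::arrange(loc$planted, bait_id, prey_id)
  )
})

test_that("KAP1FC classification puts the boundary value in the strong class", {
  mk <- function(bait_counts, ctrl) {
    counts <- rbind(KAP1 = c(bait_counts, ctrl),
                    B1 = c(rep(40, length(bait_counts)), rep(0, length(ctrl))))
    colnames(counts) <- c(sprintf("b%d", seq_along(bait_counts)),
                          sprintf("c%d", seq_along(ctrl)))
    runs <- tibble::tibble(
      run_id = colnames(counts),
      bait_id = c(rep("B1", length(bait_counts)),
                  rep("CONTROL", length(ctrl))),
      batch = "b1",
      bio_replicate = c(rep(1L, length(bait_counts)), seq_along(ctrl)),
      tech_replicate = c(seq_along(bait_counts), rep(1L, length(ctrl))),
      control_kind = c(rep("none", length(bait_counts)),
                       rep("gfp", length(ctrl)))
    )
    count_matrix(counts, runs)
  }
  k1 <- kap1_fc(mk(c(24, 24), c(3, 3)), "B1")
  expect_equal(k1$kap1fc, 3)
  expect_equal(k1$class, "strong")   # boundary included
  k2 <- kap1_fc(mk(c(3, 3), c(3, 3)), "B1")
  expect_equal(k2$kap1fc, 0)
  expect_equal(k2$class, "weak")
  k3 <- kap1_fc(mk(c(48, 48), c(3, 3)), "B1")
  expect_equal(k3$kap1fc, 4)
  expect_equal(k3$class, "strong")
  expect_error(kap1_fc(toy_matrix(c(12, 12), c(1, 1)), "BAIT1"), "KAP1")
})

test_that("unique interactors match a brute-force degree scan", {
  shared <- tidyr::expand_grid(bait_id = c("B1", "B2"),
                               prey_id = c("p1", "p2", "p3"))
  u <- unique_interactors(shared)
  expect_equal(sum(u$baits$n_unique), 0)

  star <- tibble::tibble(bait_id = c("B1", "B1", "B2"),
                         prey_id = c("p1", "p2", "p3"))
  us <- unique_interactors(star)
  expect_true(all(us$preys$unique))

  set.seed(61)
  rnd <- dplyr::distinct(tibble::tibble(
    bait_id = sample(sprintf("B%d", 1:8), 120, replace = TRUE),
    prey_id = sample(sprintf("p%d", 1:40), 120, replace = TRUE)
  ))
  ur <- unique_interactors(rnd, min_unique = 3)
  deg <- table(rnd$prey_id)
  uniq_preys <- names(deg)[deg == 1]
  brute <- vapply(sort(unique(rnd$bait_id)), function(b) {
    sum(rnd$prey_id[rnd$bait_id == b] %in% uniq_preys)
  }, 0L)
  expect_equal(ur$baits$n_unique, unname(brute))
  expect_equal(ur$baits$flagged, unname(brute >= 3))
})

test_that("TE-fraction grouping of KAP1FC is a pure reindexing with a rank test", {
  kap1 <- tibble::tibble(bait_id = sprintf("B%d", 1:10),
                         kap1fc = c(4, 5, 3.5, 4.2, 6, 0.5, 1, 1.5, 2, 0.8),
                         class = "strong")
  te <- tibble::tibble(bait_id = sprintf("B%d", 1:9),
                       fraction_te = c(0.8, 0.9, 0.5, 0.7, 0.6,
                                       0.1, 0.2, 0.39, 0.3))
  g <- kap1fc_by_te_fraction(kap1, te)
  expect_equal(nrow(g$groups), 9)  # only baits with peak data
  expect_equal(sum(g$groups$te_group == "low_te"), 4)  # 0.39 is strictly below
  expect_equal(sum(table(g$groups$te_group)), 9)
  expect_equal(g$p_value,
               suppressWarnings(stats::wilcox.test(
                 kap1$kap1fc[6:9], kap1$kap1fc[1:5])$p.value))
})

test_that("shared-partner null compares to random couples with an exact rank test", {
  edges <- tidyr::expand_grid(bait_id = sprintf("B%d", 1:8),
                              prey_id = sprintf("p%d", 1:5))
  pairs <- tibble::tibble(bait_a = "B1", bait_b = "B2")
  res <- shared_partner_null(edges, pairs, seed = 9)
  expect_equal(res$observed$shared, 5)  # identical interactomes

  disjoint <- tibble::tibble(
    bait_id = rep(c("B1", "B2", "B3", "B4"), each = 2),
    prey_id = sprintf("p%d", 1:8)
  )
  res2 <- shared_partner_null(disjoint, pairs, seed = 9)
  expect_equal(res2$observed$shared, 0)

  expect_error(
    shared_partner_null(edges, tidyr::expand_grid(bait_a = "B1",
                                                  bait_b = sprintf("B%d", 2:8)),
                        n_random = 100, seed = 1),
    "eligible"
  )
})

test_that("the exact Mann-Whitney p matches full permutation enumeration", {
  # totally separated toy groups: smallest two-sided exact p for n = 3 + 3
  p_exact <- suppressWarnings(
    stats::wilcox.test(c(1, 2, 3), c(4, 5, 6), exact = TRUE)$p.value
  )
  expect_equal(p_exact, oracle_mw_p(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(p_exact, 0.1)
  set.seed(62)
  for (i in 1:10) {
    a <- sample(seq(1, 399, by = 2), sample(3:7, 1))  # odd vs even: no ties
    b <- sample(seq(2, 400, by = 2), sample(3:7, 1))
    expect_equal(
      suppressWarnings(stats::wilcox.test(a, b, exact = TRUE)$p.value),
      oracle_mw_p(a, b)
    )
  }
})

test_that("interactome correlation reproduces brute-force Pearson and flags degenerates", {
  edges <- tibble::tibble(
    bait_id = rep(c("B1", "B2", "B3"), each = 3),
    prey_id = rep(c("p1", "p2", "p3"), 3),
    log2_fc = c(1, 2, 3, 1, 2, 3, -1, -2, -3)
  )
  cc <- interactome_correlation(edges)
  expect_equal(unname(cc$correlation["B1", "B2"]), 1)
  expect_equal(unname(cc$correlation["B1", "B3"]), -1)
  expect_true(isSymmetric(cc$correlation))
  expect_true(all(abs(cc$correlation) <= 1 + 1e-12))
  expect_equal(unname(diag(cc$correlation)), rep(1, 3))

  set.seed(63)
  rnd <- tidyr::expand_grid(bait_id = c("B1", "B2", "B3"),
                            prey_id = sprintf("p%d", 1:6)) |>
    dplyr::mutate(log2_fc = rnorm(18))
  cr <- interactome_correlation(rnd)
  prof <- matrix(rnd$log2_fc, nrow = 3, byrow = TRUE)
  brute <- cor(t(prof))
  expect_equal(unname(cr$correlation), unname(brute))

  flat <- tibble::tibble(bait_id = c("B1", "B1", "B2", "B2"),
                         prey_id = c("p1", "p2", "p1", "p2"),
                         log2_fc = c(1, 1, 1, 2))
  expect_warning(cf <- interactome_correlation(flat), "zero-variance")
  expect_false("B1" %in% cf$order)
})
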