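test_that("AP-MS simulation is a pure function of its seed", {
  cfg <- apms_sim_config(n_baits = 6, n_preys = 50, n_controls = 6, seed = 91)
  s1 <- gen_apms(cfg)
  s2 <- gen_apms(cfg)
  expect_identical(s1$matrix$counts, s2$matrix$counts)
  expect_identical(s1$truth$edges, s2$truth$edges)
  s3 <- gen_apms(apms_sim_config(n_baits = 6, n_preys = 50, n_controls = 6,
                                 seed = 92))
  expect_false(identical(s1$matrix$counts, s3$matrix$counts))
})

test_that("control counts average to the serialized background rates", {
  sim <- gen_apms(apms_sim_config(n_baits = 2, n_preys = 60,
                                  n_controls = 600, seed = 93))
  ctrl <- sim$matrix$runs$run_id[sim$matrix$runs$bait_id == "CONTROL"]
  obs <- rowMeans(sim$matrix$counts[, ctrl])
  lam <- setNames(sim$truth$lambda0$lambda0, sim$truth$lambda0$prey_id)
  # Poisson mean over 600 runs: errors of order sqrt(lambda/600)
  z <- (obs - lam[names(obs)]) / sqrt(pmax(lam[names(obs)], 0.05) / 600)
  expect_lt(mean(abs(z) > 4), 0.02)
  expect_lt(abs(mean(obs - lam[names(obs)])), 0.05)
})

test_that("without enrichment, true-edge and background fold changes are indistinguishable", {
  sim <- gen_apms(apms_sim_config(n_baits = 12, n_preys = 200,
                                  n_controls = 12,
                                  enrichment_factor = 1 + 1e-9, seed = 94))
  sc <- suppressWarnings(score_interactions(sim$matrix))
  tru <- paste(sim$truth$edges$bait_id, sim$truth$edges$prey_id)
  is_true <- paste(sc$bait_id, sc$prey_id) %in% tru
  p <- suppressWarnings(
    stats::wilcox.test(sc$avg_fc[is_true], sc$avg_fc[!is_true])$p.value
  )
  expect_gt(p, 0.01)
})

test_that("planted localization conflicts scale with the conflict rate", {
  sim <- gen_apms(apms_sim_config(n_baits = 10, n_preys = 100,
                                  n_controls = 6, seed = 95))
  baits <- sprintf("bait%03d", 1:10)
  preys <- sprintf("prey%04d", 1:100)
  none <- gen_localization(baits, preys, sim$truth$edges,
                           conflict_rate = 0, seed = 96)
  expect_equal(nrow(none$planted), 0)
  kept <- localization_filter(sim$truth$edges, none$bait_meta,
                              none$prey_annotations)
  expect_equal(nrow(kept), nrow(sim$truth$edges))

  all_c <- gen_localization(baits, preys, sim$truth$edges,
                            conflict_rate = 1, seed = 97)
  kept2 <- localization_filter(sim$truth$edges, all_c$bait_meta,
                               all_c$prey_annotations)
  nuclear <- all_c$bait_meta$bait_id[all_c$bait_meta$localization == "nuclear"]
  # all annotated (non-bait) preys of nuclear baits are gone
  left_nuc <- kept2[kept2$bait_id %in% nuclear &
                      kept2$prey_id %in% preys, ]
  expect_equal(nrow(left_nuc), 0)
  # planted list is exactly the removed set on the true edges
  removed <- dplyr::anti_join(sim$truth$edges, kept2,
                              by = c("bait_id", "prey_id"))
  expect_equal(
    dplyr::arrange(removed[, 1:2], bait_id, prey_id),
    dplyr::arrange(all_c$planted, bait_id, prey_id)
  )
})

test_that("KRAB sequence simulation honors its divergence parameters", {
  zero <- gen_krab_sequences(n_sk = 5, n_vk = 2, divergence_sk = 0,
                             divergence_vk = 0, seed = 98)
  expect_true(all(zero$sequences$seq == zero$consensus))

  sim <- gen_krab_sequences(n_sk = 150, n_vk = 50, seed = 99)
  d_cons <- classify_krab(sim$sequences,
                          sim$truth$id[sim$truth$class == "sK"],
                          tau = 0.3)$dist_to_consensus
  sk <- d_cons[sim$truth$class == "sK"]
  vk <- d_cons[sim$truth$class == "vK"]
  expect_lt(abs(mean(sk) - 0.08), 0.03)
  expect_lt(abs(mean(vk) - 0.45), 0.05)

  # expected within-group pairwise p-distance vs a direct Monte-Carlo oracle
  L <- nchar(sim$sequences$seq[1])
  set.seed(100)
  mc <- replicate(4000, {
    a <- runif(1) < 0.08; b <- runif(1) < 0.08
    if (!a && !b) FALSE
    else if (xor(a, b)) TRUE
    else sample(19, 1) > 1  # both mutated: differ unless same residue drawn
  })
  sk_seqs <- sim$sequences[sim$truth$class == "sK", ]
  d <- p_distance_matrix(sk_seqs[1:40, ])
  expect_lt(abs(mean(d[upper.tri(d)]) - mean(mc)), 0.02)

  rep1 <- gen_krab_sequences(seed = 101)
  rep2 <- gen_krab_sequences(seed = 101)
  expect_identical(rep1$sequences, rep2$sequences)
})

test_that("codon pair simulation is seed-stable and stop-free, with exact zero-branch limit", {
  same <- gen_codon_pairs(n_pairs = 5, n_codons = 30, omega = 1,
                          branch_length = 0, seed = 102)
  expect_equal(same$seq_a, same$seq_b)
  cp <- gen_codon_pairs(n_pairs = 10, n_codons = 50, omega = 1,
                        branch_length = 0.5, seed = 103)
  stops <- c("TAA", "TAG", "TGA")
  for (s in c(cp$seq_a, cp$seq_b)) {
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(codons %in% stops))
  }
  expect_identical(cp, gen_codon_pairs(n_pairs = 10, n_codons = 50,
                                       omega = 1, branch_length = 0.5,
                                       seed = 103))
})

test_that("interval set simulation hits its reciprocal overlap target", {
  for (target in c(0, 0.1, 0.3, 0.7, 1)) {
    iv <- gen_interval_sets(n_a = 100, n_b = 100,
                            reciprocal_overlap_target = target, seed = 104)
    o <- suppressWarnings(overlap_fractions(iv$a, iv$b))
    expect_lt(abs(o$fraction_a - target), 0.02)
    expect_lt(abs(o$fraction_b - target), 0.02)
  }
  ident <- gen_interval_sets(n_a = 50, n_b = 50,
                             reciprocal_overlap_target = 1, seed = 105)
  expect_equal(ident$a, ident$b)
  disj <- gen_interval_sets(n_a = 50, n_b = 50,
                            reciprocal_overlap_target = 0, seed = 106)
  expect_equal(overlap_fractions(disj$a, disj$b)$fraction_a, 0)
})

test_that("gene set simulation plants variants with known per-stage fate", {
  gs <- gen_gene_set(n_genes = 30, seed = 107)
  gs2 <- gen_gene_set(n_genes = 30, seed = 107)
  expect_identical(gs$variants, gs2$variants)
  expect_identical(gs$exons, gs2$exons)

  v <- gs$variants
  pl <- gs$truth$planted
  expect_equal(sum(grepl(",", v$alt)), pl$n_multiallelic)
  expect_equal(sum(v$filter_status != "PASS"), pl$n_nonpass)
  # PASS filter removes exactly the planted non-PASS records
  expect_equal(nrow(v) - nrow(filter_pass(v)), pl$n_nonpass)
  # region filter removes exactly the planted outside-window records
  expect_equal(nrow(v) - nrow(select_region_variants(v, gs$exons)),
               pl$n_outside)
})
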