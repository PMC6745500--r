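test_that("p-distance uses pairwise deletion of gapped columns", {
  seqs <- tibble::tibble(id = c("a", "b", "c"),
                         seq = c("ACD-F", "ACEEF", "ACD-F"))
  d <- p_distance_matrix(seqs)
  expect_equal(d["a", "b"], 0.25)  # 1 mismatch over 4 comparable columns
  expect_equal(d["a", "c"], 0)
  expect_true(isSymmetric(d))

  full <- tibble::tibble(id = c("x", "y"), seq = c("AAAA", "CCCC"))
  expect_equal(p_distance_matrix(full)["x", "y"], 1)
  gappy <- tibble::tibble(id = c("x", "y"), seq = c("A---", "-CCC"))
  expect_error(p_distance_matrix(gappy), "comparable")
})

test_that("neighbor joining solves the 2- and 3-taxon cases analytically", {
  d2 <- matrix(c(0, 0.5, 0.5, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- nj_tree(d2)
  expect_equal(sort(t2$tip.label), c("A", "B"))
  expect_equal(sort(t2$edge.length), c(0.25, 0.25))

  d3 <- matrix(c(0, .4, .6, .4, 0, .8, .6, .8, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(d3)
  bl <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(unname(bl[c("A", "B", "C")]), c(0.1, 0.3, 0.5))

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("neighbor joining reconstructs additive matrices exactly", {
  for (n in 4:8) {
    d <- random_additive_matrix(n, seed = 100 + n)
    tr <- nj_tree(d)
    back <- as.matrix(ape::cophenetic.phylo(tr))[rownames(d), colnames(d)]
    expect_equal(back, d, tolerance = 1e-8)
    # independent reference implementation agrees on additive input
    ref <- as.matrix(ape::cophenetic.phylo(ape::nj(d)))[rownames(d), colnames(d)]
    expect_equal(back, ref, tolerance = 1e-8)
  }
})

test_that("variant KRAB classification recovers well-separated planted clusters", {
  sim <- gen_krab_sequences(n_sk = 40, n_vk = 15, divergence_sk = 0.05,
                            divergence_vk = 0.6, seed = 13)
  refs <- sim$truth$id[sim$truth$class == "sK"]
  cls <- classify_krab(sim$sequences, sk_reference_ids = refs)
  expect_equal(cls$krab_class, sim$truth$class)
})

test_that("a sequence equal to the consensus is standard; a fully diverged one is variant", {
  refs <- tibble::tibble(id = c("r1", "r2", "r3"),
                         seq = c("ACDEF", "ACDEF", "ACDEG"))
  cons <- consensus_sequence(refs)
  expect_equal(cons, "ACDEF")
  probe <- tibble::tibble(id = c("same", "far"),
                          seq = c("ACDEF", "WYWYW"))
  cls <- classify_krab(dplyr::bind_rows(refs, probe), refs$id, tau = 0.3)
  expect_equal(cls$krab_class[cls$id == "same"], "sK")
  expect_equal(cls$dist_to_consensus[cls$id == "far"], 1)
  expect_equal(cls$krab_class[cls$id == "far"], "vK")
  expect_error(classify_krab(probe, character(0)), "empty")
})

test_that("logo information content spans 0 to log2(20) and ignores sequence order", {
  seqs <- tibble::tibble(
    id = sprintf("s%d", 1:20),
    seq = paste0("A", c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                 rep(c("A", "C"), 10))
  )
  logo <- consensus_logo(seqs)
  ic <- logo$information$ic
  expect_equal(ic[1], log2(20))          # invariant column
  expect_equal(ic[2], 0)                 # uniform over all 20 residues
  expect_equal(ic[3], log2(20) - 1)      # two residues at 0.5
  probs <- logo$probabilities |>
    dplyr::group_by(column) |>
    dplyr::summarise(s = sum(prob))
  expect_true(all(abs(probs$s - 1) < 1e-12))

  set.seed(14)
  shuffled <- seqs[sample(nrow(seqs)), ]
  expect_equal(tidy(consensus_logo(shuffled)), tidy(logo))
})

test_that("mostly-gap columns are dropped from logos", {
  seqs <- tibble::tibble(id = c("a", "b", "c", "d"),
                         seq = c("A-", "A-", "AC", "A-"))
  logo <- consensus_logo(seqs)
  expect_equal(nrow(logo$information), 1)
})

test_that("the pairwise alignment utility produces a sane global alignment", {
  al <- align_pair("ACDEF", "ACEF", type = "AA")
  expect_equal(nchar(al$a), nchar(al$b))
  expect_equal(gsub("-", "", al$b), "ACEF")
})
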