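test_that("variant simulation matches its design expectations", {
  # error-free homozygous sites carry no alternative reads
  h <- simulate_variants(ploidy_sim_spec("homozygous", 500, error_rate = 0,
                                         seed = 3))
  expect_true(all(h$alt_count == 0L))
  expect_true(all(h$ref_count >= 1L))

  # mean alternative fraction converges to the design p (CLT bounds)
  d <- simulate_variants(ploidy_sim_spec("diploid_het", 1e4, 50, 0.005,
                                         seed = 5))
  fd <- d$alt_count / (d$ref_count + d$alt_count)
  expect_lt(abs(mean(fd) - 0.5), 0.01)

  t3 <- simulate_variants(ploidy_sim_spec("triploid", 1e4, 50, 0.005,
                                          frac_two_thirds = 0, seed = 5))
  ft <- t3$alt_count / (t3$ref_count + t3$alt_count)
  p_design <- (1 / 3) * (1 - 0.005) + (2 / 3) * 0.005
  expect_lt(abs(mean(ft) - p_design), 0.01)

  # law of large numbers at n = 1e5: within 3 sigma (sigma <= 0.5/sqrt(n))
  big <- simulate_variants(ploidy_sim_spec("diploid_het", 1e5, 50, 0.005,
                                           seed = 9))
  fb <- big$alt_count / (big$ref_count + big$alt_count)
  expect_lt(abs(mean(fb) - 0.5), 3 * 0.5 / sqrt(1e5))

  # pure function of the spec: byte-identical replays
  expect_identical(
    simulate_variants(ploidy_sim_spec("triploid", 100, seed = 42)),
    simulate_variants(ploidy_sim_spec("triploid", 100, seed = 42)))
})

test_that("presence-matrix simulation respects the Dollo generating model", {
  tr <- ten_leaf_tree()
  # no losses: each family present in exactly the leaf set under its gain
  sim0 <- simulate_presence_matrix(gain_loss_sim_spec(tr, 40, loss_rate = 0,
                                                      seed = 2))
  for (f in seq_len(nrow(sim0$matrix))) {
    g <- node_number_of(tr, sim0$truth$gain_node[f])
    below <- tips_under(tr, g)
    expect_setequal(colnames(sim0$matrix)[sim0$matrix[f, ]], below)
  }
  # weights concentrated on the root put all gains at the root
  root_lab <- infer_gain_node(tr, tr$tip.label)
  w <- stats::setNames(1, root_lab)
  simr <- simulate_presence_matrix(
    gain_loss_sim_spec(tr, 20, gain_node_weights = w, loss_rate = 0.3,
                       seed = 4))
  expect_true(all(simr$truth$gain_node == root_lab))
  # re-draw guarantee: no family is absent everywhere even at high loss
  simh <- simulate_presence_matrix(gain_loss_sim_spec(tr, 100,
                                                      loss_rate = 0.6,
                                                      seed = 6))
  expect_true(all(rowSums(simh$matrix) >= 1L))
  # determinism
  expect_identical(sim0, simulate_presence_matrix(
    gain_loss_sim_spec(tr, 40, loss_rate = 0, seed = 2)))
})

test_that("gene-tree simulation builds the designed allo/auto topologies", {
  tr <- panagro_tree()
  donor <- panagro_donor_edge(tr)
  allo <- simulate_gene_trees(origin_sim_spec("allo", tr,
                                              panagro_parthenogens,
                                              donor_edge = donor,
                                              n_trees = 5, noise_nni = 0,
                                              seed = 8))
  for (g in allo) {
    copy2 <- grep("copy2$", g$tip.label, value = TRUE)
    expect_length(copy2, 3L)
    # extra copies form their own clade (external-donor signature)
    expect_true(ape::is.monophyletic(g, copy2))
    # grafted on the donor edge: donor clade plus the genus copy-1 leaves
    # form a clade below the graft point
    genus <- paste0(c(panagro_parthenogens, "ES5", "superbus"), "|copy1")
    expect_true(ape::is.monophyletic(g, c(copy2, genus)))
  }
  auto <- simulate_gene_trees(origin_sim_spec("auto", tr,
                                              panagro_parthenogens,
                                              n_trees = 5, noise_nni = 0,
                                              seed = 8))
  for (g in auto) {
    for (p in panagro_parthenogens) {
      # each extra copy is sister to its conspecific first copy
      pair <- paste0(p, c("|copy1", "|copy2"))
      expect_true(ape::is.monophyletic(g, pair))
    }
  }
  # NNI noise keeps the leaf set and rootedness
  noisy <- simulate_gene_trees(origin_sim_spec("auto", tr,
                                               panagro_parthenogens,
                                               n_trees = 3, noise_nni = 3,
                                               seed = 8))
  for (g in noisy) {
    expect_true(ape::is.rooted(g))
    expect_setequal(g$tip.label, auto[[1]]$tip.label)
  }
  expect_identical(
    lapply(allo, ape::write.tree),
    lapply(simulate_gene_trees(origin_sim_spec("allo", tr,
                                               panagro_parthenogens,
                                               donor_edge = donor,
                                               n_trees = 5, noise_nni = 0,
                                               seed = 8)), ape::write.tree))
})

test_that("hit-evidence simulation honours its class contracts", {
  sim <- simulate_hit_evidence(hgt_sim_spec(4, 3, 2, seed = 13))
  ai <- summarize_hits(sim$hits)
  by_role <- merge(ai, sim$truth, by = "gene_id")
  expect_true(all(by_role$ai[by_role$role == "native"] < 0))
  expect_true(all(by_role$ai[by_role$role == "hgt"] > 30))
  expect_true(all(by_role$ai[by_role$role == "contaminant"] > 0))
  # identity contracts
  expect_true(all(by_role$best_nonmeta_identity[by_role$role == "hgt"] <= 70))
  expect_true(all(
    by_role$best_nonmeta_identity[by_role$role == "contaminant"] > 70))
  # structural contracts
  g <- sim$genes
  expect_true(all(g$intron_count[sim$truth$role != "contaminant"] >= 1L))
  expect_true(all(g$intron_count[sim$truth$role == "contaminant"] == 0L))
  # expression contracts
  expect_true(all(sim$expression[sim$truth$role == "hgt"] > 100))
  expect_true(all(sim$expression[sim$truth$role == "contaminant"] < 10))
  expect_identical(sim, simulate_hit_evidence(hgt_sim_spec(4, 3, 2, seed = 13)))
})
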