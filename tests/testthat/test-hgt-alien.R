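test_that("alien_index matches its closed form and properties", {
  # equal evidence on both sides is indifferent
  expect_equal(alien_index(1e-10, 1e-10), 0)
  # no metazoan hit vs a strong non-metazoan hit: 50 * ln 10
  expect_equal(alien_index(1, 1e-50), 50 * log(10), tolerance = 1e-9)
  # both present: 45 * ln 10
  expect_equal(alien_index(1e-5, 1e-50), 45 * log(10), tolerance = 1e-9)
  expect_error(alien_index(-1, 0.5), "non-negative")

  # antisymmetry, monotonicity, bound — randomized grids
  set.seed(101)
  ev <- 10^runif(200, -180, 2)  # includes values > 1, capped
  ev2 <- 10^runif(200, -180, 2)
  expect_equal(alien_index(ev, ev2), -alien_index(ev2, ev))
  expect_true(all(abs(alien_index(ev, ev2)) <= 200 + log(2) + 1e-9))
  # decreasing the non-metazoan e-value never decreases AI
  base <- alien_index(ev, ev2)
  better <- alien_index(ev, ev2 / 10)
  expect_true(all(better >= base - 1e-12))
})

test_that("summarize_hits picks deterministic best hits per partition", {
  h <- data.frame(
    query_id = c("g1", "g1", "g2", "g3", "g3"),
    subject_id = c("nm1", "nm2", "m1", "nmA", "nmB"),
    taxon_partition = c("non_metazoan", "non_metazoan", "metazoan",
                        "non_metazoan", "non_metazoan"),
    evalue = c(1e-40, 1e-35, 1e-8, 1e-20, 1e-20),
    percent_identity = c(55, 60, 70, 40, 45),
    bitscore = c(200, 180, 90, 150, 180),
    stringsAsFactors = FALSE)
  ai <- summarize_hits(h)
  # only non-metazoan hits: AI = 40 ln 10, donor recorded
  g1 <- ai[ai$gene_id == "g1", ]
  expect_equal(g1$ai, 40 * log(10), tolerance = 1e-9)
  expect_equal(g1$donor_hint, "nm1")
  # only metazoan hits: negative AI, no candidate material
  expect_lt(ai$ai[ai$gene_id == "g2"], 0)
  # e-value tie broken by higher bitscore
  expect_equal(ai$donor_hint[ai$gene_id == "g3"], "nmB")
})

test_that("evidence collection reads structure, neighbours and expression", {
  sim <- simulate_hit_evidence(hgt_sim_spec(3, 2, 1, seed = 21))
  ai <- summarize_hits(sim$hits)
  ev <- collect_evidence(sim$genes, ai, sim$expression)
  by_role <- merge(ev, sim$truth, by = "gene_id")
  # HGT genes share contigs with natives whose best hit is metazoan
  expect_true(all(by_role$has_metazoan_neighbor[by_role$role == "hgt"]))
  expect_true(all(by_role$on_multigene_contig[by_role$role == "hgt"]))
  # contaminants sit alone on their contigs
  expect_false(any(by_role$on_multigene_contig[by_role$role == "contaminant"]))
  expect_false(any(by_role$has_metazoan_neighbor[by_role$role == "contaminant"]))

  # with no natives at all, anchors still provide metazoan neighbours
  sim0 <- simulate_hit_evidence(hgt_sim_spec(0, 5, 0, seed = 22))
  ai0 <- summarize_hits(sim0$hits)
  ev0 <- collect_evidence(sim0$genes, ai0, sim0$expression)
  hgt0 <- ev0[grepl("^hgt", ev0$gene_id), ]
  expect_equal(nrow(hgt0), 5L)
  expect_true(all(hgt0$has_metazoan_neighbor))

  # unknown gene: warning and defaults
  ai_extra <- rbind(ai, data.frame(gene_id = "ghost", best_meta_evalue = 1,
                                   best_nonmeta_evalue = 1e-60,
                                   ai = alien_index(1, 1e-60),
                                   best_nonmeta_identity = 50,
                                   donor_hint = "x"))
  expect_warning(ev2 <- collect_evidence(sim$genes, ai_extra, sim$expression),
                 "ghost")
  ghost <- ev2[ev2$gene_id == "ghost", ]
  expect_equal(ghost$intron_count, 0L)
  expect_false(ghost$on_multigene_contig)
  expect_equal(ghost$tpm, 0)
})

test_that("candidate classification applies the tier rules in order", {
  mk_ai <- function(gene, ai, ident) data.frame(
    gene_id = gene, best_meta_evalue = 1, best_nonmeta_evalue = 1,
    ai = ai, best_nonmeta_identity = ident, donor_hint = "d",
    stringsAsFactors = FALSE)
  mk_ev <- function(gene, introns, tpm) {
    d <- data.frame(gene_id = gene, intron_count = introns,
                    on_multigene_contig = TRUE,
                    has_metazoan_neighbor = TRUE, tpm = tpm,
                    stringsAsFactors = FALSE)
    d$pfam_domains <- list(character())
    d
  }
  # near-identity to a non-metazoan protein marks contamination even with
  # strong AI — the identity rule wins
  c1 <- classify_candidates(mk_ai("a", 45, 85), mk_ev("a", 2, 350))
  expect_equal(c1$status, "contaminant")
  # strong AI + introns + expression: high confidence
  c2 <- classify_candidates(mk_ai("b", 45, 55), mk_ev("b", 2, 350))
  expect_equal(c2$status, "high_confidence")
  # weak positive AI, no introns: plain candidate
  c3 <- classify_candidates(mk_ai("c", 12, 40), mk_ev("c", 0, 0))
  expect_equal(c3$status, "candidate_ai0")
  # strong AI but no expression support: strong candidate, not high conf.
  c4 <- classify_candidates(mk_ai("d", 45, 55), mk_ev("d", 2, 50))
  expect_equal(c4$status, "candidate_ai30")
  # non-positive AI is never a candidate
  c5 <- classify_candidates(mk_ai("e", -3, 90), mk_ev("e", 2, 350))
  expect_equal(c5$status, "not_candidate")
})

test_that("tier report counts match the generator contract", {
  sim <- simulate_hit_evidence(hgt_sim_spec(10, 5, 3, seed = 31))
  ai <- summarize_hits(sim$hits)
  ev <- collect_evidence(sim$genes, ai, sim$expression)
  cl <- classify_candidates(ai, ev)
  rep <- tier_report(cl, ev)
  expect_equal(rep$ai_gt0, 8L)        # 5 HGT + 3 contaminants
  expect_equal(rep$contaminants, 3L)
  expect_equal(rep$ai_gt30, 5L)       # contaminants excluded
  expect_equal(rep$high_confidence, 5L)
  # nested expression tiers are non-increasing
  expect_true(rep$tpm_gt10 >= rep$tpm_gt100 &&
              rep$tpm_gt100 >= rep$tpm_gt1000)

  # empty input: all counts zero
  empty <- tier_report(cl[0, ], ev[0, ])
  expect_equal(empty$ai_gt0, 0L)
  expect_equal(empty$contaminants, 0L)
  expect_equal(empty$ai_gt30, 0L)
})

test_that("the screen recovers every designed class exactly end-to-end", {
  sim <- simulate_hit_evidence(hgt_sim_spec(12, 8, 5, seed = 77))
  ai <- summarize_hits(sim$hits)
  ev <- collect_evidence(sim$genes, ai, sim$expression)
  cl <- classify_candidates(ai, ev)
  got <- merge(cl, sim$truth, by = "gene_id")
  expect_true(all(got$status[got$role %in% c("native", "anchor")] ==
                  "not_candidate"))
  expect_true(all(got$status[got$role == "hgt"] == "high_confidence"))
  expect_true(all(got$status[got$role == "contaminant"] == "contaminant"))
})
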