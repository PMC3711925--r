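ref_map_for_locus <- function(species = "human") {
  toy_map(species, symbols = c("GALNT13", "P1", "KCNJ3", "P2", "NR4A2"))
}

test_that("synteny evidence counts shared flanks as unordered sets", {
  m1 <- toy_map("a", c("F1", "F2", "F3", "G", "F4", "F5", "F6"))
  m2 <- toy_map("b", c("F1", "F2", "F3", "G", "F4", "F5", "F6"))
  ev <- synteny_evidence(m1, "G", m2, "G", k = 3)
  expect_equal(ev$shared_upstream, 3L)
  expect_equal(ev$shared_downstream, 3L)
  expect_false(ev$rearrangement_flag)

  ## planted inversion of downstream flanks: counts unchanged
  m3 <- toy_map("c", c("F1", "F2", "F3", "G", "F6", "F5", "F4"))
  ev2 <- synteny_evidence(m1, "G", m3, "G", k = 3)
  expect_equal(ev2$shared_downstream, 3L)
})

test_that("flanks split across chromosomes raise the rearrangement flag", {
  m1 <- toy_map("a", c("F1", "F2", "G", "F3", "F4"))
  split_feats <- rbind(
    data.frame(symbol = c("F1", "F2", "G", "F3"), chrom = "chr1",
               start = 1:4 * 1000L, end = 1:4 * 1000L + 500L,
               strand = "+", is_gap = FALSE),
    data.frame(symbol = "F4", chrom = "chr9", start = 1000L, end = 1500L,
               strand = "+", is_gap = FALSE))
  m2 <- genome_map("b", split_feats)
  ev <- synteny_evidence(m1, "G", m2, "G", k = 2)
  expect_true(ev$rearrangement_flag)
})

test_that("classification rules fire in order with a rule trace", {
  finch <- toy_map("finch", c("GALNT13", "P1", "CAND", "P2", "NR4A2"))
  ref <- ref_map_for_locus()
  ortho <- classify_locus(list(symbol = "CAND", map = finch), "KCNJ3", ref)
  expect_equal(ortho$call, "ortholog")
  expect_true(any(grepl("rule 1", ortho$rule_trace)))

  ## duplication: distinct conserved flanks in >= 2 comparator species
  dup_ctx <- c("D1", "D2", "CAND", "D3", "D4")
  finch2 <- toy_map("finch", dup_ctx)
  lizard <- toy_map("lizard", dup_ctx)
  chicken <- toy_map("chicken", dup_ctx)
  dup <- classify_locus(list(symbol = "CAND", map = finch2), "KCNJ3", ref,
                        comparator_maps = list(lizard, chicken))
  expect_equal(dup$call, "duplication")
  one_only <- classify_locus(list(symbol = "CAND", map = finch2), "KCNJ3",
                             ref, comparator_maps = list(lizard))
  expect_equal(one_only$call, "unresolved")

  ## allele: high identity on an unplaced scaffold
  un_feats <- data.frame(symbol = "CAND", chrom = "chrUn_sc1", start = 1L,
                         end = 1500L, strand = "+", is_gap = FALSE)
  finch3 <- genome_map("finch", un_feats)
  aln <- align_local("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGT")
  allele <- classify_locus(list(symbol = "CAND", map = finch3), "KCNJ3",
                           ref, alignment = aln)
  expect_equal(allele$call, "allele")

  ## pseudogene: degradation marks trump neighborhood sharing
  pg <- classify_locus(list(symbol = "CAND", map = finch), "KCNJ3", ref,
                       degradation = c("missing_start_codon", "truncated"))
  expect_equal(pg$call, "pseudogene")
  expect_true(any(grepl("degradation", pg$rule_trace)))

  ## fallback
  unres <- classify_locus(list(symbol = "CAND", map = finch2), "KCNJ3", ref)
  expect_equal(unres$call, "unresolved")
})

test_that("classification is invariant to comparator species order", {
  dup_ctx <- c("D1", "D2", "CAND", "D3", "D4")
  finch <- toy_map("finch", dup_ctx)
  ref <- ref_map_for_locus()
  maps <- list(toy_map("lizard", dup_ctx), toy_map("chicken", dup_ctx),
               toy_map("frog", c("Z1", "Z2", "Z3")))
  calls <- lapply(list(maps, rev(maps), maps[c(2, 3, 1)]), function(mm)
    classify_locus(list(symbol = "CAND", map = finch), "KCNJ3", ref,
                   comparator_maps = mm)$call)
  expect_true(all(unlist(calls) == "duplication"))
})

test_that("presence matrix distinguishes absent from unknown_gap", {
  present_map <- function(sp, with_gene = TRUE, with_gap = FALSE)
    toy_map(sp, symbols = c("F1", if (with_gene) "G" else NULL, "F2"),
            gap_at = if (with_gap) 1500L else NULL)
  maps <- list(present_map("a"), present_map("b"),
               present_map("c", with_gene = FALSE),
               present_map("d", with_gene = FALSE, with_gap = TRUE))
  pm <- build_presence_matrix("G", maps)
  expect_equal(unname(pm["G", ]),
               c("present", "present", "absent", "unknown_gap"))
  all_present <- build_presence_matrix("G", maps[1:2])
  expect_true(all(all_present == "present"))
})

test_that("Dollo reconciliation reproduces the published narratives", {
  tree <- default_species_tree()
  ## duplicated in bony vertebrates, lost in mammals
  prof1 <- setNames(rep("unknown_gap", 8),
                    c("fish", "frog", "lizard", "chicken", "finch",
                      "platypus", "mouse", "human"))
  prof1[c("fish", "lizard", "chicken", "finch")] <- "present"
  prof1[c("mouse", "human")] <- "absent"
  ev1 <- dollo_reconcile(prof1, tree)
  expect_equal(ev1$gain_node, "teleostomi")
  expect_equal(ev1$loss_branches, "mammalia")

  ## gained in tetrapods, lost in the supraprimates
  tree10 <- parse_tree(paste0(
    "(fish,(frog,((lizard,(chicken,finch)),(platypus,((mouse,human)",
    "supraprimates,(horse,cow)))mammalia)amniota)tetrapoda)root;"))
  prof2 <- setNames(rep("present", 10), tree10$tip.label)
  prof2[c("fish", "mouse", "human")] <- "absent"
  ev2 <- dollo_reconcile(prof2, tree10)
  expect_equal(ev2$gain_node, "tetrapoda")
  expect_equal(ev2$loss_branches, "supraprimates")

  ## present everywhere
  prof3 <- setNames(rep("present", 8), tree$tip.label)
  ev3 <- dollo_reconcile(prof3, tree)
  expect_equal(ev3$gain_node, "teleostomi")
  expect_equal(ev3$n_losses, 0L)

  expect_error(dollo_reconcile(
    setNames(rep("absent", 8), tree$tip.label), tree), "all-absent")
})

test_that("Dollo output is minimal: matches brute-force on random trees", {
  set.seed(21)
  for (rep in 1:40) {
    rp <- random_profile_tree(sample(4:12, 1))
    got <- dollo_reconcile(rp$profile, rp$tree)
    want <- oracle_dollo(rp$profile, rp$tree)
    expect_equal(got$n_losses, want$n)
    expect_equal(got$gain_node_id, want$node)
  }
})
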