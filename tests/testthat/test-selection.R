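test_that("NG86 site counts match the published special cases", {
  tt <- ng86_site_counts("TTT")
  expect_equal(unname(tt["s_sites"]), 1 / 3)
  expect_equal(unname(tt["n_sites"]), 8 / 3)
  atg <- ng86_site_counts("ATG")
  expect_equal(unname(atg["s_sites"]), 0)
  expect_equal(unname(atg["n_sites"]), 3)
  expect_error(ng86_site_counts("TAA"), "stop codon")
  expect_error(ng86_site_counts("AXG"), "not a codon")
})

test_that("site counts equal the genetic-code walk for all 61 codons", {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  for (codon in sense) {
    got <- ng86_site_counts(codon)
    want <- oracle_ng86_sites(codon)
    expect_equal(unname(got["s_sites"]), unname(want["s_sites"]),
                 tolerance = 1e-12, label = codon)
    expect_equal(unname(got["n_sites"]) + unname(got["s_sites"]), 3,
                 label = codon)
  }
})

test_that("dN/dS estimation handles the degenerate and toy cases", {
  same <- paste(rep("GATACT", 50), collapse = "")
  aln <- codon_alignment(c("a", "b"), list(same, same))
  est <- estimate_dnds(aln)
  expect_equal(est$ratio, "undefined_dS_zero")
  expect_equal(est$dN, 0)

  ## single synonymous change in 100 codons
  s1 <- paste(rep("TTT", 100), collapse = "")
  s2 <- paste(c(rep("TTT", 99), "TTC"), collapse = "")
  est2 <- estimate_dnds(codon_alignment(c("a", "b"), list(s1, s2)))
  expect_equal(est2$dN, 0)
  expect_gt(est2$dS, 0)
  expect_equal(est2$ratio, 0)
})

test_that("a 12-codon toy alignment equals hand-enumerated NG86", {
  ## codon-by-codon oracle: sites from the genetic-code walk; differences
  ## by explicit path enumeration for the two multi-hit codons
  s1 <- c("ATG", "TTT", "GAT", "AAA", "CCC", "GGG",
          "TTA", "ACT", "CAT", "GAA", "TGG", "TAT")
  s2 <- c("ATG", "TTC", "GAT", "AGA", "CCC", "GGG",
          "CTA", "TCT", "CAT", "GAG", "TGG", "TCC")
  aln <- codon_alignment(c("a", "b"), list(paste(s1, collapse = ""),
                                           paste(s2, collapse = "")))
  est <- estimate_dnds(aln)
  sites <- vapply(seq_along(s1), function(i)
    (oracle_ng86_sites(s1[i]) + oracle_ng86_sites(s2[i])) / 2, numeric(2))
  expect_equal(est$N_sites, sum(sites["n_sites", ]))
  expect_equal(est$S_sites, sum(sites["s_sites", ]))
  ## single-hit differences: TTT>TTC syn; AAA>AGA nonsyn; TTA>CTA syn
  ## (both Leu); ACT>TCT nonsyn; GAA>GAG syn.
  ## TAT>TCC (two hits): path via TCT = nonsyn (Y>S) + syn (S>S);
  ## path via TAC = syn (Y>Y) + nonsyn (Y>S); average 1 nonsyn + 1 syn.
  expect_equal(est$Nd, 2 + 1)
  expect_equal(est$Sd, 3 + 1)
  expect_equal(est$N_sites + est$S_sites, 3 * est$codon_pairs)
})

test_that("estimation is symmetric in its two sequences", {
  set.seed(41)
  pair <- evolve_codons(200, 0.3, omega = 0.4)
  a <- estimate_dnds(codon_alignment(c("a", "b"),
                                     list(pair[["a"]], pair[["b"]])))
  b <- estimate_dnds(codon_alignment(c("b", "a"),
                                     list(pair[["b"]], pair[["a"]])))
  expect_equal(a$ratio, b$ratio)
  expect_equal(a$dN, b$dN)
  expect_equal(a$dS, b$dS)
})

test_that("omega = 0 yields exactly zero amino-acid divergence", {
  set.seed(42)
  pair <- evolve_codons(300, 0.5, omega = 0)
  est <- estimate_dnds(codon_alignment(c("a", "b"),
                                       list(pair[["a"]], pair[["b"]])))
  expect_equal(est$Nd, 0)
  expect_equal(est$dN, 0)
})

test_that("the two-stage screen reproduces the published final set", {
  reg <- load_registry()
  flags <- screen_registry_dnds(reg)
  expect_setequal(flags$final_set,
                  c("KCNG2", "KCNMB1", "KCNK5", "KCNK10", "KCNK16",
                    "KCNK16L", "KCNK17", "KCNK18", "KCTD18", "KCNRG"))
  expect_equal(sum(grepl("^KCNK", flags$final_set)), 6L)
  ## the fixed 0.1 cutoff and 2x-revised-mean alternative are both reported
  expect_equal(flags$final_cutoff, 0.1)
  expect_true(is.finite(flags$two_x_revised_mean))
})

test_that("screen edge cases behave per contract", {
  same <- setNames(rep(0.05, 5), paste0("g", 1:5))
  fl <- flag_high_dnds(same)
  expect_length(fl$stage1_set, 0L)
  expect_length(fl$final_set, 0L)

  ratios <- setNames(c(0.02, 0.03, 0.02, 0.25), paste0("g", 1:4))
  fl2 <- flag_high_dnds(ratios)
  expect_equal(fl2$stage1_set, "g4")
  expect_equal(fl2$final_set, "g4")

  ## stage-2 recalculation can rescue an artifact
  fl3 <- flag_high_dnds(ratios, recalculated = c(g4 = 0.04))
  expect_length(fl3$final_set, 0L)
  expect_match(fl3$exclusions, "g4")

  expect_error(flag_high_dnds(setNames(NA_real_, "g1")), "numeric")
})

test_that("lineage assignment follows the dominance rule", {
  expect_equal(assign_lineage("g", 0.20, 0.05)$call, "focal_accelerated")
  expect_equal(assign_lineage("g", 0.05, 0.20)$call, "sibling_accelerated")
  expect_equal(assign_lineage("g", 0.18, 0.16)$call, "both_accelerated")
  expect_equal(assign_lineage("g", 0.04, 0.05)$call, "indeterminate")
  expect_equal(assign_lineage("g", NA, 0.2)$call, "indeterminate")
})
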