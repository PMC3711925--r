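test_that("substitution classification reproduces the published examples", {
  expect_equal(classify_substitution("T", "S"), "conservative")
  expect_equal(classify_substitution("T", "A"), "non_conservative")
  expect_equal(classify_substitution("N", "D"), "non_conservative")
  expect_equal(classify_substitution("Y", "S"), "non_conservative")
  expect_equal(classify_substitution("L", "L"), "identical")
  expect_error(classify_substitution("B", "A"), "unknown amino-acid")
})

test_that("classification is symmetric over all 400 ordered pairs", {
  for (a in AA_CODES) {
    for (b in AA_CODES) {
      expect_equal(classify_substitution(a, b), classify_substitution(b, a))
    }
  }
})

test_that("quality mask follows per-base threshold and gap intervals", {
  aligned <- list("ACGTAC", "ACGTAC")
  expect_true(all(quality_mask(aligned,
                               list(rep(60L, 6), rep(60L, 6)))))
  q <- rep(60L, 6); q[3] <- 20L
  m <- quality_mask(aligned, list(q, rep(60L, 6)))
  expect_equal(which(!m), 3L)
  m2 <- quality_mask(aligned, gap_intervals = list(cbind(2, 4), NULL))
  expect_equal(which(!m2), 2:4)
  expect_error(quality_mask(aligned, list(rep(60L, 5), rep(60L, 6))),
               "mismatch")
})

test_that("allelic-variant calls decode planted edits exactly", {
  bundle <- simulate_genomes(default_simulation_config(seed = 3))
  rep <- run_pipeline(bundle, skip = c("presence", "indels", "selection",
                                      "motifs"))
  v <- rep$variants
  gt <- bundle$ground_truth$substitutions
  for (locus in unique(gt$locus)) {
    res <- v[[locus]]
    expect_true(res$accepted)
    want <- gt[gt$locus == locus, ]
    got <- res$substitutions
    expect_equal(got$position, want$position)
    expect_equal(got$ref_aa, want$ref_aa)
    expect_equal(got$alt_aa, want$alt_aa)
    expect_equal(ifelse(got$klass == "synonymous", "synonymous", got$klass),
                 want$klass)
  }
  ## the planted single-residue deletion is carried on the same gene
  del <- v[["KCG14A"]]$indels
  expect_equal(del$kind, "deletion")
  expect_equal(del$position, 150L)
})

test_that("rejection reasons are explicit", {
  aln <- align_local("ACGTACGTACGT", "ACCTACCTACCT")  # ~83% identity
  res <- call_allelic_variants("g", "ACGTACGTACGT",
                               list(alignment = aln, placement = "unplaced"))
  expect_false(res$accepted)
  expect_match(res$reason, "identity")

  self <- align_local("ACGTACGTACGT", "ACGTACGTACGT")
  res2 <- call_allelic_variants("g", "ACGTACGTACGT",
                                list(alignment = self, placement = "placed"))
  expect_false(res2$accepted)
  expect_match(res2$reason, "duplication")

  qual <- list(primary = rep(20L, 12), secondary = rep(60L, 12))
  res3 <- call_allelic_variants("g", "ACGTACGTACGT",
                                list(alignment = self,
                                     placement = "unplaced"),
                                qualities = qual)
  expect_false(res3$accepted)
  expect_match(res3$reason, "quality")
})

test_that("indel detection reports reference coordinates and domains", {
  ## reference carries N-G at residues 681-682 inside an ion-transport
  ## domain; the derived sequence lacks them
  set.seed(31)
  n_res <- 700L
  codons <- c("GCT", "TGC", "GAT", "GAA", "TTC", "GGA", "CAT", "ATA",
              "AAA", "TTG")
  ref_codons <- sample(codons, n_res, replace = TRUE)
  ref_codons[681] <- "AAT"  # N
  ref_codons[682] <- "GGC"  # G
  ref <- paste(ref_codons, collapse = "")
  alt <- paste(ref_codons[-c(681, 682)], collapse = "")
  caln <- align_codons(c("chicken", "finch"), c(ref, alt))
  domains <- data.frame(protein = "KCNA4", start = 670L, end = 695L,
                        label = "ion_transport")
  recs <- detect_indels(caln, domains = domains,
                        species = c("chicken", "finch"),
                        protein_id = "KCNA4")
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$kind, "deletion")
  expect_equal(recs$position, 681L)
  expect_equal(recs$residues, "NG")
  expect_equal(recs$lineage, "finch")
  expect_equal(recs$domain_overlap, "ion_transport")
  expect_true(recs$in_frame)

  ## total indel residues equal gap columns / 3 in coding mode
  n_gap_cols <- sum(strsplit(caln$aligned[[2]], "")[[1]] == "-")
  expect_equal(sum(nchar(recs$residues)), n_gap_cols / 3)
})

test_that("gap runs near masked columns are flagged quality_ok = FALSE", {
  ref <- paste(rep("GAT", 30), collapse = "")
  alt <- paste(rep("GAT", 28), collapse = "")
  caln <- align_codons(c("a", "b"), c(ref, alt))
  gapcols <- which(strsplit(caln$aligned[[2]], "")[[1]] == "-")
  mask <- rep(TRUE, nchar(caln$aligned[[1]]))
  mask[gapcols[1]] <- FALSE
  recs <- detect_indels(caln, mask = mask, species = c("a", "b"))
  expect_true(all(!recs$quality_ok))
})

test_that("frame-breaking gaps are flagged, not dropped", {
  ## a 4-column gap in one sequence and a 1-column gap in the other keep
  ## both ungapped lengths in frame while breaking it locally
  caln <- codon_alignment(c("a", "b"),
                          list("ATGGATGATGATGAT-", "ATGGATG----TGATC"))
  recs <- detect_indels(caln, species = c("a", "b"))
  expect_equal(nrow(recs), 2L)
  expect_true(all(!recs$in_frame))
})
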