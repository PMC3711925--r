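nuc_scheme <- function(...) scoring_scheme("nucleotide", ...)

test_that("trivial alignments behave as specified", {
  a <- align_local("ACGTACGT", "ACGTACGT")
  expect_equal(a$percent_identity, 100)
  expect_equal(a$query_span, c(1L, 8L))

  b <- align_local("ACGT", "TTTT",
                   nuc_scheme(match = 1, mismatch = -1,
                              gap_open = 2, gap_extend = 0))
  expect_equal(b$score, 1)
  expect_equal(nchar(b$aligned_query), 1L)

  g <- align_global(list(id = "q", residues = "MKV"),
                    list(id = "t", residues = "MV"),
                    scoring_scheme("protein"))
  expect_equal(sum(strsplit(g$aligned_target, "")[[1]] == "-"), 1L)

  eq <- align_global("ACGTAC", "ACGTAC")
  expect_false(grepl("-", eq$aligned_query))
  expect_error(align_local("ACGT", "MKVW", nuc_scheme()), "alphabet")
})

test_that("local and global scores equal the plain-R DP oracle", {
  set.seed(11)
  sch <- nuc_scheme()
  for (rep in 1:40) {
    s1 <- random_dna(sample(10:40, 1))
    s2 <- random_dna(sample(10:40, 1))
    loc <- align_local(s1, s2, sch)
    glo <- align_global(s1, s2, sch)
    expect_equal(loc$score,
                 oracle_align_score(s1, s2, sch$matrix, sch$gap_open,
                                    sch$gap_extend, local = TRUE))
    expect_equal(glo$score,
                 oracle_align_score(s1, s2, sch$matrix, sch$gap_open,
                                    sch$gap_extend, local = FALSE))
  }
})

test_that("scores agree with Biostrings::pairwiseAlignment", {
  set.seed(12)
  sch <- nuc_scheme()
  mat <- sch$matrix[c("A", "C", "G", "T"), c("A", "C", "G", "T")]
  for (rep in 1:10) {
    s1 <- random_dna(30)
    s2 <- random_dna(30)
    bl <- Biostrings::pairwiseAlignment(
      s1, s2, type = "local", substitutionMatrix = mat,
      gapOpening = sch$gap_open, gapExtension = sch$gap_extend)
    loc <- align_local(s1, s2, sch)
    expect_equal(loc$score, Biostrings::score(bl))
    bg <- Biostrings::pairwiseAlignment(
      s1, s2, type = "global", substitutionMatrix = mat,
      gapOpening = sch$gap_open, gapExtension = sch$gap_extend)
    expect_equal(align_global(s1, s2, sch)$score, Biostrings::score(bg))
  }
})

test_that("score is symmetric and monotone under matched extension", {
  set.seed(13)
  sch <- nuc_scheme()
  for (rep in 1:20) {
    s1 <- random_dna(25)
    s2 <- random_dna(25)
    expect_equal(align_local(s1, s2, sch)$score,
                 align_local(s2, s1, sch)$score)
    expect_equal(align_global(s1, s2, sch)$score,
                 align_global(s2, s1, sch)$score)
    ext <- random_dna(6)
    expect_gte(align_local(paste0(s1, ext), paste0(s2, ext), sch)$score,
               align_local(s1, s2, sch)$score)
  }
})

test_that("similarity stats follow the gap-excluded denominator", {
  ## 10 columns: 8 identical, 1 same-group (T/S), 1 cross-group (T/A)
  aln <- structure(list(
    type = "global", alphabet = "protein", query_id = "q", target_id = "t",
    aligned_query = "MKVWTEDLTT", aligned_target = "MKVWTEDLSA",
    score = 0, query_span = c(1, 10), target_span = c(1, 10)),
    class = "alignment_result")
  st <- similarity_stats(aln)
  expect_equal(unname(st["percent_identity"]), 80)
  expect_equal(unname(st["percent_similarity"]), 90)

  ident <- align_global(list(id = "a", residues = "MKVWTEDLYH"),
                        list(id = "b", residues = "MKVWTEDLYH"),
                        scoring_scheme("protein"))
  expect_equal(unname(similarity_stats(ident)["percent_identity"]), 100)

  nuc <- align_local("ACGT", "ACGT")
  expect_error(similarity_stats(nuc), "protein")
})

test_that("seed-and-extend search matches the exhaustive oracle", {
  set.seed(14)
  base <- random_dna(300)
  mutate <- function(s, pct) {
    chars <- strsplit(s, "")[[1]]
    idx <- sample(length(chars), round(length(chars) * pct / 100))
    chars[idx] <- vapply(chars[idx], function(ch)
      sample(setdiff(c("A", "C", "G", "T"), ch), 1), character(1))
    paste(chars, collapse = "")
  }
  divergences <- seq(0, 19, by = 1)
  ids <- sprintf("copy%02d", divergences)
  genome <- seq_set(c("query", ids),
                    c(base, vapply(divergences, function(d)
                      mutate(base, d), character(1))))
  hits <- find_secondary_loci(genome[["query"]], genome, min_identity = 95)
  ## exhaustive oracle: align query to every annotated locus
  oracle_keep <- character(0)
  for (id in ids) {
    aln <- align_local(genome[["query"]], genome[[id]])
    if (aln$percent_identity >= 95) oracle_keep <- c(oracle_keep, id)
  }
  expect_setequal(hits$locus, oracle_keep)
  expect_true("copy00" %in% hits$locus)          # exact planted copy
  expect_equal(hits$identity[hits$locus == "copy00"], 100)
  expect_false("copy10" %in% hits$locus)         # 10% divergence excluded
  expect_equal(nrow(find_secondary_loci(genome[["query"]], seq_set(
    character(0), character(0)))), 0L)
})
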