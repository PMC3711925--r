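test_that("zero-event configs give identical gene orders everywhere", {
  cfg <- simulation_config(seed = 5, n_genes = 4L, n_codons = 30L,
                           omega_overrides = c())
  bundle <- simulate_genomes(cfg)
  pm <- build_presence_matrix(cfg$genes, bundle$maps)
  expect_true(all(pm == "present"))
  orders <- lapply(bundle$maps, function(m)
    m$features$symbol[!m$features$is_gap])
  expect_true(all(vapply(orders, identical, logical(1), orders[[1]])))
})

test_that("the same seed reproduces the bundle bit-for-bit", {
  cfg <- default_simulation_config(seed = 9)
  b1 <- simulate_genomes(cfg)
  b2 <- simulate_genomes(cfg)
  expect_identical(lapply(b1$sequences, function(s)
    vapply(s, `[[`, character(1), "residues")),
    lapply(b2$sequences, function(s)
      vapply(s, `[[`, character(1), "residues")))
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  m1 <- emit_bundle(b1, d1, force = TRUE)
  m2 <- emit_bundle(b2, d2, force = TRUE)
  expect_identical(m1$md5, m2$md5)
  expect_error(emit_bundle(b1, d1), "not empty")
})

test_that("a duplication planted on the bird branch lands in birds only", {
  cfg <- simulation_config(
    seed = 6, n_genes = 4L, n_codons = 40L, omega_overrides = c(),
    events = list(list(type = "duplication", gene = "KCG2",
                       branch = "birds", copy = "KCG2L",
                       slot = c("F10", "F11"))))
  bundle <- simulate_genomes(cfg)
  has_copy <- vapply(bundle$maps, function(m)
    any(m$features$symbol == "KCG2L"), logical(1))
  expect_setequal(names(has_copy)[has_copy], c("chicken", "finch"))
  ## distinct flanks from the parent context
  nb_parent <- neighborhood(bundle$maps$finch, "KCG2", k = 2)
  nb_copy <- neighborhood(bundle$maps$finch, "KCG2L", k = 2)
  expect_length(intersect(c(nb_parent$upstream, nb_parent$downstream),
                          c(nb_copy$upstream, nb_copy$downstream)), 0L)
})

test_that("contradictory loss/allele events are rejected", {
  expect_error(simulation_config(
    seed = 1, n_genes = 3L,
    events = list(
      list(type = "loss", gene = "KCG1", branch = "birds"),
      list(type = "allele", gene = "KCG1", copy = "KCG1A",
           scaffold = "chrUn_s", edits = list()))),
    "contradictory")
  expect_error(simulation_config(
    seed = 1, n_genes = 2L,
    events = list(list(type = "loss", gene = "KCG9", branch = "birds"))),
    "unknown gene")
})

test_that("evolved pairs are reproducible and respect omega extremes", {
  p1 <- evolve_codons(100, 0.4, omega = 0.5, seed = 77)
  p2 <- evolve_codons(100, 0.4, omega = 0.5, seed = 77)
  expect_identical(p1, p2)
  p0 <- evolve_codons(200, 0.6, omega = 0, seed = 78)
  prot <- function(s) vapply(seq(1, nchar(s), 3), function(i)
    translate_codon(substr(s, i, i + 2)), character(1))
  expect_identical(prot(p0[["a"]]), prot(p0[["b"]]))
})

test_that("an emitted bundle loads cleanly through the format readers", {
  cfg <- simulation_config(seed = 8, n_genes = 3L, n_codons = 30L,
                           omega_overrides = c())
  bundle <- simulate_genomes(cfg)
  dir <- file.path(tempdir(), "bundle_rt")
  emit_bundle(bundle, dir, force = TRUE)
  back <- load_bundle(dir)
  expect_setequal(names(back$maps), names(bundle$maps))
  for (sp in names(bundle$maps)) {
    expect_equal(back$maps[[sp]]$features$symbol,
                 bundle$maps[[sp]]$features$symbol)
    expect_equal(back$maps[[sp]]$features$start,
                 bundle$maps[[sp]]$features$start)
    expect_identical(
      vapply(back$sequences[[sp]], `[[`, character(1), "residues"),
      vapply(bundle$sequences[[sp]], `[[`, character(1), "residues"))
  }
  ## focal qualities survive the FASTQ round trip
  foc <- cfg$focal
  expect_identical(back$qualities[["KCG1"]], bundle$qualities[["KCG1"]])
  expect_equal(length(back$tree$tip.label), length(bundle$tree$tip.label))
})
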