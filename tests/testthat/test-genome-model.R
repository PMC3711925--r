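write_gff3 <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

test_that("GFF3 gene maps read, sort and round-trip coordinates exactly", {
  p <- write_gff3(c(
    "chr1\ttoy\tgene\t5000\t6000\t.\t+\t.\tID=g3;Name=G3",
    "chr1\ttoy\tgene\t100\t900\t.\t+\t.\tID=g1;Name=G1",
    "chr1\ttoy\tgene\t800\t2000\t.\t+\t.\tID=g2;Name=G2"))
  map <- read_gene_map(p, "toy")
  expect_equal(map$features$symbol, c("G1", "G2", "G3"))  # sorted by start
  expect_equal(map$features$start, c(100L, 800L, 5000L)) # overlap accepted

  out <- tempfile(fileext = ".gff3")
  write_gene_map(map, out)
  map2 <- read_gene_map(out, "toy")
  expect_identical(map$features[c("symbol", "chrom", "start", "end")],
                   map2$features[c("symbol", "chrom", "start", "end")])
})

test_that("invalid GFF3 is rejected", {
  p <- write_gff3("chr1\ttoy\tgene\t900\t100\t.\t+\t.\tID=g1;Name=G1")
  expect_error(read_gene_map(p, "toy"))
})

test_that("neighborhood returns nearest-first flanks without padding", {
  map <- toy_map(symbols = c("A", "B", "X", "C", "D"))
  nb <- neighborhood(map, "X", k = 2)
  expect_equal(nb$upstream, c("B", "A"))
  expect_equal(nb$downstream, c("C", "D"))
  ## locus at chromosome end: short list, no padding
  nb2 <- neighborhood(map, "A", k = 3)
  expect_equal(nb2$upstream, character(0))
  expect_equal(nb2$downstream, c("B", "X", "C"))
  expect_error(neighborhood(map, "ZZZ"), "absent")
})

test_that("gaps inside the window are reported alongside", {
  map <- toy_map(gap_at = 2600L)  # between X (3000) and B (2000)
  nb <- neighborhood(map, "X", k = 1)
  expect_equal(nrow(nb$gaps_in_window), 1L)
  far <- neighborhood(toy_map(), "X", k = 1)
  expect_equal(nrow(far$gaps_in_window), 0L)
})

test_that("neighborhood is symmetric under map reversal", {
  syms <- c("A", "B", "X", "C", "D", "E")
  map <- toy_map(symbols = syms)
  rev_map <- toy_map(symbols = rev(syms))
  for (k in 1:3) {
    nb <- neighborhood(map, "X", k)
    nbr <- neighborhood(rev_map, "X", k)
    expect_equal(nb$upstream, nbr$downstream)
    expect_equal(nb$downstream, nbr$upstream)
  }
})

test_that("FASTQ qualities decode as Sanger Phred and round-trip", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
  seqs <- read_sequences(fq)
  expect_equal(seqs[["r1"]]$qualities, rep(40L, 4))

  out <- tempfile(fileext = ".fastq")
  write_sequences(seqs, out, format = "fastq")
  expect_identical(readLines(out), readLines(fq))

  fa <- tempfile(fileext = ".fasta")
  write_sequences(seqs, fa)
  back <- read_sequences(fa)
  expect_equal(back[["r1"]]$residues, "ACGT")
})

test_that("Newick trees parse with their clade labels", {
  nwk <- tempfile(fileext = ".nwk")
  writeLines("((fish,(frog,((lizard,(chicken,finch)),(platypus,(mouse,human))))));",
             nwk)
  tree <- read_tree(nwk)
  expect_equal(length(tree$tip.label), 8L)
  bad <- tempfile()
  writeLines("((a,b,(c;", bad)
  expect_error(read_tree(bad), "Newick")
})

test_that("unplaced chromosome names are recognized", {
  feats <- data.frame(symbol = "G", chrom = "chrUn_scaffold9",
                      start = 1L, end = 10L, strand = "+", is_gap = FALSE)
  map <- genome_map("toy", feats)
  expect_true(is_unplaced(map, "chrUn_scaffold9"))
  expect_true(is_unplaced(map, "chr1_random"))
  expect_false(is_unplaced(map, "chr2"))
})
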