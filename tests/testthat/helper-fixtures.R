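# Small in-code fixtures shared across test files.

toy_map <- function(species = "toy",
                    symbols = c("A", "B", "X", "C", "D"),
                    chrom = "chr1", gap_at = NULL) {
  n <- length(symbols)
  feats <- data.frame(
    symbol = symbols, chrom = chrom,
    start = seq_len(n) * 1000L, end = seq_len(n) * 1000L + 500L,
    strand = "+", is_gap = FALSE, stringsAsFactors = FALSE
  )
  if (!is.null(gap_at)) {
    feats <- rbind(feats, data.frame(
      symbol = "gap", chrom = chrom, start = gap_at, end = gap_at + 200L,
      strand = "*", is_gap = TRUE, stringsAsFactors = FALSE))
  }
  genome_map(species, feats)
}

registry_header <- paste(
  c("symbol", "subfamily", "model_ids", "model_status", "ortholog_class",
    "novelty_flag", "chicken_ortholog", "dnds", "dnds_note", "dnds_flagged",
    "variant_codes", "hvc", "lman", "ra", "x", "clone"),
  collapse = "\t")

registry_row <- function(symbol = "KCNA1", subfamily = "KCNA",
                         dnds = "0.01", flagged = "FALSE",
                         codes = "", hvc = "+", lman = "+", ra = "+",
                         x = "+", clone = "FE000001",
                         ortholog_class = "one_to_one_human",
                         novelty = "none") {
  paste(c(symbol, subfamily, "ENSTGUG00000000001", "complete",
          ortholog_class, novelty, "ENSGALG00000000001", dnds, "",
          flagged, codes, hvc, lman, ra, x, clone), collapse = "\t")
}

write_registry_file <- function(rows, path = tempfile(fileext = ".tsv")) {
  con <- file(path, open = "w", encoding = "UTF-8")
  writeLines(c(registry_header, rows), con, useBytes = FALSE)
  close(con)
  path
}
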