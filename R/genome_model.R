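## Gene-map, sequence, quality and species-tree containers with
## standard-format I/O. Coordinates are 1-based inclusive internally
## (GFF3 convention); BED emission is 0-based half-open via the
## centralized converters in utils.R.

#' Construct a gene-level genome map
#'
#' @param species species name.
#' @param features data frame with columns `symbol`, `chrom`, `start`,
#'   `end`, `strand`, and optionally `is_gap` (assembly-gap intervals share
#'   the structure; their symbol is conventionally `"gap"`).
#' @param unplaced_patterns regexes identifying unplaced/unassigned
#'   chromosome names.
#' @return a `genome_map` object; features sorted by (chrom, start).
#' @export
genome_map <- function(species, features,
                       unplaced_patterns = c("Un", "_random$")) {
  req <- c("symbol", "chrom", "start", "end", "strand")
  kc_assert(all(req %in% names(features)),
            "features need columns: %s", paste(req, collapse = ", "))
  if (is.null(features$is_gap)) features$is_gap <- FALSE
  kc_assert(all(features$start <= features$end),
            "feature with end < start in map for %s", species)
  kc_assert(all(features$strand %in% c("+", "-", "*")),
            "strand must be one of +, -, *")
  features <- features[order(features$chrom, features$start,
                             features$symbol), , drop = FALSE]
  rownames(features) <- NULL
  key <- paste(features$symbol, features$chrom, features$start)
  kc_assert(!anyDuplicated(key),
            "duplicate (symbol, chrom, start) in map for %s", species)
  structure(
    list(species = species, features = features,
         unplaced_patterns = unplaced_patterns),
    class = "genome_map"
  )
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("<genome_map> %s: %d features on %d sequence(s), %d gap(s)\n",
              x$species, sum(!x$features$is_gap),
              length(unique(x$features$chrom)), sum(x$features$is_gap)))
  invisible(x)
}

#' Is a chromosome name "unplaced" (chrUn-style scaffold)?
#' @param map a `genome_map`.
#' @param chrom chromosome name(s).
#' @export
is_unplaced <- function(map, chrom) {
  Reduce(`|`, lapply(map$unplaced_patterns, grepl, x = chrom),
         rep(FALSE, length(chrom)))
}

#' Read a gene map from GFF3
#'
#' Keeps `gene` features (symbol taken from the `Name`, `gene_name` or `ID`
#' attribute, in that order) and `gap` features (recorded as assembly-gap
#' intervals).
#'
#' @param path GFF3 file (optionally gzipped).
#' @param species species label for the resulting map.
#' @return a [genome_map()].
#' @export
read_gene_map <- function(path, species) {
  kc_assert(file.exists(path), "GFF3 file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  types <- as.character(gr$type)
  keep <- types %in% c("gene", "gap")
  gr <- gr[keep]
  types <- types[keep]
  md <- S4Vectors::mcols(gr)
  symbol <- rep(NA_character_, length(gr))
  for (attr in c("Name", "gene_name", "ID")) {
    if (attr %in% names(md)) {
      vals <- as.character(md[[attr]])
      symbol <- ifelse(is.na(symbol) & !is.na(vals), vals, symbol)
    }
  }
  symbol[types == "gap"] <- "gap"
  if (anyNA(symbol)) {
    kc_stop("GFF3 gene feature without a symbol attribute (feature %d of %s)",
            which(is.na(symbol))[1], path)
  }
  feats <- data.frame(
    symbol = symbol,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = sub("\\*", "*", as.character(GenomicRanges::strand(gr))),
    is_gap = types == "gap",
    stringsAsFactors = FALSE
  )
  genome_map(species, feats)
}

#' Write a gene map to GFF3
#' @param map a `genome_map`.
#' @param path output file.
#' @export
write_gene_map <- function(map, path) {
  f <- map$features
  gr <- GenomicRanges::GRanges(
    seqnames = f$chrom,
    ranges = IRanges::IRanges(start = f$start, end = f$end),
    strand = ifelse(f$strand == "*", "*", f$strand)
  )
  gr$type <- ifelse(f$is_gap, "gap", "gene")
  gr$source <- "kccomp"
  gr$ID <- paste0(f$symbol, ":", f$chrom, ":", f$start)
  gr$Name <- f$symbol
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Flanking-gene neighborhood of a locus
#'
#' @param map a `genome_map`.
#' @param locus gene symbol present in the map.
#' @param k flank size per side.
#' @param occurrence which copy to use when the symbol occurs more than once
#'   (index into the map's sorted order), default first.
#' @return list with `upstream` and `downstream` symbol vectors (nearest
#'   first, up to `k` each, genes only), and `gaps_in_window` — gap
#'   intervals overlapping the spanned window.
#' @export
neighborhood <- function(map, locus, k = 3L, occurrence = 1L) {
  f <- map$features
  hits <- which(f$symbol == locus & !f$is_gap)
  kc_assert(length(hits) >= 1L, "locus '%s' absent from map for %s",
            locus, map$species)
  idx <- hits[occurrence]
  chrom <- f$chrom[idx]
  on_chrom <- f[f$chrom == chrom & !f$is_gap, , drop = FALSE]
  pos <- which(on_chrom$start == f$start[idx] & on_chrom$symbol == locus)[1]
  up_idx <- rev(seq_len(pos - 1L))
  down_idx <- seq(pos + 1L, length.out = max(0L, nrow(on_chrom) - pos))
  upstream <- on_chrom$symbol[head(up_idx, k)]
  downstream <- on_chrom$symbol[head(down_idx, k)]
  used <- c(head(up_idx, k), pos, head(down_idx, k))
  win_start <- min(on_chrom$start[used])
  win_end <- max(on_chrom$end[used])
  gaps <- f[f$is_gap & f$chrom == chrom &
              f$start <= win_end & f$end >= win_start, , drop = FALSE]
  list(upstream = upstream, downstream = downstream,
       gaps_in_window = gaps, chrom = chrom,
       unplaced = is_unplaced(map, chrom))
}

## ---- sequences ----------------------------------------------------------

#' Sequence record collection
#'
#' A lightweight container: a named list of records, each with `id`,
#' `residues` (upper-case string) and optional integer `qualities`
#' (Phred, one per residue).
#'
#' @param ids,residues character vectors.
#' @param qualities optional list of integer vectors (or NULL entries).
#' @export
seq_set <- function(ids, residues, qualities = NULL) {
  ids <- unname(ids)
  residues <- unname(residues)
  kc_assert(length(ids) == length(residues), "ids/residues length mismatch")
  if (is.null(qualities)) qualities <- vector("list", length(ids))
  recs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    q <- qualities[[i]]
    if (!is.null(q)) {
      kc_assert(length(q) == nchar(residues[i]),
                "qualities length mismatch for record '%s'", ids[i])
    }
    recs[[i]] <- list(id = ids[i], residues = toupper(residues[i]),
                      qualities = q)
  }
  names(recs) <- ids
  structure(recs, class = "seq_set")
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("<seq_set> %d record(s)\n", length(x)))
  invisible(x)
}

#' Guess whether a sequence set is nucleotide or protein
#' @param seqs a `seq_set` or a character string.
#' @return `"nucleotide"` or `"protein"`.
#' @export
guess_alphabet <- function(seqs) {
  s <- if (inherits(seqs, "seq_set")) {
    paste(vapply(seqs, `[[`, character(1), "residues"), collapse = "")
  } else {
    toupper(paste(seqs, collapse = ""))
  }
  chars <- unique(strsplit(gsub("-", "", s), "")[[1]])
  if (all(chars %in% c("A", "C", "G", "T", "U", "N"))) "nucleotide"
  else "protein"
}

#' Read sequences from FASTA or FASTQ
#'
#' Format is chosen from the extension (`.fq`/`.fastq` vs anything else);
#' FASTQ qualities are decoded as Sanger Phred (offset 33). Gzipped input
#' is accepted.
#'
#' @param path input file.
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return a [seq_set()].
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  kc_assert(file.exists(path), "sequence file not found: %s", path)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    format <- if (grepl("\\.(fq|fastq)$", base)) "fastq" else "fasta"
  }
  if (format == "fastq") {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    quals <- lapply(as.character(S4Vectors::mcols(x)$qualities),
                    function(q) as.integer(charToRaw(q)) - 33L)
    seq_set(names(x), as.character(x), quals)
  } else {
    x <- Biostrings::readBStringSet(path, format = "fasta")
    seq_set(names(x), as.character(x))
  }
}

#' Write sequences to FASTA or FASTQ
#'
#' FASTQ output requires every record to carry qualities (Sanger offset 33).
#' @param seqs a `seq_set`.
#' @param path output file.
#' @param format `"fasta"` or `"fastq"`.
#' @export
write_sequences <- function(seqs, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  con <- file(path, open = "w")
  on.exit(close(con))
  for (rec in seqs) {
    if (format == "fasta") {
      writeLines(c(paste0(">", rec$id), rec$residues), con)
    } else {
      kc_assert(!is.null(rec$qualities),
                "record '%s' lacks qualities for FASTQ output", rec$id)
      qchr <- rawToChar(as.raw(pmin(rec$qualities, 93L) + 33L))
      writeLines(c(paste0("@", rec$id), rec$residues, "+", qchr), con)
    }
  }
  invisible(path)
}

## ---- species tree -------------------------------------------------------

#' Read a species tree from Newick
#'
#' @param path Newick file.
#' @return an [ape::read.tree()] `phylo` object; leaf labels must be unique.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) NULL)
  kc_assert(!is.null(tree) && inherits(tree, "phylo"),
            "malformed Newick in %s", path)
  kc_assert(!anyDuplicated(tree$tip.label), "duplicate leaf labels in tree")
  tree
}

#' Parse a species tree from Newick text
#' @param text Newick string.
#' @export
parse_tree <- function(text) {
  tree <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  kc_assert(!is.null(tree) && inherits(tree, "phylo"),
            "malformed Newick text")
  tree
}
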