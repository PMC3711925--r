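## Pairwise alignment and desk-scale secondary-locus search: the in-repo
## stand-in for genome-browser BLAT alignment. Local (Smith-Waterman) and
## global (Needleman-Wunsch) alignment use affine gap penalties with the
## convention that a gap of length L costs gap_open + L * gap_extend.

#' Alignment scoring scheme
#'
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param match,mismatch scores used to build a nucleotide matrix (ignored
#'   when `matrix` is given).
#' @param matrix a named substitution matrix (e.g. BLOSUM62); default for
#'   protein schemes.
#' @param gap_open,gap_extend non-negative gap penalties.
#' @return a `scoring_scheme` object. Defaults follow common practice:
#'   BLOSUM62 with gap open 11 / extend 1 for protein, match 1 /
#'   mismatch -2 with gap open 5 / extend 2 for nucleotide.
#' @export
scoring_scheme <- function(alphabet = c("nucleotide", "protein"),
                           match = 1, mismatch = -2,
                           matrix = NULL, gap_open = NULL,
                           gap_extend = NULL) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "protein") {
    if (is.null(matrix)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      matrix <- env$BLOSUM62
    }
    gap_open <- gap_open %||% 11
    gap_extend <- gap_extend %||% 1
  } else {
    if (is.null(matrix)) {
      letters <- c("A", "C", "G", "T", "N")
      matrix <- base::matrix(mismatch, 5, 5,
                             dimnames = list(letters, letters))
      diag(matrix) <- match
      matrix["N", ] <- 0
      matrix[, "N"] <- 0
    }
    gap_open <- gap_open %||% 5
    gap_extend <- gap_extend %||% 2
  }
  kc_assert(gap_open >= 0 && gap_extend >= 0, "gap penalties must be >= 0")
  structure(list(alphabet = alphabet, matrix = matrix,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

.as_record <- function(x) {
  if (inherits(x, "seq_set")) {
    kc_assert(length(x) == 1L, "expected a single sequence record")
    x[[1]]
  } else if (is.list(x) && !is.null(x$residues)) {
    x
  } else if (is.character(x) && length(x) == 1L) {
    list(id = names(x) %||% "seq", residues = toupper(x), qualities = NULL)
  } else {
    kc_stop("cannot interpret object as a sequence record")
  }
}

.encode <- function(residues, scheme) {
  letters <- rownames(scheme$matrix)
  codes <- match(strsplit(residues, "")[[1]], letters)
  if (anyNA(codes)) {
    bad <- strsplit(residues, "")[[1]][which(is.na(codes))[1]]
    kc_stop("residue '%s' not in the %s scheme alphabet (mixed alphabets?)",
            bad, scheme$alphabet)
  }
  codes - 1L
}

.build_alignment <- function(raw, q, t, scheme, type) {
  qa <- strsplit(q$residues, "")[[1]]
  ta <- strsplit(t$residues, "")[[1]]
  aligned_query <- ifelse(is.na(raw$a1), "-", qa[raw$a1])
  aligned_target <- ifelse(is.na(raw$a2), "-", ta[raw$a2])
  res <- structure(
    list(
      type = type,
      alphabet = scheme$alphabet,
      query_id = q$id, target_id = t$id,
      aligned_query = paste(aligned_query, collapse = ""),
      aligned_target = paste(aligned_target, collapse = ""),
      score = raw$score,
      query_span = c(raw$qstart, raw$qend),
      target_span = c(raw$tstart, raw$tend)
    ),
    class = "alignment_result"
  )
  stats <- similarity_stats(res, strict = FALSE)
  res$percent_identity <- stats[["percent_identity"]]
  res$percent_similarity <- stats[["percent_similarity"]]
  res
}

.align <- function(query, target, scheme, local) {
  q <- .as_record(query)
  t <- .as_record(target)
  kc_assert(nzchar(q$residues) && nzchar(t$residues),
            "cannot align empty sequences")
  for (rec in list(q, t)) {
    kc_assert(guess_alphabet(rec$residues) == scheme$alphabet ||
                scheme$alphabet == "protein",
              "sequence alphabet does not match the scoring scheme")
  }
  if (scheme$alphabet == "nucleotide") {
    kc_assert(guess_alphabet(q$residues) == "nucleotide" &&
                guess_alphabet(t$residues) == "nucleotide",
              "mixed alphabets: nucleotide scheme on protein input")
  }
  raw <- .cpp_align(.encode(q$residues, scheme), .encode(t$residues, scheme),
                    scheme$matrix, scheme$gap_open, scheme$gap_extend, local)
  .build_alignment(raw, q, t, scheme, if (local) "local" else "global")
}

#' Smith-Waterman local alignment
#'
#' Optimal local alignment under an affine scheme; ties between equal-score
#' endpoints are broken toward the longer alignment, then the smallest query
#' start. The local score is never negative.
#'
#' @param query,target sequence records (see [seq_set()]) or plain strings.
#' @param scheme a [scoring_scheme()].
#' @return an `alignment_result` with gapped strings, score, spans, percent
#'   identity and percent similarity.
#' @export
align_local <- function(query, target,
                        scheme = scoring_scheme(guess_alphabet(.as_record(query)$residues))) {
  .align(query, target, scheme, local = TRUE)
}

#' Needleman-Wunsch global alignment
#'
#' End-to-end alignment; the score may be negative.
#' @inheritParams align_local
#' @export
align_global <- function(query, target,
                         scheme = scoring_scheme(guess_alphabet(.as_record(query)$residues))) {
  .align(query, target, scheme, local = FALSE)
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %s %s vs %s: score %.1f, id %.1f%%, sim %.1f%%\n",
              x$type, x$query_id, x$target_id, x$score,
              x$percent_identity %||% NA, x$percent_similarity %||% NA))
  invisible(x)
}

#' Identity and similarity percentages of an alignment
#'
#' Identity counts identical columns over aligned (non-gap) columns;
#' similarity additionally counts columns whose residues share a
#' conservative side-chain group. Gap columns are excluded from the
#' denominator throughout — this is alignment-identity in the
#' aligned-region sense, and it changes every percentage, so it is stated
#' here prominently.
#'
#' @param alignment an `alignment_result` (protein for similarity;
#'   nucleotide input is an error when `strict`).
#' @param conservative_groups list of residue groups; defaults to the
#'   package's side-chain grouping (see [classify_substitution()]).
#' @param strict error on nucleotide alignments (the public contract);
#'   internal callers pass `FALSE` to annotate nucleotide identities too.
#' @return named numeric: `percent_identity`, `percent_similarity`.
#' @export
similarity_stats <- function(alignment, conservative_groups = AA_GROUPS,
                             strict = TRUE) {
  stopifnot(inherits(alignment, "alignment_result"))
  if (strict) {
    kc_assert(alignment$alphabet == "protein",
              "similarity is defined for protein alignments")
  }
  qa <- strsplit(alignment$aligned_query, "")[[1]]
  ta <- strsplit(alignment$aligned_target, "")[[1]]
  aligned <- qa != "-" & ta != "-"
  n <- sum(aligned)
  if (n == 0L) {
    return(c(percent_identity = NA_real_, percent_similarity = NA_real_))
  }
  identical_col <- aligned & qa == ta
  group_of <- function(ch) {
    g <- which(vapply(conservative_groups, function(gr) ch %in% gr,
                      logical(1)))
    if (length(g)) g[1] else NA_integer_
  }
  same_group <- aligned & !identical_col &
    mapply(function(a, b) {
      ga <- group_of(a); gb <- group_of(b)
      !is.na(ga) && !is.na(gb) && ga == gb
    }, qa, ta)
  c(percent_identity = 100 * sum(identical_col) / n,
    percent_similarity = 100 * (sum(identical_col) + sum(same_group)) / n)
}

#' Seed-and-extend search for secondary loci
#'
#' Desk-scale stand-in for whole-genome BLAT: loci sharing an exact k-mer
#' with the query are locally aligned, and non-primary hits at or above the
#' identity threshold are returned. Identity is computed over the aligned
#' region (the denominator question is flagged in the output).
#'
#' @param query a sequence record (its `id` names the primary locus).
#' @param genome_seqs a [seq_set()] keyed by locus id.
#' @param min_identity percent identity threshold (default 95).
#' @param k seed size; defaults to 11 for nucleotide, 4 for protein.
#' @param scheme a [scoring_scheme()].
#' @param exclude locus ids never reported (default: the query id).
#' @param min_coverage minimum fraction of the query covered by the aligned
#'   region (default 0: pure identity threshold; orchestration layers pass
#'   a positive value to suppress trivially short perfect hits).
#' @return data frame of hits sorted by score (locus, score, identity,
#'   similarity, spans) with the alignments as a list-column; attribute
#'   `identity_denominator = "aligned_region"`.
#' @export
find_secondary_loci <- function(query, genome_seqs, min_identity = 95,
                                k = NULL, scheme = NULL,
                                exclude = NULL, min_coverage = 0) {
  q <- .as_record(query)
  alphabet <- guess_alphabet(q$residues)
  scheme <- scheme %||% scoring_scheme(alphabet)
  k <- k %||% if (alphabet == "nucleotide") 11L else 4L
  exclude <- exclude %||% q$id
  hits <- list()
  if (length(genome_seqs) == 0L) {
    return(.empty_hits())
  }
  qres <- q$residues
  nq <- nchar(qres)
  if (nq < k) return(.empty_hits())
  kmerize <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
  }
  kmers <- kmerize(qres)
  for (rec in genome_seqs) {
    if (rec$id %in% exclude) next
    if (!any(kmers %in% kmerize(rec$residues))) next
    aln <- align_local(q, rec, scheme)
    n_aligned <- sum(strsplit(aln$aligned_query, "")[[1]] != "-")
    if (!is.na(aln$percent_identity) &&
        aln$percent_identity >= min_identity &&
        n_aligned >= min_coverage * nq) {
      hits[[length(hits) + 1L]] <- list(locus = rec$id, alignment = aln)
    }
  }
  if (length(hits) == 0L) return(.empty_hits())
  df <- data.frame(
    locus = vapply(hits, `[[`, character(1), "locus"),
    score = vapply(hits, function(h) h$alignment$score, numeric(1)),
    identity = vapply(hits, function(h) h$alignment$percent_identity,
                      numeric(1)),
    similarity = vapply(hits, function(h) h$alignment$percent_similarity,
                        numeric(1)),
    stringsAsFactors = FALSE
  )
  df$alignment <- lapply(hits, `[[`, "alignment")
  df <- df[order(-df$score, df$locus), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "identity_denominator") <- "aligned_region"
  df
}

.empty_hits <- function() {
  df <- data.frame(locus = character(0), score = numeric(0),
                   identity = numeric(0), similarity = numeric(0),
                   stringsAsFactors = FALSE)
  df$alignment <- list()
  attr(df, "identity_denominator") <- "aligned_region"
  df
}

#' Export an alignment as pairwise FASTA-with-gaps
#' @param alignment an `alignment_result`.
#' @param path output file.
#' @export
write_alignment_fasta <- function(alignment, path) {
  writeLines(c(paste0(">", alignment$query_id), alignment$aligned_query,
               paste0(">", alignment$target_id), alignment$aligned_target),
             path)
  invisible(path)
}

#' Export hits in the tabular format (query, target, identity, similarity,
#' score, spans)
#' @param query_id query locus name.
#' @param hits data frame from [find_secondary_loci()].
#' @param path output TSV.
#' @export
write_hit_table <- function(query_id, hits, path) {
  tab <- data.frame(
    query = rep(query_id, nrow(hits)),
    target = hits$locus,
    identity = hits$identity,
    similarity = hits$similarity,
    score = hits$score,
    query_start = vapply(hits$alignment, function(a) a$query_span[1],
                         numeric(1)),
    query_end = vapply(hits$alignment, function(a) a$query_span[2],
                       numeric(1)),
    target_start = vapply(hits$alignment, function(a) a$target_span[1],
                          numeric(1)),
    target_end = vapply(hits$alignment, function(a) a$target_span[2],
                        numeric(1))
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
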