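## Allelic-variant calling, substitution classification, indel detection and
## functional-domain overlap annotation.

#' Side-chain groups used for conservative/non-conservative classification
#'
#' Fixed grouping: aliphatic \{A,V,L,I,M\}; aromatic \{F,W,Y\};
#' polar-uncharged \{S,T,C,N,Q\}; basic \{K,R,H\}; acidic \{D,E\};
#' G and P are singletons. This grouping reproduces the four published
#' classified examples (T/S conservative; T/A, N/D and Y/S
#' non-conservative).
#' @export
AA_GROUPS <- list(
  aliphatic = c("A", "V", "L", "I", "M"),
  aromatic = c("F", "W", "Y"),
  polar_uncharged = c("S", "T", "C", "N", "Q"),
  basic = c("K", "R", "H"),
  acidic = c("D", "E"),
  glycine = "G",
  proline = "P"
)

AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V")

#' Classify an amino-acid substitution
#'
#' @param ref_aa,alt_aa single-letter amino-acid codes.
#' @param groups side-chain groups, default [AA_GROUPS].
#' @return `"identical"`, `"conservative"` or `"non_conservative"`; the
#'   relation is symmetric.
#' @examples
#' classify_substitution("T", "S") # conservative
#' classify_substitution("T", "A") # non_conservative
#' @export
classify_substitution <- function(ref_aa, alt_aa, groups = AA_GROUPS) {
  kc_assert(ref_aa %in% AA_CODES, "unknown amino-acid code: '%s'", ref_aa)
  kc_assert(alt_aa %in% AA_CODES, "unknown amino-acid code: '%s'", alt_aa)
  if (ref_aa == alt_aa) return("identical")
  grp <- function(a) which(vapply(groups, function(g) a %in% g, logical(1)))
  if (length(intersect(grp(ref_aa), grp(alt_aa)))) "conservative"
  else "non_conservative"
}

#' Read domain annotations from a 4-column TSV
#'
#' Columns: protein, start, end, label (1-based inclusive residue
#' intervals; labels like `ion_transport`, `transmembrane`,
#' `tetramerization`).
#' @param path TSV file.
#' @return data frame of intervals.
#' @export
read_domains <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
  kc_assert(all(c("protein", "start", "end", "label") %in% names(tab)),
            "domain table needs columns protein, start, end, label")
  kc_assert(all(tab$start <= tab$end), "domain interval with end < start")
  tab
}

.domain_at <- function(domains, protein, position) {
  if (is.null(domains) || nrow(domains) == 0L) return("none")
  hit <- domains[domains$protein == protein &
                   domains$start <= position & domains$end >= position, ]
  if (nrow(hit) == 0L) "none" else hit$label[1]
}

#' Column-wise quality mask of an alignment
#'
#' A column is analyzable iff every contributing base has Phred quality at
#' or above the threshold and the column does not fall inside a declared
#' assembly-gap interval. Gap characters contribute no base and do not
#' disqualify a column by themselves.
#'
#' @param aligned list of gapped sequences (equal-length strings).
#' @param qualities list of per-base integer Phred vectors (ungapped
#'   coordinates; NULL entries mean "assume good").
#' @param gap_intervals optional list (parallel to `aligned`) of two-column
#'   matrices/data frames of 1-based ungapped intervals lying in assembly
#'   gaps.
#' @param threshold minimum Phred score per base (default 50).
#' @return logical vector, one entry per alignment column.
#' @export
quality_mask <- function(aligned, qualities = NULL, gap_intervals = NULL,
                         threshold = 50) {
  ncols <- unique(nchar(unlist(aligned)))
  kc_assert(length(ncols) == 1L, "aligned sequences differ in length")
  ok <- rep(TRUE, ncols)
  for (s in seq_along(aligned)) {
    chars <- strsplit(aligned[[s]], "")[[1]]
    res_idx <- cumsum(chars != "-")
    has_res <- chars != "-"
    q <- if (!is.null(qualities)) qualities[[s]] else NULL
    if (!is.null(q)) {
      kc_assert(length(q) == sum(has_res),
                "quality length mismatch for aligned sequence %d", s)
      bad <- has_res & q[pmax(res_idx, 1L)] < threshold
      ok[bad] <- FALSE
    }
    gi <- if (!is.null(gap_intervals)) gap_intervals[[s]] else NULL
    if (!is.null(gi) && NROW(gi) > 0L) {
      for (r in seq_len(NROW(gi))) {
        inside <- has_res & res_idx >= gi[r, 1] & res_idx <= gi[r, 2]
        ok[inside] <- FALSE
      }
    }
  }
  ok
}

#' Call allelic variants from a secondary alignment
#'
#' Acceptance rules: aligned-region identity >= `min_identity`, placement on
#' an unplaced scaffold or a gap-flanked segment, and a passing quality
#' mask. Rejections return a reason rather than an error. Accepted hits are
#' decoded codon-by-codon against the primary coding sequence; every
#' differing codon becomes a substitution record with its class and domain
#' overlap; in-frame gap runs are reported as small indels.
#'
#' @param primary_id,primary_cds id and coding sequence (string) of the
#'   primary locus.
#' @param hit one row (list) from [find_secondary_loci()]: needs `alignment`
#'   plus `placement` in `{placed, unplaced, gap_flanked}`.
#' @param qualities list(primary=, secondary=) integer Phred vectors, or
#'   NULL.
#' @param domains optional domain table from [read_domains()].
#' @param min_identity identity threshold (default 95).
#' @param phred_min per-base quality threshold (default 50).
#' @return list with `accepted` flag; when rejected, `reason`; when
#'   accepted, data frame `substitutions` (position, ref_aa, alt_aa,
#'   codon_ref, codon_alt, klass, domain_overlap) and data frame `indels`.
#' @export
call_allelic_variants <- function(primary_id, primary_cds, hit,
                                  qualities = NULL, domains = NULL,
                                  min_identity = 95, phred_min = 50) {
  aln <- hit$alignment
  placement <- hit$placement %||% "placed"
  if (is.na(aln$percent_identity) || aln$percent_identity < min_identity) {
    return(list(accepted = FALSE, reason = "below identity threshold"))
  }
  if (!placement %in% c("unplaced", "gap_flanked")) {
    return(list(accepted = FALSE, reason = "placement suggests duplication"))
  }
  mask <- quality_mask(
    list(aln$aligned_query, aln$aligned_target),
    qualities = if (!is.null(qualities)) {
      list(.clip_quality(qualities$primary, aln$query_span),
           .clip_quality(qualities$secondary, aln$target_span))
    },
    threshold = phred_min
  )
  if (!all(mask)) {
    return(list(accepted = FALSE, reason = "low-quality bases in aligned region"))
  }
  qa <- strsplit(aln$aligned_query, "")[[1]]
  ta <- strsplit(aln$aligned_target, "")[[1]]
  ## reference (primary) residue index per column
  ref_idx <- cumsum(qa != "-") + aln$query_span[1] - 1L
  frame_off <- (aln$query_span[1] - 1L) %% 3L
  subs <- list()
  aligned_cols <- which(qa != "-" & ta != "-")
  diff_cols <- aligned_cols[qa[aligned_cols] != ta[aligned_cols]]
  seen_codons <- integer(0)
  for (cc in diff_cols) {
    nt_pos <- ref_idx[cc]
    codon_i <- ((nt_pos - 1L) %/% 3L) + 1L
    if (codon_i %in% seen_codons) next
    seen_codons <- c(seen_codons, codon_i)
    codon_cols <- which(ref_idx %in% ((codon_i - 1L) * 3L + 1:3) & qa != "-")
    if (length(codon_cols) != 3L || any(ta[codon_cols] == "-")) next
    codon_ref <- paste(qa[codon_cols], collapse = "")
    codon_alt <- paste(ta[codon_cols], collapse = "")
    ref_aa <- translate_codon(codon_ref)
    alt_aa <- translate_codon(codon_alt)
    if (is.na(ref_aa) || is.na(alt_aa)) next
    klass <- if (ref_aa == alt_aa) "synonymous"
             else classify_substitution(ref_aa, alt_aa)
    subs[[length(subs) + 1L]] <- data.frame(
      position = codon_i, ref_aa = ref_aa, alt_aa = alt_aa,
      codon_ref = codon_ref, codon_alt = codon_alt, klass = klass,
      domain_overlap = .domain_at(domains, primary_id, codon_i),
      stringsAsFactors = FALSE
    )
  }
  substitutions <- if (length(subs)) do.call(rbind, subs) else
    data.frame(position = integer(0), ref_aa = character(0),
               alt_aa = character(0), codon_ref = character(0),
               codon_alt = character(0), klass = character(0),
               domain_overlap = character(0), stringsAsFactors = FALSE)
  indels <- .gap_runs_to_indels(qa, ta, ref_idx, primary_id, domains,
                                lineage_ins = "secondary",
                                lineage_del = "secondary",
                                mask = rep(TRUE, length(qa)))
  list(accepted = TRUE, substitutions = substitutions, indels = indels,
       frame_offset = frame_off)
}

.clip_quality <- function(q, span) {
  if (is.null(q)) return(NULL)
  q[span[1]:span[2]]
}

.gap_runs_to_indels <- function(qa, ta, ref_idx, protein_id, domains, mask,
                                lineage_ins = "query",
                                lineage_del = "target") {
  runs <- list()
  gap_in_q <- qa == "-"
  gap_in_t <- ta == "-"
  for (which_gap in c("q", "t")) {
    g <- if (which_gap == "q") gap_in_q else gap_in_t
    r <- rle(g)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      cols <- starts[i]:ends[i]
      residues <- if (which_gap == "q") ta[cols] else qa[cols]
      ## residue coordinates in the reference (query) protein frame
      first_ref_nt <- if (which_gap == "q") {
        if (starts[i] > 1L) ref_idx[starts[i] - 1L] + 1L else 1L
      } else {
        ref_idx[starts[i]]
      }
      pos_res <- ((first_ref_nt - 1L) %/% 3L) + 1L
      runs[[length(runs) + 1L]] <- data.frame(
        kind = if (which_gap == "q") "insertion" else "deletion",
        position = pos_res,
        residues = paste(residues, collapse = ""),
        nt_length = length(cols),
        in_frame = length(cols) %% 3L == 0L,
        quality_ok = all(mask[cols]),
        lineage = if (which_gap == "q") lineage_ins else lineage_del,
        domain_overlap = .domain_at(domains, protein_id, pos_res),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(runs)) do.call(rbind, runs) else
    data.frame(kind = character(0), position = integer(0),
               residues = character(0), nt_length = integer(0),
               in_frame = logical(0), quality_ok = logical(0),
               lineage = character(0), domain_overlap = character(0),
               stringsAsFactors = FALSE)
}

#' Detect indels from a codon alignment of a species pair
#'
#' Maximal runs of gap columns become one record each. Positions are residue
#' indices in the non-gapped (reference) sequence: the first residue of the
#' gap run for deletions, so "deletion of 'NG' at position 681" means the
#' reference carries N-G at 681-682. Insertions are assigned to the lineage
#' of the gapless sequence, deletions to the gapped one. Runs overlapping
#' masked columns get `quality_ok = FALSE` and are excluded from summary
#' counts. Frame-breaking runs (length not a multiple of 3) are flagged
#' `in_frame = FALSE`, not dropped.
#'
#' @param codon_aln a [codon_alignment()] (or list with `aligned` pair of
#'   gapped nucleotide strings and optional `mask`).
#' @param mask optional logical per column; defaults to the alignment's.
#' @param domains optional domain table.
#' @param species character(2): lineage labels of the two sequences.
#' @return data frame of indel records (kind, position, residues, lineage,
#'   domain_overlap, quality_ok, in_frame).
#' @export
detect_indels <- function(codon_aln, mask = NULL, domains = NULL,
                          species = c("query", "target"),
                          protein_id = NULL) {
  qa <- strsplit(codon_aln$aligned[[1]], "")[[1]]
  ta <- strsplit(codon_aln$aligned[[2]], "")[[1]]
  kc_assert(length(qa) == length(ta), "gapped strings differ in length")
  mask <- mask %||% codon_aln$mask %||% rep(TRUE, length(qa))
  ref_idx <- cumsum(qa != "-")
  out <- .gap_runs_to_indels(qa, ta, ref_idx,
                             protein_id = protein_id %||%
                               (codon_aln$ids[1] %||% "query"),
                             domains = domains, mask = mask,
                             lineage_ins = species[2], lineage_del = species[2])
  if (nrow(out)) {
    ## translate residues for coding-mode, in-frame runs
    out$residues <- vapply(seq_len(nrow(out)), function(i) {
      nt <- out$residues[i]
      if (out$in_frame[i] && nchar(nt) %% 3L == 0L) {
        paste(vapply(seq(1L, nchar(nt), by = 3L), function(p) {
          aa <- translate_codon(substr(nt, p, p + 2L))
          if (is.na(aa)) "X" else aa
        }, character(1)), collapse = "")
      } else nt
    }, character(1))
  }
  out
}
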