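## dN/dS estimation by the Nei-Gojobori (NG86) counting method with
## Jukes-Cantor correction, the two-stage high-selective-pressure screen,
## and lineage-acceleration assignment via an outgroup.

.genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

GENETIC_CODE_TABLE <- local({
  gc <- NULL
  function() {
    if (is.null(gc)) gc <<- .genetic_code()
    gc
  }
})

SENSE_CODONS <- local({
  sc <- NULL
  function() {
    if (is.null(sc)) {
      gc <- GENETIC_CODE_TABLE()
      sc <<- names(gc)[gc != "*"]
    }
    sc
  }
})

#' Translate a single codon
#' @param codon 3-letter nucleotide string.
#' @return amino-acid code, `"*"` for stop, or NA for untranslatable input.
#' @export
translate_codon <- function(codon) {
  gc <- GENETIC_CODE_TABLE()
  codon <- toupper(gsub("U", "T", codon))
  if (!codon %in% names(gc)) return(NA_character_)
  gc[[codon]]
}

.codon_neighbors <- function(codon) {
  nts <- c("A", "C", "G", "T")
  chars <- strsplit(codon, "")[[1]]
  out <- character(0)
  pos <- integer(0)
  for (p in 1:3) {
    for (nt in setdiff(nts, chars[p])) {
      alt <- chars
      alt[p] <- nt
      out <- c(out, paste(alt, collapse = ""))
      pos <- c(pos, p)
    }
  }
  data.frame(codon = out, position = pos, stringsAsFactors = FALSE)
}

#' NG86 expected synonymous/nonsynonymous site counts of one codon
#'
#' Each codon position contributes one site, split between synonymous and
#' nonsynonymous in proportion to its single-nucleotide neighbors;
#' mutations to stop codons are excluded from the denominator
#' (position-wise normalization), so `n + s = 3` for every sense codon.
#'
#' @param codon sense codon (stop input is an error).
#' @return named numeric `c(n_sites =, s_sites =)`.
#' @examples
#' ng86_site_counts("TTT") # s = 1/3 (only TTC is synonymous)
#' ng86_site_counts("ATG") # s = 0 (Met has no synonymous neighbor)
#' @export
ng86_site_counts <- function(codon) {
  codon <- toupper(gsub("U", "T", codon))
  aa <- translate_codon(codon)
  kc_assert(!is.na(aa), "not a codon: '%s'", codon)
  kc_assert(aa != "*", "stop codon input: '%s'", codon)
  s <- 0
  for (p in 1:3) {
    nb <- .codon_neighbors(codon)
    nb <- nb[nb$position == p, ]
    nb_aa <- vapply(nb$codon, translate_codon, character(1))
    keep <- nb_aa != "*"
    if (!any(keep)) next  # all neighbors are stops: site contributes all-N
    s <- s + sum(nb_aa[keep] == aa) / sum(keep)
  }
  c(n_sites = 3 - s, s_sites = s)
}

## Average synonymous/nonsynonymous differences between two sense codons,
## equal-weight over all minimal mutation paths that avoid stop codons
## (all paths used if every path is blocked).
.codon_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(nd = 0, sd = 0))
  p1 <- strsplit(c1, "")[[1]]
  p2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(p1 != p2)
  paths <- .permutations(diff_pos)
  count_path <- function(ord) {
    cur <- p1
    nd <- 0; sd <- 0; blocked <- FALSE
    for (p in ord) {
      prev_codon <- paste(cur, collapse = "")
      cur[p] <- p2[p]
      next_codon <- paste(cur, collapse = "")
      aa1 <- translate_codon(prev_codon)
      aa2 <- translate_codon(next_codon)
      if (aa2 == "*" || aa1 == "*") blocked <- TRUE
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
    }
    c(nd = nd, sd = sd, blocked = as.numeric(blocked))
  }
  counts <- vapply(paths, count_path, numeric(3))
  open <- counts["blocked", ] == 0
  use <- if (any(open)) counts[, open, drop = FALSE] else counts
  c(nd = mean(use["nd", ]), sd = mean(use["sd", ]))
}

.permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .permutations(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

## Lazily built lookup tables over the 61 sense codons: per-codon NG86 site
## counts and pairwise path-averaged difference counts. Pure cache: every
## entry is computed by ng86_site_counts() / .codon_pair_diffs().
.ng86_env <- new.env(parent = emptyenv())

.ng86_tables <- function() {
  if (!is.null(.ng86_env$tables)) return(.ng86_env$tables)
  codons <- SENSE_CODONS()
  sites <- t(vapply(codons, ng86_site_counts, numeric(2)))
  nd <- sd <- matrix(0, length(codons), length(codons),
                     dimnames = list(codons, codons))
  for (i in seq_along(codons)) {
    for (j in seq_along(codons)) {
      if (i < j) {
        d <- .codon_pair_diffs(codons[i], codons[j])
        nd[i, j] <- nd[j, i] <- d[["nd"]]
        sd[i, j] <- sd[j, i] <- d[["sd"]]
      }
    }
  }
  .ng86_env$tables <- list(sites = sites, nd = nd, sd = sd)
  .ng86_env$tables
}

#' Codon alignment container
#'
#' @param ids sequence identifiers (2, or 3 with an outgroup).
#' @param aligned equal-length gapped coding strings, in frame.
#' @param mask optional logical per alignment column (analyzable columns);
#'   defaults to all TRUE.
#' @return a `codon_alignment` object.
#' @export
codon_alignment <- function(ids, aligned, mask = NULL) {
  kc_assert(length(aligned) >= 2L, "need at least two sequences")
  lens <- nchar(unlist(aligned))
  kc_assert(length(unique(lens)) == 1L, "gapped strings differ in length")
  for (s in aligned) {
    kc_assert(nchar(gsub("-", "", s)) %% 3L == 0L,
              "ungapped length not a multiple of 3")
  }
  mask <- mask %||% rep(TRUE, lens[1])
  kc_assert(length(mask) == lens[1], "mask length mismatch")
  structure(list(ids = ids, aligned = aligned, mask = mask,
                 n_columns = lens[1]),
            class = "codon_alignment")
}

#' Build a codon alignment from two unaligned coding sequences
#'
#' Sequences are translated, globally aligned at the protein level
#' (BLOSUM62), and the protein alignment is back-propagated to codons —
#' the classic PAL2NAL-style construction, which keeps codon boundaries
#' intact by design.
#'
#' @param ids character(2) labels.
#' @param cds character(2) in-frame coding sequences.
#' @param mask_intervals optional list of 2 two-column matrices of ungapped
#'   nucleotide intervals to mask (low quality / assembly gaps).
#' @param qualities optional list of 2 per-base Phred vectors.
#' @param phred_min per-base threshold used with `qualities`.
#' @return a [codon_alignment()].
#' @export
align_codons <- function(ids, cds, mask_intervals = NULL, qualities = NULL,
                         phred_min = 50) {
  prot <- vapply(cds, function(s) {
    kc_assert(nchar(s) %% 3L == 0L, "coding sequence length not multiple of 3")
    paste(vapply(seq(1L, nchar(s), 3L), function(p) {
      aa <- translate_codon(substr(s, p, p + 2L))
      if (is.na(aa) || aa == "*") "X" else aa
    }, character(1)), collapse = "")
  }, character(1))
  scheme <- scoring_scheme("protein")
  aln <- align_global(list(id = ids[1], residues = prot[1]),
                      list(id = ids[2], residues = prot[2]), scheme)
  expand <- function(gapped_prot, cds_seq) {
    chars <- strsplit(gapped_prot, "")[[1]]
    res_i <- 0L
    paste(vapply(chars, function(ch) {
      if (ch == "-") return("---")
      res_i <<- res_i + 1L
      substr(cds_seq, (res_i - 1L) * 3L + 1L, res_i * 3L)
    }, character(1)), collapse = "")
  }
  g1 <- expand(aln$aligned_query, cds[1])
  g2 <- expand(aln$aligned_target, cds[2])
  gaps <- lapply(seq_len(2L), function(i) {
    iv <- if (!is.null(mask_intervals)) mask_intervals[[i]] else NULL
    iv
  })
  mask <- quality_mask(list(g1, g2),
                       qualities = qualities,
                       gap_intervals = gaps,
                       threshold = phred_min)
  ## make the mask codon-granular: a codon column triple is analyzable only
  ## if all three columns are
  ncol3 <- length(mask) - length(mask) %% 3L
  if (ncol3 > 0) {
    m3 <- matrix(mask[seq_len(ncol3)], nrow = 3L)
    mask[seq_len(ncol3)] <- rep(apply(m3, 2L, all), each = 3L)
  }
  codon_alignment(ids, list(g1, g2), mask)
}

#' NG86 dN/dS estimate from a codon alignment
#'
#' Sites are averaged over the two sequences; differences use equal-weight
#' path averaging; rates are Jukes-Cantor corrected,
#' d = -(3/4) log(1 - 4p/3). The ratio is the qualifier
#' `"undefined_dS_zero"` when dS = 0.
#'
#' @param aln a [codon_alignment()] (first two sequences are used).
#' @return a `dnds_estimate` list: `N_sites`, `S_sites`, `Nd`, `Sd`, `pN`,
#'   `pS`, `dN`, `dS`, `ratio` (numeric or qualifier string),
#'   `codon_pairs`.
#' @export
estimate_dnds <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  tabs <- .ng86_tables()
  codons <- SENSE_CODONS()
  split3 <- function(s) {
    chars <- strsplit(s, "")[[1]]
    n3 <- length(chars) %/% 3L
    vapply(seq_len(n3), function(ci)
      paste(chars[(ci - 1L) * 3L + 1:3], collapse = ""), character(1))
  }
  c1v <- split3(aln$aligned[[1]])
  c2v <- split3(aln$aligned[[2]])
  mask <- aln$mask
  ncodons <- length(c1v)
  mask3 <- vapply(seq_len(ncodons), function(ci)
    all(mask[(ci - 1L) * 3L + 1:3]), logical(1))
  i1 <- match(c1v, codons)
  i2 <- match(c2v, codons)
  ok <- mask3 & !is.na(i1) & !is.na(i2)  # drops gaps and stop/ambiguous
  pairs <- sum(ok)
  N <- sum((tabs$sites[i1[ok], "n_sites"] +
              tabs$sites[i2[ok], "n_sites"]) / 2)
  S <- sum((tabs$sites[i1[ok], "s_sites"] +
              tabs$sites[i2[ok], "s_sites"]) / 2)
  Nd <- sum(tabs$nd[cbind(i1[ok], i2[ok])])
  Sd <- sum(tabs$sd[cbind(i1[ok], i2[ok])])
  kc_assert(pairs >= 1L, "no analyzable codon pairs in alignment")
  pN <- Nd / N
  pS <- Sd / S
  kc_assert(pN < 0.75 && pS < 0.75,
            "substitution proportion >= 0.75: Jukes-Cantor correction undefined")
  jc <- function(p) if (p == 0) 0 else -0.75 * log(1 - 4 * p / 3)
  dN <- jc(pN)
  dS <- jc(pS)
  ratio <- if (dS == 0) "undefined_dS_zero" else dN / dS
  structure(
    list(N_sites = N, S_sites = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
         dN = dN, dS = dS, ratio = ratio, codon_pairs = pairs),
    class = "dnds_estimate"
  )
}

#' @export
print.dnds_estimate <- function(x, ...) {
  r <- if (is.numeric(x$ratio)) sprintf("%.4f", x$ratio) else x$ratio
  cat(sprintf("<dnds_estimate> %d codon pairs: dN %.4f, dS %.4f, dN/dS %s\n",
              x$codon_pairs, x$dN, x$dS, r))
  invisible(x)
}

#' Two-stage high-selective-pressure screen
#'
#' Stage 1 flags genes above twice the family mean of numeric ratios.
#' Stage 2 substitutes quality-recalculated ratios where supplied,
#' recomputes the mean, and takes the final set as genes whose revised
#' ratio exceeds the final cutoff (default 0.1; twice the revised mean is
#' reported alongside for comparison). Qualifier entries (`"<0.01"`)
#' participate as numeric-below-cutoff and never reach either set;
#' unavailable ratios are excluded from means.
#'
#' @param ratios named numeric vector (NA for unavailable entries).
#' @param qualifiers optional named character vector parallel to `ratios`
#'   (`"none"`, `"lt_0_01"`, `"not_available"`).
#' @param recalculated optional named numeric: revised ratios for genes with
#'   quality diagnostics; substituted at stage 2.
#' @param final_cutoff final threshold (default 0.1).
#' @return a `selection_flags` list: stage1 mean/cutoff/set, revised
#'   mean/set, `final_cutoff`, `two_x_revised_mean`, `exclusions`.
#' @export
flag_high_dnds <- function(ratios, qualifiers = NULL, recalculated = NULL,
                           final_cutoff = 0.1) {
  kc_assert(!is.null(names(ratios)), "ratios must be named by gene")
  qualifiers <- qualifiers %||%
    setNames(ifelse(is.na(ratios), "not_available", "none"), names(ratios))
  numeric_mask <- qualifiers == "none" & !is.na(ratios)
  kc_assert(sum(numeric_mask) >= 2L, "need >= 2 numeric ratios")
  stage1_mean <- mean(ratios[numeric_mask])
  stage1_cutoff <- 2 * stage1_mean
  stage1_set <- names(ratios)[numeric_mask & ratios > stage1_cutoff]

  revised <- ratios
  exclusions <- character(0)
  if (!is.null(recalculated) && length(recalculated)) {
    for (g in names(recalculated)) {
      if (g %in% names(revised)) {
        exclusions <- c(exclusions, sprintf(
          "%s: ratio %.3f replaced by quality-masked recalculation %.3f",
          g, revised[[g]], recalculated[[g]]))
        revised[[g]] <- recalculated[[g]]
        qualifiers[[g]] <- "none"
      }
    }
  }
  numeric_mask2 <- qualifiers == "none" & !is.na(revised)
  revised_mean <- mean(revised[numeric_mask2])
  final_set <- names(revised)[numeric_mask2 & revised > final_cutoff]
  structure(
    list(stage1_mean = stage1_mean, stage1_cutoff = stage1_cutoff,
         stage1_set = stage1_set, revised_mean = revised_mean,
         final_cutoff = final_cutoff,
         two_x_revised_mean = 2 * revised_mean,
         final_set = final_set, exclusions = exclusions),
    class = "selection_flags"
  )
}

#' @export
print.selection_flags <- function(x, ...) {
  cat(sprintf("Selection screen: stage-1 mean %.3f (cutoff %.3f) -> %d gene(s)\n",
              x$stage1_mean, x$stage1_cutoff, length(x$stage1_set)))
  cat(sprintf("  revised mean %.3f; final cutoff %.2f -> %d gene(s): %s\n",
              x$revised_mean, x$final_cutoff, length(x$final_set),
              paste(x$final_set, collapse = ", ")))
  invisible(x)
}

#' Lineage-acceleration assignment via an outgroup
#'
#' @param gene gene symbol.
#' @param ratio_focal_out,ratio_sibling_out dN/dS of the focal species
#'   (e.g. finch) and its sibling (e.g. chicken), each versus the outgroup.
#' @param acceleration_factor dominance factor (default 1.5; the published
#'   analysis states no criterion, so this is artifact-defined).
#' @param cutoff ratio threshold for the joint "bird_accelerated" call.
#' @return a `lineage_assignment` list with `call` in
#'   `{focal_accelerated, sibling_accelerated, both_accelerated,
#'   indeterminate}`.
#' @export
assign_lineage <- function(gene, ratio_focal_out, ratio_sibling_out,
                           acceleration_factor = 1.5, cutoff = 0.1) {
  if (is.na(ratio_focal_out) || is.na(ratio_sibling_out)) {
    call <- "indeterminate"
  } else if (ratio_focal_out >= acceleration_factor * ratio_sibling_out) {
    call <- "focal_accelerated"
  } else if (ratio_sibling_out >= acceleration_factor * ratio_focal_out) {
    call <- "sibling_accelerated"
  } else if (ratio_focal_out > cutoff && ratio_sibling_out > cutoff) {
    call <- "both_accelerated"
  } else {
    call <- "indeterminate"
  }
  structure(list(gene = gene, ratio_focal_out = ratio_focal_out,
                 ratio_sibling_out = ratio_sibling_out, call = call),
            class = "lineage_assignment")
}

#' Registry-driven selection screen
#'
#' Applies [flag_high_dnds()] to the ratio column of a loaded registry.
#' @param registry a `kc_registry`.
#' @param final_cutoff threshold, default 0.1.
#' @return a `selection_flags` object.
#' @export
screen_registry_dnds <- function(registry, final_cutoff = 0.1) {
  ratios <- setNames(registry$dnds_value, registry$symbol)
  quals <- setNames(registry$dnds_qualifier, registry$symbol)
  flag_high_dnds(ratios, qualifiers = quals, final_cutoff = final_cutoff)
}
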