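## Synteny-based locus classification and gain/loss reconciliation:
## flanking-gene evidence, the ortholog/duplication/allele/pseudogene
## decision rules, presence/absence matrices, and Dollo (single-gain)
## parsimony on the species tree.

#' Shared-flank synteny evidence between two loci
#'
#' Flank comparison uses unordered symbol sets per side (the published
#' synteny arguments rest on gene identity and adjacency, not orientation).
#' The rearrangement flag is raised when at least one query flank symbol
#' exists in the target species but on a different chromosome than the
#' target locus.
#'
#' @param query_map,target_map [genome_map()]s.
#' @param query_locus,target_locus gene symbols.
#' @param k flank window per side (default 3).
#' @param symbol_map optional named vector translating query flank symbols
#'   to target-species symbols (defaults to identity).
#' @return a `synteny_evidence` list: `shared_upstream`,
#'   `shared_downstream`, `flank_window`, `rearrangement_flag`,
#'   `gap_in_window`.
#' @export
synteny_evidence <- function(query_map, query_locus, target_map,
                             target_locus, k = 3L, symbol_map = NULL) {
  qn <- neighborhood(query_map, query_locus, k)
  tn <- neighborhood(target_map, target_locus, k)
  translate <- function(sym) {
    if (is.null(symbol_map)) sym
    else ifelse(sym %in% names(symbol_map), symbol_map[sym], sym)
  }
  q_up <- translate(qn$upstream)
  q_down <- translate(qn$downstream)
  t_flanks <- c(tn$upstream, tn$downstream)
  ## per-side counts against the union of target flanks (inversions and
  ## local shuffles leave set-level synteny intact)
  shared_up <- length(intersect(q_up, t_flanks))
  shared_down <- length(intersect(q_down, t_flanks))
  all_q <- c(q_up, q_down)
  target_feats <- target_map$features[!target_map$features$is_gap, ]
  elsewhere <- vapply(all_q, function(sym) {
    rows <- target_feats[target_feats$symbol == sym, , drop = FALSE]
    nrow(rows) > 0L && !any(rows$chrom == tn$chrom)
  }, logical(1))
  structure(
    list(shared_upstream = shared_up, shared_downstream = shared_down,
         flank_window = k,
         rearrangement_flag = any(elsewhere),
         gap_in_window = nrow(tn$gaps_in_window) > 0L ||
           nrow(qn$gaps_in_window) > 0L),
    class = "synteny_evidence"
  )
}

#' @export
print.synteny_evidence <- function(x, ...) {
  cat(sprintf("<synteny_evidence> up %d / down %d of k=%d%s\n",
              x$shared_upstream, x$shared_downstream, x$flank_window,
              if (x$rearrangement_flag) " [rearrangement]" else ""))
  invisible(x)
}

#' Placement context of a locus
#'
#' `unplaced` for chrUn-style scaffolds, `gap_flanked` when an assembly gap
#' lies within the flank window, otherwise `placed`.
#' @param map a `genome_map`.
#' @param locus symbol.
#' @param k flank window.
#' @export
placement_context <- function(map, locus, k = 3L) {
  nb <- neighborhood(map, locus, k)
  if (nb$unplaced) "unplaced"
  else if (nrow(nb$gaps_in_window) > 0L) "gap_flanked"
  else "placed"
}

#' Classify a candidate locus
#'
#' Decision rules applied in order (the call carries its rule trace):
#' 1. ortholog — shared flanks with the reference-species locus on both
#'    sides (>= 1 per side) or >= `total_flanks` shared in total;
#' 2. duplication — placed locus whose own flanks are conserved around a
#'    corresponding locus in at least `min_dup_species` comparator species;
#' 3. allele — aligned-region identity >= `allele_identity` and placement
#'    unplaced or gap-flanked;
#' 4. pseudogene — at least one degradation mark (missing start codon,
#'    truncation without a gap excuse, no transcript support);
#' 5. otherwise unresolved.
#'
#' @param candidate list(symbol=, map=) — the locus in its own species map.
#' @param parent parent/reference gene symbol in `reference_map`.
#' @param reference_map the comparator map carrying the parent locus.
#' @param comparator_maps list of additional `genome_map`s for the
#'   duplication rule (the candidate symbol is looked up in each).
#' @param alignment optional `alignment_result` of candidate vs parent.
#' @param degradation character vector of degradation marks (subset of
#'   `c("missing_start_codon", "truncated", "no_transcript_support")`).
#' @param k flank window (default 3).
#' @param allele_identity percent threshold (default 95).
#' @param min_dup_species comparator species needed for a duplication call
#'   (default 2; stricter than single-comparator practice, and said so in
#'   the trace).
#' @param total_flanks total shared flanks that also satisfy the ortholog
#'   rule (default 3).
#' @return a `locus_classification` with `call`, `evidence`, `rule_trace`.
#' @export
classify_locus <- function(candidate, parent, reference_map,
                           comparator_maps = list(), alignment = NULL,
                           degradation = character(0), k = 3L,
                           allele_identity = 95, min_dup_species = 2L,
                           total_flanks = 3L) {
  trace <- character(0)
  placement <- placement_context(candidate$map, candidate$symbol, k)
  ref_evidence <- NULL
  ## a degraded locus is never the ortholog or a functional duplication:
  ## degradation marks bypass rules 1-2 (an adjacent truncated copy shares
  ## the parent's neighborhood yet is a pseudogene)
  degraded <- length(degradation) > 0L
  if (degraded) {
    trace <- c(trace, "rules 1-2 skipped: degradation marks present")
  }
  parent_in_ref <- any(reference_map$features$symbol == parent &
                         !reference_map$features$is_gap)
  if (!degraded && parent_in_ref &&
      any(candidate$map$features$symbol == candidate$symbol)) {
    ref_evidence <- synteny_evidence(candidate$map, candidate$symbol,
                                     reference_map, parent, k)
    both_sides <- ref_evidence$shared_upstream >= 1L &&
      ref_evidence$shared_downstream >= 1L
    total <- ref_evidence$shared_upstream + ref_evidence$shared_downstream
    if (both_sides || total >= total_flanks) {
      trace <- c(trace, sprintf(
        "rule 1 (ortholog): %d/%d flanks shared with %s locus in %s",
        ref_evidence$shared_upstream, ref_evidence$shared_downstream,
        parent, reference_map$species))
      return(.locus_call("ortholog", ref_evidence, placement, alignment,
                         trace))
    }
    trace <- c(trace, sprintf(
      "rule 1 failed: %d/%d flanks shared with reference",
      ref_evidence$shared_upstream, ref_evidence$shared_downstream))
  } else if (!degraded) {
    trace <- c(trace, "rule 1 skipped: parent locus absent from reference map")
  }

  if (!degraded && placement == "placed" && length(comparator_maps)) {
    ## order-invariant over comparator species
    maps <- comparator_maps[order(vapply(comparator_maps, `[[`,
                                         character(1), "species"))]
    supporting <- 0L
    for (cm in maps) {
      if (!any(cm$features$symbol == candidate$symbol & !cm$features$is_gap))
        next
      ev <- synteny_evidence(candidate$map, candidate$symbol, cm,
                             candidate$symbol, k)
      if (ev$shared_upstream >= 1L && ev$shared_downstream >= 1L) {
        supporting <- supporting + 1L
      }
    }
    if (supporting >= min_dup_species) {
      trace <- c(trace, sprintf(
        "rule 2 (duplication): distinct conserved flanks in %d species (rule requires >= %d; stricter than single-comparator usage)",
        supporting, min_dup_species))
      return(.locus_call("duplication", ref_evidence, placement, alignment,
                         trace))
    }
    trace <- c(trace, sprintf(
      "rule 2 failed: conserved context in %d species (< %d)", supporting,
      min_dup_species))
  } else {
    trace <- c(trace, sprintf("rule 2 skipped: placement %s", placement))
  }

  identity <- if (!is.null(alignment)) alignment$percent_identity else NA_real_
  if (!is.na(identity) && identity >= allele_identity &&
      placement %in% c("unplaced", "gap_flanked")) {
    trace <- c(trace, sprintf(
      "rule 3 (allele): identity %.1f%% >= %.0f%% on %s locus",
      identity, allele_identity, placement))
    return(.locus_call("allele", ref_evidence, placement, alignment, trace))
  }
  trace <- c(trace, "rule 3 failed: identity/placement do not meet the allele rule")

  if (length(degradation)) {
    trace <- c(trace, sprintf("rule 4 (pseudogene): degradation marks [%s]",
                              paste(degradation, collapse = ", ")))
    res <- .locus_call("pseudogene", ref_evidence, placement, alignment,
                       trace)
    res$evidence$degradation <- degradation
    return(res)
  }
  trace <- c(trace, "rule 4 failed: no degradation marks")
  .locus_call("unresolved", ref_evidence, placement, alignment, trace)
}

.locus_call <- function(call, synteny, placement, alignment, trace) {
  structure(
    list(call = call,
         evidence = list(
           synteny = synteny,
           placement = placement,
           identity = if (!is.null(alignment)) alignment$percent_identity
                      else NA_real_,
           score = if (!is.null(alignment)) alignment$score else NA_real_
         ),
         rule_trace = trace),
    class = "locus_classification"
  )
}

#' @export
print.locus_classification <- function(x, ...) {
  cat(sprintf("<locus_classification> %s (placement %s)\n", x$call,
              x$evidence$placement))
  for (tr in x$rule_trace) cat("  -", tr, "\n")
  invisible(x)
}

#' Build a presence/absence matrix over species
#'
#' A gene is `present` in a species when its map carries the symbol;
#' `absent` only when the syntenic window (the whole chromosome set here,
#' desk-scale) is free of assembly gaps; otherwise `unknown_gap` — absence
#' over a gap is never called.
#'
#' @param genes gene symbols (rows).
#' @param maps named list of `genome_map`s (columns).
#' @param gap_windows optional function(map, gene) returning TRUE when an
#'   assembly gap overlaps the expected syntenic window; default checks for
#'   any gap feature in the map.
#' @return character matrix, class `presence_matrix`.
#' @export
build_presence_matrix <- function(genes, maps, gap_windows = NULL) {
  species <- vapply(maps, `[[`, character(1), "species")
  names(maps) <- species
  m <- matrix("absent", nrow = length(genes), ncol = length(species),
              dimnames = list(genes, species))
  for (sp in species) {
    f <- maps[[sp]]$features
    for (g in genes) {
      if (any(f$symbol == g & !f$is_gap)) {
        m[g, sp] <- "present"
      } else {
        gap_here <- if (!is.null(gap_windows)) {
          isTRUE(gap_windows(maps[[sp]], g))
        } else {
          any(f$is_gap)
        }
        if (gap_here) m[g, sp] <- "unknown_gap"
      }
    }
  }
  class(m) <- c("presence_matrix", class(m))
  m
}

#' Write a presence matrix as TSV (genes x species)
#' @param m a `presence_matrix`.
#' @param path output file.
#' @export
write_presence_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), unclass(m), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- Dollo reconciliation ----------------------------------------------

.tree_children <- function(tree, node) {
  tree$edge[tree$edge[, 1] == node, 2]
}

.tree_leaves_below <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  out <- character(0)
  for (ch in .tree_children(tree, node)) {
    out <- c(out, .tree_leaves_below(tree, ch))
  }
  out
}

.preorder_nodes <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  out <- integer(0)
  walk <- function(node) {
    out <<- c(out, node)
    for (ch in .tree_children(tree, node)) walk(ch)
  }
  walk(root)
  out
}

.node_label <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  lab <- tree$node.label[node - n_tip]
  if (!is.null(lab) && !is.na(lab) && nzchar(lab)) lab
  else paste0("node", node)
}

## count the minimal losses under a fixed gain node; returns NA when the
## gain node does not cover all present leaves
.dollo_losses <- function(tree, gain, present, absent) {
  leaves_below <- .tree_leaves_below(tree, gain)
  if (!all(present %in% leaves_below)) return(NULL)
  losses <- integer(0)
  descend <- function(node) {
    lv <- .tree_leaves_below(tree, node)
    if (!any(lv %in% present)) {
      if (any(lv %in% absent)) losses <<- c(losses, node)
      return(invisible(NULL))  # unknown-only subtrees stay unconstrained
    }
    for (ch in .tree_children(tree, node)) descend(ch)
  }
  for (ch in .tree_children(tree, gain)) descend(ch)
  ## a present gain-leaf (gain at a tip) has no children to descend
  losses
}

#' Dollo (single-gain) parsimony reconciliation of one phylogenetic profile
#'
#' One gain, any number of losses. Cells are `present` / `absent` /
#' `unknown_gap`; unknown cells impose no constraint (no loss is inferred
#' over an assembly gap). The gain node is the deepest (closest to the
#' root) node covering all present leaves that adds no losses beyond the
#' minimum; remaining ties break by pre-order index.
#'
#' @param profile named character vector (names = tip labels) with values
#'   in `c("present", "absent", "unknown_gap")`.
#' @param tree an [ape::read.tree()] phylo object.
#' @return a `gain_loss_events` list: `gain_node` (label), `loss_branches`
#'   (labels of the subtree roots losing the gene), `n_losses`, and the
#'   internal node numbers.
#' @export
dollo_reconcile <- function(profile, tree) {
  stopifnot(inherits(tree, "phylo"))
  kc_assert(all(names(profile) %in% tree$tip.label),
            "profile names must be tree tips")
  present <- names(profile)[profile == "present"]
  absent <- names(profile)[profile == "absent"]
  kc_assert(length(present) >= 1L, "all-absent profile: nothing to reconcile")
  candidates <- .preorder_nodes(tree)
  best <- NULL
  for (node in candidates) {
    losses <- .dollo_losses(tree, node, present, absent)
    if (is.null(losses)) next  # gain node does not cover all present leaves
    cand <- list(node = node, losses = losses, n = length(losses),
                 depth = .node_depth(tree, node))
    if (is.null(best) ||
        cand$n < best$n ||
        (cand$n == best$n && cand$depth < best$depth)) {
      best <- cand
    }
    ## pre-order scan: the first node at a given (n, depth) wins ties
  }
  structure(
    list(gain_node = .node_label(tree, best$node),
         gain_node_id = best$node,
         loss_branches = vapply(best$losses, function(nd)
           .node_label(tree, nd), character(1)),
         loss_branch_ids = best$losses,
         n_losses = best$n),
    class = "gain_loss_events"
  )
}

.node_depth <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  d <- 0L
  cur <- node
  while (cur != root) {
    parent <- tree$edge[tree$edge[, 2] == cur, 1]
    if (length(parent) == 0L) break
    cur <- parent
    d <- d + 1L
  }
  d
}

#' @export
print.gain_loss_events <- function(x, ...) {
  cat(sprintf("<gain_loss_events> gain at %s; %d loss(es)%s\n",
              x$gain_node, x$n_losses,
              if (x$n_losses) paste0(": ",
                                     paste(x$loss_branches, collapse = ", "))
              else ""))
  invisible(x)
}
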