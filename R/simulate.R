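## Ground-truthed multi-species fixture generator. A stated world: the
## default configuration IS the test bed (20 genes, 6 species, 3 planted
## duplications, 2 losses, 2 alleles, 1 pseudogene, 2 indels, one
## low-quality patch, one assembly gap), all reproducible from one seed
## through a single global random stream (tree pre-order, then event-list
## order).

DEFAULT_TREE_6SP <- paste0(
  "(fish:0.50,(frog:0.35,((lizard:0.25,(chicken:0.09,finch:0.09)",
  "birds:0.12)sauropsida:0.08,human:0.35)amniota:0.08)tetrapoda:0.10)",
  "teleostomi;")

#' The paper-style 8-species comparison tree
#'
#' Fish, frog, lizard, chicken, finch, platypus, mouse, human with named
#' clades; used for reconciliation examples and tests. The default
#' simulation bundle uses a 6-species subset (see
#' [default_simulation_config()]).
#' @export
default_species_tree <- function() {
  parse_tree(paste0(
    "(fish:0.50,(frog:0.35,((lizard:0.25,(chicken:0.09,finch:0.09)",
    "birds:0.12)sauropsida:0.08,(platypus:0.20,(mouse:0.15,human:0.15)",
    "supraprimates:0.10)mammalia:0.08)amniota:0.08)tetrapoda:0.10)",
    "teleostomi;"))
}

#' Simulation configuration
#'
#' @param seed integer; fixes every output bit-for-bit.
#' @param tree_text Newick with branch lengths in expected codon
#'   substitutions per site and labelled internal nodes.
#' @param n_genes number of family genes (symbols `KCG1..KCGn`).
#' @param n_codons coding length per gene (codons).
#' @param kappa transition/transversion rate ratio.
#' @param omega_default,omega_overrides per-gene dN/dS used by the codon
#'   model.
#' @param events list of planted events (see [default_simulation_config()]).
#' @param base_phred,low_phred quality model for the focal species.
#' @param focal,sibling,reference,outgroup species roles.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              tree_text = DEFAULT_TREE_6SP,
                              n_genes = 20L,
                              n_codons = 500L,
                              kappa = 2,
                              omega_default = 0.05,
                              omega_overrides = c(KCG11 = 0.5, KCG17 = 0.4),
                              events = list(),
                              base_phred = 60L,
                              low_phred = 20L,
                              focal = "finch",
                              sibling = "chicken",
                              reference = "human",
                              outgroup = "lizard") {
  genes <- paste0("KCG", seq_len(n_genes))
  omega <- setNames(rep(omega_default, n_genes), genes)
  for (g in names(omega_overrides)) {
    if (g %in% genes) omega[[g]] <- omega_overrides[[g]]
  }
  cfg <- structure(
    list(seed = as.integer(seed), tree_text = tree_text, genes = genes,
         n_codons = as.integer(n_codons), kappa = kappa, omega = omega,
         events = events, base_phred = base_phred, low_phred = low_phred,
         focal = focal, sibling = sibling, reference = reference,
         outgroup = outgroup),
    class = "simulation_config"
  )
  .validate_events(cfg)
  cfg
}

#' The default stated-world configuration
#'
#' 20 genes of 500 codons on 6 species; planted events: duplications of
#' KCG3 (sauropsids), KCG7 (tetrapods) and KCG12 (amniotes); losses of
#' KCG5 (human) and KCG9 (birds); finch allelic copies of KCG2 and KCG14
#' on unplaced scaffolds with a known edit list; a truncated finch
#' pseudogene of KCG6 lacking a start codon; a 2-codon finch deletion in
#' KCG4 inside an ion-transport domain and a 2-codon finch insertion in
#' KCG8; a low-quality patch in KCG10; an assembly gap replacing KCG15 in
#' frog. Genes KCG11 and KCG17 evolve with dN/dS above the 0.1 screen
#' cutoff.
#' @param seed integer seed.
#' @export
default_simulation_config <- function(seed = 1L) {
  events <- list(
    list(type = "duplication", gene = "KCG3", branch = "sauropsida",
         copy = "KCG3L", slot = c("F31", "F32")),
    list(type = "duplication", gene = "KCG7", branch = "tetrapoda",
         copy = "KCG7L", slot = c("F64", "F65")),
    list(type = "duplication", gene = "KCG12", branch = "amniota",
         copy = "KCG12L", slot = c("F65", "F66")),
    list(type = "loss", gene = "KCG5", branch = "human"),
    list(type = "loss", gene = "KCG9", branch = "birds"),
    list(type = "allele", gene = "KCG2", copy = "KCG2A",
         scaffold = "chrUn_scaffold1",
         edits = list(
           list(codon = 50L, ref = "TTT", alt = "TTC", klass = "synonymous"),
           list(codon = 120L, ref = "GGA", alt = "GGG", klass = "synonymous"),
           list(codon = 200L, ref = "ACT", alt = "TCT",
                klass = "conservative"))),
    list(type = "allele", gene = "KCG14", copy = "KCG14A",
         scaffold = "chrUn_scaffold2",
         edits = list(
           list(codon = 30L, ref = "CTG", alt = "CTA", klass = "synonymous"),
           list(codon = 90L, ref = "ACC", alt = "GCC",
                klass = "non_conservative")),
         deletion = list(codon = 150L, ref = "TTT")),
    list(type = "pseudogene", gene = "KCG6", copy = "KCG6P",
         from_codon = 100L, to_codon = 400L),
    list(type = "indel", gene = "KCG4", kind = "deletion", codon = 300L,
         codons = c("AAT", "GGC"), domain = c(295L, 310L, "ion_transport")),
    list(type = "indel", gene = "KCG8", kind = "insertion", codon = 200L,
         codons = c("GCT", "AGT"), domain = NULL),
    list(type = "low_quality", gene = "KCG10", codon_from = 10L,
         codon_to = 20L),
    list(type = "assembly_gap", gene = "KCG15", species = "frog")
  )
  simulation_config(seed = seed, events = events)
}

.validate_events <- function(cfg) {
  genes <- cfg$genes
  lost <- list()
  for (ev in cfg$events) {
    kc_assert(ev$gene %in% genes, "event targets unknown gene '%s'", ev$gene)
    if (ev$type == "loss") lost[[ev$gene]] <- ev$branch
  }
  for (ev in cfg$events) {
    if (ev$type == "allele" && !is.null(lost[[ev$gene]])) {
      tree <- parse_tree(cfg$tree_text)
      below <- .leaves_below_label(tree, lost[[ev$gene]])
      if (cfg$focal %in% below) {
        kc_stop("contradictory events: allele of %s planted below its loss",
                ev$gene)
      }
    }
  }
  invisible(TRUE)
}

.leaves_below_label <- function(tree, label) {
  if (label %in% tree$tip.label) return(label)
  n_tip <- length(tree$tip.label)
  idx <- which(tree$node.label == label)
  kc_assert(length(idx) == 1L, "no tree node labelled '%s'", label)
  .tree_leaves_below(tree, n_tip + idx)
}

## ---- codon substitution model ------------------------------------------

.is_transition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}

#' Codon rate matrix of the kappa/omega substitution model
#'
#' Single-nucleotide exchanges only; transitions weighted by `kappa`,
#' nonsynonymous changes by `omega`, mutations to stop codons excluded.
#' The matrix is scaled so one unit of branch length is one expected codon
#' substitution per site at uniform codon frequencies.
#'
#' @param kappa transition/transversion ratio.
#' @param omega dN/dS.
#' @return 61 x 61 rate matrix over sense codons.
#' @export
codon_rate_matrix <- function(kappa = 2, omega = 1) {
  codons <- SENSE_CODONS()
  n <- length(codons)
  Q <- matrix(0, n, n, dimnames = list(codons, codons))
  gc <- GENETIC_CODE_TABLE()
  for (i in seq_len(n)) {
    ci <- strsplit(codons[i], "")[[1]]
    for (j in seq_len(n)) {
      if (i == j) next
      cj <- strsplit(codons[j], "")[[1]]
      diff <- which(ci != cj)
      if (length(diff) != 1L) next
      rate <- if (.is_transition(ci[diff], cj[diff])) kappa else 1
      if (gc[[codons[i]]] != gc[[codons[j]]]) rate <- rate * omega
      Q[i, j] <- rate
    }
  }
  diag(Q) <- -rowSums(Q)
  scale <- -mean(diag(Q))
  Q / scale
}

.pmatrix_cache <- new.env(parent = emptyenv())

.transition_matrix <- function(kappa, omega, t) {
  key <- sprintf("%.8g|%.8g|%.8g", kappa, omega, t)
  if (!is.null(.pmatrix_cache[[key]])) return(.pmatrix_cache[[key]])
  Q <- codon_rate_matrix(kappa, omega)
  P <- as.matrix(Matrix::expm(Q * t))
  P[P < 0] <- 0
  P <- P / rowSums(P)
  .pmatrix_cache[[key]] <- P
  P
}

.evolve_states <- function(states, P) {
  out <- integer(length(states))
  for (s in unique(states)) {
    idx <- which(states == s)
    out[idx] <- sample.int(nrow(P), length(idx), replace = TRUE,
                           prob = P[s, ])
  }
  out
}

.codons_to_string <- function(states) {
  paste(SENSE_CODONS()[states], collapse = "")
}

#' Evolve codon sequences under a specified dN/dS
#'
#' Continuous-time codon substitution (single-nucleotide exchanges with
#' `kappa` bias; nonsynonymous changes damped by `omega`; stop codons
#' unreachable). With a `phylo` tree, sequences are evolved from a random
#' ancestor down every branch (pre-order); with a single number, a pair of
#' tips at total divergence `tree` is returned.
#'
#' @param n_codons sequence length in codons.
#' @param tree a `phylo` object or a numeric pairwise divergence (expected
#'   codon substitutions per site separating the two tips).
#' @param kappa transition/transversion ratio (default 2).
#' @param omega dN/dS (>= 0).
#' @param seed optional; when given, seeds the global stream.
#' @param ancestor optional codon-state integer vector to evolve from.
#' @return named character vector of coding sequences (tips; plus
#'   `".ancestor"` attribute of internal states when a tree is supplied).
#' @export
evolve_codons <- function(n_codons, tree, kappa = 2, omega = 0.05,
                          seed = NULL, ancestor = NULL) {
  kc_assert(omega >= 0, "omega must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  codons <- SENSE_CODONS()
  anc <- ancestor %||% sample.int(length(codons), n_codons, replace = TRUE)
  if (is.numeric(tree) && length(tree) == 1L) {
    P <- .transition_matrix(kappa, omega, tree / 2)
    tips <- c(a = .codons_to_string(.evolve_states(anc, P)),
              b = .codons_to_string(.evolve_states(anc, P)))
    attr(tips, "ancestor_states") <- anc
    return(tips)
  }
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  states <- vector("list", n_tip + tree$Nnode)
  states[[root]] <- anc
  order_idx <- .preorder_nodes(tree)
  for (node in order_idx) {
    for (edge_row in which(tree$edge[, 1] == node)) {
      child <- tree$edge[edge_row, 2]
      t <- tree$edge.length[edge_row]
      P <- .transition_matrix(kappa, omega, t)
      states[[child]] <- .evolve_states(states[[node]], P)
    }
  }
  tips <- vapply(seq_len(n_tip), function(i) .codons_to_string(states[[i]]),
                 character(1))
  names(tips) <- tree$tip.label
  attr(tips, "node_states") <- states
  tips
}

## ---- genome layout ------------------------------------------------------

.ancestral_layout <- function(cfg) {
  ## chr1: F1 F2 F3 G1 F4 F5 F6 G2 ... G10 F31 F32 F33; chr2 likewise
  n <- length(cfg$genes)
  half <- ceiling(n / 2)
  mk_chrom <- function(chrom, gene_idx, flank_offset) {
    slots <- character(0)
    fi <- flank_offset
    for (g in gene_idx) {
      slots <- c(slots, paste0("F", fi + 1:3), cfg$genes[g])
      fi <- fi + 3L
    }
    slots <- c(slots, paste0("F", fi + 1:3))
    data.frame(symbol = slots, chrom = chrom,
               slot = seq_along(slots), stringsAsFactors = FALSE)
  }
  rbind(mk_chrom("chr1", seq_len(half), 0L),
        mk_chrom("chr2", seq(half + 1L, n), half * 3L + 3L))
}

.layout_to_features <- function(layout, gene_len, symbols_present,
                                extra = NULL) {
  lay <- layout[layout$symbol %in% symbols_present, , drop = FALSE]
  start <- lay$slot * 10000L + 1L
  len <- ifelse(grepl("^F", lay$symbol), 1000L, gene_len)
  feats <- data.frame(symbol = lay$symbol, chrom = lay$chrom,
                      start = start, end = start + len - 1L,
                      strand = "+", is_gap = FALSE,
                      stringsAsFactors = FALSE)
  if (!is.null(extra)) feats <- rbind(feats, extra)
  feats
}

## insert a feature between two flank symbols of a layout
.between_slot <- function(layout, left_sym) {
  row <- layout[layout$symbol == left_sym, ]
  list(chrom = row$chrom, start = row$slot * 10000L + 5001L)
}

## ---- main generator -----------------------------------------------------

#' Simulate a multi-species fixture bundle with ground truth
#'
#' @param config a [simulation_config()].
#' @return a `sim_bundle` list: `config`, `tree`, per-species `maps`
#'   ([genome_map()]) and `sequences` ([seq_set()]), focal-species
#'   `qualities`, `domains`, `transcript_support`, and `ground_truth`
#'   (planted classifications, substitutions, indels, gain/loss events,
#'   true omega per gene, unknown-gap cells).
#' @export
simulate_genomes <- function(config = default_simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  tree <- parse_tree(config$tree_text)
  species <- tree$tip.label
  n_tip <- length(species)
  gene_len <- 3L * config$n_codons

  ## 1. evolve every gene down the tree (pre-order; gene order fixed)
  seqs <- list()        # seqs[[gene]][[species]]
  node_states <- list() # per gene, states at every node
  for (g in config$genes) {
    tips <- evolve_codons(config$n_codons, tree, kappa = config$kappa,
                          omega = config$omega[[g]])
    node_states[[g]] <- attr(tips, "node_states")
    seqs[[g]] <- as.list(tips)
  }

  ## 2. apply events in list order
  layout <- .ancestral_layout(config)
  extra_feats <- setNames(vector("list", n_tip), species)
  dropped <- setNames(rep(list(character(0)), n_tip), species)
  extra_seqs <- setNames(rep(list(list()), n_tip), species)
  domains <- data.frame(protein = character(0), start = integer(0),
                        end = integer(0), label = character(0),
                        stringsAsFactors = FALSE)
  gt_class <- list(); gt_subs <- list(); gt_indels <- list()
  gt_gainloss <- list(); gt_unknown <- list()
  focal <- config$focal

  force_codons <- function(gene, codon_idx, codons, in_species = species) {
    for (sp in in_species) {
      if (is.null(seqs[[gene]][[sp]])) next
      s <- seqs[[gene]][[sp]]
      for (k in seq_along(codon_idx)) {
        p <- (codon_idx[k] - 1L) * 3L + 1L
        substr(s, p, p + 2L) <- codons[k]
      }
      seqs[[gene]][[sp]] <<- s
    }
  }

  ## every functional gene starts with a start codon (so degradation marks
  ## computed downstream are truthful)
  for (g in config$genes) force_codons(g, 1L, "ATG")

  for (ev in config$events) {
    switch(
      ev$type,
      duplication = {
        carriers <- .leaves_below_label(tree, ev$branch)
        node_id <- if (ev$branch %in% tree$tip.label) {
          match(ev$branch, tree$tip.label)
        } else {
          n_tip + which(tree$node.label == ev$branch)
        }
        sub <- ape::keep.tip(tree, carriers)
        anc_states <- node_states[[ev$gene]][[node_id]]
        copy_tips <- evolve_codons(config$n_codons, sub,
                                   kappa = config$kappa,
                                   omega = config$omega[[ev$gene]],
                                   ancestor = anc_states)
        slotinfo <- .between_slot(layout, ev$slot[1])
        for (sp in carriers) {
          cp <- copy_tips[[sp]]
          substr(cp, 1L, 3L) <- "ATG"
          extra_seqs[[sp]][[ev$copy]] <- cp
          extra_feats[[sp]] <- rbind(extra_feats[[sp]], data.frame(
            symbol = ev$copy, chrom = slotinfo$chrom,
            start = slotinfo$start, end = slotinfo$start + gene_len - 1L,
            strand = "+", is_gap = FALSE, stringsAsFactors = FALSE))
        }
        gt_class[[ev$copy]] <- data.frame(
          locus = ev$copy, parent = ev$gene, call = "duplication",
          stringsAsFactors = FALSE)
        gt_gainloss[[ev$copy]] <- list(gene = ev$copy, gain = ev$branch,
                                       losses = character(0))
      },
      loss = {
        gone <- .leaves_below_label(tree, ev$branch)
        for (sp in gone) {
          dropped[[sp]] <- c(dropped[[sp]], ev$gene)
          seqs[[ev$gene]][[sp]] <- NULL
        }
        gt_gainloss[[ev$gene]] <- list(
          gene = ev$gene, gain = .node_label(tree, n_tip + 1L),
          losses = ev$branch)
      },
      allele = {
        edits <- ev$edits
        force_codons(ev$gene,
                     vapply(edits, `[[`, integer(1), "codon"),
                     vapply(edits, `[[`, character(1), "ref"),
                     in_species = focal)
        if (!is.null(ev$deletion)) {
          force_codons(ev$gene, ev$deletion$codon, ev$deletion$ref,
                       in_species = focal)
        }
        cds <- seqs[[ev$gene]][[focal]]
        allele <- cds
        for (ed in edits) {
          p <- (ed$codon - 1L) * 3L + 1L
          substr(allele, p, p + 2L) <- ed$alt
        }
        if (!is.null(ev$deletion)) {
          p <- (ev$deletion$codon - 1L) * 3L + 1L
          allele <- paste0(substr(allele, 1L, p - 1L),
                           substr(allele, p + 3L, nchar(allele)))
        }
        extra_seqs[[focal]][[ev$copy]] <- allele
        extra_feats[[focal]] <- rbind(extra_feats[[focal]], data.frame(
          symbol = ev$copy, chrom = ev$scaffold, start = 1001L,
          end = 1000L + nchar(allele), strand = "+", is_gap = FALSE,
          stringsAsFactors = FALSE))
        gt_class[[ev$copy]] <- data.frame(
          locus = ev$copy, parent = ev$gene, call = "allele",
          stringsAsFactors = FALSE)
        recs <- lapply(edits, function(ed) data.frame(
          locus = ev$copy, parent = ev$gene, position = ed$codon,
          ref_aa = translate_codon(ed$ref), alt_aa = translate_codon(ed$alt),
          klass = ed$klass, stringsAsFactors = FALSE))
        gt_subs[[ev$copy]] <- do.call(rbind, recs)
        if (!is.null(ev$deletion)) {
          gt_indels[[paste0(ev$copy, "_del")]] <- data.frame(
            gene = ev$copy, kind = "deletion",
            position = ev$deletion$codon,
            residues = translate_codon(ev$deletion$ref), lineage = focal,
            stringsAsFactors = FALSE)
        }
      },
      pseudogene = {
        force_codons(ev$gene, ev$from_codon, "GTG", in_species = focal)
        cds <- seqs[[ev$gene]][[focal]]
        frag <- substr(cds, (ev$from_codon - 1L) * 3L + 1L,
                       ev$to_codon * 3L)
        extra_seqs[[focal]][[ev$copy]] <- frag
        parent_row <- layout[layout$symbol == ev$gene, ]
        pstart <- parent_row$slot * 10000L + gene_len + 500L
        extra_feats[[focal]] <- rbind(extra_feats[[focal]], data.frame(
          symbol = ev$copy, chrom = parent_row$chrom, start = pstart,
          end = pstart + nchar(frag) - 1L, strand = "+", is_gap = FALSE,
          stringsAsFactors = FALSE))
        gt_class[[ev$copy]] <- data.frame(
          locus = ev$copy, parent = ev$gene, call = "pseudogene",
          stringsAsFactors = FALSE)
      },
      indel = {
        codon_idx <- ev$codon + seq_along(ev$codons) - 1L
        force_codons(ev$gene, codon_idx, ev$codons)
        if (ev$kind == "deletion") {
          ## focal lineage lacks the forced codons
          s <- seqs[[ev$gene]][[focal]]
          p <- (ev$codon - 1L) * 3L + 1L
          seqs[[ev$gene]][[focal]] <-
            paste0(substr(s, 1L, p - 1L),
                   substr(s, p + 3L * length(ev$codons), nchar(s)))
        } else {
          ## insertion exists only in the focal lineage: remove the forced
          ## codons everywhere else
          for (sp in setdiff(species, focal)) {
            if (is.null(seqs[[ev$gene]][[sp]])) next
            s <- seqs[[ev$gene]][[sp]]
            p <- (ev$codon - 1L) * 3L + 1L
            seqs[[ev$gene]][[sp]] <-
              paste0(substr(s, 1L, p - 1L),
                     substr(s, p + 3L * length(ev$codons), nchar(s)))
          }
        }
        if (!is.null(ev$domain)) {
          domains <- rbind(domains, data.frame(
            protein = ev$gene, start = as.integer(ev$domain[1]),
            end = as.integer(ev$domain[2]), label = ev$domain[3],
            stringsAsFactors = FALSE))
        }
        gt_indels[[ev$gene]] <- data.frame(
          gene = ev$gene, kind = ev$kind, position = ev$codon,
          residues = paste(vapply(ev$codons, translate_codon, character(1)),
                           collapse = ""),
          lineage = focal, stringsAsFactors = FALSE)
      },
      low_quality = NULL,   # handled with qualities below
      assembly_gap = {
        sp <- ev$species
        dropped[[sp]] <- c(dropped[[sp]], ev$gene)
        seqs[[ev$gene]][[sp]] <- NULL
        row <- layout[layout$symbol == ev$gene, ]
        gstart <- row$slot * 10000L + 1L
        extra_feats[[sp]] <- rbind(extra_feats[[sp]], data.frame(
          symbol = "gap", chrom = row$chrom, start = gstart,
          end = gstart + gene_len - 1L, strand = "*", is_gap = TRUE,
          stringsAsFactors = FALSE))
        gt_unknown[[length(gt_unknown) + 1L]] <- data.frame(
          gene = ev$gene, species = sp, stringsAsFactors = FALSE)
      },
      kc_stop("unknown event type '%s'", ev$type)
    )
  }

  ## 3. assemble maps and sequence sets
  maps <- list()
  sequences <- list()
  for (sp in species) {
    present <- c(layout$symbol[grepl("^F", layout$symbol)],
                 setdiff(config$genes, dropped[[sp]]))
    feats <- .layout_to_features(layout, gene_len, present,
                                 extra = extra_feats[[sp]])
    maps[[sp]] <- genome_map(sp, feats)
    ids <- c(setdiff(config$genes, dropped[[sp]]),
             names(extra_seqs[[sp]]))
    res <- c(lapply(setdiff(config$genes, dropped[[sp]]),
                    function(g) seqs[[g]][[sp]]),
             unname(extra_seqs[[sp]]))
    sequences[[sp]] <- seq_set(ids, unlist(res))
  }

  ## 4. focal-species qualities (base phred with planted low patches)
  qualities <- list()
  for (id in names(sequences[[focal]])) {
    qualities[[id]] <- rep(config$base_phred,
                           nchar(sequences[[focal]][[id]]$residues))
  }
  for (ev in config$events) {
    if (ev$type == "low_quality") {
      span <- ((ev$codon_from - 1L) * 3L + 1L):(ev$codon_to * 3L)
      qualities[[ev$gene]][span] <- config$low_phred
    }
  }

  transcript_support <- setdiff(names(sequences[[focal]]),
                                vapply(Filter(function(e)
                                  e$type == "pseudogene", config$events),
                                  `[[`, character(1), "copy"))

  ground_truth <- list(
    classifications = if (length(gt_class)) do.call(rbind, gt_class)
                      else NULL,
    substitutions = if (length(gt_subs)) do.call(rbind, gt_subs) else NULL,
    indels = if (length(gt_indels)) do.call(rbind, gt_indels) else NULL,
    gain_loss = gt_gainloss,
    omega = config$omega,
    unknown_gap = if (length(gt_unknown)) do.call(rbind, gt_unknown)
                  else NULL
  )

  structure(
    list(config = config, tree = tree, maps = maps, sequences = sequences,
         qualities = qualities, domains = domains,
         transcript_support = transcript_support,
         ground_truth = ground_truth, layout = layout),
    class = "sim_bundle"
  )
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf("<sim_bundle> %d species, %d genes, %d planted event(s)\n",
              length(x$maps), length(x$config$genes),
              length(x$config$events)))
  invisible(x)
}

#' Write a bundle to disk as standard formats
#'
#' Per species: a GFF3 gene map and a FASTA of coding sequences; for the
#' focal species additionally a FASTQ with qualities. Plus the Newick
#' tree, the domain TSV, ground truth as JSON, and a manifest with per-file
#' checksums and the configuration digest.
#'
#' @param bundle a `sim_bundle`.
#' @param out_dir output directory.
#' @param force overwrite a non-empty directory.
#' @return the manifest data frame, invisibly.
#' @export
emit_bundle <- function(bundle, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !force) {
    kc_stop("output directory %s is not empty (use force = TRUE)", out_dir)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (sp in names(bundle$maps)) {
    gff <- file.path(out_dir, paste0(sp, ".gff3"))
    write_gene_map(bundle$maps[[sp]], gff)
    fa <- file.path(out_dir, paste0(sp, ".fasta"))
    write_sequences(bundle$sequences[[sp]], fa)
    files <- c(files, gff, fa)
  }
  focal <- bundle$config$focal
  fq <- file.path(out_dir, paste0(focal, ".fastq"))
  qs <- bundle$sequences[[focal]]
  recs <- seq_set(names(qs),
                  vapply(qs, `[[`, character(1), "residues"),
                  bundle$qualities[names(qs)])
  write_sequences(recs, fq, format = "fastq")
  files <- c(files, fq)

  tr <- file.path(out_dir, "species_tree.nwk")
  ape::write.tree(bundle$tree, tr)
  dom <- file.path(out_dir, "domains.tsv")
  write.table(bundle$domains, dom, sep = "\t", quote = FALSE,
              row.names = FALSE)
  gt <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(bundle$ground_truth, gt, auto_unbox = TRUE,
                       digits = NA, null = "null")
  ts <- file.path(out_dir, "transcript_support.txt")
  writeLines(bundle$transcript_support, ts)
  files <- c(files, tr, dom, gt, ts)

  cfg_file <- file.path(out_dir, "config.txt")
  cfg <- bundle$config
  writeLines(c(
    sprintf("seed=%d", cfg$seed),
    sprintf("n_genes=%d", length(cfg$genes)),
    sprintf("n_codons=%d", cfg$n_codons),
    sprintf("kappa=%g", cfg$kappa),
    sprintf("focal=%s", cfg$focal),
    sprintf("tree=%s", cfg$tree_text)
  ), cfg_file)
  files <- c(files, cfg_file)

  manifest <- data.frame(
    file = basename(files),
    md5 = as.character(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  write.table(manifest, file.path(out_dir, "MANIFEST.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
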