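## Orchestration: search -> synteny classification -> presence/Dollo ->
## variants -> indels -> selection -> motifs -> expression summary.
## Logging goes to stderr (kc_log); machine outputs are returned/written
## separately. Exit codes for the CLI: 0 success, 2 validation error,
## 3 stage failure.

#' Load an emitted bundle directory back through the standard readers
#'
#' @param dir directory produced by [emit_bundle()].
#' @return a `sim_bundle`-shaped list (without ground truth unless present
#'   on disk).
#' @export
load_bundle <- function(dir) {
  kc_assert(dir.exists(dir), "bundle directory not found: %s", dir)
  cfg_lines <- readLines(file.path(dir, "config.txt"))
  cfg_get <- function(key) {
    hit <- grep(paste0("^", key, "="), cfg_lines, value = TRUE)
    sub(paste0("^", key, "="), "", hit[1])
  }
  focal <- cfg_get("focal")
  n_genes <- as.integer(cfg_get("n_genes"))
  gffs <- list.files(dir, pattern = "\\.gff3$", full.names = TRUE)
  maps <- list()
  sequences <- list()
  for (gff in gffs) {
    sp <- sub("\\.gff3$", "", basename(gff))
    maps[[sp]] <- read_gene_map(gff, sp)
    fa <- file.path(dir, paste0(sp, ".fasta"))
    sequences[[sp]] <- read_sequences(fa)
  }
  fq <- file.path(dir, paste0(focal, ".fastq"))
  qualities <- NULL
  if (file.exists(fq)) {
    qrecs <- read_sequences(fq)
    qualities <- lapply(qrecs, `[[`, "qualities")
    names(qualities) <- names(qrecs)
  }
  tree <- read_tree(file.path(dir, "species_tree.nwk"))
  dom_path <- file.path(dir, "domains.tsv")
  domains <- if (file.exists(dom_path)) read_domains(dom_path) else NULL
  ts_path <- file.path(dir, "transcript_support.txt")
  transcript_support <- if (file.exists(ts_path)) readLines(ts_path) else
    character(0)
  gt_path <- file.path(dir, "ground_truth.json")
  ground_truth <- if (file.exists(gt_path)) {
    jsonlite::fromJSON(gt_path, simplifyVector = TRUE)
  } else NULL
  structure(
    list(config = list(focal = focal, genes = paste0("KCG", seq_len(n_genes)),
                       sibling = "chicken", reference = "human",
                       outgroup = "lizard"),
         tree = tree, maps = maps, sequences = sequences,
         qualities = qualities, domains = domains,
         transcript_support = transcript_support,
         ground_truth = ground_truth),
    class = "sim_bundle"
  )
}

.degradation_marks <- function(locus_id, locus_res, parent_res,
                               transcript_support) {
  marks <- character(0)
  if (substr(locus_res, 1L, 3L) != "ATG") {
    marks <- c(marks, "missing_start_codon")
  }
  if (nchar(locus_res) < 0.8 * nchar(parent_res)) {
    marks <- c(marks, "truncated")
  }
  if (!(locus_id %in% transcript_support)) {
    marks <- c(marks, "no_transcript_support")
  }
  ## "no transcript support" alone never condemns a locus
  if (identical(marks, "no_transcript_support")) marks <- character(0)
  marks
}

## gap checker for presence calls: is there a gap feature in `map` lying
## between genes that flank `gene` in the carrier map?
.gap_window_checker <- function(carrier_map, k = 3L) {
  function(map, gene) {
    nb <- tryCatch(neighborhood(carrier_map, gene, k),
                   error = function(e) NULL)
    if (is.null(nb)) return(any(map$features$is_gap))
    flanks <- c(nb$upstream, nb$downstream)
    f <- map$features
    gaps <- f[f$is_gap, , drop = FALSE]
    if (nrow(gaps) == 0L) return(FALSE)
    for (r in seq_len(nrow(gaps))) {
      same_chrom <- f[!f$is_gap & f$chrom == gaps$chrom[r], , drop = FALSE]
      near <- same_chrom[abs(same_chrom$start - gaps$start[r]) <=
                           (k + 1L) * 20000L, , drop = FALSE]
      if (any(near$symbol %in% flanks)) return(TRUE)
    }
    FALSE
  }
}

#' Run the full curation pipeline on a bundle
#'
#' Stages (each skippable): secondary-locus search and classification,
#' presence/absence with Dollo reconciliation, allelic-variant calling,
#' indel survey, dN/dS selection screen with lineage assignment, motif
#' scanning, and (when a registry is supplied) the expression summary.
#' Deterministic given identical inputs.
#'
#' @param bundle a `sim_bundle` from [simulate_genomes()] or
#'   [load_bundle()].
#' @param registry optional `kc_registry` for the expression stage.
#' @param motif_patterns optional list of [compile_motif()] patterns.
#' @param discovery_identity identity threshold for the secondary-locus
#'   search (paralogs diverge well below the 95% allele rule, so discovery
#'   runs lower; default 60).
#' @param allele_identity allele rule threshold (default 95).
#' @param phred_min per-base quality threshold (default 50).
#' @param final_cutoff selection-screen cutoff (default 0.1).
#' @param skip character vector of stage names to skip
#'   (`search`, `presence`, `variants`, `indels`, `selection`, `motifs`).
#' @return a `pipeline_report` list with one element per stage plus
#'   `provenance` and `warnings`.
#' @export
run_pipeline <- function(bundle, registry = NULL, motif_patterns = NULL,
                         discovery_identity = 60, allele_identity = 95,
                         phred_min = 50, final_cutoff = 0.1,
                         skip = character(0)) {
  kc_assert(length(bundle$maps) > 0L && length(bundle$sequences) > 0L,
            "empty input set: no maps/sequences to analyze")
  cfg <- bundle$config
  focal <- cfg$focal
  sibling <- cfg$sibling %||% "chicken"
  reference <- cfg$reference %||% "human"
  outgroup <- cfg$outgroup %||% "lizard"
  genes <- cfg$genes
  kc_assert(focal %in% names(bundle$maps),
            "focal species '%s' missing from maps", focal)
  focal_seqs <- bundle$sequences[[focal]]
  focal_map <- bundle$maps[[focal]]
  warnings <- character(0)
  report <- list()

  run_stage <- function(name, fun) {
    if (name %in% skip) {
      kc_log("info", "stage %s: skipped", name)
      return(NULL)
    }
    kc_log("info", "stage %s: running", name)
    tryCatch(fun(), error = function(e) {
      kc_stop("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  ## ---- search + classification ----
  classifications <- run_stage("search", function() {
    comparators <- bundle$maps[setdiff(names(bundle$maps),
                                       c(focal, reference))]
    ## reference map per gene: the configured reference species unless its
    ## genome lost the gene, in which case the first comparator carrying it
    ## (the published workflow aligns to additional genomes in such cases)
    ref_map_for <- function(g) {
      ref <- bundle$maps[[reference]]
      if (any(ref$features$symbol == g & !ref$features$is_gap)) return(ref)
      for (cm in comparators) {
        if (any(cm$features$symbol == g & !cm$features$is_gap)) return(cm)
      }
      ref
    }
    out <- list()
    candidates <- list()  # best hit per secondary locus, by score
    for (g in genes) {
      if (is.null(focal_seqs[[g]])) next
      query <- focal_seqs[[g]]
      primary <- classify_locus(
        candidate = list(symbol = g, map = focal_map), parent = g,
        reference_map = ref_map_for(g),
        comparator_maps = comparators,
        alignment = NULL, degradation = character(0),
        allele_identity = allele_identity)
      out[[g]] <- data.frame(locus = g, parent = g, call = primary$call,
                             identity = NA_real_, placement =
                               primary$evidence$placement,
                             stringsAsFactors = FALSE)
      hits <- find_secondary_loci(query, focal_seqs,
                                  min_identity = discovery_identity,
                                  exclude = g, k = 13L,
                                  min_coverage = 0.25)
      for (h in seq_len(nrow(hits))) {
        locus <- hits$locus[h]
        if (locus %in% genes) next  # other family members, not copies
        prev <- candidates[[locus]]
        if (is.null(prev) || hits$score[h] > prev$score) {
          candidates[[locus]] <- list(parent = g, score = hits$score[h],
                                      identity = hits$identity[h],
                                      alignment = hits$alignment[[h]])
        }
      }
    }
    for (locus in names(candidates)) {
      cand <- candidates[[locus]]
      g <- cand$parent
      locus_res <- focal_seqs[[locus]]$residues
      degradation <- .degradation_marks(locus, locus_res,
                                        focal_seqs[[g]]$residues,
                                        bundle$transcript_support)
      cl <- classify_locus(
        candidate = list(symbol = locus, map = focal_map), parent = g,
        reference_map = ref_map_for(g),
        comparator_maps = comparators,
        alignment = cand$alignment, degradation = degradation,
        allele_identity = allele_identity)
      out[[paste(g, locus)]] <- data.frame(
        locus = locus, parent = g, call = cl$call,
        identity = cand$identity,
        placement = cl$evidence$placement, stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, out)
    tab <- tab[order(tab$locus), , drop = FALSE]
    rownames(tab) <- NULL
    tab
  })

  ## ---- presence matrix + Dollo ----
  events <- run_stage("presence", function() {
    copies <- if (!is.null(classifications)) {
      classifications$locus[classifications$call == "duplication"]
    } else character(0)
    rows <- c(genes, copies)
    pm <- build_presence_matrix(rows, bundle$maps,
                                gap_windows = .gap_window_checker(focal_map))
    evs <- list()
    for (g in rows) {
      profile <- setNames(pm[g, ], colnames(pm))
      if (all(profile != "present")) next
      if (all(profile == "present")) next
      evs[[g]] <- dollo_reconcile(profile, bundle$tree)
    }
    list(presence = pm, gain_loss = evs)
  })

  ## ---- allelic variants ----
  variants <- run_stage("variants", function() {
    out <- list()
    if (is.null(classifications)) return(NULL)
    alleles <- classifications[classifications$call == "allele", ,
                               drop = FALSE]
    for (i in seq_len(nrow(alleles))) {
      g <- alleles$parent[i]
      locus <- alleles$locus[i]
      aln <- align_local(focal_seqs[[g]], focal_seqs[[locus]])
      res <- call_allelic_variants(
        primary_id = g, primary_cds = focal_seqs[[g]]$residues,
        hit = list(alignment = aln, placement = alleles$placement[i]),
        qualities = list(primary = bundle$qualities[[g]],
                         secondary = bundle$qualities[[locus]]),
        domains = bundle$domains, min_identity = allele_identity,
        phred_min = phred_min)
      out[[locus]] <- c(res, list(locus = locus, parent = g))
    }
    out
  })

  ## ---- indel survey ----
  indels <- run_stage("indels", function() {
    out <- list()
    sib_seqs <- bundle$sequences[[sibling]]
    for (g in genes) {
      if (is.null(focal_seqs[[g]]) || is.null(sib_seqs[[g]])) next
      caln <- align_codons(
        ids = c(sibling, focal),
        cds = c(sib_seqs[[g]]$residues, focal_seqs[[g]]$residues),
        qualities = list(NULL, bundle$qualities[[g]]),
        phred_min = phred_min)
      recs <- detect_indels(caln, domains = bundle$domains,
                            species = c(sibling, focal), protein_id = g)
      if (nrow(recs)) {
        recs$gene <- g
        out[[g]] <- recs
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  })

  ## ---- selection screen ----
  selection <- run_stage("selection", function() {
    sib_seqs <- bundle$sequences[[sibling]]
    ratios <- setNames(rep(NA_real_, length(genes)), genes)
    for (g in genes) {
      if (is.null(focal_seqs[[g]]) || is.null(sib_seqs[[g]])) next
      caln <- align_codons(
        ids = c(focal, sibling),
        cds = c(focal_seqs[[g]]$residues, sib_seqs[[g]]$residues),
        qualities = list(bundle$qualities[[g]], NULL),
        phred_min = phred_min)
      est <- estimate_dnds(caln)
      ratios[[g]] <- if (is.numeric(est$ratio)) est$ratio else NA_real_
    }
    usable <- ratios[!is.na(ratios)]
    flags <- flag_high_dnds(usable, final_cutoff = final_cutoff)
    lineage <- list()
    out_seqs <- bundle$sequences[[outgroup]]
    for (g in flags$final_set) {
      if (is.null(out_seqs[[g]])) next
      r_f <- estimate_dnds(align_codons(c(focal, outgroup),
                                        c(focal_seqs[[g]]$residues,
                                          out_seqs[[g]]$residues)))
      sib <- bundle$sequences[[sibling]][[g]]
      if (is.null(sib)) next
      r_c <- estimate_dnds(align_codons(c(sibling, outgroup),
                                        c(sib$residues,
                                          out_seqs[[g]]$residues)))
      lineage[[g]] <- assign_lineage(
        g,
        if (is.numeric(r_f$ratio)) r_f$ratio else NA_real_,
        if (is.numeric(r_c$ratio)) r_c$ratio else NA_real_,
        cutoff = final_cutoff)
    }
    list(ratios = ratios, flags = flags, lineage = lineage)
  })

  ## ---- motifs ----
  motifs <- run_stage("motifs", function() {
    if (is.null(motif_patterns)) return(NULL)
    out <- list()
    for (g in genes) {
      if (is.null(focal_seqs[[g]])) next
      cds <- focal_seqs[[g]]$residues
      prot <- paste(vapply(seq(1L, nchar(cds) - 2L, 3L), function(p) {
        aa <- translate_codon(substr(cds, p, p + 2L))
        if (is.na(aa) || aa == "*") "X" else aa
      }, character(1)), collapse = "")
      out[[g]] <- scan_motifs(list(id = g, residues = prot), motif_patterns)
    }
    out
  })

  ## ---- expression ----
  expression <- run_stage("expression", function() {
    if (is.null(registry)) return(NULL)
    summarize_song_system(registry)
  })

  structure(
    list(classifications = classifications, events = events,
         variants = variants, indels = indels, selection = selection,
         motifs = motifs, expression = expression,
         provenance = list(
           focal = focal, sibling = sibling, reference = reference,
           outgroup = outgroup,
           seed = cfg$seed %||% NA_integer_,
           package_version = as.character(utils::packageVersion("kccomp"))),
         warnings = warnings),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  if (!is.null(x$classifications)) {
    cat(sprintf("  classifications: %d locus call(s) (%s)\n",
                nrow(x$classifications),
                paste(sprintf("%s=%d",
                              names(table(x$classifications$call)),
                              table(x$classifications$call)),
                      collapse = ", ")))
  }
  if (!is.null(x$events)) {
    cat(sprintf("  gain/loss: %d reconciled profile(s)\n",
                length(x$events$gain_loss)))
  }
  if (!is.null(x$selection)) {
    cat(sprintf("  selection: %d gene(s) above cutoff %.2f\n",
                length(x$selection$flags$final_set),
                x$selection$flags$final_cutoff))
  }
  if (!is.null(x$expression)) print(x$expression)
  invisible(x)
}
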