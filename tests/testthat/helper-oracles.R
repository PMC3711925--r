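# Independent oracles. These deliberately re-derive results through
# different code paths (plain-R full-matrix DP, a genetic-code walk over
# Biostrings' table, a post-order DP for Dollo) and never call the package
# implementation they check.

# ---- affine-gap DP scores (gap of length L costs open + L * ext) --------

oracle_align_score <- function(s1, s2, submat, gap_open, gap_ext,
                               local = TRUE) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -Inf
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  if (!local) {
    for (j in seq_len(m)) {
      E[1, j + 1] <- -(gap_open + j * gap_ext)
      H[1, j + 1] <- E[1, j + 1]
    }
    for (i in seq_len(n)) {
      F[i + 1, 1] <- -(gap_open + i * gap_ext)
      H[i + 1, 1] <- F[i + 1, 1]
    }
  }
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - gap_open - gap_ext,
                             E[i + 1, j] - gap_ext)
      F[i + 1, j + 1] <- max(H[i, j + 1] - gap_open - gap_ext,
                             F[i, j + 1] - gap_ext)
      h <- max(H[i, j] + submat[a[i], b[j]],
               E[i + 1, j + 1], F[i + 1, j + 1])
      if (local) h <- max(h, 0)
      H[i + 1, j + 1] <- h
      if (local && h > best) best <- h
    }
  }
  if (local) best else H[n + 1, m + 1]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# ---- NG86 site counts by an independent genetic-code walk ---------------

oracle_ng86_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  aa <- gc[[codon]]
  s_total <- 0
  for (pos in 1:3) {
    syn <- 0L
    nonstop <- 0L
    for (nt in nts) {
      if (substr(codon, pos, pos) == nt) next
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (gc[[mut]] == "*") next
      nonstop <- nonstop + 1L
      if (gc[[mut]] == aa) syn <- syn + 1L
    }
    if (nonstop > 0L) s_total <- s_total + syn / nonstop
  }
  c(n_sites = 3 - s_total, s_sites = s_total)
}

# ---- Dollo minimal-loss search by post-order DP --------------------------

# For a fixed gain node: classify every node below it as has-present /
# absent-only / unknown-only by post-order aggregation, and count edges
# from a present-side parent into absent-only subtrees.
oracle_dollo <- function(profile, tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  kids <- function(nd) tree$edge[tree$edge[, 1] == nd, 2]
  state <- function(nd) {
    if (nd <= n_tip) {
      v <- profile[[tree$tip.label[nd]]]
      return(switch(v, present = "P", absent = "A", unknown_gap = "U"))
    }
    st <- vapply(kids(nd), state, character(1))
    if (any(st == "P")) "P" else if (any(st == "A")) "A" else "U"
  }
  leaves_below <- function(nd) {
    if (nd <= n_tip) return(tree$tip.label[nd])
    unlist(lapply(kids(nd), leaves_below))
  }
  losses_under <- function(gain) {
    count <- 0L
    walk <- function(nd) {
      for (ch in kids(nd)) {
        st <- state(ch)
        if (st == "A") count <<- count + 1L
        else if (st == "P") walk(ch)
        # unknown-only: unconstrained, no loss
      }
    }
    walk(gain)
    count
  }
  present <- names(profile)[profile == "present"]
  best <- NULL
  preorder <- function(nd) c(nd, unlist(lapply(kids(nd), preorder)))
  for (nd in preorder(root)) {
    if (!all(present %in% leaves_below(nd))) next
    nl <- losses_under(nd)
    depth <- 0L; cur <- nd
    while (cur != root) {
      cur <- tree$edge[tree$edge[, 2] == cur, 1]
      depth <- depth + 1L
    }
    if (is.null(best) || nl < best$n ||
        (nl == best$n && depth < best$depth)) {
      best <- list(node = nd, n = nl, depth = depth)
    }
  }
  best
}

random_profile_tree <- function(n_leaves) {
  tree <- ape::rtree(n_leaves, tip.label = paste0("sp", seq_len(n_leaves)))
  vals <- sample(c("present", "absent", "unknown_gap"), n_leaves,
                 replace = TRUE, prob = c(0.5, 0.35, 0.15))
  if (!any(vals == "present")) vals[sample(n_leaves, 1)] <- "present"
  list(tree = tree, profile = setNames(vals, tree$tip.label))
}
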