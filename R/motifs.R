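## PROSITE-style motif compilation and fingerprint-fraction scanning.
## Motif presence is an exact pattern match (no mismatch tolerance); family
## fingerprints are reported as "k/n motifs present".

#' Compile a PROSITE-style pattern
#'
#' Supported grammar, elements separated by `-`: residue literals (`G`),
#' alternations (`[ST]`), exclusions (`{P}`), wildcards `x`, and counted
#' wildcards `x(2)` or `x(2,4)`. Patterns compile to a finite-length
#' regular expression matcher.
#'
#' @param pattern pattern text, e.g. `"[ST]-x(2)-D"`.
#' @param id,family optional labels carried on the matcher.
#' @return a `motif_pattern` object.
#' @examples
#' compile_motif("G-Y-G")        # the K-channel selectivity-filter literal
#' compile_motif("[ST]-x(2)-D")
#' @export
compile_motif <- function(pattern, id = pattern, family = NA_character_) {
  kc_assert(is.character(pattern) && length(pattern) == 1L &&
              nzchar(trim_ws(pattern)), "empty motif pattern")
  elements <- strsplit(trim_ws(pattern), "-", fixed = TRUE)[[1]]
  rx <- character(length(elements))
  for (i in seq_along(elements)) {
    el <- trim_ws(elements[i])
    if (grepl("^[A-WYZ]$", el) || el == "X") {
      rx[i] <- if (el == "X") "." else el
    } else if (grepl("^x$", el)) {
      rx[i] <- "."
    } else if (grepl("^x\\(([0-9]+)(,([0-9]+))?\\)$", el)) {
      m <- regexec("^x\\(([0-9]+)(,([0-9]+))?\\)$", el)
      parts <- regmatches(el, m)[[1]]
      lo <- parts[2]
      hi <- parts[4]
      rx[i] <- if (nzchar(hi)) sprintf(".{%s,%s}", lo, hi)
               else sprintf(".{%s}", lo)
    } else if (grepl("^\\[[A-Z]+\\]$", el)) {
      rx[i] <- el
    } else if (grepl("^\\{[A-Z]+\\}$", el)) {
      rx[i] <- sprintf("[^%s]", substr(el, 2L, nchar(el) - 1L))
    } else {
      kc_stop("motif parse error at element '%s' of pattern '%s'",
              el, pattern)
    }
  }
  structure(
    list(id = id, family = family, pattern = pattern,
         regex = paste(rx, collapse = "")),
    class = "motif_pattern"
  )
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s: %s -> /%s/\n", x$id, x$pattern, x$regex))
  invisible(x)
}

#' Read a motif set from TSV (columns id, family, pattern)
#' @param path TSV file.
#' @return list of `motif_pattern`s.
#' @export
read_motifs <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
  kc_assert(all(c("id", "family", "pattern") %in% names(tab)),
            "motif table needs columns id, family, pattern")
  lapply(seq_len(nrow(tab)), function(i) {
    compile_motif(tab$pattern[i], id = tab$id[i], family = tab$family[i])
  })
}

#' Scan a protein for a motif set
#'
#' Each motif is marked present at its leftmost exact match; the fingerprint
#' fraction is (motifs present) / (motifs in set).
#'
#' @param protein a sequence record or plain string.
#' @param patterns list of [compile_motif()] results.
#' @param family optional family label for the result (defaults to the
#'   first pattern's).
#' @return a `fingerprint_result`: `hits` data frame (id, present,
#'   position), `k`, `n`, and `fraction` rendered "k/n".
#' @export
scan_motifs <- function(protein, patterns, family = NULL) {
  rec <- .as_record(protein)
  kc_assert(nzchar(rec$residues), "empty protein sequence")
  if (length(patterns) == 0L) {
    return(structure(list(protein = rec$id, family = family %||% NA_character_,
                          hits = data.frame(id = character(0),
                                            present = logical(0),
                                            position = integer(0)),
                          k = 0L, n = 0L, fraction = "0/0"),
                     class = "fingerprint_result"))
  }
  hits <- data.frame(
    id = vapply(patterns, `[[`, character(1), "id"),
    present = FALSE, position = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(patterns)) {
    m <- regexpr(patterns[[i]]$regex, rec$residues, perl = TRUE)
    if (m[1] != -1L) {
      hits$present[i] <- TRUE
      hits$position[i] <- as.integer(m[1])
    }
  }
  k <- sum(hits$present)
  n <- nrow(hits)
  structure(
    list(protein = rec$id,
         family = family %||% patterns[[1]]$family,
         hits = hits, k = k, n = n,
         fraction = sprintf("%d/%d", k, n)),
    class = "fingerprint_result"
  )
}

#' @export
print.fingerprint_result <- function(x, ...) {
  cat(sprintf("<fingerprint_result> %s vs %s: %s motifs present\n",
              x$protein, x$family, x$fraction))
  invisible(x)
}
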