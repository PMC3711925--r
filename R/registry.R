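## Curated K-channel gene registry: data model for the published gene table
## plus the missing-gene survey, and the counting/reconciliation operations
## that reproduce the headline totals.

KC_SUBFAMILIES <- c(
  "KCNA", "KCNAB", "KCNB", "KCNF", "KCNG", "KCNS", "KCNV", "KCNC", "KCND",
  "KCNIP", "KCNH", "KCNE", "KCNQ", "KCNMA", "KCNMB", "KCNN", "KCNT", "KCNJ",
  "KCNK", "HCN", "KCTD"
)

KC_MODEL_STATUS <- c("complete", "partial", "none")
KC_ORTHOLOG_CLASS <- c("one_to_one_human", "novel_non_human", "pseudogene")
KC_NOVELTY_FLAGS <- c("none", "delta", "hash", "dollar")
KC_VARIANT_CODES <- c("S", "C", "NC", "I", "D")
KC_MISSING_CATEGORIES <- c(
  "human_pseudogene", "missing_in_finch", "missing_in_birds",
  "missing_in_sauropsids", "missing_in_tetrapods_or_mammal_specific"
)

REGISTRY_COLUMNS <- c(
  "symbol", "subfamily", "model_ids", "model_status", "ortholog_class",
  "novelty_flag", "chicken_ortholog", "dnds", "dnds_note", "dnds_flagged",
  "variant_codes", "hvc", "lman", "ra", "x", "clone"
)

#' Path to a fixture shipped with the package
#' @param file file name under `extdata`; default lists available fixtures.
#' @export
kc_fixture <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "kccomp")))
  }
  path <- system.file("extdata", file, package = "kccomp")
  kc_assert(nzchar(path), "no packaged fixture named '%s'", file)
  path
}

.parse_clone <- function(clone) {
  clone <- trim_ws(clone)
  if (clone %in% c("No clone", "No clone∑")) {
    list(id = NA_character_, status = "no_clone")
  } else if (grepl("†$", clone)) {
    list(id = sub("†$", "", clone), status = "untested")
  } else {
    kc_assert(grepl("^[A-Z]{2}[0-9]+$", clone),
              "unrecognized clone field: '%s'", clone)
    list(id = clone, status = "tested")
  }
}

.parse_dnds <- function(raw) {
  raw <- trim_ws(raw)
  if (raw %in% c("N/A", "NA", "")) {
    list(value = NA_real_, qualifier = "not_available")
  } else if (raw %in% c("<0.01", "< 0.01")) {
    list(value = NA_real_, qualifier = "lt_0_01")
  } else {
    val <- suppressWarnings(as.numeric(raw))
    kc_assert(!is.na(val) && val >= 0, "malformed dN/dS value: '%s'", raw)
    list(value = val, qualifier = "none")
  }
}

#' Load the curated gene registry from its TSV dialect
#'
#' The dialect is UTF-8, tab-separated, one header row, with columns
#' `symbol, subfamily, model_ids, model_status, ortholog_class, novelty_flag,
#' chicken_ortholog, dnds, dnds_note, dnds_flagged, variant_codes,
#' hvc, lman, ra, x, clone`. Expression cells carry the printed tokens
#' (`"+++ (↑↑)"`, `"o"`, `"N.D."`, `"NS"`); `dnds` is a number, `"<0.01"`
#' or `"N/A"`; `clone` is an accession, `accession†` (clone exists but was
#' not scored), or `"No clone"`.
#'
#' @param path TSV file; defaults to the packaged table.
#' @return a `kc_registry` data frame, one row per validated gene record,
#'   with parsed columns (`dnds_value`, `dnds_qualifier`, list-columns
#'   `model_ids` and `variant_codes`, `expression` profiles, `clone_id`,
#'   `clone_status`) alongside the raw dialect columns.
#' @export
load_registry <- function(path = kc_fixture("table1_registry.tsv")) {
  kc_assert(file.exists(path), "registry file not found: %s", path)
  tab <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    colClasses = "character", check.names = FALSE,
                    quote = "", fileEncoding = "UTF-8")
  missing_cols <- setdiff(REGISTRY_COLUMNS, names(tab))
  kc_assert(length(missing_cols) == 0L,
            "registry header lacks column(s): %s",
            paste(missing_cols, collapse = ", "))
  tab <- tab[REGISTRY_COLUMNS]
  if (nrow(tab) == 0L) {
    out <- tab
    out$expression <- list()
    class(out) <- c("kc_registry", class(out))
    return(out)
  }

  dup <- tab$symbol[duplicated(tab$symbol)]
  kc_assert(length(dup) == 0L, "duplicate symbol(s) in registry: %s",
            paste(unique(dup), collapse = ", "))

  check_enum <- function(col, allowed) {
    bad <- which(!(tab[[col]] %in% allowed))
    if (length(bad)) {
      kc_stop("row %d, column '%s': invalid value '%s'",
              bad[1], col, tab[[col]][bad[1]])
    }
  }
  check_enum("subfamily", KC_SUBFAMILIES)
  check_enum("model_status", KC_MODEL_STATUS)
  check_enum("ortholog_class", KC_ORTHOLOG_CLASS)
  check_enum("novelty_flag", KC_NOVELTY_FLAGS)
  check_enum("dnds_flagged", c("TRUE", "FALSE"))

  parsed_dnds <- lapply(tab$dnds, .parse_dnds)
  parsed_clone <- lapply(tab$clone, .parse_clone)
  variant_codes <- split_list_field(tab$variant_codes)
  for (i in seq_along(variant_codes)) {
    bad <- setdiff(variant_codes[[i]], KC_VARIANT_CODES)
    if (length(bad)) {
      kc_stop("row %d, column 'variant_codes': unknown code '%s'", i, bad[1])
    }
  }
  expression <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    expression[[i]] <- tryCatch(
      expression_profile(tab$hvc[i], tab$lman[i], tab$ra[i], tab$x[i]),
      error = function(e) kc_stop("row %d (%s): %s", i, tab$symbol[i],
                                  conditionMessage(e))
    )
  }

  out <- tab
  out$model_ids <- split_list_field(tab$model_ids)
  out$variant_codes <- variant_codes
  out$dnds_value <- vapply(parsed_dnds, `[[`, numeric(1), "value")
  out$dnds_qualifier <- vapply(parsed_dnds, `[[`, character(1), "qualifier")
  out$dnds_flagged <- as.logical(tab$dnds_flagged)
  out$clone_id <- vapply(parsed_clone, `[[`, character(1), "id")
  out$clone_status <- vapply(parsed_clone, `[[`, character(1), "status")
  out$expression <- expression

  ## invariants
  bad <- out$dnds_flagged &
    !(out$dnds_qualifier == "none" & !is.na(out$dnds_value) &
        out$dnds_value > 0.1)
  kc_assert(!any(bad),
            "dnds_flagged requires a numeric ratio > 0.1 (rows: %s)",
            paste(which(bad), collapse = ", "))
  is_novel <- out$ortholog_class == "novel_non_human"
  is_delta <- out$novelty_flag == "delta"
  kc_assert(all(is_novel == is_delta),
            "novel_non_human class and delta flag must coincide (rows: %s)",
            paste(which(is_novel != is_delta), collapse = ", "))

  class(out) <- c("kc_registry", class(out))
  out
}

#' Serialize a registry back to the TSV dialect
#'
#' Writes the raw dialect columns; `load_registry(write_registry(x))` is
#' byte-identical to the input up to column order.
#' @param registry a `kc_registry`.
#' @param path output file.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "kc_registry"))
  raw <- as.data.frame(registry)[REGISTRY_COLUMNS]
  raw$model_ids <- join_list_field(registry$model_ids)
  raw$variant_codes <- join_list_field(registry$variant_codes)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(raw, con, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Load the missing-gene survey fixture
#'
#' @param path TSV with columns `symbol`, `category`; defaults to the
#'   packaged fixture.
#' @return data frame of missing-gene records; categories partition the set.
#' @export
load_missing_genes <- function(path = kc_fixture("missing_genes.tsv")) {
  tab <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    colClasses = "character", fileEncoding = "UTF-8")
  kc_assert(all(c("symbol", "category") %in% names(tab)),
            "missing-gene table needs columns symbol, category")
  bad <- setdiff(tab$category, KC_MISSING_CATEGORIES)
  kc_assert(length(bad) == 0L, "unknown missing-gene category: %s", bad[1])
  kc_assert(!anyDuplicated(tab$symbol), "duplicate missing-gene symbol")
  tab
}

## ---- declarative predicates ---------------------------------------------

#' Declarative registry predicates
#'
#' `kc_pred(field, relation, value)` builds an atomic predicate on a registry
#' field; combine with `kc_and()` / `kc_or()`. Supported relations:
#' `eq`, `ne`, `gt`, `ge`, `lt`, `le`, `in`, `contains` (for list-columns
#' such as `variant_codes`). Predicates on `dnds` apply to the numeric value;
#' records with qualifier `"<0.01"` are treated as numeric 0.005 only when
#' `coerce_qualifiers = TRUE` is passed to [count_by_predicate()], otherwise
#' they (and `N/A`) never satisfy a numeric relation.
#'
#' @param field registry column name (parsed names allowed, e.g. `dnds`).
#' @param relation relation name.
#' @param value comparison value.
#' @return a `kc_predicate` object.
#' @export
kc_pred <- function(field, relation = "eq", value = NULL) {
  structure(list(kind = "atom", field = field, relation = relation,
                 value = value),
            class = "kc_predicate")
}

#' @rdname kc_pred
#' @param ... predicates to combine.
#' @export
kc_and <- function(...) {
  structure(list(kind = "and", parts = list(...)), class = "kc_predicate")
}

#' @rdname kc_pred
#' @export
kc_or <- function(...) {
  structure(list(kind = "or", parts = list(...)), class = "kc_predicate")
}

#' @rdname kc_pred
#' @export
kc_false <- function() {
  structure(list(kind = "false"), class = "kc_predicate")
}

.eval_predicate <- function(pred, registry, coerce_qualifiers = FALSE) {
  n <- nrow(registry)
  if (pred$kind == "false") return(rep(FALSE, n))
  if (pred$kind == "and") {
    return(Reduce(`&`, lapply(pred$parts, .eval_predicate, registry,
                              coerce_qualifiers)))
  }
  if (pred$kind == "or") {
    return(Reduce(`|`, lapply(pred$parts, .eval_predicate, registry,
                              coerce_qualifiers)))
  }
  field <- pred$field
  if (field == "dnds") {
    vals <- registry$dnds_value
    if (coerce_qualifiers) {
      vals[registry$dnds_qualifier == "lt_0_01"] <- 0.005
    }
  } else {
    kc_assert(field %in% names(registry), "unknown field name: '%s'", field)
    vals <- registry[[field]]
  }
  rel <- pred$relation
  value <- pred$value
  out <- switch(
    rel,
    eq = vals == value,
    ne = vals != value,
    gt = vals > value,
    ge = vals >= value,
    lt = vals < value,
    le = vals <= value,
    `in` = vals %in% value,
    contains = vapply(vals, function(v) value %in% v, logical(1)),
    kc_stop("unknown relation: '%s'", rel)
  )
  out[is.na(out)] <- FALSE
  out
}

#' Count registry records matching a predicate
#'
#' @param registry a `kc_registry`.
#' @param predicate a [kc_pred()] (possibly composed).
#' @param coerce_qualifiers treat `"<0.01"` dN/dS entries as 0.005.
#' @return integer count.
#' @examples
#' reg <- load_registry()
#' count_by_predicate(reg, kc_pred("ortholog_class", "eq", "one_to_one_human"))
#' count_by_predicate(reg, kc_pred("dnds", "gt", 0.1))
#' @export
count_by_predicate <- function(registry, predicate, coerce_qualifiers = FALSE) {
  stopifnot(inherits(registry, "kc_registry"),
            inherits(predicate, "kc_predicate"))
  sum(.eval_predicate(predicate, registry, coerce_qualifiers))
}

#' Reconcile the finch registry against the human missing-gene survey
#'
#' Checks the arithmetic identities linking the finch catalog to the human
#' start set: `finch_total = one_to_one + novel_non_human` and
#' `human_start = one_to_one + nrow(missing)`. Violations are report
#' content, not errors.
#'
#' @param registry a `kc_registry`.
#' @param missing data frame from [load_missing_genes()].
#' @return a `kc_reconciliation` list of totals, per-category missing counts
#'   and a character vector `violations`.
#' @export
reconcile_annotations <- function(registry, missing) {
  stopifnot(inherits(registry, "kc_registry"))
  finch_total <- nrow(registry)
  one_to_one <- sum(registry$ortholog_class == "one_to_one_human")
  novel <- sum(registry$ortholog_class == "novel_non_human")
  missing_total <- nrow(missing)
  category_counts <- table(factor(missing$category,
                                  levels = KC_MISSING_CATEGORIES))
  human_start <- one_to_one + missing_total

  violations <- character(0)
  if (finch_total != one_to_one + novel) {
    violations <- c(violations, sprintf(
      "finch_total (%d) != one_to_one (%d) + novel_non_human (%d)",
      finch_total, one_to_one, novel))
  }
  overlap <- intersect(registry$symbol, missing$symbol)
  if (length(overlap)) {
    violations <- c(violations, sprintf(
      "symbols in both registry and missing set: %s",
      paste(overlap, collapse = ", ")))
  }
  structure(
    list(
      finch_total = finch_total,
      one_to_one = one_to_one,
      novel_non_human = novel,
      missing_total = missing_total,
      missing_by_category = as.integer(category_counts),
      missing_categories = names(category_counts),
      human_start = human_start,
      violations = violations
    ),
    class = "kc_reconciliation"
  )
}

#' @export
print.kc_reconciliation <- function(x, ...) {
  cat("Gene-family reconciliation\n")
  cat(sprintf("  finch total:        %d = %d one-to-one + %d novel\n",
              x$finch_total, x$one_to_one, x$novel_non_human))
  cat(sprintf("  human start set:    %d = %d one-to-one + %d missing\n",
              x$human_start, x$one_to_one, x$missing_total))
  if (length(x$violations)) {
    cat("  VIOLATIONS:\n")
    for (v in x$violations) cat("   -", v, "\n")
  } else {
    cat("  identities hold\n")
  }
  invisible(x)
}

#' @export
print.kc_registry <- function(x, ...) {
  cat(sprintf("<kc_registry> %d gene records, %d subfamilies\n",
              nrow(x), length(unique(x$subfamily))))
  invisible(x)
}
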