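## Semi-quantitative in situ expression scoring for song-system nuclei.
##
## Levels follow the o / + / ++ / +++ scale (0-3); enrichment relative to the
## surrounding brain subdivision is scored with one or two up- or down-arrows
## mapped to directions -2..+2. A nucleus is "differential" iff its direction
## is non-zero; a cell like "o (↓)" is differential-by-absence: it counts
## toward marker calls but not toward "expressed".

SONG_NUCLEI <- c("hvc", "lman", "ra", "x")
AFP_NUCLEI <- c("lman", "x")   # anterior forebrain pathway
DMP_NUCLEI <- c("hvc", "ra")   # direct motor pathway

.level_map <- c("o" = 0L, "+" = 1L, "++" = 2L, "+++" = 3L)
.dir_map <- c(
  "↓↓" = -2L, "↓" = -1L,
  "↑" = 1L, "↑↑" = 2L
)

#' Parse one expression-table cell
#'
#' Grammar: a level token (`o`, `+`, `++`, `+++`) optionally followed by a
#' parenthesized arrow token (one or two `↑`/`↓`), or the row
#' markers `N.D.` (not determined) and `NS` (no signal detected).
#'
#' @param token cell text, e.g. `"+++ (↑↑)"`.
#' @return a list with `status` (`"scored"`, `"not_determined"`,
#'   `"no_signal"`), and for scored cells integer `level` (0-3) and
#'   `direction` (-2..2).
#' @examples
#' parse_expression_cell("+++ (↑↑)") # level 3, direction +2
#' parse_expression_cell("o (↓)")         # level 0, direction -1
#' @export
parse_expression_cell <- function(token) {
  kc_assert(is.character(token) && length(token) == 1L,
            "expression token must be a single string")
  tok <- trim_ws(token)
  if (tok %in% c("N.D.", "ND", "N.D")) {
    return(list(status = "not_determined", level = NA_integer_,
                direction = NA_integer_))
  }
  if (tok %in% c("NS", "No signal Detected")) {
    return(list(status = "no_signal", level = NA_integer_,
                direction = NA_integer_))
  }
  m <- regexec("^(o|\\+{1,3})(?:\\s*\\((↑{1,2}|↓{1,2})\\))?$", tok)
  parts <- regmatches(tok, m)[[1]]
  if (length(parts) == 0L) {
    kc_stop("unknown expression token: '%s'", token)
  }
  level <- .level_map[[parts[2]]]
  direction <- if (nzchar(parts[3])) .dir_map[[parts[3]]] else 0L
  list(status = "scored", level = level, direction = direction)
}

.render_cell <- function(status, level, direction) {
  if (status == "not_determined") return("N.D.")
  if (status == "no_signal") return("NS")
  lev <- names(.level_map)[match(level, .level_map)]
  if (direction == 0L) return(lev)
  arrow <- names(.dir_map)[match(direction, .dir_map)]
  paste0(lev, " (", arrow, ")")
}

#' Build an expression profile from four nucleus tokens
#'
#' @param hvc,lman,ra,x cell tokens as printed in the registry table.
#' @return an `expression_profile` list: `status` plus per-nucleus
#'   `level` and `direction` integer vectors (named hvc/lman/ra/x).
#' @export
expression_profile <- function(hvc, lman, ra, x) {
  cells <- lapply(c(hvc = hvc, lman = lman, ra = ra, x = x),
                  parse_expression_cell)
  statuses <- vapply(cells, `[[`, character(1), "status")
  status <- if (all(statuses == "not_determined")) {
    "not_determined"
  } else if (all(statuses == "no_signal")) {
    "no_signal"
  } else if (all(statuses == "scored")) {
    "scored"
  } else {
    kc_stop("inconsistent expression row: mixed cell statuses [%s]",
            paste(statuses, collapse = ", "))
  }
  structure(
    list(
      status = status,
      level = vapply(cells, `[[`, integer(1), "level"),
      direction = vapply(cells, `[[`, integer(1), "direction")
    ),
    class = "expression_profile"
  )
}

#' @export
format.expression_profile <- function(x, ...) {
  if (x$status != "scored") return(toupper(x$status))
  paste(mapply(.render_cell, "scored", x$level, x$direction),
        collapse = " | ")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat("<expression_profile>", format(x), "\n")
  invisible(x)
}

#' Call pathway markers from a scored profile
#'
#' A nucleus is differential iff its arrow direction is non-zero. A gene is a
#' marker of the anterior forebrain pathway (AFP = LMAN, Area X) or the
#' direct motor pathway (DMP = HVC, RA) iff it is differential in at least
#' one member nucleus.
#'
#' @param profile an [expression_profile()].
#' @param pathways named list of nucleus sets; defaults to AFP/DMP.
#' @return list with `differential` (named logical per nucleus) and
#'   `markers` (named logical per pathway). Unscored profiles yield empty
#'   calls.
#' @export
call_markers <- function(profile,
                         pathways = list(AFP = AFP_NUCLEI, DMP = DMP_NUCLEI)) {
  stopifnot(inherits(profile, "expression_profile"))
  if (profile$status != "scored") {
    return(list(differential = setNames(logical(0), character(0)),
                markers = setNames(logical(0), character(0))))
  }
  differential <- profile$direction != 0L
  markers <- vapply(pathways, function(nuclei) any(differential[nuclei]),
                    logical(1))
  list(differential = differential, markers = markers)
}

#' Summarize song-system expression over a registry
#'
#' Reproduces the curated bookkeeping: `probed` counts genes with a tested
#' clone and a determined outcome; `brain_expressed` counts scored genes;
#' `song_system_expressed` counts scored genes with level >= 1 in at least
#' one of the four nuclei; `afp_markers`/`dmp_markers` count genes
#' differential in at least one pathway nucleus (deduplicated per gene;
#' membership uses "scored", so differential-by-absence rows count).
#'
#' @param registry a `kc_registry` from [load_registry()].
#' @return a `song_summary` list of counts plus per-category symbol lists.
#' @export
summarize_song_system <- function(registry) {
  stopifnot(inherits(registry, "kc_registry"))
  profs <- registry$expression
  status <- vapply(profs, `[[`, character(1), "status")
  tested_clone <- registry$clone_status == "tested"
  probed <- tested_clone & status != "not_determined"
  scored <- probed & status == "scored"
  expressed <- scored & vapply(profs, function(p) {
    p$status == "scored" && any(p$level >= 1L)
  }, logical(1))
  calls <- lapply(profs, call_markers)
  afp <- scored & vapply(calls, function(cl) isTRUE(cl$markers["AFP"][[1]]),
                         logical(1))
  dmp <- scored & vapply(calls, function(cl) isTRUE(cl$markers["DMP"][[1]]),
                         logical(1))
  per_nucleus <- lapply(setNames(SONG_NUCLEI, SONG_NUCLEI), function(nuc) {
    sel <- scored & vapply(profs, function(p) {
      p$status == "scored" && p$direction[[nuc]] != 0L
    }, logical(1))
    registry$symbol[sel]
  })
  structure(
    list(
      probed = sum(probed),
      brain_expressed = sum(scored),
      song_system_expressed = sum(expressed),
      afp_markers = sum(afp),
      dmp_markers = sum(dmp),
      symbols = list(
        probed = registry$symbol[probed],
        brain_expressed = registry$symbol[scored],
        song_system_expressed = registry$symbol[expressed],
        afp_markers = registry$symbol[afp],
        dmp_markers = registry$symbol[dmp]
      ),
      per_nucleus_markers = per_nucleus
    ),
    class = "song_summary"
  )
}

#' @export
print.song_summary <- function(x, ...) {
  cat("Song-system expression summary\n")
  cat(sprintf("  probed:                 %d\n", x$probed))
  cat(sprintf("  brain expressed:        %d\n", x$brain_expressed))
  cat(sprintf("  song-system expressed:  %d\n", x$song_system_expressed))
  cat(sprintf("  AFP markers (LMAN/X):   %d\n", x$afp_markers))
  cat(sprintf("  DMP markers (HVC/RA):   %d\n", x$dmp_markers))
  invisible(x)
}
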