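# GO-term over-representation: per-term one-sided Fisher exact tests of a
# selected protein list against an annotated background universe, with no
# multiplicity adjustment ("classic" per-term testing).

#' Load a protein-to-GO annotation map
#'
#' Two-column TSV (protein_id, GO ID) with an optional third column giving
#' the term name. Duplicate (protein, term) lines are collapsed.
#'
#' @param path Path to the annotation TSV (no header).
#' @return List with `map` (named list: protein -> character vector of
#'   terms) and `names` (named character vector: term -> name, possibly
#'   empty).
#' @export
load_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty annotation file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol < 2)) {
    stop("malformed annotation line ", which(ncol < 2)[1], " in ", path,
         ": expected at least 2 tab-separated columns")
  }
  prot <- vapply(parts, `[[`, "", 1)
  term <- vapply(parts, `[[`, "", 2)
  bad <- !grepl("^GO:[0-9]{7}$", term)
  if (any(bad)) {
    stop("malformed GO ID '", term[which(bad)[1]], "' at line ",
         which(bad)[1], " in ", path)
  }
  nm <- vapply(parts,
               function(p) if (length(p) >= 3) p[[3]] else NA_character_,
               character(1))

  dup <- duplicated(paste(prot, term, sep = "\r"))
  prot <- prot[!dup]; term <- term[!dup]; nm <- nm[!dup]
  term_names <- nm[!is.na(nm)]
  names(term_names) <- term[!is.na(nm)]
  term_names <- term_names[!duplicated(names(term_names))]
  list(map = split(term, prot), names = term_names)
}

#' Per-term Fisher exact over-representation
#'
#' The universe is the set of background proteins carrying at least one
#' annotation (unannotated proteins are excluded and counted in a
#' message); this matches the convention of the GO-enrichment tool family,
#' where expected counts are computed against the annotated background
#' only. Each term is tested independently with a one-sided
#' (over-representation) Fisher exact test, i.e. the hypergeometric upper
#' tail, with no multiple-testing correction. No ontology-graph
#' propagation is performed: proteins are annotated only to the terms
#' listed.
#'
#' @param selected Character vector of selected protein IDs; must be a
#'   subset of `background`.
#' @param background Character vector of background protein IDs.
#' @param annotations Result of [load_annotations()], or a bare
#'   protein -> terms list.
#' @return Data frame with one row per term, sorted by p-value:
#'   term_id, term_name, n_background, n_selected, n_expected, p_value.
#' @export
enrich <- function(selected, background, annotations) {
  if (is.list(annotations) && !is.null(annotations$map)) {
    map <- annotations$map
    term_names <- annotations$names
  } else {
    map <- annotations
    term_names <- character(0)
  }
  if (length(map) == 0) stop("annotation map is empty")
  selected <- unique(selected)
  background <- unique(background)
  extra <- setdiff(selected, background)
  if (length(extra) > 0) {
    stop("selected proteins missing from background: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }

  universe <- intersect(background, names(map))
  n_unannot <- length(background) - length(universe)
  if (n_unannot > 0) {
    message("enrich: ", n_unannot,
            " background protein(s) without annotation excluded from the ",
            "universe")
  }
  if (length(universe) == 0) stop("no annotated background proteins")
  sel_u <- intersect(selected, universe)

  long <- data.frame(
    protein = rep(names(map), lengths(map)),
    term = unlist(map, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  long <- long[long$protein %in% universe, , drop = FALSE]
  terms <- sort(unique(long$term))
  U <- length(universe)
  K <- length(sel_u)

  rows <- lapply(terms, function(tm) {
    prot_t <- unique(long$protein[long$term == tm])
    m <- length(prot_t)
    x <- length(intersect(prot_t, sel_u))
    p <- stats::phyper(x - 1, m, U - m, K, lower.tail = FALSE)
    data.frame(term_id = tm,
               term_name = if (tm %in% names(term_names)) {
                 unname(term_names[tm])
               } else NA_character_,
               n_background = m, n_selected = x,
               n_expected = m * K / U, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
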