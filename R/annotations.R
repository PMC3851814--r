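#' Build an annotation set from direct protein-term annotations
#'
#' Applies set semantics to the direct \code{(protein, term, evidence)}
#' triples, attaches the aspect of every term, computes the propagation
#' closure over ancestors (true-path rule) and the per-aspect corpus sizes
#' (number of proteins with at least one annotation in the aspect).
#' Evidence codes are kept on direct annotations only; the propagated sets
#' are plain term-id sets.
#'
#' @param direct data.frame with columns \code{protein}, \code{term},
#'   \code{evidence}.
#' @param dag an \code{ontology_dag}; terms are resolved through
#'   \code{alt_id} and unknown terms are dropped with a warning.
#' @return an object of class \code{annotation_set} with elements
#'   \code{direct} (data.frame protein/term/evidence/aspect),
#'   \code{propagated} (named list protein -> term-id vector) and
#'   \code{corpus_size} (named integer per aspect).
#' @export
annotation_set <- function(direct, dag) {
  stopifnot(is.data.frame(direct),
            all(c("protein", "term", "evidence") %in% names(direct)))
  direct <- data.frame(protein = as.character(direct$protein),
                       term = as.character(direct$term),
                       evidence = as.character(direct$evidence),
                       stringsAsFactors = FALSE)
  direct$term <- resolve_term(dag, direct$term)
  bad <- is.na(direct$term)
  if (any(bad)) {
    warning("dropped ", sum(bad), " annotation row(s) with unknown term id(s)")
    direct <- direct[!bad, , drop = FALSE]
  }
  if (nrow(direct) == 0L) stop("no usable annotation rows")
  direct <- unique(direct)
  direct$aspect <- unname(dag$aspect[direct$term])
  rownames(direct) <- NULL

  by_protein <- split(direct$term, direct$protein)
  propagated <- lapply(by_protein, function(tt) {
    tt <- unique(tt)
    res <- tt
    for (t in tt) res <- union(res, term_ancestors(dag, t))
    res
  })
  corpus_size <- vapply(ASPECTS, function(asp)
    length(unique(direct$protein[direct$aspect == asp])), 1L)
  structure(list(direct = direct, propagated = propagated,
                 corpus_size = corpus_size),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", length(x$propagated), "proteins,",
      nrow(x$direct), "direct annotations\n")
  cat("  corpus sizes:",
      paste(names(x$corpus_size), x$corpus_size, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Parse a GAF 2.x annotation file
#'
#' Reads tab-separated GO-annotation rows (column 2 = protein id, column 4 =
#' qualifier, column 5 = term id, column 7 = evidence code), skipping
#' \code{!} comment lines and rows carrying a \code{NOT} qualifier, then
#' builds the propagation closure via \code{\link{annotation_set}}.
#'
#' @param path path to a GAF file.
#' @param dag an \code{ontology_dag} used to resolve term ids and aspects.
#' @return an \code{annotation_set}.
#' @export
parse_gaf <- function(path, dag) {
  if (!file.exists(path)) stop("GAF file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (length(lines) == 0L) stop("no usable annotation rows in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, 1L) >= 7L
  if (!all(ok)) stop("GAF row(s) with fewer than 7 columns: line(s) ",
                     paste(which(!ok)[seq_len(min(5L, sum(!ok)))], collapse = ", "))
  protein <- vapply(fields, `[[`, "", 2L)
  qualifier <- vapply(fields, `[[`, "", 4L)
  term <- vapply(fields, `[[`, "", 5L)
  evidence <- vapply(fields, `[[`, "", 7L)
  keep <- !grepl("(^|\\|)NOT($|\\|)", qualifier)
  direct <- data.frame(protein = trimws(protein[keep]),
                       term = trimws(term[keep]),
                       evidence = trimws(evidence[keep]),
                       stringsAsFactors = FALSE)
  if (nrow(direct) == 0L) stop("no usable annotation rows in ", path)
  annotation_set(direct, dag)
}

# Direct annotation terms of one protein in one aspect (unique ids; empty
# character vector when the protein is unannotated there).
direct_terms <- function(annot, protein, aspect) {
  d <- annot$direct
  unique(d$term[d$protein == protein & d$aspect == aspect])
}

# Split of direct terms per protein for an aspect, as a named list (faster
# than repeated direct_terms calls in batch feature computation).
direct_terms_index <- function(annot, aspect) {
  d <- annot$direct[annot$direct$aspect == aspect, , drop = FALSE]
  lapply(split(d$term, d$protein), unique)
}
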