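ASPECTS <- c("BP", "MF", "CC")
NAMESPACE_TO_ASPECT <- c(biological_process = "BP",
                         molecular_function = "MF",
                         cellular_component = "CC")
ASPECT_TO_NAMESPACE <- c(BP = "biological_process",
                         MF = "molecular_function",
                         CC = "cellular_component")
RECOGNIZED_RELATIONS <- c("is_a", "part_of")

# Internal constructor for the ontology DAG container.
#
# parents: named list; parents[[id]] is a named character vector whose names
# are parent ids and whose values are edge types ("is_a"/"part_of").
new_ontology_dag <- function(ids, names_, aspects, obsolete, parents,
                             alt_id = character(), validate = TRUE,
                             warn_roots = TRUE) {
  names(names_) <- ids
  names(aspects) <- ids
  names(obsolete) <- ids
  parents <- parents[ids]
  names(parents) <- ids
  children <- lapply(ids, function(i) character())
  names(children) <- ids
  for (id in ids) {
    for (p in names(parents[[id]])) {
      children[[p]] <- c(children[[p]], id)
    }
  }
  roots <- character()
  for (asp in ASPECTS) {
    cand <- ids[aspects == asp & !obsolete &
                  vapply(parents, length, 1L) == 0L]
    if (length(cand) == 0L) next
    if (length(cand) > 1L) {
      cand <- sort(cand)
      if (warn_roots)
        warning("aspect ", asp, " has ", length(cand),
                " parentless terms; using ", cand[1L], " as root")
    }
    roots[asp] <- cand[1L]
  }
  dag <- structure(list(terms = ids, name = names_, aspect = aspects,
                        obsolete = obsolete, parents = parents,
                        children = children, roots = roots, alt_id = alt_id,
                        cache = new.env(parent = emptyenv())),
                   class = "ontology_dag")
  if (validate) validate_acyclic(dag)
  dag
}

# Kahn's algorithm over child -> parent edges; errors on a cycle.
validate_acyclic <- function(dag) {
  indeg <- vapply(dag$parents, length, 1L)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    id <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in dag$children[[id]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen != length(dag$terms))
    stop("ontology contains a cycle among: ",
         paste(names(indeg)[indeg > 0L], collapse = ", "))
  invisible(dag)
}

#' Parse an OBO-format ontology
#'
#' Reads an OBO 1.2/1.4 flat file into a directed acyclic graph covering the
#' three Gene Ontology aspects.  Only \code{is_a} and \code{part_of}
#' relations are retained; any other relationship type (e.g.
#' \code{regulates}) is dropped with a warning.  Obsolete terms are kept but
#' flagged, and \code{alt_id}s are mapped to their primary term id.
#'
#' @param path path to an OBO file.
#' @return An object of class \code{ontology_dag} with elements
#'   \code{terms}, \code{name}, \code{aspect}, \code{obsolete},
#'   \code{parents} (named list of named edge-type vectors),
#'   \code{children}, \code{roots} (per-aspect root ids) and \code{alt_id}.
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("format-version: 1.2", "", "[Term]", "id: GO:0000001",
#'   "name: root", "namespace: biological_process", "", "[Term]",
#'   "id: GO:0000002", "name: child", "namespace: biological_process",
#'   "is_a: GO:0000001"), obo)
#' dag <- parse_obo(obo)
#' dag$roots
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  in_term <- FALSE
  cur <- NULL
  stanzas <- list()
  flush <- function() if (!is.null(cur)) stanzas[[length(stanzas) + 1L]] <<- cur
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]], which = "right")
    if (ln == "" || startsWith(ln, "!")) next
    if (grepl("^\\[.*\\]$", ln)) {
      flush()
      cur <- NULL
      in_term <- identical(ln, "[Term]")
      if (in_term) cur <- list(line = i)
      next
    }
    m <- regmatches(ln, regexec("^([A-Za-z_]+): *(.*)$", ln))[[1L]]
    if (length(m) == 0L) {
      if (in_term) stop("malformed OBO stanza at line ", i, ": ", ln)
      next  # header free-text lines are ignored
    }
    if (!in_term) next
    key <- m[[2L]]
    val <- m[[3L]]
    cur[[key]] <- c(cur[[key]], val)
  }
  flush()
  if (length(stanzas) == 0L) stop("no [Term] stanzas found in ", path)

  strip_comment <- function(x) trimws(sub(" *!.*$", "", x))
  ids <- character()
  nm <- character()
  asp <- character()
  obs <- logical()
  parents <- list()
  alt <- character()
  dropped_types <- character()
  for (st in stanzas) {
    if (is.null(st$id)) stop("OBO [Term] stanza near line ", st$line, " lacks an id")
    id <- strip_comment(st$id[[1L]])
    ns <- if (!is.null(st$namespace)) strip_comment(st$namespace[[1L]]) else NA_character_
    aspect <- NAMESPACE_TO_ASPECT[ns]
    if (is.na(aspect))
      stop("term ", id, " has missing or unrecognized namespace: ", ns)
    pv <- character()
    for (p in st$is_a) pv[strip_comment(p)] <- "is_a"
    for (r in st$relationship) {
      parts <- strsplit(strip_comment(r), "[ \t]+")[[1L]]
      if (length(parts) < 2L) stop("malformed relationship line in term ", id)
      if (parts[[1L]] %in% RECOGNIZED_RELATIONS) {
        pv[parts[[2L]]] <- parts[[1L]]
      } else {
        dropped_types <- c(dropped_types, parts[[1L]])
      }
    }
    ids <- c(ids, id)
    nm <- c(nm, if (!is.null(st$name)) st$name[[1L]] else id)
    asp <- c(asp, unname(aspect))
    obs <- c(obs, isTRUE(tolower(strip_comment(st$is_obsolete %||% "false")[1L]) == "true"))
    parents[[id]] <- pv
    for (a in st$alt_id) alt[strip_comment(a)] <- id
  }
  if (length(dropped_types))
    warning("dropped ", length(dropped_types), " edge(s) with unrecognized relation type(s): ",
            paste(sort(unique(dropped_types)), collapse = ", "))
  # drop edges pointing at unknown terms
  known <- ids
  parents <- lapply(parents, function(pv) {
    keep <- names(pv) %in% known
    if (!all(keep)) warning("dropped edge(s) to unknown parent term(s): ",
                            paste(names(pv)[!keep], collapse = ", "))
    pv[keep]
  })
  new_ontology_dag(ids, nm, asp, obs, parents, alt)
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("ontology_dag:", length(x$terms), "terms;",
      sum(vapply(x$parents, length, 1L)), "edges\n")
  for (asp in names(x$roots))
    cat("  ", asp, "root:", x$roots[[asp]],
        "(", sum(x$aspect == asp & !x$obsolete), "terms )\n")
  invisible(x)
}

# Resolve a possibly-alternate term id to its primary id (NA if unknown).
resolve_term <- function(dag, id) {
  out <- id
  unknown <- !(out %in% dag$terms)
  if (any(unknown)) {
    mapped <- dag$alt_id[out[unknown]]
    out[unknown] <- ifelse(is.na(mapped), NA_character_, mapped)
  }
  out
}

#' Ancestors of an ontology term
#'
#' Transitive closure over \code{is_a}/\code{part_of} parent edges.
#' Results are memoized on the DAG object.
#'
#' @param dag an \code{ontology_dag}.
#' @param id a term id.
#' @param include_self include \code{id} itself in the result.
#' @return character vector of ancestor term ids.
#' @export
term_ancestors <- function(dag, id, include_self = FALSE) {
  if (!(id %in% dag$terms)) stop("unknown term: ", id)
  key <- paste0("anc:", id)
  res <- dag$cache[[key]]
  if (is.null(res)) {
    ps <- names(dag$parents[[id]])
    res <- ps
    for (p in ps) res <- union(res, term_ancestors(dag, p))
    dag$cache[[key]] <- res
  }
  if (include_self) union(id, res) else res
}

#' Descendants of an ontology term
#'
#' @inheritParams term_ancestors
#' @return character vector of descendant term ids.
#' @export
term_descendants <- function(dag, id, include_self = FALSE) {
  if (!(id %in% dag$terms)) stop("unknown term: ", id)
  key <- paste0("desc:", id)
  res <- dag$cache[[key]]
  if (is.null(res)) {
    ch <- dag$children[[id]]
    res <- ch
    for (c_ in ch) res <- union(res, term_descendants(dag, c_))
    dag$cache[[key]] <- res
  }
  if (include_self) union(id, res) else res
}

# Shortest-path depth of every term of an aspect from the aspect root,
# counting is_a/part_of edges alike.  Memoized.
term_depths <- function(dag, aspect) {
  key <- paste0("depth:", aspect)
  res <- dag$cache[[key]]
  if (!is.null(res)) return(res)
  root <- dag$roots[[aspect]]
  if (is.null(root) || is.na(root)) stop("aspect ", aspect, " has no root")
  depth <- c(stats::setNames(0L, root))
  frontier <- root
  while (length(frontier)) {
    nxt <- character()
    for (id in frontier) {
      for (ch in dag$children[[id]]) {
        if (is.na(depth[ch])) {
          depth[ch] <- depth[[id]] + 1L
          nxt <- c(nxt, ch)
        }
      }
    }
    frontier <- nxt
  }
  dag$cache[[key]] <- depth
  depth
}

# Shortest upward distance from `id` to each of its ancestors (incl. self, 0).
term_updist <- function(dag, id) {
  key <- paste0("updist:", id)
  res <- dag$cache[[key]]
  if (!is.null(res)) return(res)
  dist <- c(stats::setNames(0L, id))
  frontier <- id
  while (length(frontier)) {
    nxt <- character()
    for (t in frontier) {
      for (p in names(dag$parents[[t]])) {
        if (is.na(dist[p])) {
          dist[p] <- dist[[t]] + 1L
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- nxt
  }
  dag$cache[[key]] <- dist
  dist
}

#' Information content of ontology terms
#'
#' For each term \eqn{t} of the aspect, \eqn{IC(t) = -\ln p(t)} where
#' \eqn{p(t)} is the fraction of the aspect's annotated proteins that carry
#' \eqn{t}.  Under the default \code{counts = "propagated"} a protein
#' carries \eqn{t} if \eqn{t} or any of its descendants annotates the
#' protein (true-path rule); \code{counts = "direct"} uses direct
#' annotations only.  Terms annotating no protein are omitted (they have no
#' finite probability mass), and the aspect root always has IC 0 under
#' propagated counts.
#'
#' @param dag an \code{ontology_dag}.
#' @param annot an \code{annotation_set} (see \code{\link{parse_gaf}}).
#' @param aspect one of \code{"BP"}, \code{"MF"}, \code{"CC"}.
#' @param counts \code{"propagated"} (default) or \code{"direct"}.
#' @return An \code{ic_table}: list with \code{aspect} and \code{ic}, a
#'   named non-negative numeric vector in nats.
#' @export
compute_ic <- function(dag, annot, aspect, counts = c("propagated", "direct")) {
  counts <- match.arg(counts)
  aspect <- match.arg(aspect, ASPECTS)
  cs <- annot$corpus_size[[aspect]]
  if (is.null(cs) || is.na(cs) || cs < 1L)
    stop("no proteins annotated in aspect ", aspect)
  if (counts == "propagated") {
    tab <- table(unlist(lapply(annot$propagated, function(tt)
      unique(tt[dag$aspect[tt] == aspect])), use.names = FALSE))
  } else {
    d <- annot$direct[annot$direct$aspect == aspect, , drop = FALSE]
    tab <- table(unique(d[, c("protein", "term")])$term)
  }
  n <- as.numeric(tab)
  ic <- -log(n / cs)
  names(ic) <- names(tab)
  ic[ic < 0] <- 0  # guard against fp noise at p = 1
  structure(list(aspect = aspect, ic = ic, counts = counts,
                 corpus_size = cs), class = "ic_table")
}

#' Common ancestor with maximal information content
#'
#' Each term counts as its own ancestor, so for nested terms the deeper term
#' itself can be the answer.  Ties on IC are broken by the lexicographically
#' smallest term id so the result is deterministic.
#'
#' @param dag an \code{ontology_dag}.
#' @param ic an \code{ic_table} for the terms' aspect.
#' @param t1,t2 term ids of the same aspect.
#' @return the id of the max-IC common ancestor.
#' @export
max_ic_common_ancestor <- function(dag, ic, t1, t2) {
  for (t in c(t1, t2)) if (!(t %in% dag$terms)) stop("unknown term: ", t)
  if (dag$aspect[[t1]] != dag$aspect[[t2]])
    stop("terms ", t1, " and ", t2, " belong to different aspects")
  ca <- intersect(term_ancestors(dag, t1, include_self = TRUE),
                  term_ancestors(dag, t2, include_self = TRUE))
  if (length(ca) == 0L) stop("no common ancestor of ", t1, " and ", t2)
  vals <- ic$ic[ca]
  vals[is.na(vals)] <- 0
  names(vals) <- ca
  best <- max(vals)
  sort(names(vals)[vals == best])[[1L]]
}

#' Transitive reduction of a DAG slice
#'
#' Removes every edge implied by a longer path, yielding the smallest graph
#' with the same transitive closure as the input slice.
#'
#' @param dag an \code{ontology_dag}.
#' @param terms term ids delimiting the slice (default: all terms).
#' @return an \code{ontology_dag} restricted to \code{terms} with redundant
#'   edges removed.
#' @export
transitive_reduction <- function(dag, terms = NULL) {
  terms <- terms %||% dag$terms
  if (!all(terms %in% dag$terms)) stop("slice contains unknown terms")
  par <- lapply(dag$parents[terms], function(pv) pv[names(pv) %in% terms])
  names(par) <- terms
  # cycle check within the slice
  indeg <- vapply(par, length, 1L)
  ch <- lapply(terms, function(i) character())
  names(ch) <- terms
  for (id in terms) for (p in names(par[[id]])) ch[[p]] <- c(ch[[p]], id)
  queue <- terms[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    id <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (c_ in ch[[id]]) {
      indeg[[c_]] <- indeg[[c_]] - 1L
      if (indeg[[c_]] == 0L) queue <- c(queue, c_)
    }
  }
  if (seen != length(terms)) stop("cycle detected in slice")
  # ancestors-within-slice, memoized locally
  memo <- new.env(parent = emptyenv())
  anc <- function(id) {
    res <- memo[[id]]
    if (is.null(res)) {
      ps <- names(par[[id]])
      res <- ps
      for (p in ps) res <- union(res, anc(p))
      memo[[id]] <- res
    }
    res
  }
  red <- par
  for (id in terms) {
    pv <- par[[id]]
    if (length(pv) < 2L) next
    pnames <- names(pv)
    keep <- rep(TRUE, length(pv))
    for (k in seq_along(pv)) {
      others <- pnames[-k]
      implied <- unique(unlist(lapply(others, anc), use.names = FALSE))
      if (pnames[[k]] %in% implied) keep[[k]] <- FALSE
    }
    red[[id]] <- pv[keep]
  }
  new_ontology_dag(terms, dag$name[terms], dag$aspect[terms],
                   dag$obsolete[terms], red, validate = FALSE,
                   warn_roots = FALSE)
}
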