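# Topological clustering semantic similarity (TCSS): partition an aspect's
# DAG into high-IC subgraphs hanging below an information-content threshold,
# normalize IC within each subgraph (ICS) and across the meta-graph of
# low-IC terms (ICM), and score protein pairs by the normalized IC of the
# best common ancestor of their annotation terms.

#' Information content of annotation (ICA)
#'
#' \eqn{ICA(t) = -\ln(|P_t \cup \bigcup_{c} P_c| / N)} where \eqn{P_t} is
#' the set of proteins directly annotated with \eqn{t}, the union runs over
#' the descendants of \eqn{t}, and \eqn{N} is the number of proteins
#' annotated in the aspect.  With \code{descendants = "all"} (default) this
#' equals the propagated-count information content of
#' \code{\link{compute_ic}}; \code{descendants = "children"} restricts the
#' union to immediate children.
#'
#' @inheritParams compute_ic
#' @param descendants \code{"all"} or \code{"children"}.
#' @return named numeric vector of ICA values (nats) over the aspect's
#'   annotation-bearing terms.
#' @export
tcss_ica <- function(dag, annot, aspect, descendants = c("all", "children")) {
  descendants <- match.arg(descendants)
  aspect <- match.arg(aspect, ASPECTS)
  cs <- annot$corpus_size[[aspect]]
  if (is.null(cs) || is.na(cs) || cs < 1L)
    stop("no proteins annotated in aspect ", aspect)
  idx <- direct_terms_index(annot, aspect)
  proteins <- names(idx)
  terms <- sort(unique(unlist(idx, use.names = FALSE)))
  # all terms with >= 1 direct annotation below-or-at them
  all_terms <- sort(unique(unlist(lapply(terms, function(t)
    term_ancestors(dag, t, include_self = TRUE)), use.names = FALSE)))
  all_terms <- all_terms[dag$aspect[all_terms] == aspect]
  ica <- vapply(all_terms, function(t) {
    fam <- if (descendants == "all")
      term_descendants(dag, t, include_self = TRUE)
    else
      union(t, dag$children[[t]])
    n <- sum(vapply(idx, function(tt) any(tt %in% fam), TRUE))
    -log(n / cs)
  }, 1.0)
  ica[ica < 0] <- 0
  ica <- ica[is.finite(ica)]
  ica
}

#' Partition an aspect DAG into TCSS subgraphs
#'
#' An IC threshold cuts the aspect DAG: the subgraph roots are the terms at
#' or above the threshold whose parents are all below it, and each subgraph
#' consists of a root plus its annotation-bearing descendants.  Subgraphs
#' whose roots have ICA within \code{merge_tolerance} of each other are
#' merged.  Terms below the threshold form the meta-graph (together with the
#' subgraph roots).  Each subgraph's edge set is cleaned by
#' \code{\link{transitive_reduction}} and terms reachable from several roots
#' are duplicated into every such subgraph.  ICS normalizes ICA by the
#' subgraph maximum, ICM by the meta-graph maximum.
#'
#' If no term reaches the threshold, a single subgraph rooted at the aspect
#' root and covering the whole aspect is returned.
#'
#' @inheritParams compute_ic
#' @param ic_threshold IC cut in nats; default \code{0.35 * max(ICA)}.
#' @param merge_tolerance absolute ICA tolerance for merging subgraph roots;
#'   default \code{0.05 * max(ICA)}.
#' @param descendants passed to \code{\link{tcss_ica}}.
#' @return an object of class \code{tcss_partition}: \code{subgraphs} (list
#'   of \code{list(root, terms, reduced)}), \code{membership} (term ->
#'   subgraph indices), \code{meta_terms}, \code{ica}, \code{ics} (per
#'   subgraph), \code{icm}.
#' @export
tcss_partition <- function(dag, annot, aspect, ic_threshold = NULL,
                           merge_tolerance = NULL,
                           descendants = c("all", "children")) {
  aspect <- match.arg(aspect, ASPECTS)
  ica <- tcss_ica(dag, annot, aspect, descendants)
  mx <- max(ica)
  ic_threshold <- ic_threshold %||% (0.35 * mx)
  merge_tolerance <- merge_tolerance %||% (0.05 * mx)
  if (ic_threshold < 0) stop("ic_threshold must be >= 0")
  terms <- names(ica)
  # roots: terms at/above the cut whose parents (with ICA) are all below it
  is_root <- vapply(terms, function(t) {
    if (ica[[t]] < ic_threshold) return(FALSE)
    ps <- names(dag$parents[[t]])
    ps <- ps[ps %in% terms]
    length(ps) == 0L || all(ica[ps] < ic_threshold)
  }, TRUE)
  roots <- sort(terms[is_root])
  single <- length(roots) == 0L
  if (single) roots <- dag$roots[[aspect]]

  groups <- if (single || length(roots) == 1L) {
    list(roots)
  } else {
    # single-linkage grouping of roots whose ICA values are within tolerance
    ord <- roots[order(ica[roots], roots)]
    g <- list(ord[[1L]])
    for (r in ord[-1L]) {
      last <- g[[length(g)]]
      if (ica[[r]] - ica[[last[length(last)]]] <= merge_tolerance) {
        g[[length(g)]] <- c(last, r)
      } else {
        g[[length(g) + 1L]] <- r
      }
    }
    g
  }

  subgraphs <- lapply(groups, function(rs) {
    tt <- unique(unlist(lapply(rs, function(r)
      term_descendants(dag, r, include_self = TRUE)), use.names = FALSE))
    tt <- intersect(tt, terms)
    root <- rs[order(ica[rs], rs)][[1L]]
    list(root = root, terms = sort(tt),
         reduced = transitive_reduction(dag, sort(tt)))
  })
  membership <- new.env(parent = emptyenv())
  for (m in seq_along(subgraphs)) {
    for (t in subgraphs[[m]]$terms) {
      membership[[t]] <- c(membership[[t]], m)
    }
  }
  meta_terms <- if (single) dag$roots[[aspect]] else
    sort(union(terms[ica < ic_threshold], roots))
  ics <- lapply(subgraphs, function(sg) {
    v <- ica[sg$terms]
    smax <- max(v)
    if (smax > 0) v / smax else v * 0
  })
  mv <- ica[intersect(meta_terms, terms)]
  icm <- if (length(mv) && max(mv) > 0) mv / max(mv) else mv * 0
  structure(list(aspect = aspect, subgraphs = subgraphs,
                 membership = membership, meta_terms = meta_terms,
                 ica = ica, ics = ics, icm = icm,
                 ic_threshold = ic_threshold,
                 merge_tolerance = merge_tolerance, dag = dag),
            class = "tcss_partition")
}

#' @export
print.tcss_partition <- function(x, ...) {
  cat("tcss_partition (", x$aspect, "): ", length(x$subgraphs),
      " subgraph(s), ", length(x$meta_terms), " meta term(s), threshold ",
      signif(x$ic_threshold, 4), "\n", sep = "")
  invisible(x)
}

# Best normalized-IC common ancestor of two terms under a partition.
tcss_term_score <- function(part, s, t) {
  dag <- part$dag
  shared <- intersect(part$membership[[s]], part$membership[[t]])
  ca <- intersect(term_ancestors(dag, s, include_self = TRUE),
                  term_ancestors(dag, t, include_self = TRUE))
  pick <- function(cand, table) {
    cand <- intersect(cand, names(table))
    if (length(cand) == 0L) return(NA_real_)
    v <- part$ica[cand]
    best <- sort(cand[v == max(v)])[[1L]]
    table[[best]]
  }
  if (length(shared)) {
    vs <- vapply(shared, function(m)
      pick(intersect(ca, part$subgraphs[[m]]$terms), part$ics[[m]]), 1.0)
    vs <- vs[!is.na(vs)]
    # a merged subgraph can contain both terms without an in-set common
    # ancestor; fall through to the meta-graph in that case
    if (length(vs)) return(max(vs))
  }
  v <- pick(intersect(ca, part$meta_terms), part$icm)
  if (is.na(v)) 0 else v
}

#' TCSS similarity between two proteins
#'
#' Scores every pair of annotation terms: if the terms share a subgraph the
#' score is the within-subgraph normalized IC (ICS) of their best common
#' ancestor; otherwise it is the meta-graph normalized IC (ICM) of the best
#' common ancestor among meta terms.  The protein similarity is the maximum
#' over all term pairs; it is symmetric and lies in [0, 1].
#'
#' @param partition a \code{tcss_partition}.
#' @param annot the \code{annotation_set} used to build the partition.
#' @param i,j protein ids.
#' @param cache optional environment memoizing term-pair scores.
#' @return similarity in [0, 1], or \code{NA} if either protein carries no
#'   usable annotation in the partition's aspect.
#' @export
tcss_protein_sim <- function(partition, annot, i, j, cache = NULL) {
  ti <- intersect(direct_terms(annot, i, partition$aspect), names(partition$ica))
  tj <- intersect(direct_terms(annot, j, partition$aspect), names(partition$ica))
  tcss_termset_sim(partition, ti, tj, cache)
}

tcss_termset_sim <- function(partition, ti, tj, cache = NULL) {
  if (length(ti) == 0L || length(tj) == 0L) return(NA_real_)
  best <- 0
  for (s in ti) {
    for (t in tj) {
      if (is.null(cache)) {
        v <- tcss_term_score(partition, s, t)
      } else {
        k <- paste(min(s, t), max(s, t), sep = "\r")
        v <- cache[[k]]
        if (is.null(v)) {
          v <- tcss_term_score(partition, s, t)
          cache[[k]] <- v
        }
      }
      if (v > best) best <- v
    }
  }
  best
}
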