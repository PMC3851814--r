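# Wang's graph-based semantic similarity: every term defines DAG_t (the
# term plus its ancestors); semantic contributions decay multiplicatively
# along edges with a per-edge-type weight, taking the max over paths, and
# two terms are compared by the contributions of their shared ancestors.

#' Semantic contributions of a term's ancestor DAG
#'
#' \eqn{S_t(t) = 1} and, for every ancestor \eqn{n},
#' \eqn{S_t(n) = \max\{ w_e \cdot S_t(n') \}} over the children \eqn{n'} of
#' \eqn{n} inside \eqn{DAG_t}, where \eqn{w_e} is the weight of the edge
#' type joining \eqn{n'} to \eqn{n}.
#'
#' @param dag an \code{ontology_dag}.
#' @param t anchor term id.
#' @param w_is_a,w_part_of semantic contribution factors in (0, 1] for the
#'   two edge types (defaults 0.8 and 0.6, the values conventionally used
#'   with this measure).
#' @return an object of class \code{wang_contributions}: \code{anchor},
#'   \code{s_values} (named numeric over \eqn{DAG_t}) and \code{sv}, their
#'   sum.
#' @export
wang_contributions <- function(dag, t, w_is_a = 0.8, w_part_of = 0.6) {
  if (!(t %in% dag$terms)) stop("unknown term: ", t)
  stopifnot(w_is_a > 0, w_is_a <= 1, w_part_of > 0, w_part_of <= 1)
  w <- c(is_a = w_is_a, part_of = w_part_of)
  dag_t <- term_ancestors(dag, t, include_self = TRUE)
  memo <- new.env(parent = emptyenv())
  memo[[t]] <- 1
  s_of <- function(n) {
    res <- memo[[n]]
    if (!is.null(res)) return(res)
    ch <- intersect(dag$children[[n]], dag_t)
    # each child c carries the edge type of its parent record for n
    res <- max(vapply(ch, function(c_) {
      type <- dag$parents[[c_]][[n]]
      w[[type]] * s_of(c_)
    }, 1.0))
    memo[[n]] <- res
    res
  }
  s_values <- vapply(dag_t, s_of, 1.0)
  structure(list(anchor = t, s_values = s_values, sv = sum(s_values)),
            class = "wang_contributions")
}

#' Wang similarity between two ontology terms
#'
#' \deqn{Sim(m, n) = \frac{\sum_{t \in T_m \cap T_n} S_m(t) + S_n(t)}
#'                        {SV(m) + SV(n)}}
#' over the shared terms of the two ancestor DAGs.  Equals 1 iff the terms
#' coincide; symmetric.
#'
#' @inheritParams wang_contributions
#' @param m,n term ids of the same aspect.
#' @return similarity in (0, 1].
#' @export
wang_term_sim <- function(dag, m, n, w_is_a = 0.8, w_part_of = 0.6) {
  for (t in c(m, n)) if (!(t %in% dag$terms)) stop("unknown term: ", t)
  if (dag$aspect[[m]] != dag$aspect[[n]])
    stop("terms ", m, " and ", n, " belong to different aspects")
  cm <- wang_contributions(dag, m, w_is_a, w_part_of)
  cn <- wang_contributions(dag, n, w_is_a, w_part_of)
  shared <- intersect(names(cm$s_values), names(cn$s_values))
  if (length(shared) == 0L) stop("terms share no ancestors")
  sum(cm$s_values[shared] + cn$s_values[shared]) / (cm$sv + cn$sv)
}

#' Wang similarity between two proteins
#'
#' The maximum \code{\link{wang_term_sim}} over the cross product of the two
#' proteins' direct annotation terms in the aspect.
#'
#' @inheritParams wang_contributions
#' @param annot an \code{annotation_set}.
#' @param i,j protein ids.
#' @param aspect one of \code{"BP"}, \code{"MF"}, \code{"CC"}.
#' @param cache optional environment memoizing per-term contribution tables
#'   and term-pair similarities across calls.
#' @return similarity in [0, 1], or \code{NA} if either protein has no
#'   annotation in the aspect.
#' @export
wang_protein_sim <- function(dag, annot, i, j, aspect,
                             w_is_a = 0.8, w_part_of = 0.6, cache = NULL) {
  aspect <- match.arg(aspect, ASPECTS)
  ti <- intersect(direct_terms(annot, i, aspect), dag$terms)
  tj <- intersect(direct_terms(annot, j, aspect), dag$terms)
  wang_termset_sim(dag, ti, tj, w_is_a, w_part_of, cache)
}

wang_termset_sim <- function(dag, ti, tj, w_is_a = 0.8, w_part_of = 0.6,
                             cache = NULL) {
  if (length(ti) == 0L || length(tj) == 0L) return(NA_real_)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  contrib <- function(t) {
    k <- paste0("c\r", t)
    v <- cache[[k]]
    if (is.null(v)) {
      v <- wang_contributions(dag, t, w_is_a, w_part_of)
      cache[[k]] <- v
    }
    v
  }
  best <- 0
  for (s in ti) {
    for (t in tj) {
      k <- paste("s", min(s, t), max(s, t), sep = "\r")
      v <- cache[[k]]
      if (is.null(v)) {
        cs <- contrib(s)
        ct <- contrib(t)
        shared <- intersect(names(cs$s_values), names(ct$s_values))
        v <- if (length(shared))
          sum(cs$s_values[shared] + ct$s_values[shared]) / (cs$sv + ct$sv)
        else 0
        cache[[k]] <- v
      }
      if (v > best) best <- v
    }
  }
  best
}
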