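# IntelliGO vector-space semantic similarity: each protein is a vector over
# its directly annotated terms with coefficients alpha_t = w(EC) * IAF(t),
# compared by a cosine under a non-orthogonal term basis whose inner
# products reflect the DAG position of the two terms.

#' Default evidence-code weight table
#'
#' Experimental codes weigh 1.0, computational/curator-assigned codes 0.8,
#' electronic (IEA) and unknown codes 0.6.  All weights are user-overridable.
#'
#' @return an object of class \code{ec_weight_table}: list with
#'   \code{weights} (named numeric) and \code{default_weight}.
#' @export
default_ec_weights <- function() {
  experimental <- c("EXP", "IDA", "IMP", "IPI", "IGI", "IEP")
  curated <- c("ISS", "ISO", "ISA", "ISM", "IGC", "IBA", "IBD", "IKR",
               "IRD", "RCA", "TAS", "NAS", "IC")
  w <- c(stats::setNames(rep(1.0, length(experimental)), experimental),
         stats::setNames(rep(0.8, length(curated)), curated),
         IEA = 0.6)
  structure(list(weights = w, default_weight = 0.6),
            class = "ec_weight_table")
}

ec_weight <- function(table, ec) {
  w <- table$weights[ec]
  w[is.na(w)] <- table$default_weight
  unname(w)
}

#' Inverse annotation frequency of a term
#'
#' \eqn{IAF(t) = \ln(N / n_t)} where \eqn{N} is the number of proteins
#' annotated in the aspect and \eqn{n_t} the number of proteins directly
#' annotated with \eqn{t}; 0 when every protein carries the term.
#'
#' @param annot an \code{annotation_set}.
#' @param aspect one of \code{"BP"}, \code{"MF"}, \code{"CC"}.
#' @param t term id.
#' @return non-negative real.
#' @export
intelligo_iaf <- function(annot, aspect, t) {
  aspect <- match.arg(aspect, ASPECTS)
  cs <- annot$corpus_size[[aspect]]
  if (is.null(cs) || is.na(cs) || cs < 1L)
    stop("no proteins annotated in aspect ", aspect)
  d <- annot$direct
  n <- length(unique(d$protein[d$term == t & d$aspect == aspect]))
  if (n == 0L) stop("term ", t, " directly annotates no protein in ", aspect)
  log(cs / n)
}

# Basis-term inner product: 2 d(LCA) / (minSPL + 2 d(LCA)) with d the
# shortest-path depth from the aspect root and minSPL the shortest path
# s -> LCA -> t; the LCA is the max-IC common ancestor.  1 for s == t, 0
# when the only common ancestor sits at the root (depth 0).
intelligo_basis_product <- function(dag, ic, s, t) {
  if (s == t) return(1)
  a <- max_ic_common_ancestor(dag, ic, s, t)
  depth <- term_depths(dag, dag$aspect[[s]])
  d <- as.numeric(depth[[a]])
  if (d == 0) return(0)
  spl <- as.numeric(term_updist(dag, s)[[a]] + term_updist(dag, t)[[a]])
  2 * d / (spl + 2 * d)
}

# IAF for every directly annotated term of an aspect at once.
intelligo_iaf_table <- function(annot, aspect) {
  cs <- annot$corpus_size[[aspect]]
  d <- annot$direct[annot$direct$aspect == aspect, , drop = FALSE]
  tab <- table(unique(d[, c("protein", "term")])$term)
  iaf <- log(cs / as.numeric(tab))
  names(iaf) <- names(tab)
  iaf
}

# Annotation vector of one protein: coefficients alpha over direct terms.
intelligo_vector <- function(annot, protein, aspect, ec_weights, iaf = NULL) {
  d <- annot$direct
  d <- d[d$protein == protein & d$aspect == aspect, , drop = FALSE]
  if (nrow(d) == 0L) return(NULL)
  iaf <- iaf %||% intelligo_iaf_table(annot, aspect)
  terms <- unique(d$term)
  alpha <- vapply(terms, function(t) {
    w <- max(ec_weight(ec_weights, d$evidence[d$term == t]))
    w * iaf[[t]]
  }, 1.0)
  alpha[alpha > 0]
}

# Generalized inner product of two annotation vectors under the basis
# products, memoizing basis products (and nothing else) in `cache`.
intelligo_inner <- function(dag, ic, va, vb, cache = NULL) {
  bp <- function(s, t) {
    if (is.null(cache)) return(intelligo_basis_product(dag, ic, s, t))
    k <- paste(min(s, t), max(s, t), sep = "\r")
    v <- cache[[k]]
    if (is.null(v)) {
      v <- intelligo_basis_product(dag, ic, s, t)
      cache[[k]] <- v
    }
    v
  }
  total <- 0
  for (s in names(va)) {
    for (t in names(vb)) {
      total <- total + va[[s]] * vb[[t]] * bp(s, t)
    }
  }
  total
}

# Cosine of two prebuilt annotation vectors (NULL/empty -> NA).
intelligo_vec_sim <- function(dag, ic, vi, vj, cache = NULL) {
  if (is.null(vi) || is.null(vj) || length(vi) == 0L || length(vj) == 0L)
    return(NA_real_)
  denom <- sqrt(intelligo_inner(dag, ic, vi, vi, cache)) *
    sqrt(intelligo_inner(dag, ic, vj, vj, cache))
  if (denom <= 0) return(NA_real_)
  min(1, max(0, intelligo_inner(dag, ic, vi, vj, cache) / denom))
}

#' IntelliGO similarity between two proteins
#'
#' Builds each protein's annotation vector (coefficients
#' \eqn{\alpha_t = w(EC) \cdot IAF(t)} over its direct terms, taking the
#' best evidence-code weight when a term is annotated under several codes)
#' and returns the generalized cosine
#' \deqn{Sim(i, j) = \frac{\vec i * \vec j}
#'   {\sqrt{\vec i * \vec i}\sqrt{\vec j * \vec j}}}
#' where the generalized inner product expands over term pairs with the
#' DAG-positional basis product (see package vignette; the basis formula
#' follows the original IntelliGO publication).
#'
#' @param dag an \code{ontology_dag}.
#' @param annot an \code{annotation_set}.
#' @param i,j protein ids.
#' @param aspect one of \code{"BP"}, \code{"MF"}, \code{"CC"}.
#' @param ec_weights an \code{ec_weight_table}.
#' @param ic optional precomputed \code{ic_table} for the aspect (used to
#'   pick max-IC common ancestors); computed from \code{annot} when absent.
#' @param cache optional environment memoizing basis products across calls.
#' @return similarity in [0, 1], or \code{NA} if either protein has no
#'   positive-coefficient direct annotation in the aspect.
#' @export
intelligo_protein_sim <- function(dag, annot, i, j, aspect,
                                  ec_weights = default_ec_weights(),
                                  ic = NULL, cache = NULL) {
  aspect <- match.arg(aspect, ASPECTS)
  ic <- ic %||% compute_ic(dag, annot, aspect)
  iaf <- intelligo_iaf_table(annot, aspect)
  vi <- intelligo_vector(annot, i, aspect, ec_weights, iaf)
  vj <- intelligo_vector(annot, j, aspect, ec_weights, iaf)
  intelligo_vec_sim(dag, ic, vi, vj, cache)
}
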