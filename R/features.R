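# Assembly of per-pair heterogeneous feature matrices.

GO_MEASURES <- c("tcss", "intelligo", "wang")
TOPO_FEATURES <- c("jaccard", "aa", "ra")

#' Names of all available pair features
#'
#' Three GO semantic-similarity measures crossed with the three GO aspects,
#' the co-pathway similarity, and the three topological similarities: 13
#' columns in total.
#'
#' @return character vector of feature names.
#' @export
all_features <- function() {
  c(as.vector(outer(GO_MEASURES, ASPECTS, paste, sep = "_")),
    "kegg", TOPO_FEATURES)
}

#' Compute a feature matrix for protein pairs
#'
#' One column per requested feature; entries where a measure cannot work
#' (protein unannotated in the aspect, absent from every pathway, or absent
#' from the network) are \code{NA} and are imputed at training time, never
#' here.
#'
#' @param pairs data.frame or 2-column matrix of protein-id pairs.
#' @param features subset of \code{\link{all_features}()}.
#' @param dag,annot ontology and annotations (required for GO features).
#' @param pm \code{pathway_membership} (required for \code{"kegg"}).
#' @param net \code{ppi_network} (required for topological features).
#' @param ec_weights evidence-code weights for IntelliGO.
#' @param wang_weights named vector \code{c(is_a=, part_of=)}.
#' @param tcss_ic_threshold,tcss_merge_tolerance passed to
#'   \code{\link{tcss_partition}} (NULL = defaults).
#' @param mask_edge leave-one-out topology: drop the scored pair's own edge
#'   before taking neighborhoods.
#' @return data.frame(protein_a, protein_b, one numeric column per feature).
#' @export
build_features <- function(pairs, features = all_features(), dag = NULL,
                           annot = NULL, pm = NULL, net = NULL,
                           ec_weights = default_ec_weights(),
                           wang_weights = c(is_a = 0.8, part_of = 0.6),
                           tcss_ic_threshold = NULL,
                           tcss_merge_tolerance = NULL,
                           mask_edge = FALSE) {
  unknown <- setdiff(features, all_features())
  if (length(unknown))
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
  p <- as_pair_df(pairs)
  go <- grep("^(tcss|intelligo|wang)_(BP|MF|CC)$", features, value = TRUE)
  if (length(go) && (is.null(dag) || is.null(annot)))
    stop("GO features require `dag` and `annot`")
  if ("kegg" %in% features && is.null(pm))
    stop("the kegg feature requires `pm`")
  if (any(TOPO_FEATURES %in% features) && is.null(net))
    stop("topological features require `net`")

  out <- p
  n <- nrow(p)
  aspects_needed <- unique(sub("^[a-z]+_", "", go))
  ic <- list()
  part <- list()
  tindex <- list()
  for (asp in aspects_needed) {
    tindex[[asp]] <- direct_terms_index(annot, asp)
    if (any(startsWith(go, "intelligo")))
      ic[[asp]] <- compute_ic(dag, annot, asp)
    if (any(startsWith(go, "tcss")))
      part[[asp]] <- tcss_partition(dag, annot, asp,
                                    ic_threshold = tcss_ic_threshold,
                                    merge_tolerance = tcss_merge_tolerance)
  }
  caches <- new.env(parent = emptyenv())
  get_cache <- function(key) {
    v <- caches[[key]]
    if (is.null(v)) {
      v <- new.env(parent = emptyenv())
      caches[[key]] <- v
    }
    v
  }
  in_net <- if (!is.null(net)) (p$protein_a %in% net$nodes) &
    (p$protein_b %in% net$nodes) else NULL

  for (f in features) {
    if (f %in% TOPO_FEATURES) {
      fun <- switch(f, jaccard = jaccard_sim, aa = adamic_adar_sim,
                    ra = resource_allocation_sim)
      out[[f]] <- vapply(seq_len(n), function(k) {
        if (!in_net[[k]]) return(NA_real_)
        fun(net, p$protein_a[[k]], p$protein_b[[k]], mask_edge = mask_edge)
      }, 1.0)
    } else if (f == "kegg") {
      out[[f]] <- vapply(seq_len(n), function(k)
        kegg_sim(pm, p$protein_a[[k]], p$protein_b[[k]]), 1.0)
    } else {
      measure <- sub("_.*$", "", f)
      asp <- sub("^.*_", "", f)
      ti <- tindex[[asp]]
      cache <- get_cache(f)
      out[[f]] <- switch(measure,
        wang = vapply(seq_len(n), function(k) {
          a <- intersect(ti[[p$protein_a[[k]]]] %||% character(), dag$terms)
          b <- intersect(ti[[p$protein_b[[k]]]] %||% character(), dag$terms)
          wang_termset_sim(dag, a, b, wang_weights[["is_a"]],
                           wang_weights[["part_of"]], cache)
        }, 1.0),
        tcss = vapply(seq_len(n), function(k) {
          a <- intersect(ti[[p$protein_a[[k]]]] %||% character(),
                         names(part[[asp]]$ica))
          b <- intersect(ti[[p$protein_b[[k]]]] %||% character(),
                         names(part[[asp]]$ica))
          tcss_termset_sim(part[[asp]], a, b, cache)
        }, 1.0),
        intelligo = {
          iaf <- intelligo_iaf_table(annot, asp)
          prots <- unique(c(p$protein_a, p$protein_b))
          vecs <- lapply(prots, intelligo_vector, annot = annot,
                         aspect = asp, ec_weights = ec_weights, iaf = iaf)
          names(vecs) <- prots
          vapply(seq_len(n), function(k)
            intelligo_vec_sim(dag, ic[[asp]], vecs[[p$protein_a[[k]]]],
                              vecs[[p$protein_b[[k]]]], cache), 1.0)
        })
    }
  }
  out
}
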