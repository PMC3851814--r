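# Seeded generators for toy ontologies, annotations, pathway tables and
# gold-standard networks emulating the structure of binary and co-complex
# yeast interaction benchmarks, so the whole pipeline is testable offline.

#' Generate a toy three-aspect ontology
#'
#' Each aspect is an independent mostly-tree DAG: a full \code{branching}-ary
#' tree of \code{depth} levels below the aspect root, with a fraction
#' \code{diamond_frac} of non-root terms receiving a second parent drawn
#' from shallower non-ancestor terms (creating diamond motifs), and a
#' fraction \code{part_of_frac} of edges typed \code{part_of} instead of
#' \code{is_a}.
#'
#' @param branching children per internal term.
#' @param depth tree depth below the root (so \code{branching = 2, depth =
#'   3} gives 15 terms per aspect).
#' @param diamond_frac fraction of terms given a second parent.
#' @param part_of_frac fraction of edges typed \code{part_of}.
#' @param seed RNG seed; the same seed reproduces the ontology exactly.
#' @return an \code{ontology_dag}.
#' @export
make_toy_ontology <- function(branching = 2L, depth = 3L, diamond_frac = 0.1,
                              part_of_frac = 0.15, seed = 1L) {
  stopifnot(branching >= 1L, depth >= 1L)
  with_seed(seed, {
    ids <- character()
    nm <- character()
    asp <- character()
    parents <- list()
    counter <- 0L
    next_id <- function() {
      counter <<- counter + 1L
      sprintf("GO:%07d", counter)
    }
    edge_type <- function() if (stats::runif(1) < part_of_frac) "part_of" else "is_a"
    for (aspect in ASPECTS) {
      root <- next_id()
      ids <- c(ids, root)
      nm <- c(nm, ASPECT_TO_NAMESPACE[[aspect]])
      asp <- c(asp, aspect)
      parents[[root]] <- character()
      level_ids <- list(root)
      by_depth <- list(root)
      for (d in seq_len(depth)) {
        new_level <- character()
        for (parent in by_depth[[d]]) {
          for (b in seq_len(branching)) {
            id <- next_id()
            ids <- c(ids, id)
            nm <- c(nm, paste0("term ", id))
            asp <- c(asp, aspect)
            pv <- stats::setNames(edge_type(), parent)
            parents[[id]] <- pv
            new_level <- c(new_level, id)
          }
        }
        by_depth[[d + 1L]] <- new_level
      }
      # diamond parents: extra edge from a shallower non-ancestor term
      aspect_terms <- unlist(by_depth, use.names = FALSE)
      term_depth <- rep(seq_along(by_depth) - 1L,
                        vapply(by_depth, length, 1L))
      names(term_depth) <- aspect_terms
      deep <- aspect_terms[term_depth >= 2L]
      n_extra <- round(diamond_frac * length(deep))
      if (n_extra > 0L) {
        for (id in sample(deep, n_extra)) {
          anc <- character()
          cur <- names(parents[[id]])
          while (length(cur)) {
            anc <- union(anc, cur)
            cur <- unique(unlist(lapply(cur, function(x) names(parents[[x]])),
                                 use.names = FALSE))
          }
          cand <- setdiff(aspect_terms[term_depth < term_depth[[id]]],
                          c(anc, id))
          if (length(cand) == 0L) next
          extra <- if (length(cand) == 1L) cand else sample(cand, 1L)
          parents[[id]][extra] <- edge_type()
        }
      }
    }
    new_ontology_dag(ids, nm, asp, rep(FALSE, length(ids)), parents)
  })
}

#' Serialize an ontology to OBO format
#'
#' Deterministic (terms sorted by id), so identical DAGs produce
#' byte-identical files.
#'
#' @param dag an \code{ontology_dag}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_obo <- function(dag, path) {
  out <- c("format-version: 1.2", "ontology: synthetic-toy")
  for (id in sort(dag$terms)) {
    out <- c(out, "", "[Term]",
             paste0("id: ", id),
             paste0("name: ", dag$name[[id]]),
             paste0("namespace: ", ASPECT_TO_NAMESPACE[[dag$aspect[[id]]]]))
    pv <- dag$parents[[id]]
    for (p in sort(names(pv))) {
      out <- c(out, if (pv[[p]] == "is_a") paste0("is_a: ", p)
               else paste0("relationship: part_of ", p))
    }
    if (isTRUE(dag$obsolete[[id]])) out <- c(out, "is_obsolete: true")
  }
  writeLines(out, path)
  invisible(path)
}

#' Serialize an annotation set to GAF 2.2
#'
#' @param annot an \code{annotation_set}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gaf <- function(annot, path) {
  d <- annot$direct[order(annot$direct$protein, annot$direct$term,
                          annot$direct$evidence), , drop = FALSE]
  aspect_letter <- c(BP = "P", MF = "F", CC = "C")
  rows <- sprintf("SYN\t%s\t%s\t\t%s\tSYN_REF:0000001\t%s\t\t%s\t\t\tprotein\ttaxon:0\t20130101\tSYN\t\t",
                  d$protein, d$protein, d$term, d$evidence,
                  aspect_letter[d$aspect])
  writeLines(c("!gaf-version: 2.2", rows), path)
  invisible(path)
}

# Terms of an aspect lying in the deepest third of the DAG (used for
# informative, high-IC annotations), plus the full aspect term list.
aspect_term_pools <- function(dag, aspect) {
  depth <- term_depths(dag, aspect)
  cut <- max(depth) * 2 / 3
  list(all = names(depth)[depth > 0],        # exclude the root itself
       deep = names(depth)[depth >= cut])
}

random_ec <- function(n) sample(c("IDA", "IMP", "ISS", "TAS", "IEA"), n,
                                replace = TRUE)

new_benchmark <- function(dag, annot, pm, net, positives, negatives, seed,
                          params) {
  pairs <- rbind(positives, negatives)
  labels <- c(rep(1L, nrow(positives)), rep(-1L, nrow(negatives)))
  structure(list(dag = dag, annot = annot, pm = pm, net = net,
                 positives = positives, negatives = negatives,
                 gold = list(pairs = pairs, labels = labels),
                 seed = seed, params = params),
            class = "synthetic_benchmark")
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  cat("synthetic_benchmark (", x$params$mode, "): ",
      length(x$net$nodes), " proteins, ",
      nrow(x$positives), " positives, ", nrow(x$negatives),
      " negatives (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Synthetic co-complex gold standard
#'
#' Emulates a complex-derived interaction benchmark: proteins are
#' partitioned into disjoint complexes rendered as full cliques (matrix
#' model), positives are all within-complex pairs, and negatives are
#' degree-preserving sampled pairs, which are necessarily cross-complex.
#' Proteins of a complex share a deep cellular-component signature term
#' with probability \code{annotation_coherence} and carry random BP/MF
#' terms; pathway membership is correlated with the complexes.  Because the
#' network is a disjoint union of cliques, any cross-complex pair has no
#' common neighbors and all three topological similarities are exactly 0.
#'
#' @param n_complexes number of complexes (>= 2).
#' @param size_range integer range (min, max) of complex sizes, sampled
#'   uniformly.
#' @param annotation_coherence probability in [0, 1] that a member carries
#'   its complex's signature annotations/pathway.
#' @param seed RNG seed.
#' @return a \code{synthetic_benchmark}: list with \code{dag},
#'   \code{annot}, \code{pm}, \code{net}, \code{positives},
#'   \code{negatives}, \code{gold}, \code{seed}, \code{params}.
#' @export
make_cocomplex_benchmark <- function(n_complexes = 30L, size_range = c(5L, 10L),
                                     annotation_coherence = 0.9, seed = 42L) {
  stopifnot(n_complexes >= 2L, size_range[1L] >= 2L)
  dag <- make_toy_ontology(branching = 3L, depth = 4L, diamond_frac = 0.1,
                           seed = seed + 101L)
  with_seed(seed, {
    size_pool <- seq.int(size_range[1L], size_range[2L])
    sizes <- size_pool[sample.int(length(size_pool), n_complexes,
                                  replace = TRUE)]
    n_prot <- sum(sizes)
    proteins <- sprintf("P%04d", seq_len(n_prot))
    complex_of <- rep(seq_len(n_complexes), sizes)
    members <- split(proteins, complex_of)

    edges <- do.call(rbind, lapply(members, function(m) {
      cmb <- utils::combn(m, 2L)
      data.frame(protein_a = cmb[1L, ], protein_b = cmb[2L, ],
                 stringsAsFactors = FALSE)
    }))
    rownames(edges) <- NULL
    net <- ppi_network(edges, nodes = proteins)
    positives <- edges

    pools <- lapply(ASPECTS, function(a) aspect_term_pools(dag, a))
    names(pools) <- ASPECTS
    sig_cc <- sample(pools$CC$deep, n_complexes, replace = TRUE)
    pathways <- sprintf("pw%03d", seq_len(n_complexes))
    noise_pw <- sprintf("pwx%02d", 1:5)

    rows <- list()
    pw_rows <- list()
    for (k in seq_len(n_complexes)) {
      for (prot in members[[k]]) {
        cc <- if (stats::runif(1) < annotation_coherence) sig_cc[[k]] else
          sample(pools$CC$all, 1L)
        bp <- sample(pools$BP$all, sample(1:2, 1L))
        mf <- sample(pools$MF$all, sample(1:2, 1L))
        terms <- c(cc, bp, mf)
        rows[[length(rows) + 1L]] <-
          data.frame(protein = prot, term = terms,
                     evidence = random_ec(length(terms)),
                     stringsAsFactors = FALSE)
        pw <- character()
        if (stats::runif(1) < annotation_coherence) pw <- pathways[[k]]
        if (stats::runif(1) < 0.2) pw <- c(pw, sample(noise_pw, 1L))
        if (length(pw))
          pw_rows[[length(pw_rows) + 1L]] <-
            data.frame(protein = prot, pathway = pw, stringsAsFactors = FALSE)
      }
    }
    annot <- annotation_set(do.call(rbind, rows), dag)
    pm <- pathway_membership(do.call(rbind, pw_rows))
    negatives <- sample_negatives(positives, seed = seed + 1L)
    new_benchmark(dag, annot, pm, net, positives, negatives, seed,
                  list(mode = "cocomplex", n_complexes = n_complexes,
                       size_range = size_range,
                       annotation_coherence = annotation_coherence))
  })
}

#' Synthetic binary-interaction gold standard
#'
#' Emulates a binary (pairwise-measured) interaction benchmark.  The
#' network grows by duplication-divergence (each new protein attaches to a
#' random anchor and copies each of the anchor's neighbors with probability
#' \code{p_copy}, so neighborhoods overlap), then random edges are added or
#' removed to reach exactly \code{n_interactions}.  Interacting pairs share
#' a deep biological-process term with probability
#' \code{annotation_coherence}; MF and CC sharing is weaker (0.3 x), and
#' pathway co-membership is enriched on edges.  Defaults mirror a published
#' binary yeast gold standard of 1263 interactions among 1078 proteins
#' (mean degree about 2.34).
#'
#' @param n_proteins number of proteins.
#' @param n_interactions number of interactions (edges).
#' @param annotation_coherence probability that an interacting pair shares
#'   a deep BP term.
#' @param p_copy neighbor-copy probability of the growth model.
#' @param seed RNG seed.
#' @return a \code{synthetic_benchmark}.
#' @export
make_binary_benchmark <- function(n_proteins = 1078L, n_interactions = 1263L,
                                  annotation_coherence = 0.8, p_copy = 0.25,
                                  seed = 1L) {
  stopifnot(n_proteins >= 4L)
  if (n_interactions > choose(n_proteins, 2L))
    stop("n_interactions exceeds the number of available pairs")
  if (n_interactions < 1L) stop("n_interactions must be >= 1")
  dag <- make_toy_ontology(branching = 3L, depth = 4L, diamond_frac = 0.1,
                           seed = seed + 101L)
  with_seed(seed, {
    proteins <- sprintf("P%04d", seq_len(n_proteins))
    ekeys <- new.env(parent = emptyenv())
    ea <- character()
    eb <- character()
    add_edge <- function(a, b) {
      if (a == b) return(FALSE)
      k <- pair_key(a, b)
      if (!is.null(ekeys[[k]])) return(FALSE)
      ekeys[[k]] <- TRUE
      ea <<- c(ea, a)
      eb <<- c(eb, b)
      TRUE
    }
    adj <- lapply(proteins, function(p) character())
    names(adj) <- proteins
    link <- function(a, b) {
      if (add_edge(a, b)) {
        adj[[a]] <<- c(adj[[a]], b)
        adj[[b]] <<- c(adj[[b]], a)
      }
    }
    link(proteins[1L], proteins[2L])
    link(proteins[2L], proteins[3L])
    link(proteins[1L], proteins[3L])
    for (k in 4:n_proteins) {
      v <- proteins[[k]]
      anchor <- sample(proteins[seq_len(k - 1L)], 1L)
      link(v, anchor)
      for (nb in adj[[anchor]]) {
        if (nb != v && stats::runif(1) < p_copy) link(v, nb)
      }
    }
    # adjust to the exact edge count
    while (length(ea) > n_interactions) {
      drop <- sample(length(ea), 1L)
      ekeys[[pair_key(ea[[drop]], eb[[drop]])]] <- NULL
      ea <- ea[-drop]
      eb <- eb[-drop]
    }
    while (length(ea) < n_interactions) {
      cand <- sample(proteins, 2L)
      add_edge(cand[[1L]], cand[[2L]])
    }
    edges <- data.frame(protein_a = pmin(ea, eb), protein_b = pmax(ea, eb),
                        stringsAsFactors = FALSE)
    net <- ppi_network(edges, nodes = proteins)
    positives <- network_edges(net)

    pools <- lapply(ASPECTS, function(a) aspect_term_pools(dag, a))
    names(pools) <- ASPECTS
    rows <- list()
    for (prot in proteins) {
      terms <- c(sample(pools$BP$all, sample(1:2, 1L)),
                 sample(pools$MF$all, 1L),
                 sample(pools$CC$all, 1L))
      rows[[length(rows) + 1L]] <-
        data.frame(protein = prot, term = terms,
                   evidence = random_ec(length(terms)),
                   stringsAsFactors = FALSE)
    }
    weak <- 0.3 * annotation_coherence
    for (k in seq_len(nrow(positives))) {
      a <- positives$protein_a[[k]]
      b <- positives$protein_b[[k]]
      shared <- character()
      if (stats::runif(1) < annotation_coherence)
        shared <- sample(pools$BP$deep, 1L)
      if (stats::runif(1) < weak) shared <- c(shared, sample(pools$MF$deep, 1L))
      if (stats::runif(1) < weak) shared <- c(shared, sample(pools$CC$deep, 1L))
      if (length(shared)) {
        rows[[length(rows) + 1L]] <-
          data.frame(protein = rep(c(a, b), each = length(shared)),
                     term = rep(shared, 2L),
                     evidence = random_ec(2L * length(shared)),
                     stringsAsFactors = FALSE)
      }
    }
    annot <- annotation_set(do.call(rbind, rows), dag)

    pathways <- sprintf("pw%03d", seq_len(max(2L, n_proteins %/% 20L)))
    pw_rows <- list()
    for (prot in proteins) {
      n_pw <- sample(0:2, 1L)
      if (n_pw > 0L)
        pw_rows[[length(pw_rows) + 1L]] <-
          data.frame(protein = prot,
                     pathway = sample(pathways, n_pw),
                     stringsAsFactors = FALSE)
    }
    for (k in seq_len(nrow(positives))) {
      if (stats::runif(1) < 0.4) {
        pw <- sample(pathways, 1L)
        pw_rows[[length(pw_rows) + 1L]] <-
          data.frame(protein = c(positives$protein_a[[k]],
                                 positives$protein_b[[k]]),
                     pathway = pw, stringsAsFactors = FALSE)
      }
    }
    pm <- pathway_membership(do.call(rbind, pw_rows))
    negatives <- sample_negatives(positives, seed = seed + 1L)
    new_benchmark(dag, annot, pm, net, positives, negatives, seed,
                  list(mode = "binary", n_proteins = n_proteins,
                       n_interactions = n_interactions,
                       annotation_coherence = annotation_coherence,
                       p_copy = p_copy))
  })
}

#' Write a synthetic benchmark to plain-text files
#'
#' Writes \code{ontology.obo}, \code{annotations.gaf}, \code{pathways.tsv},
#' \code{network.tsv}, \code{gold_positives.tsv}, \code{gold_negatives.tsv}
#' and \code{params.json} into \code{dir}; all files round-trip through the
#' package parsers.
#'
#' @param bench a \code{synthetic_benchmark}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_obo(bench$dag, file.path(dir, "ontology.obo"))
  write_gaf(bench$annot, file.path(dir, "annotations.gaf"))
  pw <- bench$pm$pathways
  pw_df <- data.frame(protein = rep(names(pw), lengths(pw)),
                      pathway = unlist(pw, use.names = FALSE))
  pw_df <- pw_df[order(pw_df$protein, pw_df$pathway), , drop = FALSE]
  utils::write.table(pw_df, file.path(dir, "pathways.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_pairs <- function(df, file)
    utils::write.table(df[order(df$protein_a, df$protein_b), , drop = FALSE],
                       file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  write_pairs(network_edges(bench$net), "network.tsv")
  write_pairs(bench$positives, "gold_positives.tsv")
  write_pairs(bench$negatives, "gold_negatives.tsv")
  jsonlite::write_json(c(bench$params, list(seed = bench$seed)),
                       file.path(dir, "params.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}
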