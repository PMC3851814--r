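# Fixtures are built in code at test time; no data files.

# 3-term is_a chain r <- a <- b with proteins P1:{b}, P2:{a}, P3:{r}.
chain_fixture <- function() {
  obo <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: biological_process",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: a", "namespace: biological_process",
    "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000003", "name: b", "namespace: biological_process",
    "is_a: GO:0000002"), obo)
  dag <- parse_obo(obo)
  gaf <- tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.2",
               gaf_row("P1", "GO:0000003", "IDA"),
               gaf_row("P2", "GO:0000002", "IDA"),
               gaf_row("P3", "GO:0000001", "IDA")), gaf)
  annot <- parse_gaf(gaf, dag)
  list(dag = dag, annot = annot, r = "GO:0000001", a = "GO:0000002",
       b = "GO:0000003")
}

gaf_row <- function(protein, term, evidence, qualifier = "") {
  paste("SYN", protein, protein, qualifier, term, "SYN_REF:1", evidence,
        "", "P", "", "", "protein", "taxon:0", "20130101", "SYN", "", "",
        sep = "\t")
}

# Complete graph on 4 proteins.
k4_network <- function() {
  ppi_network(t(utils::combn(c("a", "b", "c", "d"), 2L)))
}

# Star with a center and n leaves.
star_network <- function(n_leaves = 5L) {
  leaves <- paste0("x", seq_len(n_leaves))
  ppi_network(data.frame(a = "c", b = leaves))
}

# Random small single-aspect DAG written as OBO and parsed back; term i >= 2
# picks 1-2 parents among earlier terms, with random edge types.
random_dag <- function(n_terms, seed, p_two_parents = 0.4) {
  set.seed(seed)
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  lines <- c("format-version: 1.2", "",
             "[Term]", paste0("id: ", ids[[1L]]),
             "name: biological_process", "namespace: biological_process")
  for (i in seq(2L, n_terms)) {
    k <- if (i > 2L && stats::runif(1) < p_two_parents) 2L else 1L
    ps <- sample(seq_len(i - 1L), min(k, i - 1L))
    lines <- c(lines, "", "[Term]", paste0("id: ", ids[[i]]),
               paste0("name: t", i), "namespace: biological_process")
    for (p in ps) {
      if (stats::runif(1) < 0.3) {
        lines <- c(lines, paste0("relationship: part_of ", ids[[p]]))
      } else {
        lines <- c(lines, paste0("is_a: ", ids[[p]]))
      }
    }
  }
  obo <- tempfile(fileext = ".obo")
  writeLines(lines, obo)
  parse_obo(obo)
}

# --- independent oracles -------------------------------------------------

# Wang semantic contributions by exhaustive upward-path enumeration:
# S_t(a) = max over all directed paths t -> a of the product of edge weights.
oracle_wang_svalues <- function(dag, t, w_is_a = 0.8, w_part_of = 0.6) {
  w <- c(is_a = w_is_a, part_of = w_part_of)
  best <- new.env(parent = emptyenv())
  walk <- function(node, acc) {
    prev <- best[[node]]
    if (is.null(prev) || acc > prev) best[[node]] <- acc
    pv <- dag$parents[[node]]
    for (p in names(pv)) walk(p, acc * w[[pv[[p]]]])
  }
  walk(t, 1)
  unlist(as.list(best))
}

oracle_wang_term_sim <- function(dag, m, n, w_is_a = 0.8, w_part_of = 0.6) {
  sm <- oracle_wang_svalues(dag, m, w_is_a, w_part_of)
  sn <- oracle_wang_svalues(dag, n, w_is_a, w_part_of)
  shared <- intersect(names(sm), names(sn))
  sum(sm[shared] + sn[shared]) / (sum(sm) + sum(sn))
}

# AUC by exhaustive positive-negative pair counting with half credit for ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels > 0]
  neg <- scores[labels <= 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Ancestor set by plain unmemoized DFS over parent edges.
oracle_ancestors <- function(dag, id) {
  seen <- character()
  stack <- names(dag$parents[[id]])
  while (length(stack)) {
    x <- stack[[1L]]
    stack <- stack[-1L]
    if (x %in% seen) next
    seen <- c(seen, x)
    stack <- c(stack, names(dag$parents[[x]]))
  }
  seen
}

# Reachability matrix (including self) by repeated boolean matrix squaring.
oracle_reachability <- function(dag) {
  n <- length(dag$terms)
  adj <- matrix(FALSE, n, n, dimnames = list(dag$terms, dag$terms))
  for (id in dag$terms) adj[id, names(dag$parents[[id]])] <- TRUE
  reach <- adj | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}

# Common-neighbor statistics straight from an adjacency matrix.
oracle_topology <- function(net, i, j) {
  n <- length(net$nodes)
  a <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  for (v in net$nodes) a[v, net$adj[[v]]] <- 1L
  common <- names(which(a[i, ] == 1L & a[j, ] == 1L))
  deg <- rowSums(a)
  list(jaccard = if (sum(a[i, ] | a[j, ]) == 0) 0 else
         length(common) / sum(a[i, ] == 1L | a[j, ] == 1L),
       aa = sum(1 / log(deg[common])),
       ra = sum(1 / deg[common]))
}
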