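# Link-prediction similarities on the PPI graph: Jaccard neighborhood
# overlap, Adamic-Adar and resource allocation, all over common neighbors
# of a protein pair in a simple undirected network.

#' Construct a PPI network from an edge table
#'
#' Symmetrizes the edge list, silently dropping self-loops and duplicate
#' edges (counts are reported via \code{message}).
#'
#' @param edges data.frame or 2-column matrix of protein-id pairs.
#' @param nodes optional character vector of node ids to include even when
#'   isolated.
#' @return an object of class \code{ppi_network}: list with \code{nodes}
#'   and \code{adj}, a named list of neighbor-id vectors.
#' @export
ppi_network <- function(edges, nodes = NULL) {
  e <- as_pair_df(edges)
  n0 <- nrow(e)
  self <- e$protein_a == e$protein_b
  e <- e[!self, , drop = FALSE]
  dup <- duplicated(pair_key(e$protein_a, e$protein_b))
  e <- e[!dup, , drop = FALSE]
  if (sum(self) || sum(dup))
    message("dropped ", sum(self), " self-loop(s) and ", sum(dup),
            " duplicate edge(s) of ", n0, " input line(s)")
  nodes <- sort(unique(c(e$protein_a, e$protein_b, nodes)))
  adj <- lapply(nodes, function(n) character())
  names(adj) <- nodes
  for (k in seq_len(nrow(e))) {
    a <- e$protein_a[[k]]
    b <- e$protein_b[[k]]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj <- lapply(adj, function(x) sort(unique(x)))
  structure(list(nodes = nodes, adj = adj), class = "ppi_network")
}

#' Load a PPI edge list from a TSV file
#'
#' Two whitespace-separated protein ids per line; \code{#} comment lines
#' allowed.  An empty file yields an empty network.
#'
#' @param path path to the edge-list file.
#' @return a \code{ppi_network}.
#' @export
load_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  idx <- which(keep)
  if (length(idx) == 0L)
    return(structure(list(nodes = character(), adj = list()),
                     class = "ppi_network"))
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  ok <- vapply(fields, length, 1L) == 2L
  if (!all(ok))
    stop("edge-list line ", idx[which(!ok)[1L]], " does not have two fields")
  ppi_network(data.frame(a = vapply(fields, `[[`, "", 1L),
                         b = vapply(fields, `[[`, "", 2L),
                         stringsAsFactors = FALSE))
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("ppi_network:", length(x$nodes), "nodes,",
      sum(vapply(x$adj, length, 1L)) / 2, "edges\n")
  invisible(x)
}

#' Network edges as a pair table
#'
#' @param net a \code{ppi_network}.
#' @return data.frame(protein_a, protein_b), each undirected edge once.
#' @export
network_edges <- function(net) {
  a <- rep(names(net$adj), vapply(net$adj, length, 1L))
  b <- unlist(net$adj, use.names = FALSE)
  keep <- a < b
  data.frame(protein_a = a[keep], protein_b = b[keep],
             stringsAsFactors = FALSE)
}

#' Node degrees
#'
#' @param net a \code{ppi_network}.
#' @return named integer vector of degrees.
#' @export
network_degrees <- function(net) {
  vapply(net$adj, length, 1L)
}

check_node <- function(net, i) {
  if (!(i %in% net$nodes)) stop("unknown protein in network: ", i)
}

pair_neighborhoods <- function(net, i, j, mask_edge = FALSE) {
  check_node(net, i)
  check_node(net, j)
  ni <- net$adj[[i]]
  nj <- net$adj[[j]]
  if (mask_edge) {
    ni <- setdiff(ni, j)
    nj <- setdiff(nj, i)
  }
  list(ni = ni, nj = nj)
}

#' Jaccard neighborhood similarity
#'
#' \eqn{|N(i) \cap N(j)| / |N(i) \cup N(j)|}; 0 when both neighborhoods are
#' empty.
#'
#' @param net a \code{ppi_network}.
#' @param i,j protein ids present in the network.
#' @param mask_edge drop the edge (i, j) itself, if present, before taking
#'   neighborhoods (leave-one-out variant).
#' @return similarity in [0, 1].
#' @export
jaccard_sim <- function(net, i, j, mask_edge = FALSE) {
  nb <- pair_neighborhoods(net, i, j, mask_edge)
  u <- union(nb$ni, nb$nj)
  if (length(u) == 0L) return(0)
  length(intersect(nb$ni, nb$nj)) / length(u)
}

#' Adamic-Adar similarity
#'
#' \eqn{\sum_{n \in N(i) \cap N(j)} 1 / \log k_n}, down-weighting
#' high-degree common neighbors.  Natural log by default; a common neighbor
#' necessarily has degree >= 2, so every term is finite.
#'
#' @inheritParams jaccard_sim
#' @param base logarithm base.
#' @return non-negative real.
#' @export
adamic_adar_sim <- function(net, i, j, mask_edge = FALSE, base = exp(1)) {
  nb <- pair_neighborhoods(net, i, j, mask_edge)
  common <- intersect(nb$ni, nb$nj)
  if (length(common) == 0L) return(0)
  deg <- vapply(net$adj[common], length, 1L)
  sum(1 / log(deg, base = base))
}

#' Resource-allocation similarity
#'
#' \eqn{\sum_{n \in N(i) \cap N(j)} 1 / k_n}: common neighbors act as
#' resource transmitters splitting one unit among their neighbors.
#'
#' @inheritParams jaccard_sim
#' @return non-negative real.
#' @export
resource_allocation_sim <- function(net, i, j, mask_edge = FALSE) {
  nb <- pair_neighborhoods(net, i, j, mask_edge)
  common <- intersect(nb$ni, nb$nj)
  if (length(common) == 0L) return(0)
  deg <- vapply(net$adj[common], length, 1L)
  sum(1 / deg)
}
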