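# Co-pathway similarity from a protein -> pathway membership table.

#' Parse a protein-pathway membership table
#'
#' Two-column TSV (protein id, pathway id), one membership per line;
#' duplicates collapse under set semantics.  Lines starting with \code{#}
#' are ignored.
#'
#' @param path path to the TSV file.
#' @return an object of class \code{pathway_membership}: list with
#'   \code{pathways}, a named list protein -> character vector of pathway
#'   ids.
#' @export
parse_pathway_table <- function(path) {
  if (!file.exists(path)) stop("pathway table not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  idx <- which(keep)
  fields <- strsplit(lines[keep], "[ \t]+")
  ok <- vapply(fields, length, 1L) == 2L
  if (!all(ok))
    stop("malformed pathway table line ", idx[which(!ok)[1L]],
         ": expected two fields")
  protein <- vapply(fields, `[[`, "", 1L)
  pathway <- vapply(fields, `[[`, "", 2L)
  structure(list(pathways = lapply(split(pathway, protein), unique)),
            class = "pathway_membership")
}

#' Pathway membership from a data.frame
#'
#' @param df data.frame with protein ids in column 1 and pathway ids in
#'   column 2.
#' @return a \code{pathway_membership}.
#' @export
pathway_membership <- function(df) {
  structure(list(pathways = lapply(split(as.character(df[[2L]]),
                                         as.character(df[[1L]])), unique)),
            class = "pathway_membership")
}

#' Co-pathway (KEGG-style) similarity
#'
#' Jaccard index of the two proteins' pathway sets:
#' \eqn{|P(i) \cap P(j)| / |P(i) \cup P(j)|}.  When neither protein belongs
#' to any pathway the measure cannot work and \code{NA} is returned; when
#' exactly one set is empty the similarity is 0.
#'
#' @param pm a \code{pathway_membership}.
#' @param i,j protein ids.
#' @return similarity in [0, 1] or \code{NA}.
#' @export
kegg_sim <- function(pm, i, j) {
  pi_ <- pm$pathways[[i]] %||% character()
  pj <- pm$pathways[[j]] %||% character()
  if (length(pi_) == 0L && length(pj) == 0L) return(NA_real_)
  if (length(pi_) == 0L || length(pj) == 0L) return(0)
  length(intersect(pi_, pj)) / length(union(pi_, pj))
}
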