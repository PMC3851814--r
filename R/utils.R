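# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Canonical key for an unordered protein pair.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# Coerce a pair container (data.frame or 2-column matrix) to a
# data.frame(protein_a, protein_b) of character ids.
as_pair_df <- function(pairs) {
  if (is.matrix(pairs)) pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!is.data.frame(pairs) || ncol(pairs) < 2L)
    stop("pairs must be a data.frame or matrix with two id columns")
  out <- data.frame(protein_a = as.character(pairs[[1L]]),
                    protein_b = as.character(pairs[[2L]]),
                    stringsAsFactors = FALSE)
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
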