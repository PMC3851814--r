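# Config-driven end-to-end runs: simulate -> features -> CV -> report.

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML configs require the yaml package; use JSON instead")
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  } else if (is.list(config)) {
    config
  } else {
    stop("config must be a file path or a list")
  }
}

#' Run a configured prediction pipeline
#'
#' Executes the requested stages and writes their outputs plus a JSON
#' report that echoes the full configuration.  The config (a list, or a
#' path to a JSON/YAML file) supports:
#' \describe{
#'   \item{outdir}{output directory (required).}
#'   \item{seed}{integer seed for all stochastic steps (default 1).}
#'   \item{simulate}{list(mode = "cocomplex"/"binary", plus generator
#'     arguments); writes the benchmark files into \code{outdir}.}
#'   \item{inputs}{alternatively, paths: \code{obo}, \code{gaf},
#'     \code{pathways}, \code{network}, \code{positives},
#'     \code{negatives} (optional; sampled when absent).}
#'   \item{evaluate}{list(feature_sets = named list of feature-name
#'     vectors, cv_folds = 10); appends per-set pooled CV AUCs to the
#'     report and writes ROC points as CSV.}
#' }
#' All inputs are validated before anything is written; a missing input
#' file aborts with no partial outputs.
#'
#' @param config list or path to a JSON/YAML config file.
#' @return the report, invisibly (also written to
#'   \code{outdir/report.json}).
#' @export
run_pipeline <- function(config) {
  cfg <- read_config(config)
  if (is.null(cfg$outdir)) stop("config lacks `outdir`")
  seed <- as.integer(cfg$seed %||% 1L)

  # validate everything up front: no partial outputs on bad input
  if (is.null(cfg$simulate)) {
    if (is.null(cfg$inputs)) stop("config needs either `simulate` or `inputs`")
    need <- c("obo", "gaf", "pathways", "network", "positives")
    for (nm in need) {
      path <- cfg$inputs[[nm]]
      if (is.null(path)) stop("config inputs lack `", nm, "`")
      if (!file.exists(path)) stop("input file not found: ", path)
    }
    if (!is.null(cfg$inputs$negatives) && !file.exists(cfg$inputs$negatives))
      stop("input file not found: ", cfg$inputs$negatives)
  } else {
    mode <- cfg$simulate$mode %||% "cocomplex"
    if (!mode %in% c("cocomplex", "binary"))
      stop("unknown simulate mode: ", mode)
  }
  if (!is.null(cfg$evaluate)) {
    fsets <- cfg$evaluate$feature_sets %||% list(all = all_features())
    for (fs in fsets) {
      bad <- setdiff(unlist(fs), all_features())
      if (length(bad)) stop("unknown feature name(s): ",
                            paste(bad, collapse = ", "))
    }
  }

  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package_version = as.character(utils::packageVersion("ppilink")),
                 seed = seed, config = cfg)

  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    bench <- if (identical(sim$mode %||% "cocomplex", "cocomplex")) {
      make_cocomplex_benchmark(
        n_complexes = as.integer(sim$n_complexes %||% 30L),
        size_range = as.integer(unlist(sim$size_range %||% c(5L, 10L))),
        annotation_coherence = sim$annotation_coherence %||% 0.9,
        seed = as.integer(sim$seed %||% seed))
    } else {
      make_binary_benchmark(
        n_proteins = as.integer(sim$n_proteins %||% 1078L),
        n_interactions = as.integer(sim$n_interactions %||% 1263L),
        annotation_coherence = sim$annotation_coherence %||% 0.8,
        seed = as.integer(sim$seed %||% seed))
    }
    write_benchmark(bench, cfg$outdir)
    dag <- bench$dag
    annot <- bench$annot
    pm <- bench$pm
    net <- bench$net
    positives <- bench$positives
    negatives <- bench$negatives
    report$counts <- list(proteins = length(net$nodes),
                          positives = nrow(positives),
                          negatives = nrow(negatives))
  } else {
    dag <- parse_obo(cfg$inputs$obo)
    annot <- parse_gaf(cfg$inputs$gaf, dag)
    pm <- parse_pathway_table(cfg$inputs$pathways)
    net <- load_edge_list(cfg$inputs$network)
    positives <- as_pair_df(utils::read.table(cfg$inputs$positives,
                                              sep = "\t",
                                              stringsAsFactors = FALSE))
    negatives <- if (!is.null(cfg$inputs$negatives))
      as_pair_df(utils::read.table(cfg$inputs$negatives, sep = "\t",
                                   stringsAsFactors = FALSE))
    else sample_negatives(positives, seed = seed)
    report$counts <- list(proteins = length(net$nodes),
                          positives = nrow(positives),
                          negatives = nrow(negatives))
  }

  if (!is.null(cfg$evaluate)) {
    fsets <- cfg$evaluate$feature_sets %||% list(all = all_features())
    folds <- as.integer(cfg$evaluate$cv_folds %||% 10L)
    pairs <- rbind(positives, negatives)
    labels <- c(rep(1L, nrow(positives)), rep(-1L, nrow(negatives)))
    feats <- build_features(pairs, features = unique(unlist(fsets)),
                            dag = dag, annot = annot, pm = pm, net = net)
    results <- list()
    for (nm in names(fsets)) {
      cols <- unlist(fsets[[nm]])
      cv <- cross_validate(feats[, cols, drop = FALSE], labels, k = folds,
                           seed = seed)
      utils::write.csv(cv$roc,
                       file.path(cfg$outdir, paste0("roc_", nm, ".csv")),
                       row.names = FALSE)
      results[[nm]] <- list(auc = cv$auc, n = length(labels),
                            features = cols)
    }
    report$evaluate <- results
  }

  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
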