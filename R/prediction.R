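# Gold-standard assembly, SVM training, cross-validation and ROC/AUC.

#' Degree-preserving negative sampling
#'
#' Draws as many non-interacting pairs as there are positives, over the
#' proteins of the positive set, such that each protein's incidence count
#' among the negatives equals its degree among the positives.  Implemented
#' as seeded edge-stub shuffling with rejection of self-pairs, duplicate
#' pairs and pairs present in the positive set; after
#' \code{max_restarts} failed shuffles the best attempt is returned with a
#' warning (its size may fall short).
#'
#' @param positives data.frame or 2-column matrix of positive pairs.
#' @param seed integer RNG seed; the result is deterministic given the seed.
#' @param max_restarts number of full shuffles to attempt.
#' @return data.frame(protein_a, protein_b) of sampled negative pairs.
#' @export
sample_negatives <- function(positives, seed = 1L, max_restarts = 100L) {
  pos <- as_pair_df(positives)
  if (nrow(pos) == 0L) stop("positive set is empty")
  pos_keys <- pair_key(pos$protein_a, pos$protein_b)
  deg <- table(c(pos$protein_a, pos$protein_b))
  stubs <- rep(names(deg), as.integer(deg))
  n_pairs <- length(stubs) %/% 2L
  bad_pairs <- function(a, b) {
    keys <- pair_key(a, b)
    which(a == b | keys %in% pos_keys |
            duplicated(keys) | duplicated(keys, fromLast = TRUE))
  }
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(max_restarts)) {
      s <- sample(stubs)
      a <- s[seq(1L, by = 2L, length.out = n_pairs)]
      b <- s[seq(2L, by = 2L, length.out = n_pairs)]
      # partner swaps keep the degree multiset while dissolving invalid pairs
      for (sweep in seq_len(200L)) {
        bad <- bad_pairs(a, b)
        if (length(bad) == 0L) break
        j <- sample.int(n_pairs, length(bad), replace = TRUE)
        for (k in seq_along(bad)) {
          i <- bad[[k]]
          jj <- j[[k]]
          if (i == jj) next
          tmp <- b[[i]]
          b[[i]] <- b[[jj]]
          b[[jj]] <- tmp
        }
      }
      bad <- bad_pairs(a, b)
      if (length(bad) == 0L) {
        return(data.frame(protein_a = pmin(a, b), protein_b = pmax(a, b),
                          stringsAsFactors = FALSE))
      }
      keys <- pair_key(a, b)
      valid <- a != b & !duplicated(keys) & !(keys %in% pos_keys)
      if (is.null(best) || sum(valid) > nrow(best)) {
        best <- data.frame(protein_a = pmin(a, b)[valid],
                           protein_b = pmax(a, b)[valid],
                           stringsAsFactors = FALSE)
      }
    }
    warning("degree-preserving sampling did not converge after ",
            max_restarts, " restarts; returning ", nrow(best), " of ",
            n_pairs, " pairs")
    best
  })
}

#' ROC curve and AUC from decision scores
#'
#' The AUC is the Mann-Whitney probability that a random positive outscores
#' a random negative, with half credit for ties; it equals the trapezoidal
#' area under the threshold-swept ROC curve returned alongside.
#'
#' @param scores numeric decision values, larger = more positive.
#' @param labels class labels; positives are values \code{> 0} (e.g. +1/-1).
#' @return an object of class \code{ppi_roc}: list with \code{roc}
#'   (data.frame fpr/tpr from (0,0) to (1,1)) and \code{auc}.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- as.numeric(labels) > 0
  np <- sum(pos)
  nn <- sum(!pos)
  if (np == 0L || nn == 0L) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  grp_last <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  tpr <- c(0, cumsum(p)[grp_last] / np, 1)
  fpr <- c(0, cumsum(!p)[grp_last] / nn, 1)
  roc <- unique(data.frame(fpr = fpr, tpr = tpr))
  rownames(roc) <- NULL
  structure(list(roc = roc, auc = auc), class = "ppi_roc")
}

#' @export
print.ppi_roc <- function(x, ...) {
  cat("ROC with", nrow(x$roc), "points; AUC =", format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' Train the interaction classifier
#'
#' Imputes missing feature values with per-column training medians, drops
#' zero-variance columns (with a warning), standardizes the remainder and
#' fits a C-classification SVM with an RBF kernel at the library defaults
#' (cost 1, gamma = 1/n_features).  Decision values are oriented so that
#' larger means more interaction-like.
#'
#' @param features numeric data.frame or matrix of per-pair features
#'   (\code{NA} = missing).
#' @param labels vector of +1/-1 labels, one per row.
#' @param cost,gamma SVM hyperparameters; \code{gamma = NULL} uses
#'   1/n_features.
#' @param seed RNG seed for the fit.
#' @return an object of class \code{ppi_classifier}.
#' @export
train_ppi_classifier <- function(features, labels, cost = 1, gamma = NULL,
                                 seed = 1L) {
  x <- as.matrix(as.data.frame(features))
  storage.mode(x) <- "double"
  y <- factor(ifelse(as.numeric(labels) > 0, 1L, -1L), levels = c(-1L, 1L))
  if (nlevels(droplevels(y)) < 2L) stop("training data contains a single class")
  if (min(table(y)) < 2L) stop("need at least 2 samples per class")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  medians <- apply(x, 2L, stats::median, na.rm = TRUE)
  if (any(is.na(medians)))
    stop("all-missing feature column(s): ",
         paste(colnames(x)[is.na(medians)], collapse = ", "))
  for (k in seq_len(ncol(x))) x[is.na(x[, k]), k] <- medians[[k]]
  sds <- apply(x, 2L, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    warning("dropped zero-variance feature column(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) == 0L) stop("no informative feature columns left")
  centers <- colMeans(x)
  scales <- apply(x, 2L, stats::sd)
  xs <- scale(x, center = centers, scale = scales)
  gamma <- gamma %||% (1 / ncol(xs))
  model <- with_seed(seed, e1071::svm(xs, y, type = "C-classification",
                                      kernel = "radial", cost = cost,
                                      gamma = gamma, scale = FALSE))
  d <- attr(stats::predict(model, xs, decision.values = TRUE),
            "decision.values")[, 1L]
  flip <- if (mean(d[y == 1L]) >= mean(d[y == -1L])) 1 else -1
  structure(list(model = model, feature_names = names(medians),
                 kept = colnames(x), medians = medians, centers = centers,
                 scales = scales, flip = flip, cost = cost, gamma = gamma),
            class = "ppi_classifier")
}

#' @export
print.ppi_classifier <- function(x, ...) {
  cat("ppi_classifier: RBF SVM on", length(x$kept), "feature(s), cost",
      x$cost, ", gamma", format(x$gamma, digits = 4), "\n")
  invisible(x)
}

#' Decision values for new feature rows
#'
#' Missing entries are imputed with the training medians (never with query
#' statistics), columns are standardized with the training statistics, and
#' the signed decision value of the SVM is returned (positive = predicted
#' interaction).
#'
#' @param clf a \code{ppi_classifier}.
#' @param features data.frame or matrix with exactly the training feature
#'   columns.
#' @return numeric vector of decision values.
#' @export
decision_values <- function(clf, features) {
  x <- as.matrix(as.data.frame(features))
  storage.mode(x) <- "double"
  if (is.null(colnames(x)) && ncol(x) == length(clf$feature_names))
    colnames(x) <- clf$feature_names
  if (!identical(sort(colnames(x)), sort(clf$feature_names)))
    stop("feature columns do not match the training configuration")
  x <- x[, clf$feature_names, drop = FALSE]
  for (k in colnames(x)) x[is.na(x[, k]), k] <- clf$medians[[k]]
  x <- x[, clf$kept, drop = FALSE]
  xs <- scale(x, center = clf$centers, scale = clf$scales)
  if (nrow(xs) == 0L) return(numeric())
  d <- attr(stats::predict(clf$model, xs, decision.values = TRUE),
            "decision.values")[, 1L]
  unname(d * clf$flip)
}

#' Score query pairs and flag predicted non-interactions
#'
#' Query pairs whose decision value falls below \code{threshold} are flagged
#' as predicted false positives (label -1); candidate pairs scored above the
#' threshold are predicted interactions (+1), which for non-edges amounts to
#' recovering false negatives.
#'
#' @param clf a \code{ppi_classifier}.
#' @param query_features data.frame with columns \code{protein_a},
#'   \code{protein_b} and the training feature columns.
#' @param threshold decision-value cut (default 0).
#' @return data.frame(protein_a, protein_b, score, label).
#' @export
predict_query <- function(clf, query_features, threshold = 0) {
  stopifnot(all(c("protein_a", "protein_b") %in% names(query_features)))
  feats <- query_features[, setdiff(names(query_features),
                                    c("protein_a", "protein_b")),
                          drop = FALSE]
  if (nrow(feats) == 0L)
    return(data.frame(protein_a = character(), protein_b = character(),
                      score = numeric(), label = integer(),
                      stringsAsFactors = FALSE))
  d <- decision_values(clf, feats)
  data.frame(protein_a = query_features$protein_a,
             protein_b = query_features$protein_b,
             score = d, label = ifelse(d >= threshold, 1L, -1L),
             stringsAsFactors = FALSE)
}

#' Stratified k-fold cross-validation of the interaction classifier
#'
#' Assigns samples to folds stratified by class under a fixed seed, trains
#' on each training split and scores the held-out fold, so every sample is
#' scored exactly once by a model not trained on it.  Pooled scores yield
#' the ROC curve and AUC; per-fold AUCs are also reported.
#'
#' @inheritParams train_ppi_classifier
#' @param k number of folds (default 10).
#' @return an object of class \code{ppi_cv}: list with \code{fold}
#'   (assignments), \code{scores} (pooled decision values), \code{labels},
#'   \code{roc}, \code{auc} and \code{fold_auc}.
#' @export
cross_validate <- function(features, labels, k = 10L, seed = 1L,
                           cost = 1, gamma = NULL) {
  x <- as.data.frame(features)
  y <- ifelse(as.numeric(labels) > 0, 1L, -1L)
  n <- nrow(x)
  if (n < k) stop("need at least k samples")
  fold <- integer(n)
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  scores <- numeric(n)
  for (f in seq_len(k)) {
    test <- fold == f
    if (!any(test)) next
    if (length(unique(y[!test])) < 2L)
      stop("a training split lost one class; use fewer folds")
    clf <- train_ppi_classifier(x[!test, , drop = FALSE], y[!test],
                                cost = cost, gamma = gamma, seed = seed + f)
    scores[test] <- decision_values(clf, x[test, , drop = FALSE])
  }
  r <- roc_auc(scores, y)
  fold_auc <- vapply(seq_len(k), function(f) {
    if (length(unique(y[fold == f])) < 2L) return(NA_real_)
    roc_auc(scores[fold == f], y[fold == f])$auc
  }, 1.0)
  structure(list(fold = fold, scores = scores, labels = y,
                 roc = r$roc, auc = r$auc, fold_auc = fold_auc, k = k),
            class = "ppi_cv")
}

#' @export
print.ppi_cv <- function(x, ...) {
  cat(x$k, "-fold CV: pooled AUC = ", format(x$auc, digits = 4), "\n", sep = "")
  invisible(x)
}
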