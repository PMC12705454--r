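## CTS gene-panel derivation and random-forest classification: one-vs-all
## Kruskal-Wallis gene ranking, tenfold cross-validated panel-size selection,
## final forest fit with out-of-bag diagnostics, posterior prediction.

#' Kruskal-Wallis test on a list of groups
#'
#' Rank-based H statistic with tie correction; p from a chi-squared
#' distribution with (number of groups - 1) degrees of freedom. Delegates to
#' \code{stats::kruskal.test}.
#'
#' @param groups List of >= 2 numeric vectors (all non-empty; total n >= 3).
#' @return List with \code{H} and \code{p}.
#' @export
kruskal_wallis <- function(groups) {
  stop_if(length(groups) < 2, "need >= 2 groups")
  stop_if(any(lengths(groups) == 0), "empty group")
  stop_if(sum(lengths(groups)) < 3, "need total n >= 3")
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p = kt$p.value)
}

## Vectorized one-vs-all Kruskal-Wallis over the rows of a matrix.
## `ranks` are row-wise midranks of the expression matrix; `in_group` is a
## logical sample vector. Tie correction depends on the gene only.
kw_rows_binary <- function(ranks, in_group, tie_correction) {
  n <- ncol(ranks)
  n1 <- sum(in_group)
  n2 <- n - n1
  R1 <- rowSums(ranks[, in_group, drop = FALSE])
  R2 <- n * (n + 1) / 2 - R1
  H <- (12 / (n * (n + 1))) * (R1^2 / n1 + R2^2 / n2) - 3 * (n + 1)
  H <- H / tie_correction
  H[!is.finite(H)] <- 0           # constant genes: no separation
  p <- stats::pchisq(H, df = 1, lower.tail = FALSE)
  list(H = H, p = p)
}

#' Rank genes by one-vs-all Kruskal-Wallis significance
#'
#' For each gene and each CTS, tests the gene's expression in that CTS
#' against all other samples; genes are ordered by their best (smallest)
#' one-vs-all p-value, ties broken by the largest H, then lexicographically.
#' Constant genes rank last.
#'
#' @param expr Genes x samples matrix.
#' @param cts_labels Per-sample CTS labels (>= 2 classes).
#' @param top_n Ranking truncated to this many genes (default 5000).
#' @return A \code{gene_ranking}: data frame with \code{gene}, per-class
#'   \code{H_<class>} and \code{p_<class>}, \code{min_p}, \code{max_H},
#'   ordered by rank.
#' @export
rank_genes <- function(expr, cts_labels, top_n = 5000) {
  check_expression(expr)
  stop_if(length(cts_labels) != ncol(expr),
          "'cts_labels' must have one entry per sample")
  cts_labels <- droplevels(as.factor(cts_labels))
  stop_if(nlevels(cts_labels) < 2, "labels must cover >= 2 CTSs")

  n <- ncol(expr)
  ranks <- t(apply(expr, 1, rank))
  tie_correction <- apply(expr, 1, function(x) {
    t <- table(x)
    1 - sum(t^3 - t) / (n^3 - n)
  })

  out <- data.frame(gene = rownames(expr), stringsAsFactors = FALSE)
  for (cl in levels(cts_labels)) {
    kw <- kw_rows_binary(ranks, cts_labels == cl, tie_correction)
    out[[paste0("H_", cl)]] <- kw$H
    out[[paste0("p_", cl)]] <- kw$p
  }
  pcols <- grep("^p_", names(out))
  hcols <- grep("^H_", names(out))
  out$min_p <- do.call(pmin, out[pcols])
  out$max_H <- do.call(pmax, out[hcols])
  out <- out[order(out$min_p, -out$max_H, out$gene), , drop = FALSE]
  out <- utils::head(out, top_n)
  rownames(out) <- NULL
  class(out) <- c("gene_ranking", "data.frame")
  out
}

## Stratified fold assignment: within each class, samples are shuffled and
## folds dealt round-robin. Deterministic given the seed.
stratified_folds <- function(labels, folds, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

#' Cross-validated panel-size selection
#'
#' Stratified tenfold cross-validation over a grid of panel sizes. Within
#' each training fold the gene ranking is recomputed (avoiding selection
#' leakage) and a random forest is trained on the top-ranked genes of each
#' size; misclassification rate, multiclass Brier score and average
#' correct-class probability are accumulated over held-out folds. The
#' selected size is the smallest whose CV error is below
#' \code{error_threshold}; if none qualifies, the best size is returned with
#' a warning.
#'
#' @param expr Genes x samples matrix (typically core samples only).
#' @param labels Per-sample CTS labels; every class needs >= \code{folds}
#'   members.
#' @param grid Panel sizes to evaluate.
#' @param folds Number of CV folds.
#' @param n_trees Trees per forest.
#' @param error_threshold CV misclassification threshold for selection.
#' @param seed Integer seed (fold assignment and forests).
#' @return A \code{cv_report}: data frame \code{table} (size, cv_error,
#'   brier, avg_correct_prob), \code{selected} size, \code{folds},
#'   \code{seed}.
#' @export
cv_panel_selection <- function(expr, labels, grid = c(seq(2, 30, by = 2), 40, 50),
                               folds = 10, n_trees = 500,
                               error_threshold = 0.05, seed = 1L) {
  check_expression(expr)
  labels <- droplevels(as.factor(labels))
  stop_if(any(table(labels) < folds),
          "every class needs at least 'folds' members")
  grid <- sort(unique(pmin(grid, nrow(expr))))
  fold <- stratified_folds(labels, folds, seed)

  n <- ncol(expr)
  classes <- levels(labels)
  miss <- matrix(0, nrow = length(grid), ncol = folds)
  brier <- matrix(0, nrow = length(grid), ncol = folds)
  cprob <- matrix(0, nrow = length(grid), ncol = folds)
  nfold <- integer(folds)

  for (f in seq_len(folds)) {
    test <- fold == f
    nfold[f] <- sum(test)
    ranking <- rank_genes(expr[, !test, drop = FALSE], labels[!test],
                          top_n = max(grid))
    xtr <- t(expr[, !test, drop = FALSE])
    xte <- t(expr[, test, drop = FALSE])
    ytr <- labels[!test]
    yte <- labels[test]
    for (gi in seq_along(grid)) {
      panel <- ranking$gene[seq_len(grid[gi])]
      rf <- with_seed(seed + 1000L * f + gi, {
        randomForest::randomForest(x = xtr[, panel, drop = FALSE], y = ytr,
                                   ntree = n_trees)
      })
      prob <- stats::predict(rf, xte[, panel, drop = FALSE], type = "prob")
      pred <- classes[max.col(prob, ties.method = "first")]
      onehot <- outer(as.character(yte), classes, "==") * 1
      miss[gi, f] <- mean(pred != as.character(yte))
      brier[gi, f] <- mean(rowSums((prob - onehot)^2))
      cprob[gi, f] <- mean(prob[cbind(seq_len(nrow(prob)),
                                      match(yte, classes))])
    }
  }
  wt <- nfold / n
  tab <- data.frame(size = grid,
                    cv_error = as.vector(miss %*% wt),
                    brier = as.vector(brier %*% wt),
                    avg_correct_prob = as.vector(cprob %*% wt))
  ok <- which(tab$cv_error < error_threshold)
  if (length(ok)) {
    selected <- tab$size[min(ok)]
  } else {
    selected <- tab$size[which.min(tab$cv_error)]
    warning(sprintf("no panel size reached CV error < %g; returning best (%d genes)",
                    error_threshold, selected))
  }
  structure(list(table = tab, selected = selected, folds = folds, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Panel-size cross-validation (%d folds): selected %d genes\n",
              x$folds, x$selected))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Fit the final CTS random-forest classifier
#'
#' @param expr Genes x samples matrix.
#' @param labels Per-sample CTS labels (every class present).
#' @param panel Gene-id vector (non-empty, all present in \code{expr}).
#' @param n_trees Trees (default 500).
#' @param seed Integer seed.
#' @return A \code{cts_model} with the forest, panel, class labels,
#'   out-of-bag error and per-class OOB votes.
#' @export
fit_cts_model <- function(expr, labels, panel, n_trees = 500, seed = 1L) {
  check_expression(expr)
  stop_if(length(panel) == 0, "'panel' must be non-empty")
  panel <- unname(as.character(panel))
  missing <- setdiff(panel, rownames(expr))
  stop_if(length(missing) > 0,
          "panel gene(s) absent from expression: ",
          paste(missing, collapse = ", "))
  labels <- as.factor(labels)
  absent <- levels(labels)[table(labels) == 0]
  stop_if(length(absent) > 0,
          "class(es) absent from training data: ", paste(absent, collapse = ", "))
  x <- t(expr[panel, , drop = FALSE])
  rf <- with_seed(seed, randomForest::randomForest(x = x, y = labels,
                                                   ntree = n_trees))
  oob <- unname(rf$err.rate[n_trees, "OOB"])
  structure(list(forest = rf, panel = panel, classes = levels(labels),
                 n_trees = n_trees, seed = seed, oob_error = oob,
                 oob_votes = rf$votes),
            class = "cts_model")
}

#' @export
print.cts_model <- function(x, ...) {
  cat(sprintf("CTS random-forest classifier: %d-gene panel, %d trees\n",
              length(x$panel), x$n_trees))
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  out-of-bag error: %.3f\n", x$oob_error))
  invisible(x)
}

#' @export
summary.cts_model <- function(object, ...) {
  print(object)
  cat("  OOB confusion matrix:\n")
  print(object$forest$confusion)
  invisible(object)
}

#' Predict consensus subtypes for new samples
#'
#' @param object A [fit_cts_model()] result.
#' @param expr Genes x samples matrix containing every panel gene.
#' @param ... Unused.
#' @return Data frame with \code{sample_id}, \code{cts} (argmax posterior,
#'   ties to the lowest class index) and one posterior column per class;
#'   attribute \code{frac_confident} is the fraction of samples whose
#'   maximum posterior exceeds 0.8.
#' @export
predict.cts_model <- function(object, expr, ...) {
  check_expression(expr, min_samples = 1)
  missing <- setdiff(object$panel, rownames(expr))
  stop_if(length(missing) > 0,
          "missing panel gene(s): ", paste(missing, collapse = ", "))
  x <- t(expr[object$panel, , drop = FALSE])
  prob <- stats::predict(object$forest, x, type = "prob")
  prob <- prob / rowSums(prob)
  lab <- object$classes[max.col(prob, ties.method = "first")]
  out <- data.frame(sample_id = colnames(expr),
                    cts = factor(lab, levels = object$classes),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(prob))
  rownames(out) <- NULL
  attr(out, "frac_confident") <- mean(apply(prob, 1, max) > 0.8)
  out
}

#' Multiclass Brier score
#'
#' Mean over samples of the squared distance between the posterior vector
#' and the one-hot truth; ranges 0 (perfect) to 2 (certain and wrong).
#'
#' @param posteriors Samples x classes probability matrix (rows sum to 1;
#'   column names are the class labels).
#' @param labels True class per sample.
#' @return Scalar in [0, 2].
#' @export
brier_score <- function(posteriors, labels) {
  stop_if(is.null(colnames(posteriors)), "'posteriors' needs class colnames")
  stop_if(max(abs(rowSums(posteriors) - 1)) > 1e-6, "rows must sum to 1")
  labels <- as.character(labels)
  stop_if(!all(labels %in% colnames(posteriors)),
          "label outside posterior classes")
  onehot <- outer(labels, colnames(posteriors), "==") * 1
  mean(rowSums((posteriors - onehot)^2))
}

## Midrank (Mann-Whitney) AUC of `score` for the positive class `pos`.
auc_rank <- function(score, pos) {
  n1 <- sum(pos)
  n0 <- sum(!pos)
  stop_if(n1 == 0 || n0 == 0, "AUC undefined: one class is empty")
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-all ROC AUC per class
#'
#' Mann-Whitney (midrank) AUC of each class's posterior probability against
#' membership of that class.
#'
#' @param posteriors Samples x classes probability matrix with class
#'   colnames.
#' @param labels True class per sample; every class must have both members
#'   and non-members.
#' @return Named numeric vector of per-class AUCs.
#' @export
one_vs_all_auc <- function(posteriors, labels) {
  labels <- as.character(labels)
  vapply(colnames(posteriors), function(cl) {
    auc_rank(posteriors[, cl], labels == cl)
  }, 0)
}
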