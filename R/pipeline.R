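## End-to-end convenience wrapper: simulate -> harmonize -> network -> MCL
## -> core samples -> classifier -> prediction.

#' Run the consensus subtyping pipeline on a cohort
#'
#' Chains the full analysis: batch adjustment of the expression matrix (if a
#' batch vector is present), construction of the cross-system subtype
#' network, Markov clustering with an inflation sweep scored by node
#' silhouette on one-minus-Jaccard distance, mapping of clusters to
#' consensus subtypes, identification of core samples, gene ranking and
#' cross-validated panel selection on core samples, final random-forest fit
#' and full-cohort prediction.
#'
#' @param cohort A [generate_cohort()] result, or a list with elements
#'   \code{expression}, \code{labels} (a [label_system_set()]) and
#'   optionally \code{batch}.
#' @param n_boot Permutations per network edge.
#' @param alpha Significance threshold for edge-based CTS augmentation.
#' @param inflations Inflation grid for the MCL sweep.
#' @param grid Panel sizes for cross-validation.
#' @param folds CV folds.
#' @param n_trees Trees per forest.
#' @param seed Integer seed for every stochastic step.
#' @return A \code{cts_pipeline} list with elements \code{expression}
#'   (harmonized), \code{graph}, \code{sweep}, \code{consensus},
#'   \code{core}, \code{cv}, \code{model}, \code{predictions}.
#' @export
run_cts_pipeline <- function(cohort, n_boot = 199, alpha = 0.05,
                             inflations = 1:7,
                             grid = c(seq(2, 30, by = 2), 40, 50),
                             folds = 10, n_trees = 500, seed = 1L) {
  expr <- cohort$expression
  if (!is.null(cohort$batch) && nlevels(as.factor(cohort$batch)) > 1) {
    expr <- combat_adjust(expr, cohort$batch)$adjusted
  }
  graph <- build_network(cohort$labels, n_boot = n_boot, alpha = alpha,
                         seed = seed)
  A <- network_adjacency(graph)
  sweep_res <- inflation_sweep(A, item_distance = 1 - A,
                               inflations = inflations)
  consensus <- map_clusters_to_cts(graph, sweep_res$clusters, alpha = alpha)
  core <- identify_core_samples(cohort$labels, consensus)

  core_ids <- unlist(core, use.names = FALSE)
  core_lab <- factor(rep(names(core), lengths(core)), levels = names(core))
  names(core_lab) <- core_ids
  core_expr <- expr[, core_ids, drop = FALSE]

  cv <- cv_panel_selection(core_expr, core_lab, grid = grid, folds = folds,
                           n_trees = n_trees, seed = seed)
  ranking <- rank_genes(core_expr, core_lab, top_n = max(grid))
  panel <- ranking$gene[seq_len(cv$selected)]
  model <- fit_cts_model(core_expr, core_lab, panel, n_trees = n_trees,
                         seed = seed)
  predictions <- stats::predict(model, expr)

  structure(list(expression = expr, graph = graph, sweep = sweep_res,
                 consensus = consensus, core = core, cv = cv, model = model,
                 predictions = predictions, seed = seed),
            class = "cts_pipeline")
}

#' @export
print.cts_pipeline <- function(x, ...) {
  cat("Consensus subtyping pipeline\n")
  print(x$graph)
  cat(sprintf("  MCL inflation selected: %g (clusters: %d)\n",
              x$sweep$selected, length(unique(x$sweep$clusters))))
  print(x$consensus)
  cat(sprintf("  core samples: %d (%.1f%% of cohort)\n",
              sum(lengths(x$core)),
              100 * sum(lengths(x$core)) / length(x$graph$universe)))
  print(x$model)
  cat(sprintf("  confident predictions (posterior > 0.8): %.1f%%\n",
              100 * attr(x$predictions, "frac_confident")))
  invisible(x)
}
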