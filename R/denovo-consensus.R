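## Resampling consensus clustering: estimates the number of subtypes de novo
## and quantifies concordance with CTS assignments.

#' One-minus-Pearson sample distance
#'
#' @param expr Genes x samples matrix (>= 2 genes, per-sample variance > 0).
#' @return Symmetric samples x samples distance matrix with values in [0, 2].
#' @export
one_minus_pearson <- function(expr) {
  stop_if(nrow(expr) < 2, "need >= 2 genes")
  v <- apply(expr, 2, stats::var)
  stop_if(any(v == 0), "zero-variance sample(s): ",
          paste(colnames(expr)[v == 0], collapse = ", "))
  d <- 1 - stats::cor(expr)
  diag(d) <- 0
  d
}

#' Consensus clustering configuration
#'
#' @param p_item Fraction of samples drawn (without replacement) per
#'   resampling iteration.
#' @param p_gene Fraction of genes drawn per iteration.
#' @param n_reps Resampling iterations (default 1000).
#' @param k_range Cluster numbers evaluated (min >= 2).
#' @param linkage Agglomeration scheme for \code{hclust} (default
#'   \code{"average"}).
#' @param k_tol Relative tolerance for k selection: the smallest k whose
#'   cophenetic correlation lies within this fraction of the maximum is
#'   chosen (the statistic plateaus once the true structure is reached, so
#'   a strict argmax would pick noise on the plateau).
#' @param seed Integer seed.
#' @return A \code{consensus_config} list.
#' @export
consensus_config <- function(p_item = 0.9, p_gene = 0.9, n_reps = 1000,
                             k_range = 2:10, linkage = "average",
                             k_tol = 0.005, seed = 1L) {
  stop_if(p_item <= 0 || p_item > 1 || p_gene <= 0 || p_gene > 1,
          "resampling fractions must lie in (0, 1]")
  stop_if(min(k_range) < 2, "'k_range' minimum must be >= 2")
  stop_if(k_tol < 0, "'k_tol' must be non-negative")
  structure(list(p_item = p_item, p_gene = p_gene,
                 n_reps = as.integer(n_reps), k_range = as.integer(k_range),
                 linkage = linkage, k_tol = k_tol, seed = as.integer(seed)),
            class = "consensus_config")
}

#' Resampling consensus clustering
#'
#' For each iteration, subsamples items and genes, clusters the subsample
#' hierarchically on one-minus-Pearson distance, and cuts the tree at each k
#' in the range, accumulating co-cluster and co-sampling tallies. The per-k
#' consensus matrix is co-cluster count over co-sampling count. k-selection
#' statistics: empirical CDF of consensus values and its area (non-decreasing
#' in k), delta-area, mean silhouette of the consensus partition on
#' \code{1 - M(k)}, and the cophenetic correlation between the full-data
#' distance and the dendrogram of the consensus matrix at k. The selected k
#' is the smallest whose cophenetic correlation is within \code{k_tol} of
#' the maximum — the statistic plateaus beyond the true cluster number, so
#' the parsimonious end of the plateau is taken (delta-area and silhouette
#' are reported as secondary evidence).
#'
#' @param expr Genes x samples matrix; needs at least \code{2 * max(k_range)}
#'   samples.
#' @param config A [consensus_config()].
#' @return A \code{consensus_result}: \code{consensus} (list of per-k
#'   matrices), \code{table} (k, cdf_auc, delta_area, mean_silhouette,
#'   cophenetic), \code{labels} (per-k assignments from the consensus
#'   matrix), \code{selected_k}.
#' @export
consensus_cluster <- function(expr, config = consensus_config()) {
  check_expression(expr)
  n <- ncol(expr)
  stop_if(n < 2 * max(config$k_range),
          "need at least 2 * max(k_range) samples")
  ks <- config$k_range
  full_dist <- one_minus_pearson(expr)

  hits <- lapply(ks, function(k) matrix(0, n, n))
  names(hits) <- as.character(ks)
  cooc <- matrix(0, n, n)
  n_item <- max(2, round(config$p_item * n))
  n_gene <- max(2, round(config$p_gene * nrow(expr)))

  with_seed(config$seed, {
    for (rep in seq_len(config$n_reps)) {
      items <- sort(sample.int(n, n_item))
      genes <- sample.int(nrow(expr), n_gene)
      d <- 1 - stats::cor(expr[genes, items, drop = FALSE])
      hc <- stats::hclust(stats::as.dist(d), method = config$linkage)
      cooc[items, items] <- cooc[items, items] + 1
      for (k in ks) {
        ct <- stats::cutree(hc, k = min(k, n_item))
        same <- outer(ct, ct, "==") * 1
        hits[[as.character(k)]][items, items] <-
          hits[[as.character(k)]][items, items] + same
      }
    }
  })

  consensus <- lapply(hits, function(h) {
    M <- h / ifelse(cooc > 0, cooc, 1)
    M[cooc == 0] <- 0
    dimnames(M) <- list(colnames(expr), colnames(expr))
    M
  })

  cdf_auc <- function(M) {
    x <- sort(M[upper.tri(M)])
    x <- c(0, x, 1)
    cdf <- (seq_along(x) - 1) / (length(x) - 1)
    sum(diff(x) * cdf[-1])
  }

  labels <- list()
  tab <- data.frame(k = ks, cdf_auc = NA_real_, delta_area = NA_real_,
                    mean_silhouette = NA_real_, cophenetic = NA_real_)
  for (i in seq_along(ks)) {
    k <- ks[i]
    M <- consensus[[as.character(k)]]
    hc <- stats::hclust(stats::as.dist(1 - M), method = config$linkage)
    lab <- stats::cutree(hc, k = k)
    labels[[as.character(k)]] <- lab
    tab$cdf_auc[i] <- cdf_auc(M)
    tab$mean_silhouette[i] <-
      if (length(unique(lab)) >= 2) silhouette_widths(1 - M, lab)$mean else NA
    tab$cophenetic[i] <- cophenetic_correlation(full_dist, hc)
  }
  tab$delta_area <- c(tab$cdf_auc[1],
                      diff(tab$cdf_auc) / utils::head(tab$cdf_auc, -1))
  cmax <- max(tab$cophenetic)
  selected_k <- min(ks[tab$cophenetic >= cmax - config$k_tol * abs(cmax)])

  structure(list(consensus = consensus, table = tab, labels = labels,
                 selected_k = selected_k, config = config),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus clustering over k = %s (%d reps): selected k = %d\n",
              paste(range(x$config$k_range), collapse = "-"),
              x$config$n_reps, x$selected_k))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Cophenetic correlation of a dendrogram with a distance matrix
#'
#' Pearson correlation between the original pairwise distances and the
#' cophenetic distances implied by the dendrogram.
#'
#' @param distance Symmetric distance matrix or \code{dist} over the same
#'   items as the dendrogram (>= 3 items).
#' @param dendrogram An \code{hclust} object.
#' @return Correlation in [-1, 1].
#' @export
cophenetic_correlation <- function(distance, dendrogram) {
  d <- stats::as.dist(distance)
  stop_if(attr(d, "Size") < 3, "need >= 3 items")
  stats::cor(as.vector(d), as.vector(stats::cophenetic(dendrogram)))
}

#' Row-normalized concordance table between two labelings
#'
#' @param labels_a,labels_b Label vectors over the same samples.
#' @return Matrix of percentages: each row (a-class) sums to 100 and gives
#'   the distribution over b-classes. Empty a-classes give a zero row with a
#'   warning.
#' @export
concordance_table <- function(labels_a, labels_b) {
  stop_if(length(labels_a) != length(labels_b),
          "labelings must cover the same samples")
  la <- if (is.factor(labels_a)) labels_a else factor(labels_a)
  lb <- if (is.factor(labels_b)) labels_b else factor(labels_b)
  tab <- table(la, lb)
  rs <- rowSums(tab)
  if (any(rs == 0)) warning("empty class(es): ",
                            paste(rownames(tab)[rs == 0], collapse = ", "))
  out <- 100 * sweep(unclass(tab), 1, ifelse(rs > 0, rs, 1), "/")
  out[rs == 0, ] <- 0
  out
}
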