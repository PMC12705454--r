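## Subtype agreement network: Jaccard similarity, permutation and
## hypergeometric overlap tests between subtype partitions from independent
## classification systems.

#' Construct a label-system set
#'
#' Bundles per-sample categorical labels from multiple named classification
#' systems over a shared sample universe.
#'
#' @param sample_ids Character vector of unique sample ids.
#' @param systems Named list; each element a factor/character vector of
#'   labels, one per sample (order matching \code{sample_ids}).
#' @return A \code{label_system_set}.
#' @export
label_system_set <- function(sample_ids, systems) {
  stop_if(anyDuplicated(sample_ids) > 0, "duplicate sample ids")
  stop_if(length(systems) < 1 || is.null(names(systems)),
          "'systems' must be a named list")
  systems <- lapply(systems, function(s) {
    stop_if(length(s) != length(sample_ids),
            "each system must label every sample exactly once")
    stop_if(anyNA(s), "missing labels are not allowed")
    s <- as.factor(s)
    names(s) <- sample_ids
    s
  })
  structure(list(sample_ids = sample_ids, systems = systems),
            class = "label_system_set")
}

#' @export
print.label_system_set <- function(x, ...) {
  cat(sprintf("Label-system set: %d samples, %d systems\n",
              length(x$sample_ids), length(x$systems)))
  for (nm in names(x$systems)) {
    cat(sprintf("  %s: %s\n", nm,
                paste(levels(x$systems[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

#' Jaccard index of two sample sets
#'
#' @param A,B Vectors of sample ids (sets).
#' @return \eqn{|A \cap B| / |A \cup B|} in [0, 1].
#' @export
jaccard_index <- function(A, B) {
  A <- unique(A); B <- unique(B)
  u <- length(union(A, B))
  stop_if(u == 0, "both sets are empty")
  length(intersect(A, B)) / u
}

#' Permutation p-value for the Jaccard overlap of two subtypes
#'
#' Permutes one system's label vector over samples and counts how often the
#' permuted Jaccard index reaches the observed one, using the add-one
#' estimator \eqn{p = (1 + \#\{J^* \ge J\}) / (n_{boot} + 1)} so p is never 0.
#'
#' @param labels_a,labels_b Per-sample label vectors of the two systems
#'   (same sample order).
#' @param subtype_a,subtype_b The subtype (label value) of each system whose
#'   member sets are compared.
#' @param n_boot Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return p-value in (0, 1].
#' @export
jaccard_bootstrap_p <- function(labels_a, labels_b, subtype_a, subtype_b,
                                n_boot = 999, seed = 1L) {
  stop_if(n_boot < 100, "'n_boot' must be >= 100")
  stop_if(length(labels_a) != length(labels_b),
          "label vectors must have equal length")
  in_a <- labels_a == subtype_a
  in_b <- labels_b == subtype_b
  if (length(unique(labels_b)) < 2) {
    warning("system B assigns a single label; p = 1")
    return(1)
  }
  obs <- sum(in_a & in_b) / sum(in_a | in_b)
  with_seed(seed, {
    hits <- 0L
    n <- length(labels_b)
    for (i in seq_len(n_boot)) {
      perm <- in_b[sample.int(n)]
      j <- sum(in_a & perm) / sum(in_a | perm)
      if (j >= obs) hits <- hits + 1L
    }
    (1 + hits) / (n_boot + 1)
  })
}

#' One-sided hypergeometric overlap p-value
#'
#' Probability of observing an overlap of at least \code{k} samples between a
#' set of size \code{K} and a set of size \code{n} drawn from a universe of
#' size \code{N}: \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(N, K, n).
#'
#' @param k Observed overlap count.
#' @param K Size of the first set.
#' @param n Size of the second set.
#' @param N Universe size.
#' @return One-sided p-value.
#' @export
hypergeom_overlap_p <- function(k, K, n, N) {
  stop_if(k < 0 || K < 0 || n < 0 || N < 0 || k > min(K, n) ||
            K > N || n > N, "inconsistent counts: need 0 <= k <= min(K, n) <= N")
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, order-preserving with respect to
#' the input positions and clipped at 1.
#'
#' @param p Vector of p-values in [0, 1].
#' @return Adjusted q-values, same order as input.
#' @export
bh_adjust <- function(p) {
  stop_if(anyNA(p), "NA/NaN p-values are not allowed")
  stop_if(any(p < 0 | p > 1), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Build the cross-system subtype agreement network
#'
#' One node per (system, subtype) pair with its member-sample set; one edge
#' per cross-system subtype pair carrying the Jaccard index, a permutation
#' p-value, a one-sided hypergeometric overlap p-value (universe = the shared
#' sample set) and its BH-adjusted q over the full cross-system edge family.
#' Edges are retained regardless of significance; q is an attribute used
#' downstream.
#'
#' @param labels A [label_system_set()] with >= 2 systems.
#' @param n_boot Permutations per edge for the Jaccard p-value.
#' @param alpha Significance threshold stored on the object (used by
#'   consensus mapping).
#' @param seed Integer seed.
#' @return A \code{subtype_graph} with data frames \code{nodes}
#'   (system, subtype, size) and \code{edges} (system_a, subtype_a, system_b,
#'   subtype_b, jaccard, p_boot, p_hyper, q_hyper), plus \code{members},
#'   a named list of member-sample sets keyed \code{system:subtype}.
#' @export
build_network <- function(labels, n_boot = 999, alpha = 0.05, seed = 1L) {
  stop_if(!inherits(labels, "label_system_set"),
          "'labels' must be a label_system_set")
  stop_if(length(labels$systems) < 2, "need >= 2 systems")
  universe <- labels$sample_ids
  N <- length(universe)
  stop_if(N < 2, "fewer than 2 samples in the shared universe")

  sys_names <- names(labels$systems)
  nodes <- do.call(rbind, lapply(sys_names, function(s) {
    data.frame(system = s, subtype = levels(labels$systems[[s]]),
               stringsAsFactors = FALSE)
  }))
  members <- lapply(seq_len(nrow(nodes)), function(i) {
    s <- nodes$system[i]
    universe[labels$systems[[s]] == nodes$subtype[i]]
  })
  names(members) <- paste(nodes$system, nodes$subtype, sep = ":")
  nodes$size <- lengths(members)

  edges <- list()
  si <- 0L
  for (a in seq_along(sys_names)) {
    for (b in seq_along(sys_names)) {
      if (b <= a) next
      la <- labels$systems[[a]]
      lb <- labels$systems[[b]]
      for (sa in levels(la)) {
        for (sb in levels(lb)) {
          si <- si + 1L
          ma <- members[[paste(sys_names[a], sa, sep = ":")]]
          mb <- members[[paste(sys_names[b], sb, sep = ":")]]
          k <- length(intersect(ma, mb))
          edges[[length(edges) + 1L]] <- data.frame(
            system_a = sys_names[a], subtype_a = sa,
            system_b = sys_names[b], subtype_b = sb,
            jaccard = jaccard_index(ma, mb),
            p_boot = jaccard_bootstrap_p(la, lb, sa, sb, n_boot = n_boot,
                                         seed = seed + si),
            p_hyper = hypergeom_overlap_p(k, length(ma), length(mb), N),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  edges <- do.call(rbind, edges)
  edges$q_hyper <- bh_adjust(edges$p_hyper)

  structure(list(nodes = nodes, edges = edges, members = members,
                 universe = universe, alpha = alpha),
            class = "subtype_graph")
}

#' @export
print.subtype_graph <- function(x, ...) {
  cat(sprintf("Subtype network: %d nodes, %d cross-system edges, %d samples\n",
              nrow(x$nodes), nrow(x$edges), length(x$universe)))
  sig <- sum(x$edges$q_hyper < x$alpha)
  cat(sprintf("  %d edge(s) with hypergeometric q < %.2g\n", sig, x$alpha))
  invisible(x)
}

#' Jaccard adjacency matrix of a subtype graph
#'
#' Symmetric node x node matrix of Jaccard weights (zero within systems and
#' on the diagonal), the input to Markov clustering.
#'
#' @param graph A [build_network()] result.
#' @param prune_alpha Optional: zero out edges with hypergeometric
#'   q >= \code{prune_alpha}.
#' @return Symmetric numeric matrix with \code{system:subtype} dimnames.
#' @export
network_adjacency <- function(graph, prune_alpha = NULL) {
  stop_if(!inherits(graph, "subtype_graph"), "'graph' must be a subtype_graph")
  ids <- paste(graph$nodes$system, graph$nodes$subtype, sep = ":")
  A <- matrix(0, nrow = length(ids), ncol = length(ids),
              dimnames = list(ids, ids))
  e <- graph$edges
  if (!is.null(prune_alpha)) e <- e[e$q_hyper < prune_alpha, , drop = FALSE]
  ia <- match(paste(e$system_a, e$subtype_a, sep = ":"), ids)
  ib <- match(paste(e$system_b, e$subtype_b, sep = ":"), ids)
  for (i in seq_along(ia)) {
    A[ia[i], ib[i]] <- A[ib[i], ia[i]] <- e$jaccard[i]
  }
  A
}

#' Write a subtype graph as a TSV edge list
#'
#' @param graph A \code{subtype_graph}.
#' @param path Output file.
#' @export
write_network_edges <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a subtype graph in GraphML format (requires igraph)
#'
#' @param graph A \code{subtype_graph}.
#' @param path Output file.
#' @export
write_network_graphml <- function(graph, path) {
  stop_if(!requireNamespace("igraph", quietly = TRUE),
          "GraphML export requires the 'igraph' package")
  ids <- paste(graph$nodes$system, graph$nodes$subtype, sep = ":")
  e <- graph$edges
  el <- data.frame(from = paste(e$system_a, e$subtype_a, sep = ":"),
                   to = paste(e$system_b, e$subtype_b, sep = ":"),
                   weight = e$jaccard, p_boot = e$p_boot,
                   p_hyper = e$p_hyper, q_hyper = e$q_hyper)
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = data.frame(name = ids,
                                                           size = graph$nodes$size))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
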