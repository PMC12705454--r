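## Markov clustering of the subtype network, inflation selection by
## silhouette, mapping of clusters to consensus transcriptomic subtypes
## (CTS), and identification of core samples.

#' Markov clustering parameters
#'
#' @param expansion Integer matrix-power of the expansion step.
#' @param inflation Element-wise power of the inflation step (>= 1);
#'   controls granularity.
#' @param self_loops Add self-loops before normalization (loop weight =
#'   the node's maximum incident edge weight, so clustering is invariant to
#'   uniform rescaling of all weights).
#' @param prune_threshold Entries below this are zeroed after each inflation.
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the max absolute change of the flow
#'   matrix.
#' @param n_repeats Repeats used by [inflation_sweep()] to confirm stability.
#' @return An \code{mcl_params} list.
#' @export
mcl_params <- function(expansion = 2L, inflation = 2, self_loops = TRUE,
                       prune_threshold = 1e-5, max_iter = 5000L, tol = 1e-6,
                       n_repeats = 10L) {
  stop_if(inflation < 1, "'inflation' must be >= 1")
  stop_if(tol <= 0, "'tol' must be positive")
  stop_if(expansion < 2, "'expansion' must be an integer >= 2")
  structure(list(expansion = as.integer(expansion), inflation = inflation,
                 self_loops = self_loops, prune_threshold = prune_threshold,
                 max_iter = as.integer(max_iter), tol = tol,
                 n_repeats = as.integer(n_repeats)),
            class = "mcl_params")
}

#' Markov clustering (MCL) of a weighted graph
#'
#' Alternates flow expansion (matrix power) and inflation (element-wise power
#' with column renormalization), pruning small entries, until the flow matrix
#' stabilizes; clusters are read from the attractor structure of the limit
#' matrix. Deterministic for a fixed input.
#'
#' @param adjacency Symmetric non-negative weight matrix (with dimnames).
#' @param params An [mcl_params()] object.
#' @return List with \code{cluster} (named integer assignment, cluster ids
#'   contiguous from 1 in order of first appearance), \code{n_iter}, and
#'   \code{attractors} (node names).
#' @export
mcl_cluster <- function(adjacency, params = mcl_params()) {
  stop_if(!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency),
          "'adjacency' must be a square matrix")
  stop_if(any(adjacency < 0), "weights must be non-negative")
  stop_if(max(abs(adjacency - t(adjacency))) > 1e-12,
          "'adjacency' must be symmetric")
  n <- nrow(adjacency)
  ids <- rownames(adjacency) %||% as.character(seq_len(n))

  M <- adjacency
  if (params$self_loops) {
    loop <- apply(M, 2, max)
    loop[loop == 0] <- 1          # isolated nodes still need a self-loop
    diag(M) <- loop
  }
  M <- sweep(M, 2, colSums(M), "/")

  normalize <- function(x) {
    cs <- colSums(x)
    empty <- which(cs == 0)      # column fully pruned: keep flow on itself
    if (length(empty)) {
      x[cbind(empty, empty)] <- 1
      cs[empty] <- 1
    }
    sweep(x, 2, cs, "/")
  }
  iter <- 0L
  repeat {
    iter <- iter + 1L
    M2 <- M
    for (e in seq_len(params$expansion - 1L)) M2 <- M2 %*% M
    M2 <- M2^params$inflation
    M2[M2 < params$prune_threshold] <- 0
    M2 <- normalize(M2)
    change <- max(abs(M2 - M))
    M <- M2
    if (change < params$tol) break
    stop_if(iter >= params$max_iter,
            sprintf("MCL did not converge in %d iterations (residual %.3g)",
                    params$max_iter, change))
  }

  ## Attractors carry positive diagonal flow; attractor systems are merged
  ## when they attract a common node. Each node joins the system receiving
  ## its largest flow mass (ties -> lowest cluster index).
  eps <- 1e-8
  attractors <- which(diag(M) > eps)
  if (length(attractors) == 0) attractors <- seq_len(n)
  sys_id <- seq_along(attractors)
  for (j in seq_len(n)) {
    att_in <- which(M[attractors, j] > eps)
    if (length(att_in) > 1) {
      tgt <- min(sys_id[att_in])
      sys_id[att_in] <- tgt
    }
  }
  sys_id <- match(sys_id, sort(unique(sys_id)))
  n_sys <- max(sys_id)

  cluster <- integer(n)
  for (j in seq_len(n)) {
    mass <- vapply(seq_len(n_sys), function(s) {
      sum(M[attractors[sys_id == s], j])
    }, 0)
    if (all(mass <= eps)) {
      cluster[j] <- NA_integer_   # no flow received; resolved below
    } else {
      cluster[j] <- which.max(mass)
    }
  }
  if (anyNA(cluster)) {
    cluster[is.na(cluster)] <- n_sys + seq_len(sum(is.na(cluster)))
  }
  cluster <- match(cluster, unique(cluster))
  names(cluster) <- ids
  list(cluster = cluster, n_iter = iter, attractors = ids[attractors])
}

#' Silhouette widths of a clustering
#'
#' Per-item silhouette widths \eqn{s(i) = (b - a) / \max(a, b)} (a = mean
#' within-cluster distance, b = smallest mean distance to another cluster;
#' singletons score 0), with per-cluster and overall means. Computation is
#' delegated to \pkg{cluster}.
#'
#' @param distance A \code{dist} or symmetric distance matrix.
#' @param labels Cluster assignment (>= 2 clusters).
#' @return A \code{silhouette_report} list: \code{widths} (per item),
#'   \code{cluster_means}, \code{mean}.
#' @export
silhouette_widths <- function(distance, labels) {
  d <- stats::as.dist(distance)
  labels <- as.integer(as.factor(labels))
  stop_if(length(unique(labels)) < 2, "silhouette needs >= 2 clusters")
  sil <- cluster::silhouette(labels, d)
  widths <- if (is.matrix(sil)) {
    sil[, "sil_width"]
  } else {
    rep(0, length(labels))       # every cluster a singleton: s(i) = 0
  }
  names(widths) <- attr(d, "Labels") %||% as.character(seq_along(labels))
  cm <- tapply(widths, labels, mean)
  structure(list(widths = widths,
                 cluster_means = cm,
                 mean = mean(widths)),
            class = "silhouette_report")
}

#' @export
print.silhouette_report <- function(x, ...) {
  cat(sprintf("Silhouette: overall mean %.3f over %d items, %d clusters\n",
              x$mean, length(x$widths), length(x$cluster_means)))
  invisible(x)
}

#' Inflation sweep for Markov clustering
#'
#' Runs MCL across a grid of inflation factors (default 1-7, with inflation 1
#' replaced by 1.01 since inflation must exceed 1 for contraction), scoring
#' each by the mean silhouette of the induced node clustering under
#' \code{item_distance}. The selected inflation maximizes mean silhouette,
#' ties broken toward the smaller inflation. Each inflation is repeated
#' \code{n_repeats} times to confirm that the (deterministic) partition is
#' stable.
#'
#' @param adjacency Symmetric non-negative weight matrix.
#' @param item_distance Node-level distance matrix for silhouette scoring
#'   (e.g. one minus the Jaccard adjacency).
#' @param inflations Numeric grid within [1, 7].
#' @param n_repeats Repeats per inflation.
#' @param params Base [mcl_params()]; inflation is overridden per grid point.
#' @return List with \code{table} (data frame: inflation, n_clusters,
#'   mean_silhouette, stable), \code{selected} (inflation value) and
#'   \code{clusters} (assignment at the selected inflation).
#' @export
inflation_sweep <- function(adjacency, item_distance, inflations = 1:7,
                            n_repeats = 10L, params = mcl_params()) {
  stop_if(any(inflations < 1 | inflations > 7),
          "'inflations' must lie within [1, 7]")
  rows <- list()
  assignments <- list()
  for (inf in inflations) {
    p <- params
    p$inflation <- max(inf, 1.01)
    runs <- lapply(seq_len(n_repeats), function(i) mcl_cluster(adjacency, p))
    cl <- runs[[1]]$cluster
    stable <- all(vapply(runs, function(r) identical(r$cluster, cl), TRUE))
    k <- length(unique(cl))
    msil <- if (k >= 2) silhouette_widths(item_distance, cl)$mean else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(inflation = inf, n_clusters = k,
                                            mean_silhouette = msil,
                                            stable = stable)
    assignments[[as.character(inf)]] <- cl
  }
  tab <- do.call(rbind, rows)
  stop_if(all(tab$n_clusters <= 1), "no structure: every inflation yields one cluster")
  ok <- which(!is.na(tab$mean_silhouette))
  sel <- ok[which.max(tab$mean_silhouette[ok])]   # first max = smaller inflation
  list(table = tab, selected = tab$inflation[sel],
       clusters = assignments[[as.character(tab$inflation[sel])]])
}

#' Map MCL clusters to consensus transcriptomic subtypes
#'
#' Every multi-node MCL cluster becomes a CTS (ids contiguous from 1, in
#' cluster order). Each CTS member set is the cluster's subtypes; when a
#' cluster has no member from some classification system (a coarse system
#' cannot split across every consensus group), the member set is augmented
#' with that system's subtype(s) whose BH-adjusted hypergeometric overlap
#' q-value against a cluster member falls below \code{alpha} — this is how a
#' 2-class system's subtype can serve more than one CTS. Singleton or
#' unclustered nodes are reported separately (mirroring a low-prevalence
#' subtype that fails to cluster).
#'
#' @param graph A [build_network()] result.
#' @param clusters Named cluster assignment over the graph's nodes (e.g.
#'   from [mcl_cluster()] or [inflation_sweep()]).
#' @param alpha Significance threshold for the augmentation rule (defaults
#'   to the graph's alpha).
#' @return A \code{consensus_map}: \code{cts} (list of member-node character
#'   vectors, names \code{CTS1..}), \code{cluster} (input assignment),
#'   \code{unclustered} (singleton nodes).
#' @export
map_clusters_to_cts <- function(graph, clusters, alpha = NULL) {
  stop_if(!inherits(graph, "subtype_graph"), "'graph' must be a subtype_graph")
  alpha <- alpha %||% graph$alpha
  ids <- paste(graph$nodes$system, graph$nodes$subtype, sep = ":")
  stop_if(!all(ids %in% names(clusters)), "clusters must cover every node")
  cl <- clusters[ids]
  sizes <- table(cl)
  multi <- as.integer(names(sizes)[sizes >= 2])
  stop_if(length(multi) == 0, "no multi-node cluster found")
  multi <- sort(multi)

  e <- graph$edges
  ea <- paste(e$system_a, e$subtype_a, sep = ":")
  eb <- paste(e$system_b, e$subtype_b, sep = ":")

  all_systems <- unique(graph$nodes$system)
  cts <- list()
  for (i in seq_along(multi)) {
    core_nodes <- ids[cl == multi[i]]
    sig <- e$q_hyper < alpha
    candidates <- unique(c(ea[sig & eb %in% core_nodes],
                           eb[sig & ea %in% core_nodes]))
    candidates <- setdiff(candidates, core_nodes)
    missing_sys <- setdiff(all_systems, sub(":.*$", "", core_nodes))
    aug <- candidates[sub(":.*$", "", candidates) %in% missing_sys]
    cts[[paste0("CTS", i)]] <- sort(union(core_nodes, aug))
  }
  unclustered <- ids[cl %in% as.integer(names(sizes)[sizes == 1])]
  structure(list(cts = cts, cluster = cl, unclustered = unclustered,
                 alpha = alpha),
            class = "consensus_map")
}

#' @export
print.consensus_map <- function(x, ...) {
  cat(sprintf("Consensus map: %d CTS(s)\n", length(x$cts)))
  for (nm in names(x$cts)) {
    cat(sprintf("  %s: %s\n", nm, paste(x$cts[[nm]], collapse = ", ")))
  }
  if (length(x$unclustered)) {
    cat("  unclustered:", paste(x$unclustered, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Identify core samples of each consensus subtype
#'
#' A sample is core for a CTS if, for every classification system, its label
#' belongs to that CTS's member set. Samples qualifying for more than one
#' CTS (possible only through shared member subtypes) are treated as
#' non-core so that core sets are disjoint.
#'
#' @param labels A [label_system_set()].
#' @param consensus A [map_clusters_to_cts()] result.
#' @return Named list (\code{CTS1..}) of core sample-id vectors, with an
#'   attribute \code{ambiguous} counting samples that matched several CTSs.
#' @export
identify_core_samples <- function(labels, consensus) {
  stop_if(!inherits(labels, "label_system_set"),
          "'labels' must be a label_system_set")
  stop_if(!inherits(consensus, "consensus_map"),
          "'consensus' must be a consensus_map")
  sys_names <- names(labels$systems)
  n <- length(labels$sample_ids)
  match_mat <- matrix(TRUE, nrow = n, ncol = length(consensus$cts),
                      dimnames = list(labels$sample_ids, names(consensus$cts)))
  for (k in names(consensus$cts)) {
    mem <- consensus$cts[[k]]
    mem_sys <- sub(":.*$", "", mem)
    for (s in sys_names) {
      allowed <- sub("^[^:]*:", "", mem[mem_sys == s])
      if (length(allowed) == 0) {
        warning(sprintf("%s has no member subtype from system '%s'; system ignored",
                        k, s))
        next
      }
      match_mat[, k] <- match_mat[, k] &
        (as.character(labels$systems[[s]]) %in% allowed)
    }
  }
  n_match <- rowSums(match_mat)
  ambiguous <- sum(n_match > 1)
  core <- lapply(names(consensus$cts), function(k) {
    labels$sample_ids[match_mat[, k] & n_match == 1]
  })
  names(core) <- names(consensus$cts)
  attr(core, "ambiguous") <- ambiguous
  core
}
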