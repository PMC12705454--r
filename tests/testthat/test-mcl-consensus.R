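test_that("MCL separates disconnected components and merges complete graphs", {
  # two disjoint triangles
  A <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  for (tri in list(1:3, 4:6)) {
    A[tri, tri] <- 1
  }
  diag(A) <- 0
  cl <- mcl_cluster(A)$cluster
  expect_equal(length(unique(cl)), 2)
  expect_equal(unname(cl[1:3]), rep(cl[["a"]], 3))
  expect_equal(unname(cl[4:6]), rep(cl[["d"]], 3))

  # complete uniform graph: a single cluster
  K <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(K) <- 0
  expect_equal(length(unique(mcl_cluster(K)$cluster)), 1)
})

test_that("MCL recovers planted blocks exactly (ARI = 1)", {
  skip_if_not_installed("mclust")
  A <- make_block_graph()
  cl <- mcl_cluster(A)$cluster
  expect_equal(mclust::adjustedRandIndex(cl, attr(A, "blocks")), 1)
})

test_that("MCL is invariant to node relabeling and uniform weight scaling", {
  A <- make_block_graph(n_per = 4)
  base <- mcl_cluster(A)$cluster
  # uniform scaling
  expect_equal(mcl_cluster(A * 7.3)$cluster, base)
  # node permutation
  set.seed(61)
  perm <- sample(nrow(A))
  Ap <- A[perm, perm]
  clp <- mcl_cluster(Ap)$cluster
  expect_equal(length(unique(clp)), length(unique(base)))
  # same partition after undoing the permutation
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(clp[rownames(A)], base), 1)
})

test_that("the inflation sweep selects a 3-cluster solution on planted blocks", {
  A <- make_block_graph()
  sw <- inflation_sweep(A, 1 - A, inflations = 1:7, n_repeats = 10)
  expect_equal(sw$table$inflation, 1:7)
  expect_true(all(sw$table$stable))
  expect_equal(length(unique(sw$clusters)), 3)
  # granularity is non-decreasing in inflation on this graph
  expect_true(all(diff(sw$table$n_clusters) >= 0))
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(sw$clusters, attr(A, "blocks")), 1)
})

test_that("the sweep errors when no inflation yields structure", {
  K <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(K) <- 0
  expect_error(inflation_sweep(K, 1 - K, inflations = c(2, 3), n_repeats = 2),
               "no structure")
})

test_that("silhouette widths match the textbook formula and a brute-force oracle", {
  # hand example: points 0, 0.1, 5, 5.1 in clusters AABB
  x <- c(0, 0.1, 5, 5.1)
  d <- as.matrix(dist(x))
  s <- silhouette_widths(d, c("A", "A", "B", "B"))
  expect_equal(unname(s$widths[1]), (mean(c(5, 5.1)) - 0.1) / mean(c(5, 5.1)),
               tolerance = 1e-10)
  expect_equal(unname(s$widths[1]), 0.9802, tolerance = 1e-4)

  # tight far-apart duplicate clusters: widths approach 1
  y <- rep(c(0, 100), each = 3) + rep(c(0, 1e-9, 2e-9), 2)
  sy <- silhouette_widths(as.matrix(dist(y)), rep(c("A", "B"), each = 3))
  expect_gt(sy$mean, 0.999)

  # brute-force double-loop oracle, exact on random instances
  brute_sil <- function(d, lab) {
    n <- nrow(d)
    vapply(seq_len(n), function(i) {
      own <- setdiff(which(lab == lab[i]), i)
      if (length(own) == 0) return(0)
      a <- mean(d[i, own])
      b <- min(vapply(setdiff(unique(lab), lab[i]), function(cl) {
        mean(d[i, lab == cl])
      }, 0))
      (b - a) / max(a, b)
    }, 0)
  }
  set.seed(62)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    pts <- matrix(rnorm(n * 2), n, 2)
    d <- as.matrix(dist(pts))
    lab <- sample(1:3, n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(unname(silhouette_widths(d, lab)$widths),
                 brute_sil(d, lab), tolerance = 1e-10)
  }
  expect_error(silhouette_widths(d, rep(1, n)), ">= 2 clusters")
})

test_that("random labels on separated blobs give near-zero mean silhouette", {
  x <- make_blobs(63, n_per = 20, g = 30)
  d <- as.matrix(dist(t(x)))
  set.seed(64)
  s <- silhouette_widths(d, sample(attr(x, "blocks")))
  expect_lt(s$mean, 0.1)
})

test_that("clusters map to consensus subtypes with gap-filling augmentation", {
  truth <- factor(rep(1:3, times = c(45, 30, 45)))
  ids <- sprintf("s%03d", seq_along(truth))
  labels <- perfect_labels(truth, ids)
  g <- build_network(labels, n_boot = 199, seed = 65)
  A <- network_adjacency(g)
  sw <- inflation_sweep(A, 1 - A, inflations = 2:4, n_repeats = 2)
  cm <- map_clusters_to_cts(g, sw$clusters)
  expect_equal(length(cm$cts), 3)
  ideal <- ideal_consensus()$cts
  # each ideal triple appears as one CTS member set (Mars4 never assigned:
  # it is empty under perfect labelers)
  got <- lapply(cm$cts, function(x) sort(setdiff(x, "mars:Mars4")))
  for (triple in ideal) {
    expect_true(any(vapply(got, identical, TRUE, sort(triple))))
  }
  # SRS2 serves two consensus subtypes through the augmentation rule
  n_srs2 <- sum(vapply(cm$cts, function(x) "srs:SRS2" %in% x, TRUE))
  expect_gte(n_srs2, 2)
})

test_that("core samples follow the consensus map and stay disjoint", {
  cm <- ideal_consensus()
  ids <- c("p1", "p2", "p3")
  labels <- label_system_set(ids, list(
    srs = c("SRS1", "SRS1", "SRS2"),
    mars = c("Mars2", "Mars1", "Mars3"),
    stanford = c("Inflammopathic", "Adaptive", "Adaptive")))
  core <- identify_core_samples(labels, cm)
  expect_equal(core$CTS1, "p1")       # concordant triple
  expect_false("p2" %in% unlist(core))  # discordant labels
  expect_equal(core$CTS2, "p3")
  expect_equal(attr(core, "ambiguous"), 0)

  # fully concordant labelers: every sample is core, sets are disjoint
  truth <- factor(rep(1:3, each = 25))
  ids <- sprintf("s%03d", seq_along(truth))
  full <- identify_core_samples(perfect_labels(truth, ids), cm)
  expect_equal(sum(lengths(full)), length(ids))
  expect_equal(anyDuplicated(unlist(full)), 0)
})

test_that("core fraction tracks the product of realized labeler concordances", {
  co <- small_cohort(seed = 66, n = 1000, g = 60, nsig = 5)
  g <- build_network(co$labels, n_boot = 199, seed = 3)
  A <- network_adjacency(g)
  sw <- inflation_sweep(A, 1 - A, inflations = 1:7, n_repeats = 2)
  cm <- map_clusters_to_cts(g, sw$clusters)
  core <- identify_core_samples(co$labels, cm)
  tr <- as.integer(co$true_subtype)
  correct <- list(srs = c("SRS1", "SRS2", "SRS2"),
                  mars = c("Mars2", "Mars1", "Mars3"),
                  stanford = c("Inflammopathic", "Coagulopathic", "Adaptive"))
  prod_conc <- prod(vapply(names(correct), function(s) {
    mean(as.character(co$labels$systems[[s]]) == correct[[s]][tr])
  }, 0))
  expect_lt(abs(sum(lengths(core)) / 1000 - prod_conc), 0.03)
  expect_equal(anyDuplicated(unlist(core)), 0)
})
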