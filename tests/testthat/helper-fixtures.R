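# Shared fixture builders (everything generated in code).

# Three well-separated Gaussian sample blobs, genes x samples.
make_blobs <- function(seed, n_per = 40, g = 100, sep = 2, noise = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(3 * g, 0, sep), nrow = g)
  x <- do.call(cbind, lapply(1:3, function(k) {
    centers[, k] + matrix(rnorm(g * n_per, 0, noise), g, n_per)
  }))
  dimnames(x) <- list(sprintf("g%03d", seq_len(g)),
                      sprintf("s%03d", seq_len(3 * n_per)))
  attr(x, "blocks") <- rep(1:3, each = n_per)
  x
}

# Planted 3-block adjacency with strong within- and weak between-block weights.
make_block_graph <- function(n_per = 5, within = 0.9, between = 0.05) {
  blocks <- rep(1:3, each = n_per)
  A <- matrix(between, 3 * n_per, 3 * n_per)
  A[outer(blocks, blocks, "==")] <- within
  diag(A) <- 0
  dimnames(A) <- list(paste0("n", seq_len(3 * n_per)),
                      paste0("n", seq_len(3 * n_per)))
  attr(A, "blocks") <- blocks
  A
}

# Small synthetic cohort for structural tests.
small_cohort <- function(seed = 1, n = 400, g = 200, nsig = 10, ...) {
  generate_cohort(sim_config(n_samples = n, n_genes = g,
                             n_signature_genes_per_subtype = nsig,
                             seed = seed, ...))
}

# Perfectly concordant labelers (diagonal confusion).
perfect_labels <- function(truth, sample_ids) {
  truth <- as.integer(truth)
  label_system_set(sample_ids, list(
    srs = c("SRS1", "SRS2", "SRS2")[truth],
    mars = c("Mars2", "Mars1", "Mars3")[truth],
    stanford = c("Inflammopathic", "Coagulopathic", "Adaptive")[truth]
  ))
}

# The consensus member map the three-system design induces.
ideal_consensus <- function() {
  structure(list(
    cts = list(CTS1 = c("mars:Mars2", "srs:SRS1", "stanford:Inflammopathic"),
               CTS2 = c("mars:Mars3", "srs:SRS2", "stanford:Adaptive"),
               CTS3 = c("mars:Mars1", "srs:SRS2", "stanford:Coagulopathic")),
    cluster = NULL, unclustered = character(0), alpha = 0.05),
    class = "consensus_map")
}
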