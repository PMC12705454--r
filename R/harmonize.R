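## Harmonization: transcript collapsing, parametric empirical-Bayes batch
## adjustment, and PCA inspection of co-normalized data.

#' Collapse a transcript-level matrix to unique genes
#'
#' Each gene's expression is the arithmetic mean of its transcripts' values,
#' per sample. Output genes are ordered lexicographically.
#'
#' @param transcript_matrix Transcripts x samples numeric matrix with
#'   transcript rownames.
#' @param transcript_to_gene Named character vector mapping transcript id to
#'   gene id (or a two-column data frame \code{transcript}, \code{gene}).
#' @return Genes x samples matrix.
#' @export
collapse_transcripts <- function(transcript_matrix, transcript_to_gene) {
  stop_if(!is.matrix(transcript_matrix) || is.null(rownames(transcript_matrix)),
          "'transcript_matrix' must be a matrix with transcript rownames")
  if (is.data.frame(transcript_to_gene)) {
    map <- stats::setNames(as.character(transcript_to_gene$gene),
                           as.character(transcript_to_gene$transcript))
  } else {
    map <- transcript_to_gene
  }
  tx <- rownames(transcript_matrix)
  unmapped <- setdiff(tx, names(map))
  stop_if(length(unmapped) > 0,
          "unmapped transcript(s): ", paste(unmapped, collapse = ", "))
  gene <- map[tx]
  sums <- rowsum(transcript_matrix, group = gene)
  counts <- as.vector(table(gene)[rownames(sums)])
  out <- sums / counts
  out[order(rownames(out)), , drop = FALSE]
}

#' Batch adjustment by parametric empirical Bayes
#'
#' Removes additive and multiplicative batch effects from a log-scale
#' expression matrix by the standard parametric empirical-Bayes procedure:
#' per-gene standardization against the batch-size-weighted grand mean and
#' pooled variance, method-of-moments normal/inverse-gamma priors on the
#' per-batch location (\eqn{\gamma}) and scale (\eqn{\delta^2}) parameters,
#' iterative posterior estimation, and back-transformation. The design
#' contains batch only (no covariates). Genes with zero pooled variance are
#' dropped with a message; they cannot be standardized and carry no
#' clustering signal.
#'
#' @param expr Genes x samples numeric matrix (log2 scale).
#' @param batch Per-sample batch labels (>= 2 samples per batch).
#' @param parametric Only the parametric mode is implemented; must be TRUE.
#' @param conv Convergence tolerance of the iterative posterior solver.
#' @return List with \code{adjusted} (matrix, same shape up to dropped
#'   zero-variance genes) and \code{adjustment} (a \code{batch_adjustment}
#'   with grand means, EB-shrunk \code{gamma_star}/\code{delta_star} per
#'   (batch, gene), and the prior hyperparameters per batch).
#' @export
combat_adjust <- function(expr, batch, parametric = TRUE, conv = 1e-4) {
  check_expression(expr)
  stop_if(!isTRUE(parametric), "only the parametric EB mode is implemented")
  stop_if(length(batch) != ncol(expr), "'batch' must have one entry per sample")
  batch <- droplevels(as.factor(batch))
  nb <- table(batch)
  stop_if(any(nb < 2), "every batch needs >= 2 samples; offending: ",
          paste(names(nb)[nb < 2], collapse = ", "))

  if (nlevels(batch) == 1) {
    adj <- structure(list(grand_mean = rowMeans(expr),
                          var_pooled = apply(expr, 1, stats::var),
                          gamma_star = NULL, delta_star = NULL,
                          priors = NULL, batches = levels(batch)),
                     class = "batch_adjustment")
    return(list(adjusted = expr, adjustment = adj))
  }

  n <- ncol(expr)
  batches <- levels(batch)
  idx <- lapply(batches, function(b) which(batch == b))
  names(idx) <- batches

  batch_means <- vapply(idx, function(i) rowMeans(expr[, i, drop = FALSE]),
                        numeric(nrow(expr)))              # genes x batches
  w <- as.vector(nb[batches]) / n
  grand_mean <- as.vector(batch_means %*% w)
  resid <- expr - batch_means[, as.integer(batch), drop = FALSE]
  var_pooled <- rowMeans(resid^2)                          # MLE pooled variance

  zero_var <- var_pooled <= .Machine$double.eps
  if (any(zero_var)) {
    message(sum(zero_var), " zero-variance gene(s) dropped before adjustment")
    expr <- expr[!zero_var, , drop = FALSE]
    batch_means <- batch_means[!zero_var, , drop = FALSE]
    grand_mean <- grand_mean[!zero_var]
    var_pooled <- var_pooled[!zero_var]
  }
  g <- nrow(expr)

  s_data <- (expr - grand_mean) / sqrt(var_pooled)

  gamma_hat <- vapply(idx, function(i) rowMeans(s_data[, i, drop = FALSE]),
                      numeric(g))                          # genes x batches
  delta_hat <- vapply(idx, function(i) {
    apply(s_data[, i, drop = FALSE], 1, stats::var)
  }, numeric(g))

  gamma_bar <- colMeans(gamma_hat)
  t2 <- apply(gamma_hat, 2, stats::var)
  a_prior <- vapply(seq_along(batches), function(j) {
    m <- mean(delta_hat[, j]); s2 <- stats::var(delta_hat[, j])
    (2 * s2 + m^2) / s2
  }, 0)
  b_prior <- vapply(seq_along(batches), function(j) {
    m <- mean(delta_hat[, j]); s2 <- stats::var(delta_hat[, j])
    (m * s2 + m^3) / s2
  }, 0)

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (j in seq_along(batches)) {
    nj <- length(idx[[j]])
    sd_j <- s_data[, idx[[j]], drop = FALSE]
    g_old <- gamma_hat[, j]
    d_old <- delta_hat[, j]
    change <- 1
    iter <- 0
    while (change > conv && iter < 200) {
      g_new <- (t2[j] * nj * gamma_hat[, j] + d_old * gamma_bar[j]) /
        (t2[j] * nj + d_old)
      sum2 <- rowSums((sd_j - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior[j]) / (nj / 2 + a_prior[j] - 1)
      change <- max(abs(g_new - g_old) / abs(g_old),
                    abs(d_new - d_old) / abs(d_old), na.rm = TRUE)
      g_old <- g_new
      d_old <- d_new
      iter <- iter + 1
    }
    gamma_star[, j] <- g_old
    delta_star[, j] <- d_old
  }

  adjusted <- s_data
  for (j in seq_along(batches)) {
    i <- idx[[j]]
    adjusted[, i] <- (s_data[, i, drop = FALSE] - gamma_star[, j]) /
      sqrt(delta_star[, j])
  }
  adjusted <- adjusted * sqrt(var_pooled) + grand_mean

  adj <- structure(
    list(grand_mean = stats::setNames(grand_mean, rownames(expr)),
         var_pooled = stats::setNames(var_pooled, rownames(expr)),
         gamma_hat = gamma_hat, delta_hat = delta_hat,
         gamma_star = gamma_star, delta_star = delta_star,
         priors = data.frame(batch = batches, gamma_bar = gamma_bar,
                             t2 = t2, a_prior = a_prior, b_prior = b_prior),
         batches = batches),
    class = "batch_adjustment")
  list(adjusted = adjusted, adjustment = adj)
}

#' @export
print.batch_adjustment <- function(x, ...) {
  cat(sprintf("Empirical-Bayes batch adjustment: %d gene(s), %d batch(es)\n",
              length(x$grand_mean), length(x$batches)))
  if (!is.null(x$priors)) print(x$priors)
  invisible(x)
}

#' PCA overview of an expression matrix
#'
#' Principal components of the gene-centered data, for inspecting sample
#' structure before and after co-normalization.
#'
#' @param expr Genes x samples matrix.
#' @param n_components Number of components to return.
#' @return List with \code{scores} (samples x components) and
#'   \code{explained} (non-increasing variance fractions summing to <= 1).
#' @export
pca_overview <- function(expr, n_components = 2) {
  check_expression(expr)
  stop_if(n_components > min(dim(expr)),
          "'n_components' exceeds min(genes, samples)")
  pc <- stats::prcomp(t(expr), center = TRUE, scale. = FALSE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained = explained[seq_len(n_components)])
}
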