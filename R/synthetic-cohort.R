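## Synthetic sepsis cohort generator.
##
## Emulates the statistical structure the downstream subtyping analysis
## assumes: a three-subtype whole-blood expression signal with
## subtype-specific signature genes and platform/batch effects; three noisy
## labeler systems of 2, 4 and 3 classes (SRS-, Mars- and
## inflammopathic/adaptive/coagulopathic-like) with configurable concordance
## to truth; severity covariates correlated with subtype; confounded binary
## treatment assignment; and exponential 28-day survival with subtype- and
## treatment-dependent hazards.

#' Default labeler confusion specifications
#'
#' Builds the three label-system specifications used by the synthetic cohort:
#' a 2-class system (\code{SRS1}/\code{SRS2}), a 4-class system
#' (\code{Mars1}-\code{Mars4}) and a 3-class system (\code{Inflammopathic},
#' \code{Adaptive}, \code{Coagulopathic}). Each specification carries a
#' 3 x k confusion matrix \eqn{P(label | true subtype)} whose rows sum to 1.
#' The "correct" label of each true subtype follows the consensus map: subtype
#' 1 corresponds to (SRS1, Mars2, Inflammopathic), subtype 2 to (SRS2, Mars1,
#' Coagulopathic) and subtype 3 to (SRS2, Mars3, Adaptive); \code{Mars4} is a
#' low-prevalence error sink, mirroring its failure to form a cluster.
#'
#' @param concordance Probability that a system emits the correct label for a
#'   sample's true subtype (the confusion-matrix "diagonal"); the remaining
#'   mass is spread uniformly over the other labels of that system.
#' @return Named list of systems, each with elements \code{labels} (class
#'   names) and \code{confusion} (3 x k row-stochastic matrix).
#' @export
default_labeler_specs <- function(concordance = 0.9) {
  stop_if(concordance < 0 || concordance > 1,
          "'concordance' must be in [0, 1]")
  mk <- function(labels, correct) {
    k <- length(labels)
    cm <- matrix((1 - concordance) / (k - 1), nrow = 3, ncol = k,
                 dimnames = list(paste0("subtype", 1:3), labels))
    for (s in 1:3) cm[s, correct[s]] <- concordance
    cm
  }
  list(
    srs = list(labels = c("SRS1", "SRS2"),
               confusion = mk(c("SRS1", "SRS2"), c("SRS1", "SRS2", "SRS2"))),
    mars = list(labels = paste0("Mars", 1:4),
                confusion = local({
                  # Mars4 is a low-prevalence error sink (it never forms its
                  # own consensus cluster): it receives a fifth of the error
                  # mass, the two other wrong labels share the rest.
                  correct <- c("Mars2", "Mars1", "Mars3")
                  cm <- mk(paste0("Mars", 1:4), correct)
                  err <- 1 - concordance
                  for (s in 1:3) {
                    wrong <- setdiff(colnames(cm), c(correct[s], "Mars4"))
                    cm[s, wrong] <- err * 0.8 / 2
                    cm[s, "Mars4"] <- err * 0.2
                  }
                  cm
                })),
    stanford = list(labels = c("Inflammopathic", "Adaptive", "Coagulopathic"),
                    confusion = mk(c("Inflammopathic", "Adaptive",
                                     "Coagulopathic"),
                                   c("Inflammopathic", "Coagulopathic",
                                     "Adaptive")))
  )
}

#' Default clinical generating model
#'
#' Severity covariates correlated with subtype (SOFA, APACHE-type score,
#' septic shock, infection site), a confounded logistic treatment-assignment
#' model (probability of corticosteroid treatment increases with severity),
#' and an exponential 28-day survival model with per-subtype baseline hazards
#' and per-subtype treatment log-hazard ratios. Defaults reproduce the
#' qualitative picture of ICU sepsis cohorts: ~16/29/16% 28-day mortality in
#' subtypes 1-3 untreated, treatment harmful in subtypes 1-2 and protective
#' in subtype 3.
#'
#' @return List of coefficients; see the field names in the source.
#' @export
default_clinical_spec <- function() {
  list(
    age_mean = 61, age_sd = 15,
    sofa_base = c(7, 7, 6), sofa_sd = 2.5,
    apache_base = c(50, 75, 55), apache_sd = 20,
    shock_prob = c(0.35, 0.34, 0.19),
    site_probs = rbind(subtype1 = c(lung = 0.45, abdominal = 0.44, other = 0.11),
                       subtype2 = c(lung = 0.46, abdominal = 0.30, other = 0.24),
                       subtype3 = c(lung = 0.70, abdominal = 0.11, other = 0.19)),
    hosp_icu_mean_days = 3,
    # treated ~ logistic(intercept + b_sofa*SOFA + b_shock*shock + b_age*age)
    treat_coefs = c(intercept = -3.2, sofa = 0.18, shock = 1.0, age = 0.01),
    # exponential hazards per day; P(death by 28d) = 1 - exp(-28 * rate)
    baseline_hazard = c(0.0062, 0.0120, 0.0062),
    treatment_loghr = c(1.2, 1.2, -0.5)
  )
}

#' Configure a synthetic sepsis cohort
#'
#' @param n_samples Number of patients.
#' @param n_genes Total number of genes (log2-scale expression).
#' @param n_signature_genes_per_subtype Signature genes planted per subtype;
#'   \code{3 * n_signature_genes_per_subtype} must not exceed \code{n_genes}.
#' @param subtype_proportions Length-3 probability vector of true subtype
#'   prevalences (defaults follow a 497/213/412 split).
#' @param effect_size Mean log2 shift of a subtype's signature genes in
#'   samples of that subtype.
#' @param noise_sd Residual log2 standard deviation of every gene.
#' @param baseline Baseline log2 expression level.
#' @param batch_spec Optional named list describing batches; each element is
#'   \code{list(gamma =, delta =, prop =)} with an additive shift, a
#'   multiplicative scale (scalar or per-gene vector) and an assignment
#'   proportion. \code{NULL} means a single unshifted batch.
#' @param labeler_specs Label-system specifications as produced by
#'   [default_labeler_specs()].
#' @param clinical_spec Clinical model as produced by [default_clinical_spec()].
#' @param censor_day Administrative censoring time in days.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return A \code{sim_config} list, validated.
#' @export
sim_config <- function(n_samples = 1000,
                       n_genes = 2000,
                       n_signature_genes_per_subtype = 30,
                       subtype_proportions = c(0.44, 0.19, 0.37),
                       effect_size = 2,
                       noise_sd = 1,
                       baseline = 6,
                       batch_spec = NULL,
                       labeler_specs = default_labeler_specs(),
                       clinical_spec = default_clinical_spec(),
                       censor_day = 28,
                       seed = 1L) {
  stop_if(length(subtype_proportions) != 3,
          "'subtype_proportions' must have length 3")
  check_prob_vector(subtype_proportions, "subtype_proportions")
  stop_if(3 * n_signature_genes_per_subtype > n_genes,
          "'n_signature_genes_per_subtype' x 3 exceeds 'n_genes'")
  stop_if(noise_sd < 0, "'noise_sd' must be non-negative")
  for (sys in names(labeler_specs)) {
    cm <- labeler_specs[[sys]]$confusion
    stop_if(nrow(cm) != 3, sprintf("confusion matrix of '%s' must have 3 rows", sys))
    for (r in seq_len(nrow(cm))) {
      check_prob_vector(cm[r, ], sprintf("labeler_specs$%s$confusion[%d, ]", sys, r))
    }
  }
  if (!is.null(batch_spec)) {
    stop_if(is.null(names(batch_spec)) || any(names(batch_spec) == ""),
            "'batch_spec' must be a named list")
    props <- vapply(batch_spec, function(b) b$prop %||% NA_real_, 0)
    check_prob_vector(props, "batch_spec proportions")
  }
  structure(
    list(n_samples = as.integer(n_samples),
         n_genes = as.integer(n_genes),
         n_signature_genes_per_subtype = as.integer(n_signature_genes_per_subtype),
         subtype_proportions = subtype_proportions,
         effect_size = effect_size, noise_sd = noise_sd, baseline = baseline,
         batch_spec = batch_spec, labeler_specs = labeler_specs,
         clinical_spec = clinical_spec, censor_day = censor_day,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Generate a synthetic sepsis cohort
#'
#' Draws true subtypes, a genes x samples log2 expression matrix with planted
#' subtype signatures (and batch effects if configured), noisy labels from
#' each configured classification system (independent across systems given
#' the true subtype), and a clinical table with confounded treatment
#' assignment and exponential survival censored at \code{censor_day}.
#'
#' @param config A [sim_config()] object.
#' @return A \code{cts_cohort} list with elements \code{expression}
#'   (genes x samples), \code{true_subtype} (factor \code{1:3}),
#'   \code{batch} (factor or NULL), \code{labels} (a [label_system_set()]),
#'   \code{clinical} (data frame), \code{signature_genes} (list of gene-id
#'   vectors per subtype) and \code{config}.
#' @export
generate_cohort <- function(config) {
  stop_if(!inherits(config, "sim_config"), "'config' must be a sim_config")
  with_seed(config$seed, {
    n <- config$n_samples
    g <- config$n_genes
    sample_ids <- sprintf("S%04d", seq_len(n))
    gene_ids <- sprintf("G%05d", seq_len(g))

    truth <- factor(sample(1:3, n, replace = TRUE,
                           prob = config$subtype_proportions),
                    levels = 1:3)
    names(truth) <- sample_ids

    expr <- matrix(stats::rnorm(g * n, mean = config$baseline,
                                sd = config$noise_sd),
                   nrow = g, ncol = n, dimnames = list(gene_ids, sample_ids))
    nsig <- config$n_signature_genes_per_subtype
    signature_genes <- lapply(1:3, function(k) {
      gene_ids[((k - 1) * nsig + 1):(k * nsig)]
    })
    names(signature_genes) <- paste0("subtype", 1:3)
    for (k in 1:3) {
      in_k <- truth == k
      if (any(in_k) && nsig > 0) {
        expr[signature_genes[[k]], in_k] <-
          expr[signature_genes[[k]], in_k] + config$effect_size
      }
    }

    batch <- NULL
    if (!is.null(config$batch_spec)) {
      props <- vapply(config$batch_spec, function(b) b$prop, 0)
      batch <- factor(sample(names(config$batch_spec), n, replace = TRUE,
                             prob = props),
                      levels = names(config$batch_spec))
      names(batch) <- sample_ids
      expr <- apply_batch_effects(expr, batch, config$batch_spec)
    }

    systems <- lapply(config$labeler_specs, function(spec) {
      lab <- character(n)
      for (k in 1:3) {
        idx <- which(truth == k)
        if (length(idx)) {
          lab[idx] <- sample(spec$labels, length(idx), replace = TRUE,
                             prob = spec$confusion[k, ])
        }
      }
      factor(lab, levels = spec$labels)
    })
    labels <- label_system_set(sample_ids, systems)

    clinical <- simulate_clinical(truth, config$clinical_spec,
                                  config$censor_day)
    clinical$sample_id <- sample_ids
    clinical <- clinical[, c("sample_id",
                             setdiff(names(clinical), "sample_id"))]

    structure(list(expression = expr, true_subtype = truth, batch = batch,
                   labels = labels, clinical = clinical,
                   signature_genes = signature_genes, config = config),
              class = "cts_cohort")
  })
}

#' @export
print.cts_cohort <- function(x, ...) {
  cat(sprintf("Synthetic sepsis cohort: %d samples x %d genes\n",
              ncol(x$expression), nrow(x$expression)))
  cat("  true subtype counts:",
      paste(sprintf("%d=%d", 1:3, as.vector(table(x$true_subtype))),
            collapse = ", "), "\n")
  cat("  label systems:", paste(names(x$labels$systems), collapse = ", "), "\n")
  if (!is.null(x$batch)) {
    cat("  batches:", paste(levels(x$batch), collapse = ", "), "\n")
  }
  invisible(x)
}

## Clinical covariates, confounded treatment, exponential survival.
simulate_clinical <- function(truth, spec, censor_day) {
  n <- length(truth)
  k <- as.integer(truth)
  age <- round(stats::rnorm(n, spec$age_mean, spec$age_sd))
  age <- pmin(pmax(age, 18), 95)
  sex <- factor(sample(c("male", "female"), n, replace = TRUE),
                levels = c("male", "female"))
  sofa <- pmax(0, round(stats::rnorm(n, spec$sofa_base[k], spec$sofa_sd)))
  apache <- pmax(0, round(stats::rnorm(n, spec$apache_base[k], spec$apache_sd)))
  shock <- stats::rbinom(n, 1, spec$shock_prob[k])
  site <- vapply(k, function(kk) {
    sample(colnames(spec$site_probs), 1, prob = spec$site_probs[kk, ])
  }, "")
  site <- factor(site, levels = colnames(spec$site_probs))
  hosp_to_icu <- stats::rpois(n, spec$hosp_icu_mean_days)

  b <- spec$treat_coefs
  eta <- b["intercept"] + b["sofa"] * sofa + b["shock"] * shock + b["age"] * age
  treated <- stats::rbinom(n, 1, stats::plogis(eta))

  rate <- spec$baseline_hazard[k] * exp(spec$treatment_loghr[k] * treated)
  t_event <- stats::rexp(n, rate)
  event <- as.integer(t_event <= censor_day)
  time <- pmin(t_event, censor_day)

  data.frame(age = age, sex = sex, sofa = sofa, apache = apache,
             site = site, shock = shock, hosp_to_icu = hosp_to_icu,
             treated = treated, time = time, event = event,
             stringsAsFactors = FALSE)
}

#' Apply additive/multiplicative batch effects to an expression matrix
#'
#' The generative inverse of empirical-Bayes batch adjustment:
#' \eqn{x'_{gs} = \delta_{b(s),g} x_{gs} + \gamma_{b(s),g}}.
#'
#' @param expr Genes x samples matrix.
#' @param batch Per-sample batch id (length \code{ncol(expr)}).
#' @param spec Named list keyed by batch id; each element has \code{gamma}
#'   and \code{delta}, scalars or per-gene vectors.
#' @return Matrix of the same dimensions.
#' @export
apply_batch_effects <- function(expr, batch, spec) {
  check_expression(expr, min_samples = 1)
  stop_if(length(batch) != ncol(expr),
          "'batch' must have one entry per sample")
  batch <- as.character(batch)
  unknown <- setdiff(unique(batch), names(spec))
  stop_if(length(unknown) > 0,
          "unknown batch id(s): ", paste(unknown, collapse = ", "))
  out <- expr
  for (b in unique(batch)) {
    cols <- batch == b
    gamma <- rep(spec[[b]]$gamma %||% 0, length.out = nrow(expr))
    delta <- rep(spec[[b]]$delta %||% 1, length.out = nrow(expr))
    out[, cols] <- out[, cols, drop = FALSE] * delta + gamma
  }
  out
}

#' Generate synthetic single-cell counts with planted gene-set enrichment
#'
#' Produces a sparse cells x genes count matrix in which each named cell type
#' over-expresses its designated gene set by a configured fold, as a fixture
#' for rank-based gene-set activity scoring.
#'
#' @param gene_sets Named list of gene-id vectors; one cell type is created
#'   per set (same names), plus a \code{"background"} type with no enrichment.
#' @param gene_universe Character vector of all gene ids (must contain every
#'   set gene).
#' @param n_cells_per_type Cells generated per cell type.
#' @param fold Fold-increase of the Poisson rate of a type's set genes
#'   (\code{fold = 1} means no enrichment).
#' @param base_rate Baseline Poisson rate per gene per cell.
#' @param seed Integer seed.
#' @return List with \code{counts} (sparse \code{dgCMatrix}, cells x genes)
#'   and \code{cell_types} (factor, one per cell).
#' @export
generate_single_cell <- function(gene_sets, gene_universe,
                                 n_cells_per_type = 100, fold = 4,
                                 base_rate = 0.3, seed = 1L) {
  stop_if(length(gene_sets) == 0 || is.null(names(gene_sets)),
          "'gene_sets' must be a non-empty named list")
  for (nm in names(gene_sets)) {
    stop_if(length(gene_sets[[nm]]) == 0,
            sprintf("gene set '%s' is empty", nm))
    missing <- setdiff(gene_sets[[nm]], gene_universe)
    stop_if(length(missing) > 0,
            sprintf("gene set '%s' has genes outside the universe: %s",
                    nm, paste(utils::head(missing, 5), collapse = ", ")))
  }
  stop_if(fold < 0, "'fold' must be non-negative")
  types <- c(names(gene_sets), "background")
  n_cells <- n_cells_per_type * length(types)
  g <- length(gene_universe)
  with_seed(seed, {
    if (n_cells == 0) {
      counts <- Matrix::Matrix(0, nrow = 0, ncol = g, sparse = TRUE,
                               dimnames = list(NULL, gene_universe))
      return(list(counts = methods::as(counts, "CsparseMatrix"),
                  cell_types = factor(character(0), levels = types)))
    }
    cell_types <- factor(rep(types, each = n_cells_per_type), levels = types)
    cell_ids <- sprintf("cell%05d", seq_len(n_cells))
    rates <- matrix(base_rate, nrow = n_cells, ncol = g,
                    dimnames = list(cell_ids, gene_universe))
    for (nm in names(gene_sets)) {
      rows <- cell_types == nm
      rates[rows, gene_sets[[nm]]] <- base_rate * fold
    }
    counts <- matrix(stats::rpois(n_cells * g, as.vector(rates)),
                     nrow = n_cells, dimnames = dimnames(rates))
    list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "CsparseMatrix"),
         cell_types = stats::setNames(cell_types, cell_ids))
  })
}
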