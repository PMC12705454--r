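## Readers/writers for the plain-text formats used by the pipeline:
## expression TSV (genes as rows), labels CSV (long), clinical CSV, GMT gene
## sets, MatrixMarket single-cell counts, model/consensus JSON.

#' Write an expression matrix as TSV (gene id in the first column)
#' @param expr Genes x samples matrix.
#' @param path Output file.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression TSV written by [write_expression_tsv()]
#' @param path Input file.
#' @return Genes x samples matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write label systems as a long CSV (sample_id, system, label)
#' @param labels A [label_system_set()].
#' @param path Output file.
#' @export
write_labels_csv <- function(labels, path) {
  long <- do.call(rbind, lapply(names(labels$systems), function(s) {
    data.frame(sample_id = labels$sample_ids, system = s,
               label = as.character(labels$systems[[s]]))
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long labels CSV into a label-system set
#' @param path Input file.
#' @return A [label_system_set()].
#' @export
read_labels_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(long$sample_id)
  systems <- lapply(split(long, long$system), function(d) {
    d$label[match(ids, d$sample_id)]
  })
  label_system_set(ids, systems)
}

#' Read gene sets in GMT format
#'
#' Delegates to \code{fgsea::gmtPathways} when available, with a plain
#' tab-separated fallback (set name, description, gene ids).
#'
#' @param path GMT file.
#' @return Named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1)
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of gene-id vectors.
#' @param path Output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write sparse single-cell counts as MatrixMarket plus a cell CSV
#' @param sc A [generate_single_cell()] result.
#' @param dir Output directory (created if needed); writes
#'   \code{counts.mtx}, \code{genes.csv}, \code{cells.csv}.
#' @export
write_single_cell <- function(sc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(sc$counts, file.path(dir, "counts.mtx"))
  utils::write.csv(data.frame(gene_id = colnames(sc$counts)),
                   file.path(dir, "genes.csv"), row.names = FALSE)
  utils::write.csv(data.frame(cell_id = names(sc$cell_types),
                              cell_type = as.character(sc$cell_types)),
                   file.path(dir, "cells.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read single-cell counts written by [write_single_cell()]
#' @param dir Directory containing \code{counts.mtx}, \code{genes.csv},
#'   \code{cells.csv}.
#' @return List with \code{counts} (sparse cells x genes) and
#'   \code{cell_types}.
#' @export
read_single_cell <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "counts.mtx")),
                        "CsparseMatrix")
  genes <- utils::read.csv(file.path(dir, "genes.csv"))
  cells <- utils::read.csv(file.path(dir, "cells.csv"))
  dimnames(counts) <- list(cells$cell_id, genes$gene_id)
  list(counts = counts,
       cell_types = stats::setNames(factor(cells$cell_type), cells$cell_id))
}

#' Serialize a consensus map to JSON
#' @param consensus A [map_clusters_to_cts()] result.
#' @param path Output file.
#' @export
write_consensus_json <- function(consensus, path) {
  jsonlite::write_json(list(cts = consensus$cts,
                            cluster = as.list(consensus$cluster),
                            unclustered = consensus$unclustered,
                            alpha = consensus$alpha),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a CTS classifier (JSON metadata + binary forest sidecar)
#' @param model A [fit_cts_model()] result.
#' @param path Base path; writes \code{<path>.json} and \code{<path>.rds}.
#' @export
save_cts_model <- function(model, path) {
  jsonlite::write_json(list(panel = model$panel, classes = model$classes,
                            n_trees = model$n_trees, seed = model$seed,
                            oob_error = model$oob_error),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  saveRDS(model, paste0(path, ".rds"))
  invisible(path)
}

#' Load a CTS classifier saved by [save_cts_model()]
#' @param path Base path used at save time.
#' @return A \code{cts_model}.
#' @export
load_cts_model <- function(path) {
  readRDS(paste0(path, ".rds"))
}
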