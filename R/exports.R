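#' Export the biomarker rank heat-map data
#'
#' Per-sample ranks (computed within each full sample profile) of the
#' biomarker probes. Columns are ordered by class then sample id; rows by
#' the leaf order of a complete-linkage hierarchical clustering of the rank
#' rows, so the output is a deterministic function of the data and invariant
#' to the input sample order.
#'
#' @param mat probe x sample log2 matrix.
#' @param biomarker character vector of probe ids (subset of the matrix).
#' @param labels two-level factor named by sample id.
#' @param path optional TSV output path.
#' @return rank matrix (biomarker probes x samples), invisibly when written.
#' @export
export_heatmap_data <- function(mat, biomarker, labels, path = NULL) {
  labels <- .align_labels(mat, labels)
  unknown <- setdiff(biomarker, rownames(mat))
  if (length(unknown))
    stop("unknown probe(s): ", paste(unknown, collapse = ", "))
  col_order <- names(labels)[order(labels, names(labels))]
  R <- rank_matrix(mat[, col_order, drop = FALSE])[biomarker, , drop = FALSE]
  if (nrow(R) > 2L) {
    hc <- hclust(dist(R), method = "complete")
    R <- R[hc$order, , drop = FALSE]
  }
  if (!is.null(path)) {
    write_expression_matrix(R, path)
    return(invisible(R))
  }
  R
}

#' Write a rank signature as two-column TSV (probe, direction)
#'
#' @param sig an [extract_signature()] result.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "rank_signature"))
  df <- data.frame(probe = c(sig$up, sig$down),
                   direction = rep(c("up", "down"), each = sig$s),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a sample-similarity network
#'
#' Converts a signature distance matrix (entries in `[0, 2]`) into an edge
#' list: similarity is `1 - d/2`; pairs whose similarity does not exceed the
#' threshold are dropped as negligible. The default threshold drops the
#' weakest quartile of similarities. Edge weight is the distance (short
#' edge = similar samples); a node table carries the class labels.
#'
#' @param dmat symmetric distance matrix from [distance_matrix()].
#' @param labels two-level factor named by sample id.
#' @param threshold keep edges with similarity strictly above this value;
#'   `NULL` (default) uses the lower quartile of off-diagonal similarities.
#' @param path optional path prefix; writes `<path>_edges.tsv` and
#'   `<path>_nodes.tsv`.
#' @return list with `edges` (source, target, weight) and `nodes`
#'   (id, class).
#' @export
export_similarity_network <- function(dmat, labels, threshold = NULL,
                                      path = NULL) {
  stopifnot(is.matrix(dmat), nrow(dmat) == ncol(dmat))
  if (max(abs(dmat - t(dmat))) > 1e-8) stop("distance matrix must be symmetric")
  ids <- colnames(dmat)
  labels <- labels[ids]
  n <- ncol(dmat)
  pr <- which(upper.tri(dmat), arr.ind = TRUE)
  sim <- 1 - dmat[pr] / 2
  if (is.null(threshold)) threshold <- unname(quantile(sim, 0.25))
  keep <- sim > threshold
  edges <- data.frame(source = ids[pr[keep, 1L]], target = ids[pr[keep, 2L]],
                      weight = dmat[pr][keep], stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- data.frame(id = ids, class = as.character(labels),
                      stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(edges, paste0(path, "_edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(nodes, paste0(path, "_nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(edges = edges, nodes = nodes, threshold = threshold)
}
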