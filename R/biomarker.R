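#' Biomarker as the union of per-sample signatures
#'
#' @param signatures list of [extract_signature()] results.
#' @return sorted character vector: every probe included in at least one
#'   sample signature (up or down set).
#' @export
biomarker_union <- function(signatures) {
  if (!length(signatures)) stop("at least one signature is required")
  sort(unique(unlist(lapply(signatures, function(sg) c(sg$up, sg$down)))))
}

# Internal: two-sided rank-sum p-value. Exact null distribution when both
# groups have <= 10 samples and no ties; tie-corrected normal approximation
# with continuity correction otherwise. The exact two-sided p doubles the
# smaller tail (capped at 1), matching the symmetric U null.
.ranksum_p <- function(x, y) {
  has_ties <- anyDuplicated(c(x, y)) > 0L
  if (!has_ties && length(x) <= 10 && length(y) <= 10) {
    .ranksum_p_exact(x, y)
  } else {
    .ranksum_p_normal(x, y)
  }
}

.ranksum_p_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (u > n1 * n2 / 2) {
    min(1, 2 * pwilcox(u - 1, n1, n2, lower.tail = FALSE))
  } else {
    min(1, 2 * pwilcox(u, n1, n2))
  }
}

.ranksum_p_normal <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tt <- table(r)
  mu <- n1 * n2 / 2
  sig2 <- n1 * n2 / 12 * ((n1 + n2 + 1) -
                          sum(tt^3 - tt) / ((n1 + n2) * (n1 + n2 - 1)))
  if (sig2 <= 0) return(1)
  z <- u - mu
  z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sig2)  # continuity correction
  min(1, 2 * pnorm(-abs(z)))
}

#' Per-probe differential statistics
#'
#' log2 fold change oriented first-declared-class minus second (positive =
#' up in the first class), with a two-sided Wilcoxon rank-sum p-value:
#' exact when both groups have at most 10 samples and the probe's values are
#' tie-free, tie-corrected normal approximation otherwise. At fixed group
#' sizes the exact p-values lie on a discrete attainable grid.
#'
#' @param mat probe x sample log2 matrix.
#' @param labels two-level factor named by sample id (>= 2 per class).
#' @param probes probe ids to test; default all rows.
#' @return data.frame: probe, log2fc, p, direction.
#' @export
differential_stats <- function(mat, labels, probes = rownames(mat)) {
  labels <- .align_labels(mat, labels)
  if (any(table(labels) < 2L)) stop("each class needs at least 2 samples")
  miss <- setdiff(probes, rownames(mat))
  if (length(miss)) stop("unknown probe(s): ", paste(miss, collapse = ", "))
  mat <- mat[probes, names(labels), drop = FALSE]
  lev <- levels(labels)
  i1 <- labels == lev[1L]
  lfc <- rowMeans(mat[, i1, drop = FALSE]) - rowMeans(mat[, !i1, drop = FALSE])
  pv <- apply(mat, 1L, function(v) .ranksum_p(v[i1], v[!i1]))
  data.frame(probe = probes, log2fc = unname(lfc), p = unname(pv),
             direction = ifelse(lfc > 0, paste("up in", lev[1L]),
                                ifelse(lfc < 0, paste("up in", lev[2L]),
                                       "none")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pathway-restricted ("reverse") biomarker search
#'
#' Restricts the matrix to probes whose mapped genes intersect the given
#' gene set (original probe order preserved), then runs the full
#' optimise/classify/permute pipeline on the restriction to test whether
#' the pathway alone supports classification.
#'
#' @inheritParams ga_optimize
#' @param gene_set character vector of gene symbols.
#' @param map probe-to-gene map as from [read_probe_map()].
#' @param B number of probe-label permutations.
#' @param paper_mode if `TRUE` (default) the reported accuracy is the GA's
#'   cross-validated fitness with selection performed once on all samples;
#'   if `FALSE`, an additional honest nested estimate via
#'   [cross_validate_ga()] is included.
#' @return `biomarker_result`: list with `probes`, `genes`, `s`, `accuracy`,
#'   `permutation_p`, `stats` (per-probe differential table),
#'   `null_accuracies`, and `honest_accuracy` when requested.
#' @export
pathway_restricted_search <- function(mat, labels, gene_set, map,
                                      ga = ga_config(), k = 5, p = 1,
                                      B = 100, paper_mode = TRUE) {
  hit <- vapply(rownames(mat), function(pr) {
    g <- map[[pr]]
    !is.null(g) && length(intersect(g, gene_set)) > 0L
  }, logical(1L))
  n_hit <- sum(hit)
  if (n_hit < 2L * ga$s_range[1L])
    stop("only ", n_hit, " probe(s) map to the gene set; need at least ",
         2L * ga$s_range[1L])
  run_signature_pipeline(mat[hit, , drop = FALSE], labels, map = map,
                         ga = ga, k = k, p = p, B = B,
                         paper_mode = paper_mode)
}

#' Full signature pipeline on one matrix: optimise, permute, extract
#'
#' Runs the candidate-pool/GA optimisation, extracts the biomarker as the
#' union of the per-sample signatures over the selected probes (with
#' per-probe differential statistics), and assesses significance by a
#' probe-label permutation test. The permutation test deliberately operates
#' on the *input* matrix of this stage (e.g. all probes of a pathway
#' restriction) at the selected signature size, never on the GA-selected
#' probe subset: the optimiser maximises cross-validated accuracy and its
#' selected subsets reach high accuracy even on effect-free data, so a null
#' built from permutations of the post-selection matrix would be
#' anti-conservative. The reported `accuracy` is therefore the
#' selection-free cross-validated accuracy of the stage input;
#' `ga_fitness` carries the optimiser's own (optimistically biased)
#' cross-validated fitness, and `honest_accuracy` (when `paper_mode =
#' FALSE`) the fully nested estimate.
#'
#' @inheritParams pathway_restricted_search
#' @return `biomarker_result` (see [pathway_restricted_search()]).
#' @export
run_signature_pipeline <- function(mat, labels, map = NULL,
                                   ga = ga_config(), k = 5, p = 1, B = 100,
                                   paper_mode = TRUE) {
  labels <- .align_labels(mat, labels)
  mat <- mat[, names(labels)]
  fit <- ga_optimize(mat, labels, ga = ga, k = k, p = p)
  sub <- mat[fit$best$probes, , drop = FALSE]
  perm <- permutation_test(mat, labels, fit$best$s, p = p, k = k, B = B,
                           seed = ga$seed)
  ranks <- rank_matrix(sub)
  sigs <- lapply(seq_len(ncol(ranks)),
                 function(j) extract_signature(ranks[, j], fit$best$s))
  probes <- biomarker_union(sigs)
  stats <- differential_stats(mat, labels, probes)
  genes <- if (is.null(map)) character(0) else
    sort(unique(unlist(map[intersect(probes, names(map))], use.names = FALSE)))
  out <- list(probes = probes, genes = genes, s = fit$best$s,
              selected = fit$best$probes, accuracy = perm$observed,
              ga_fitness = fit$best$fitness, trace = fit$trace,
              permutation_p = perm$p, null_accuracies = perm$null_accuracies,
              stats = stats)
  if (!paper_mode)
    out$honest_accuracy <- cross_validate_ga(mat, labels, ga, k, p)$accuracy
  structure(out, class = "biomarker_result")
}

#' @export
print.biomarker_result <- function(x, ...) {
  cat("Rank-signature biomarker: ", length(x$probes), " probes (",
      length(x$genes), " mapped genes), s = ", x$s, "\n", sep = "")
  cat(sprintf("  CV accuracy %.3f; permutation p = %.4f (B = %d)\n",
              x$accuracy, x$permutation_p, length(x$null_accuracies)))
  if (!is.null(x$honest_accuracy))
    cat(sprintf("  honest nested-CV accuracy %.3f\n", x$honest_accuracy))
  invisible(x)
}

#' Hypergeometric over-representation analysis with step-down Bonferroni
#'
#' For each gene set (intersected with the universe) the raw p-value is the
#' upper hypergeometric tail `P(X >= overlap)`; multiplicity is controlled
#' by the step-down Bonferroni (Holm) procedure: with raw p-values sorted
#' ascending, `adj_i = max_{j <= i} (m - j + 1) p_j`, capped at 1. Counting
#' is gene-level: a gene counts once however many probes map to it.
#'
#' @param gene_list character vector of hit genes; must lie in `universe`.
#' @param collection GMT-style list as from [read_gmt()].
#' @param universe character vector of all assayable genes.
#' @return data.frame sorted by raw p: set, overlap, set_size,
#'   universe_size, list_size, p_raw, p_adj.
#' @export
ora_enrichment <- function(gene_list, collection, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe")
  gene_list <- unique(gene_list)
  out_of <- setdiff(gene_list, universe)
  if (length(out_of))
    stop("gene_list outside universe: ", paste(utils::head(out_of, 5L),
                                               collapse = ", "))
  M <- length(universe); nl <- length(gene_list)
  rows <- lapply(names(collection), function(nm) {
    gs <- intersect(collection[[nm]]$genes, universe)
    K <- length(gs)
    k <- length(intersect(gene_list, gs))
    praw <- if (K == 0L) 1 else phyper(k - 1, K, M - K, nl, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, universe_size = M,
               list_size = nl, p_raw = praw, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  ord <- order(df$p_raw, df$set)
  df <- df[ord, , drop = FALSE]
  m <- nrow(df)
  df$p_adj <- pmin(1, cummax((m - seq_len(m) + 1) * df$p_raw))
  rownames(df) <- NULL
  df
}
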