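#' Classify one sample by lowest average signature distance
#'
#' The held-out sample is assigned to the class whose training members have
#' the lowest mean symmetrised signature distance to it. An exact tie goes
#' to the first class in the declared class order and is flagged.
#'
#' @param test_ranks named rank profile of the test sample.
#' @param train_ranks probe x sample rank matrix of the training samples.
#' @param labels two-level factor naming the training samples' classes.
#' @param s signature size.
#' @inheritParams enrichment_score
#' @return list with `class`, `mean_distances` (named by class), `tie`.
#' @export
classify_sample <- function(test_ranks, train_ranks, labels, s, p = 1) {
  labels <- labels[colnames(train_ranks)]
  if (anyNA(labels)) stop("every training sample needs a label")
  if (any(table(labels) < 1L)) stop("each class needs at least one training sample")
  sig_t <- extract_signature(test_ranks, s)
  d <- vapply(seq_len(ncol(train_ranks)), function(j) {
    rj <- train_ranks[, j]
    signature_distance(sig_t, rj, extract_signature(rj, s), test_ranks, p)
  }, numeric(1L))
  md <- vapply(levels(labels), function(cl) mean(d[labels == cl]), numeric(1L))
  tie <- abs(md[1L] - md[2L]) < 1e-12
  cls <- if (tie) levels(labels)[1L] else levels(labels)[which.min(md)]
  list(class = cls, mean_distances = md, tie = tie)
}

# Internal: stratified fold assignment. Each class's samples are shuffled
# (when a seed is supplied the caller has already seeded the RNG) and dealt
# round-robin across folds. Errors when a training fold would lose a class.
.make_folds <- function(labels, k, stratified = TRUE, shuffle = TRUE) {
  n <- length(labels)
  if (k < 2L || k > n) stop("k must lie in [2, n_samples]")
  fold <- integer(n)
  if (stratified) {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      if (shuffle) idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    idx <- if (shuffle) sample.int(n) else seq_len(n)
    fold[idx] <- rep_len(seq_len(k), n)
  }
  for (f in seq_len(k))
    if (any(table(labels[fold != f]) < 1L))
      stop("fold ", f, " would leave a training set without one class; ",
           "stratification impossible for k = ", k)
  names(fold) <- names(labels)
  fold
}

# Internal: cross-validated accuracy from a precomputed distance matrix.
# Valid because, for a fixed probe universe and signature size, a sample's
# signature does not depend on which other samples are in the training fold.
.cv_from_dmat <- function(D, labels, fold) {
  lev <- levels(labels)
  n <- length(labels)
  pred <- character(n)
  tie <- logical(n)
  for (i in seq_len(n)) {
    train <- which(fold != fold[i])
    m1 <- mean(D[i, train[labels[train] == lev[1L]]])
    m2 <- mean(D[i, train[labels[train] == lev[2L]]])
    tie[i] <- abs(m1 - m2) < 1e-12
    pred[i] <- if (tie[i]) lev[1L] else lev[if (m1 < m2) 1L else 2L]
  }
  list(accuracy = mean(pred == as.character(labels)), predicted = pred,
       tie = tie)
}

#' Cross-validated classification accuracy
#'
#' Stratified k-fold cross-validation of the rank-signature classifier.
#' Signatures are intrinsic per-sample quantities (each sample's own top and
#' bottom `s` probes), so held-out samples never influence the training
#' signatures. Deterministic given `seed`.
#'
#' @inheritParams distance_matrix
#' @param labels two-level factor named by the matrix's sample ids.
#' @param k number of folds (default 5; `k = n` gives leave-one-out).
#' @param stratified deal each class round-robin across folds (default).
#' @param seed integer seed for the fold shuffle; `NULL` keeps sample order.
#' @param dmat optional precomputed [distance_matrix()].
#' @return list with `accuracy`, `folds` (data.frame: sample, fold, truth,
#'   predicted, tie), and the fold assignment.
#' @export
cross_validate <- function(mat, labels, s, p = 1, k = 5, stratified = TRUE,
                           seed = NULL, dmat = NULL) {
  labels <- .align_labels(if (is.null(dmat)) mat else dmat, labels)
  if (is.null(dmat)) dmat <- distance_matrix(mat[, names(labels)], s, p)
  if (!is.null(seed)) set.seed(seed)
  fold <- .make_folds(labels, as.integer(k), stratified,
                      shuffle = !is.null(seed))
  res <- .cv_from_dmat(dmat[names(labels), names(labels)], labels, fold)
  list(accuracy = res$accuracy,
       folds = data.frame(sample = names(labels), fold = fold,
                          truth = as.character(labels),
                          predicted = res$predicted, tie = res$tie,
                          stringsAsFactors = FALSE),
       fold_assignment = fold)
}

#' Empirical permutation p-value (add-one convention)
#'
#' `p = (r + 1) / (B + 1)` with `r` the number of null statistics at least
#' as large as the observed one; never exactly zero, floor `1/(B+1)`.
#'
#' @param observed observed statistic (classification accuracy).
#' @param null_accuracies numeric vector of B null statistics.
#' @return p-value in `[1/(B+1), 1]`.
#' @export
permutation_pvalue <- function(observed, null_accuracies) {
  B <- length(null_accuracies)
  if (!B) stop("null_accuracies must be non-empty")
  (sum(null_accuracies >= observed) + 1) / (B + 1)
}

#' Probe-label permutation test of classification accuracy
#'
#' Each permutation independently shuffles, within every sample, the
#' assignment of expression values to probe labels — destroying the probe
#' correspondence across samples while preserving each sample's value
#' distribution — and recomputes the cross-validated accuracy with the same
#' fold assignment. (A single global relabeling shared by all samples leaves
#' every signature distance unchanged and cannot form a null.) The p-value
#' uses the add-one convention of [permutation_pvalue()].
#'
#' @inheritParams cross_validate
#' @param B number of permutations (study scale 10000; small-scale default
#'   100).
#' @param seed integer seed governing folds and permutations.
#' @return list with `p`, `observed`, `null_accuracies`, `folds`.
#' @export
permutation_test <- function(mat, labels, s, p = 1, k = 5, B = 100,
                             seed = 1L) {
  labels <- .align_labels(mat, labels)
  mat <- mat[, names(labels)]
  ranks <- rank_matrix(mat)
  set.seed(seed)
  fold <- .make_folds(labels, as.integer(k), stratified = TRUE)
  D <- distance_matrix(mat, s, p, ranks = ranks)
  obs <- .cv_from_dmat(D, labels, fold)$accuracy
  N <- nrow(ranks)
  nulls <- vapply(seq_len(B), function(b) {
    perm <- ranks
    for (j in seq_len(ncol(perm))) perm[, j] <- ranks[sample.int(N), j]
    Dp <- distance_matrix(NULL, s, p, ranks = perm)
    .cv_from_dmat(Dp, labels, fold)$accuracy
  }, numeric(1L))
  list(p = permutation_pvalue(obs, nulls), observed = obs,
       null_accuracies = nulls, fold_assignment = fold)
}
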