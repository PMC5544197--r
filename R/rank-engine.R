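#' Rank-transform one expression profile
#'
#' Ascending ranks (1 = lowest expression), ties averaged. Invariant under
#' any strictly increasing transform of the values.
#'
#' @param values named numeric vector (probe -> log2 expression), length >= 2.
#' @return named numeric vector of ranks.
#' @export
rank_transform <- function(values) {
  if (length(values) < 2L) stop("at least 2 probes are required")
  if (is.null(names(values))) stop("values must be named by probe id")
  if (any(!is.finite(values))) stop("non-finite expression value")
  rank(values, ties.method = "average")
}

#' Rank-transform every sample of a matrix
#' @param mat probe x sample numeric matrix.
#' @return matrix of per-sample ranks, same dimnames.
#' @export
rank_matrix <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2L)
  apply(mat, 2L, rank, ties.method = "average")
}

#' Extract a sample's rank signature
#'
#' The signature of a sample is the ordered set of its `s` highest-ranked
#' probes (`up`, in descending rank order) and its `s` lowest-ranked probes
#' (`down`, ascending). A tie spanning either cut is resolved by
#' lexicographic probe-id order and flagged in the result.
#'
#' @param ranks named rank vector from [rank_transform()].
#' @param s signature size, `1 <= s <= floor(N/2)`.
#' @return object of class `rank_signature`: list with `up`, `down`, `s`,
#'   `ties_at_cut`.
#' @export
extract_signature <- function(ranks, s) {
  N <- length(ranks)
  s <- as.integer(s)
  if (s < 1L || s > N %/% 2L)
    stop("signature size s = ", s, " outside [1, ", N %/% 2L, "]")
  up_ord <- order(-ranks, names(ranks))
  dn_ord <- order(ranks, names(ranks))
  sr_up <- ranks[up_ord]
  sr_dn <- ranks[dn_ord]
  ties <- (s < N && (sr_up[s] == sr_up[s + 1L] || sr_dn[s] == sr_dn[s + 1L]))
  structure(list(up = names(ranks)[up_ord[seq_len(s)]],
                 down = names(ranks)[dn_ord[seq_len(s)]],
                 s = s, ties_at_cut = ties),
            class = "rank_signature")
}

#' Weighted enrichment score of a probe set in a ranked profile
#'
#' The profile's probes are ordered by descending rank and walked once: a
#' probe in the set ("hit") adds its weight `|rank - (N+1)/2|^p` divided by
#' the summed hit weights; a miss subtracts `1/(N - |S|)`. The score is the
#' signed maximum deviation of this running sum from zero, in `[-1, 1]`.
#' With `p = 0` this is the classic Kolmogorov-Smirnov form; `p = 1`
#' (default) weights hits by their centred-rank magnitude. If every hit sits
#' exactly at the centre rank the weights degenerate to zero and uniform
#' weights are used. When the maximal positive and negative deviations tie
#' in magnitude, the positive one is returned.
#'
#' @param probe_set character vector; non-empty proper subset of the
#'   profile's probes.
#' @param ranks named rank vector from [rank_transform()].
#' @param p weight exponent, finite and `>= 0`; default 1.
#' @return scalar in `[-1, 1]`.
#' @export
enrichment_score <- function(probe_set, ranks, p = 1) {
  N <- length(ranks)
  if (!length(probe_set)) stop("probe_set must be non-empty")
  probe_set <- unique(probe_set)
  if (!all(probe_set %in% names(ranks)))
    stop("probe_set contains probes absent from the profile")
  if (length(probe_set) >= N)
    stop("probe_set must be a proper subset of the profile (miss increment undefined)")
  if (!is.finite(p) || p < 0) stop("weight exponent p must be finite and >= 0")
  ord <- order(-ranks, names(ranks))
  pos <- match(probe_set, names(ranks)[ord])
  w <- abs(ranks[probe_set] - (N + 1) / 2)^p
  .es_cpp(as.integer(pos), as.numeric(w), N)
}

#' Symmetrised signature distance between two samples
#'
#' The directed similarity of sample i seen in profile j is
#' `(ES(up_i in j) - ES(down_i in j)) / 2`; the distance is
#' `1 - (sim(i->j) + sim(j->i)) / 2`, in `[0, 2]`. Zero for a tie-free
#' profile against itself, 2 for exactly reversed rankings.
#'
#' @param sig_i,sig_j [extract_signature()] results for the two samples.
#' @param ranks_i,ranks_j the samples' rank profiles over a shared probe
#'   universe.
#' @inheritParams enrichment_score
#' @return scalar distance in `[0, 2]`.
#' @export
signature_distance <- function(sig_i, ranks_j, sig_j, ranks_i, p = 1) {
  if (length(ranks_i) != length(ranks_j) ||
      !all(names(ranks_i) %in% names(ranks_j)))
    stop("rank profiles do not share a probe universe")
  sim_ij <- (enrichment_score(sig_i$up, ranks_j, p) -
             enrichment_score(sig_i$down, ranks_j, p)) / 2
  sim_ji <- (enrichment_score(sig_j$up, ranks_i, p) -
             enrichment_score(sig_j$down, ranks_i, p)) / 2
  1 - (sim_ij + sim_ji) / 2
}

# Internal fast path: per-sample descending-rank positions, hit weights and
# signature index matrices for the compiled all-pairs distance.
.sig_engine <- function(ranks, s, p = 1) {
  N <- nrow(ranks); n <- ncol(ranks)
  probe_names <- rownames(ranks)
  pos <- matrix(0L, N, n)
  up <- matrix(0L, s, n)
  down <- matrix(0L, s, n)
  seqN <- seq_len(N)
  for (j in seq_len(n)) {
    r <- ranks[, j]
    if (anyDuplicated(r)) {          # ties: lexicographic probe-id tie-break
      ord <- order(-r, probe_names)
      dn <- order(r, probe_names)
    } else {
      ord <- order(r, decreasing = TRUE)
      dn <- rev(ord)
    }
    pos[ord, j] <- seqN
    up[, j] <- ord[seq_len(s)]
    down[, j] <- dn[seq_len(s)]
  }
  w <- if (p == 1) abs(ranks - (N + 1) / 2) else abs(ranks - (N + 1) / 2)^p
  list(pos = pos, w = w, up = up, down = down)
}

#' All-pairs signature distance matrix
#'
#' @param mat probe x sample log2 expression matrix (>= 2 samples).
#' @param s signature size.
#' @inheritParams enrichment_score
#' @param ranks optional precomputed [rank_matrix()] (overrides `mat`).
#' @return symmetric sample x sample matrix, zero diagonal for tie-free
#'   profiles, entries in `[0, 2]`.
#' @export
distance_matrix <- function(mat, s, p = 1, ranks = NULL) {
  if (is.null(ranks)) ranks <- rank_matrix(mat)
  if (ncol(ranks) < 2L) stop("at least 2 samples are required")
  if (s < 1L || s > nrow(ranks) %/% 2L)
    stop("signature size s = ", s, " outside [1, ", nrow(ranks) %/% 2L, "]")
  eng <- .sig_engine(ranks, as.integer(s), p)
  D <- .pair_distance_cpp(eng$pos, eng$w, eng$up, eng$down)
  dimnames(D) <- list(colnames(ranks), colnames(ranks))
  D
}
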