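# Independent reference implementations used as oracles. These deliberately
# re-derive each quantity by the most literal route (full running sums, full
# enumeration) and never call into the package's own fast paths.

# Naive O(N * |S|) weighted enrichment-score running sum: order all probes by
# descending rank (probe-id tie-break), walk the whole list, track the signed
# maximum deviation from zero.
naive_es <- function(probe_set, ranks, p = 1) {
  N <- length(ranks)
  ord <- order(-ranks, names(ranks))
  probes <- names(ranks)[ord]
  hit <- probes %in% probe_set
  w <- abs(ranks[ord] - (N + 1) / 2)^p
  W <- sum(w[hit])
  if (W <= 0) {
    w[] <- 1
    W <- sum(hit)
  }
  miss_dec <- 1 / (N - sum(hit))
  w <- unname(w)
  run <- numeric(N)
  acc <- 0
  for (i in seq_len(N)) {
    acc <- if (hit[i]) acc + w[i] / W else acc - miss_dec
    run[i] <- acc
  }
  smax <- max(0, run)
  smin <- min(0, run)
  # signed maximum deviation; a tie in magnitude (up to float drift in the
  # accumulated sum) resolves to the positive deviation
  if (smax >= -smin - 1e-9) smax else smin
}

# Exact two-sided rank-sum p-value by full enumeration of all C(n1+n2, n1)
# group assignments: P(|W - E[W]| >= |w_obs - E[W]|), ties handled by
# average ranks. Feasible for n1 + n2 <= 16.
enum_ranksum_p <- function(x, y) {
  n1 <- length(x)
  all_v <- c(x, y)
  r <- rank(all_v)
  mu <- n1 * mean(r)
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  combs <- utils::combn(length(all_v), n1)
  stat <- apply(combs, 2L, function(idx) abs(sum(r[idx]) - mu))
  mean(stat >= obs - 1e-9)
}

# Small named random expression matrix.
rand_mat <- function(N, n, seed = 1) {
  set.seed(seed)
  matrix(rnorm(N * n), N, n,
         dimnames = list(sprintf("p%03d", seq_len(N)),
                         sprintf("s%02d", seq_len(n))))
}

two_class <- function(n_per_class, classes = c("A", "B"),
                      samples = sprintf("s%02d", seq_len(2 * n_per_class))) {
  cohort_labels(samples, rep(classes, each = n_per_class),
                class_order = classes)
}
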