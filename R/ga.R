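#' Configuration for the genetic signature optimizer
#'
#' @param pop_size population size (>= 2); default 40.
#' @param generations number of generations; default 30.
#' @param crossover_prob per-pair uniform crossover probability; default 0.7.
#' @param mutation_prob per-bit flip probability; `NULL` (default) uses
#'   `1/pool_size`.
#' @param elitism number of elites copied unchanged; default 2.
#' @param tournament_size tournament selection size; default 3.
#' @param s_range admissible signature sizes `[s_min, s_max]`; default
#'   `c(2, 25)`.
#' @param pool_size candidate-pool size `m`: the GA searches over the top-m
#'   probes by absolute standardised two-sample rank-sum statistic;
#'   default 100.
#' @param init_prob initial probe-inclusion probability; default 0.5.
#' @param refine run a deterministic single-bit local refinement (memetic
#'   hill-climb over mask bits and admissible sizes) on the best individual
#'   after the last generation; default `TRUE`.
#' @param seed integer seed.
#' @return validated list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 40, generations = 30, crossover_prob = 0.7,
                      mutation_prob = NULL, elitism = 2, tournament_size = 3,
                      s_range = c(2, 25), pool_size = 100, init_prob = 0.5,
                      refine = TRUE, seed = 1L) {
  cfg <- list(pop_size = as.integer(pop_size),
              generations = as.integer(generations),
              crossover_prob = crossover_prob, mutation_prob = mutation_prob,
              elitism = as.integer(elitism),
              tournament_size = as.integer(tournament_size),
              s_range = as.integer(s_range), pool_size = as.integer(pool_size),
              init_prob = init_prob, refine = isTRUE(refine),
              seed = as.integer(seed))
  if (cfg$pop_size < 2L) stop("population size must be >= 2")
  for (pr in c(cfg$crossover_prob, cfg$mutation_prob, cfg$init_prob))
    if (!is.null(pr) && (pr < 0 || pr > 1)) stop("probabilities must lie in [0, 1]")
  if (length(cfg$s_range) != 2L || cfg$s_range[1] < 1L ||
      cfg$s_range[1] > cfg$s_range[2])
    stop("s_range must be an increasing pair of sizes >= 1")
  if (cfg$elitism >= cfg$pop_size) stop("elitism must be below pop_size")
  structure(cfg, class = "ga_config")
}

#' Rank candidate probes by two-sample rank statistic
#'
#' Standardised (tie-corrected) Wilcoxon rank-sum z per probe; the candidate
#' pool for the optimizer is the top `m` probes by `|z|`.
#'
#' @param mat probe x sample log2 matrix.
#' @param labels two-level factor named by sample id.
#' @param m pool size (capped at the number of probes).
#' @return character vector of probe ids, strongest first.
#' @export
candidate_pool <- function(mat, labels, m) {
  z <- .ranksum_z(mat, labels)
  m <- min(as.integer(m), nrow(mat))
  names(z)[order(-abs(z), names(z))][seq_len(m)]
}

# Standardised (tie-corrected) rank-sum z per probe.
.ranksum_z <- function(mat, labels) {
  labels <- .align_labels(mat, labels)
  mat <- mat[, names(labels), drop = FALSE]
  g1 <- labels == levels(labels)[1L]
  n1 <- sum(g1); n2 <- sum(!g1); n <- n1 + n2
  R <- rank_matrix(t(mat))        # rank within each probe across samples
  W <- colSums(R[g1, , drop = FALSE])
  mu <- n1 * (n + 1) / 2
  ties <- apply(mat, 1L, function(x) {
    tt <- table(x); sum(tt^3 - tt)
  })
  sig2 <- n1 * n2 / 12 * ((n + 1) - ties / (n * (n - 1)))
  setNames(ifelse(sig2 > 0, (W - mu) / sqrt(sig2), 0), rownames(mat))
}

# Fitness comparator. Cross-validated accuracy on 2n samples lives on a
# coarse grid and saturates quickly, so exact accuracy ties are broken by
# (1) the mean per-probe discriminability of the masked probes (their
# absolute standardised rank-sum statistic): probes without marginal group
# separation drag the mean down and are pruned; (2) fuller coverage (larger
# mask) — at a strong planted effect every true probe saturates the
# rank-sum statistic at its complete-separation maximum, so among
# equally-strong masks the complete one wins, which is what makes the
# biomarker (union of signatures) recover redundant signal probes; (3) the
# larger signature size — the biomarker is the union of per-sample
# signatures, so among equally accurate sizes the more complete one yields
# the more reproducible probe union, while parsimony on the probe set
# itself is already enforced by (1)-(2). Remaining ties keep the incumbent.
.ga_better <- function(a, b) {
  if (is.null(b)) return(TRUE)
  if (a$fitness != b$fitness) return(a$fitness > b$fitness)
  if (abs(a$meanz - b$meanz) > 1e-9) return(a$meanz > b$meanz)
  na <- sum(a$mask); nb <- sum(b$mask)
  if (na != nb) return(na > nb)
  a$s > b$s
}

# Repair a chromosome so that 2*s <= sum(mask) and s within s_range.
.ga_repair <- function(mask, s, s_range) {
  need <- 2L * max(s_range[1L], 1L)
  if (sum(mask) < need) {
    off <- which(!mask)
    mask[off[sample.int(length(off), need - sum(mask))]] <- TRUE
  }
  s <- min(max(s, s_range[1L]), s_range[2L], sum(mask) %/% 2L)
  list(mask = mask, s = s)
}

#' Genetic-algorithm optimisation of the classification signature
#'
#' Chromosome: a signature size `s` plus a binary inclusion mask over the
#' candidate pool (top-m probes by absolute rank-sum statistic, computed on
#' the supplied data). Fitness is the stratified cross-validated accuracy of
#' the rank-signature classifier on the matrix restricted to the masked
#' probes (ranks recomputed within the restriction); exact accuracy ties
#' are broken by the mean per-probe discriminability of the masked probes,
#' then toward fuller coverage (larger mask, larger `s`) — accuracy on few
#' samples saturates, and the biomarker reported downstream is a union of
#' signatures, so completeness of equally-strong masks matters; see the
#' methods vignette. Tournament selection, uniform crossover, bit-flip
#' mutation and elitism; the per-generation best fitness trace is
#' non-decreasing.
#'
#' @inheritParams cross_validate
#' @param ga a [ga_config()].
#' @param pool optional explicit candidate pool (character probe ids),
#'   overriding the rank-statistic pool.
#' @param init_population optional list of `list(mask =, s =)` chromosomes
#'   used (recycled/truncated to `pop_size`) as the initial population.
#' @return list with `best` (`probes`, `s`, `fitness`), `trace`
#'   (per-generation best fitness), `pool`.
#' @export
ga_optimize <- function(mat, labels, ga = ga_config(), k = 5, p = 1,
                        pool = NULL, init_population = NULL) {
  stopifnot(inherits(ga, "ga_config"))
  labels <- .align_labels(mat, labels)
  mat <- mat[, names(labels)]
  set.seed(ga$seed)
  if (is.null(pool)) pool <- candidate_pool(mat, labels, ga$pool_size)
  m <- length(pool)
  if (m < 2L * ga$s_range[1L])
    stop("candidate pool (", m, " probes) smaller than 2*s_min = ",
         2L * ga$s_range[1L])
  s_range <- c(ga$s_range[1L], min(ga$s_range[2L], m %/% 2L))
  mut <- if (is.null(ga$mutation_prob)) 1 / m else ga$mutation_prob
  sub <- mat[pool, , drop = FALSE]

  # one fold assignment for every fitness evaluation; no reseeding inside
  # the GA loop, so the whole run is a single deterministic random stream
  fold <- .make_folds(labels, as.integer(k), stratified = TRUE)
  zpool <- abs(.ranksum_z(sub, labels))
  new_ind <- function(mask, s) {
    r <- .ga_repair(mask, s, s_range)
    D <- distance_matrix(sub[r$mask, , drop = FALSE], r$s, p)
    list(mask = r$mask, s = r$s,
         fitness = .cv_from_dmat(D, labels, fold)$accuracy,
         meanz = mean(zpool[r$mask]))
  }

  popn <- vector("list", ga$pop_size)
  for (i in seq_len(ga$pop_size)) {
    ch <- if (!is.null(init_population))
      init_population[[(i - 1L) %% length(init_population) + 1L]]
    else {
      s_choices <- seq.int(s_range[1L], s_range[2L])
      list(mask = runif(m) < ga$init_prob,
           s = s_choices[sample.int(length(s_choices), 1L)])
    }
    popn[[i]] <- new_ind(ch$mask, ch$s)
  }
  best_of <- function(pp) {
    b <- NULL
    for (ind in pp) if (.ga_better(ind, b)) b <- ind
    b
  }
  best <- best_of(popn)
  trace <- numeric(ga$generations)
  tournament <- function() {
    best_of(popn[sample.int(ga$pop_size, min(ga$tournament_size, ga$pop_size))])
  }
  for (gen in seq_len(ga$generations)) {
    ord <- order(vapply(popn, function(i) -i$fitness, numeric(1L)),
                 vapply(popn, function(i) -i$meanz, numeric(1L)),
                 vapply(popn, function(i) -sum(i$mask), numeric(1L)),
                 vapply(popn, function(i) -i$s, numeric(1L)))
    nxt <- popn[ord[seq_len(ga$elitism)]]
    while (length(nxt) < ga$pop_size) {
      p1 <- tournament(); p2 <- tournament()
      c1 <- p1$mask; c2 <- p2$mask; s1 <- p1$s; s2 <- p2$s
      if (runif(1) < ga$crossover_prob) {
        swap <- runif(m) < 0.5
        tmp <- c1[swap]; c1[swap] <- c2[swap]; c2[swap] <- tmp
        if (runif(1) < 0.5) { tmp <- s1; s1 <- s2; s2 <- tmp }
      }
      for (ch in list(list(c1, s1), list(c2, s2))) {
        if (length(nxt) >= ga$pop_size) break
        mask <- xor(ch[[1]], runif(m) < mut)
        s <- ch[[2]]
        if (runif(1) < 0.2) s <- s + sample(c(-1L, 1L), 1L)
        nxt[[length(nxt) + 1L]] <- new_ind(mask, s)
      }
    }
    popn <- nxt
    gb <- best_of(popn)
    if (.ga_better(gb, best)) best <- gb
    trace[gen] <- best$fitness
  }
  if (ga$refine) {
    # deterministic memetic refinement: greedy single-bit flips until no
    # flip improves, then a sweep over admissible signature sizes
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (b in seq_len(m)) {
        cand_mask <- best$mask
        cand_mask[b] <- !cand_mask[b]
        if (sum(cand_mask) < 2L * s_range[1L]) next
        cand <- new_ind(cand_mask, best$s)
        if (.ga_better(cand, best)) { best <- cand; improved <- TRUE }
      }
    }
    for (s_try in seq(s_range[1L], min(s_range[2L], sum(best$mask) %/% 2L))) {
      cand <- new_ind(best$mask, s_try)
      if (.ga_better(cand, best)) best <- cand
    }
  }
  list(best = list(probes = pool[best$mask], s = best$s,
                   fitness = best$fitness),
       trace = trace, pool = pool)
}

#' Honest (nested) cross-validated accuracy of the optimised classifier
#'
#' For each outer fold the candidate pool and the GA run on the training
#' samples only; the held-out samples are then classified with the selected
#' probe subset and signature size. This is the honest estimate of the whole
#' procedure's accuracy; [ga_optimize()] on all samples (the "paper mode"
#' of [run_full_pipeline()]) performs selection once on the full data.
#'
#' @inheritParams ga_optimize
#' @return list with `accuracy`, per-fold selections, fold assignment.
#' @export
cross_validate_ga <- function(mat, labels, ga = ga_config(), k = 5, p = 1) {
  labels <- .align_labels(mat, labels)
  mat <- mat[, names(labels)]
  set.seed(ga$seed)
  fold <- .make_folds(labels, as.integer(k), stratified = TRUE)
  pred <- character(length(labels))
  sel <- vector("list", k)
  for (f in seq_len(as.integer(k))) {
    tr <- names(labels)[fold != f]
    te <- names(labels)[fold == f]
    if (!length(te)) next
    fit <- ga_optimize(mat[, tr, drop = FALSE], droplevels(labels[tr]),
                       ga = ga, k = min(k, min(table(labels[tr]))), p = p)
    sel[[f]] <- fit$best
    sub <- mat[fit$best$probes, , drop = FALSE]
    r_tr <- rank_matrix(sub[, tr, drop = FALSE])
    for (ss in te) {
      r_te <- rank_transform(sub[, ss])
      pred[match(ss, names(labels))] <-
        classify_sample(r_te, r_tr, labels[tr], fit$best$s, p)$class
    }
  }
  list(accuracy = mean(pred == as.character(labels)),
       fold_selections = sel, fold_assignment = fold)
}
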