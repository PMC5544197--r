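mk_sig <- function(up, down) {
  structure(list(up = up, down = down, s = length(up), ties_at_cut = FALSE),
            class = "rank_signature")
}

test_that("biomarker union folds membership over all signatures", {
  s1 <- mk_sig(c("a"), c("b"))
  s2 <- mk_sig(c("b"), c("c"))
  expect_identical(biomarker_union(list(s1, s2)), c("a", "b", "c"))
  expect_identical(biomarker_union(list(s1, s1)), c("a", "b"))
  expect_error(biomarker_union(list()), "at least one")

  # oracle: independent fold over membership flags of 20 random signatures
  set.seed(50)
  probes <- sprintf("p%02d", 1:40)
  sigs <- lapply(1:20, function(i) {
    pick <- sample(probes, 8)
    mk_sig(pick[1:4], pick[5:8])
  })
  member <- rep(FALSE, 40)
  names(member) <- probes
  for (sg in sigs) member[c(sg$up, sg$down)] <- TRUE
  expect_identical(biomarker_union(sigs), sort(names(member)[member]))
  for (sg in sigs)
    expect_true(all(c(sg$up, sg$down) %in% biomarker_union(sigs)))
})

test_that("differential stats: orientation, null identity, exact p", {
  m <- matrix(c(1, 2, 3, 4,   1, 2, 3, 4), 2, 4, byrow = TRUE,
              dimnames = list(c("pa", "pb"), sprintf("s%d", 1:4)))
  m["pb", ] <- c(5, 6, 1, 2)
  lab <- cohort_labels(colnames(m), c("IS", "IS", "IR", "IR"),
                       class_order = c("IS", "IR"))
  st <- differential_stats(m, lab)
  expect_equal(st$log2fc[1], (1 + 2) / 2 - (3 + 4) / 2)
  expect_identical(st$direction, c("up in IR", "up in IS"))
  expect_equal(st$p[1], 2 / 6, tolerance = 1e-12)  # groups {1,2} vs {3,4}

  # identical groups -> lfc 0, p 1
  m2 <- rbind(px = c(1, 2, 1, 2))
  colnames(m2) <- colnames(m)
  st2 <- differential_stats(m2, lab)
  expect_equal(st2$log2fc, 0)
  expect_equal(st2$p, 1)
  expect_error(differential_stats(m, lab, probes = "nope"), "unknown")
})

test_that("exact rank-sum p equals full enumeration for group sizes <= 8", {
  set.seed(60)
  for (n1 in c(3, 5, 8)) for (n2 in c(3, 6, 8)) {
    x <- rnorm(n1); y <- rnorm(n2) + 0.8
    m <- rbind(p1 = c(x, y))
    colnames(m) <- sprintf("s%02d", seq_len(n1 + n2))
    lab <- cohort_labels(colnames(m), rep(c("A", "B"), c(n1, n2)))
    got <- differential_stats(m, lab)$p
    expect_equal(got, enum_ranksum_p(x, y), tolerance = 1e-9,
                 label = sprintf("n1=%d n2=%d", n1, n2))
  }
})

test_that("approximate p tracks the enumeration oracle within 0.02 at 6 vs 6", {
  set.seed(61)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(6) + runif(1, 0, 1.5)
    # continuous data: exact branch equals enumeration to float precision
    expect_lt(abs(ranksig:::.ranksum_p(x, y) - enum_ranksum_p(x, y)), 1e-12)
    # the normal branch, forced on the same data, stays within 0.02
    expect_lt(abs(ranksig:::.ranksum_p_normal(x, y) - enum_ranksum_p(x, y)),
              0.02)
  }
})

test_that("ORA matches the closed-form hypergeometric tail and Holm rule", {
  universe <- sprintf("G%02d", 1:20)
  coll <- list(S = list(description = "", genes = universe[1:5]))
  hit <- ora_enrichment(universe[1:5], coll, universe)
  expect_equal(hit$p_raw, 1 / choose(20, 5), tolerance = 1e-12)

  # saturation: list = universe -> raw p 1 for any set
  sat <- ora_enrichment(universe, coll, universe)
  expect_equal(sat$p_raw, 1)

  # Holm step-down on a constructed raw p vector {0.01, 0.02, 0.5}
  coll3 <- list(A = list(description = "", genes = universe[1:4]),
                B = list(description = "", genes = universe[3:8]),
                C = list(description = "", genes = universe[10:12]))
  res <- ora_enrichment(universe[1:6], coll3, universe)
  manual <- sort(res$p_raw)
  expect_equal(res$p_adj, pmin(1, cummax((3:1) * manual)))
  expect_true(all(res$p_adj >= res$p_raw))
  expect_true(all(res$overlap <= pmin(res$set_size, res$list_size)))
  expect_error(ora_enrichment("G99", coll3, universe), "outside")
  expect_error(ora_enrichment("G01", coll3, character(0)), "empty")
})

test_that("holm adjustment reproduces the worked three-set example", {
  # direct check of the step-down rule on p = {0.01, 0.02, 0.5}
  p <- c(0.01, 0.02, 0.5)
  adj <- pmin(1, cummax((length(p) - seq_along(p) + 1) * p))
  expect_equal(adj, c(0.03, 0.04, 0.5))
})

test_that("restricted search to all genes equals the unrestricted run", {
  ch <- generate_cohort(synthetic_config(n_probes = 200, n_diff_probes = 20,
                                         log2fc = 2, noise_sd = 0.2,
                                         mapped_fraction = 1, seed = 70))
  ga <- ga_config(pool_size = 40, generations = 5, s_range = c(2, 10),
                  seed = 70)
  all_genes <- unique(unlist(ch$probe_gene_map, use.names = FALSE))
  a <- pathway_restricted_search(ch$matrix, ch$labels, all_genes,
                                 ch$probe_gene_map, ga = ga, B = 20)
  b <- run_signature_pipeline(ch$matrix, ch$labels, map = ch$probe_gene_map,
                              ga = ga, B = 20)
  expect_identical(a$probes, b$probes)
  expect_identical(a$accuracy, b$accuracy)
  expect_identical(a$permutation_p, b$permutation_p)

  expect_error(pathway_restricted_search(ch$matrix, ch$labels,
                                         c("NOT_A_GENE"),
                                         ch$probe_gene_map, ga = ga),
               "0 probe")
})
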