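test_that("classify_sample takes the argmin class and flags exact ties", {
  # separable toy geometry: class A samples share the test sample's ordering
  m <- rand_mat(12, 5, seed = 30)
  m[, 2] <- m[, 1] + rnorm(12, 0, 1e-3)     # s02 ~ s01
  m[, 3] <- -m[, 1]                          # s03 reversed
  m[, 4] <- -m[, 1] + rnorm(12, 0, 1e-3)
  m[, 5] <- m[, 1] + rnorm(12, 0, 1e-3)     # held-out sample, class A-like
  lab <- cohort_labels(sprintf("s%02d", 1:4), c("A", "A", "B", "B"),
                       class_order = c("A", "B"))
  ranks <- rank_matrix(m)
  res <- classify_sample(ranks[, 5], ranks[, 1:4], lab, s = 3)
  expect_identical(res$class, "A")
  expect_lt(res$mean_distances[["A"]], res$mean_distances[["B"]])

  # exact tie: both classes at identical mean distance -> first class, flag
  # (one training sample per class is legal for classify_sample)
  m2 <- cbind(a = m[, 1], b = -m[, 1])
  lab2 <- setNames(factor(c("A", "B"), levels = c("B", "A")), c("a", "b"))
  r2 <- rank_matrix(m2)
  test <- rank_transform(m[, 2])
  d_a <- signature_distance(extract_signature(test, 3), r2[, "a"],
                            extract_signature(r2[, "a"], 3), test)
  d_b <- signature_distance(extract_signature(test, 3), r2[, "b"],
                            extract_signature(r2[, "b"], 3), test)
  if (abs(d_a - d_b) < 1e-12) {
    res2 <- classify_sample(test, r2, lab2, s = 3)
    expect_true(res2$tie)
    expect_identical(res2$class, "B")      # first declared class
  }
  expect_error(classify_sample(test, r2, lab2[1], s = 3), "label")
})

test_that("leave-one-out on a separable 4-sample cohort is perfect", {
  set.seed(41)
  base <- rnorm(20)
  m <- cbind(a = base + rnorm(20, 0, .01), b = base + rnorm(20, 0, .01),
             c = -base + rnorm(20, 0, .01), d = -base + rnorm(20, 0, .01))
  rownames(m) <- sprintf("p%02d", 1:20)
  lab <- cohort_labels(colnames(m), c("X", "X", "Y", "Y"))
  cv <- cross_validate(m, lab, s = 5, k = 4, seed = 1)   # k = n: LOO
  expect_equal(cv$accuracy, 1.0)
  expect_identical(nrow(cv$folds), 4L)
})

test_that("cross_validate agrees with explicit per-fold classify_sample", {
  ch <- generate_cohort(synthetic_config(n_probes = 200, n_diff_probes = 40,
                                         log2fc = 1, noise_sd = 0.3,
                                         n_per_group = 5, seed = 2))
  cv <- cross_validate(ch$matrix, ch$labels, s = 20, k = 5, seed = 9)
  ranks <- rank_matrix(ch$matrix)
  for (i in seq_along(ch$labels)) {
    f <- cv$fold_assignment[i]
    train <- names(ch$labels)[cv$fold_assignment != f]
    pred <- classify_sample(ranks[, i], ranks[, train, drop = FALSE],
                            ch$labels[train], s = 20)$class
    expect_identical(pred, cv$folds$predicted[i])
  }
})

test_that("accuracy is invariant to sample order and stratification errors out", {
  ch <- generate_cohort(synthetic_config(n_probes = 150, n_diff_probes = 30,
                                         log2fc = 2, noise_sd = 0.2, seed = 3))
  acc1 <- cross_validate(ch$matrix, ch$labels, s = 15, k = 5, seed = 7)$accuracy
  set.seed(1)
  shuffled <- sample(colnames(ch$matrix))
  acc2 <- cross_validate(ch$matrix[, shuffled], ch$labels[shuffled],
                         s = 15, k = 5, seed = 7)$accuracy
  expect_identical(acc1, acc2)
  expect_error(cross_validate(ch$matrix, ch$labels, s = 15, k = 25, seed = 1),
               "k must lie")
})

test_that("permutation p-value follows the add-one closed form", {
  expect_equal(permutation_pvalue(1.0, rep(0.5, 10000)), 1 / 10001)
  expect_equal(round(permutation_pvalue(1.0, rep(0.5, 10000)), 4), 0.0001)
  expect_equal(permutation_pvalue(0.1, rep(0.5, 50)), 1.0)
  expect_equal(permutation_pvalue(0.9, c(rep(1, 49), rep(0.3, 9951))),
               50 / 10001)
  expect_equal(round(permutation_pvalue(0.9, c(rep(1, 49), rep(0.3, 9951))),
                     4), 0.005)
  expect_error(permutation_pvalue(1, numeric(0)), "non-empty")
  # monotone non-increasing in the observed statistic
  nulls <- runif(200)
  ps <- vapply(seq(0, 1, 0.1), permutation_pvalue,
               numeric(1L), null_accuracies = nulls)
  expect_true(all(diff(ps) <= 0))
})

test_that("permutation test is seed-reproducible and floors on strong signal", {
  ch <- generate_cohort(synthetic_config(n_probes = 400, n_diff_probes = 40,
                                         log2fc = 2, noise_sd = 0.2, seed = 11))
  a <- permutation_test(ch$matrix, ch$labels, s = 20, k = 5, B = 50, seed = 5)
  b <- permutation_test(ch$matrix, ch$labels, s = 20, k = 5, B = 50, seed = 5)
  expect_identical(a$null_accuracies, b$null_accuracies)
  expect_equal(a$observed, 1.0)
  expect_equal(a$p, 1 / 51)
})
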