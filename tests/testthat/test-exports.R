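test_that("heat-map export is shaped and order-invariant", {
  m <- rand_mat(20, 6, seed = 80)
  lab <- two_class(3, samples = colnames(m))
  bio <- rownames(m)[c(3, 7, 11, 15)]
  R <- export_heatmap_data(m, bio, lab)
  expect_identical(nrow(R), length(bio))     # row count = biomarker size
  expect_setequal(rownames(R), bio)
  # ranks are within each full sample profile
  full <- rank_matrix(m)
  for (s in colnames(R)) expect_equal(R[, s], full[rownames(R), s])

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  export_heatmap_data(m, bio, lab, path = f1)
  set.seed(81)
  shuf <- sample(colnames(m))
  export_heatmap_data(m[, shuf], lab[shuf], path = f2, biomarker = bio)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(export_heatmap_data(m, c("nope"), lab), "unknown probe")

  m2 <- m[1:2, 1:4]
  expect_identical(dim(export_heatmap_data(m2, rownames(m2),
                                           two_class(2, samples = colnames(m2)))),
                   c(2L, 4L))
})

test_that("signatures write as two-column probe/direction TSV", {
  r <- rank_transform(setNames(c(5, 1, 4, 2, 3), letters[1:5]))
  f <- withr::local_tempfile()
  write_signature(extract_signature(r, 2), f)
  df <- read.delim(f, stringsAsFactors = FALSE)
  expect_identical(df$probe, c("a", "c", "b", "d"))
  expect_identical(df$direction, c("up", "up", "down", "down"))
})

test_that("similarity network thresholds edges as documented", {
  m <- rand_mat(30, 3, seed = 82)
  lab <- setNames(factor(c("A", "A", "B")), colnames(m))
  D <- distance_matrix(m, s = 5)
  net_all <- export_similarity_network(D, lab, threshold = 0)
  expect_identical(nrow(net_all$edges), 3L)       # complete graph on 3 nodes
  net_none <- export_similarity_network(D, lab, threshold = 1)
  expect_identical(nrow(net_none$edges), 0L)
  # default drops the weakest quartile
  net_def <- export_similarity_network(D, lab)
  expect_lte(nrow(net_def$edges), 3L)
  expect_identical(net_def$nodes$class, c("A", "A", "B"))
})

test_that("strong-signal network clusters by class under single-link cut", {
  ok <- 0L
  for (sd in 1:10) {
    ch <- generate_cohort(synthetic_config(n_probes = 300, n_diff_probes = 60,
                                           log2fc = 2, noise_sd = 0.2,
                                           seed = sd))
    D <- distance_matrix(ch$matrix, s = 30)
    hc <- hclust(as.dist(D), method = "single")
    cl <- cutree(hc, k = 2)
    is_cl <- unique(cl[ch$labels == "IS"])
    ir_cl <- unique(cl[ch$labels == "IR"])
    if (length(is_cl) == 1L && length(ir_cl) == 1L && is_cl != ir_cl)
      ok <- ok + 1L
  }
  expect_gte(ok, 6L)
})

test_that("full pipeline is deterministic and reports its headline numbers", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  cfg <- list(seed = 5,
              simulate = list(n_probes = 300, n_diff_probes = 20,
                              log2fc = 2, noise_sd = 0.2, seed = 5),
              pool_size = 30, pop_size = 20, generations = 5,
              s_range = c(2, 10), permutations = 50)
  man1 <- run_full_pipeline(c(cfg, list(out_dir = dir1)))
  man2 <- run_full_pipeline(c(cfg, list(out_dir = dir2)))
  for (f in c("biomarker.tsv", "enrichment.tsv", "heatmap_ranks.tsv",
              "network_edges.tsv", "network_nodes.tsv")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)),
                     label = f)
  }
  expect_equal(man1$results$accuracy, 1.0)
  expect_equal(man1$results$permutation_p, 1 / 51)
  expect_true(file.exists(file.path(dir1, "manifest.json")))
  expect_error(run_full_pipeline(list(expression = "no/such/file.tsv")),
               "missing input path")
})

test_that("CLI subcommands simulate, classify and ora run end to end", {
  out <- withr::local_tempdir()
  ranksig_cli(c("simulate", "--n-probes", "200", "--n-diff", "20",
                "--log2fc", "2", "--noise-sd", "0.2", "--seed", "3",
                "--out", out))
  expect_true(all(file.exists(file.path(
    out, c("expression.tsv", "labels.tsv", "probe_map.tsv",
           "gene_sets.gmt", "clinical.csv", "truth.json")))))
  rep <- file.path(out, "cv.json")
  cv <- ranksig_cli(c("classify", "--expression",
                      file.path(out, "expression.tsv"),
                      "--labels", file.path(out, "labels.tsv"),
                      "--signature-size", "20", "--seed", "3",
                      "--out", rep))
  expect_equal(cv$accuracy, 1.0)
  expect_true(file.exists(rep))

  genes_f <- file.path(out, "genes.txt")
  map <- read_probe_map(file.path(out, "probe_map.tsv"))
  writeLines(unique(unlist(map))[1:10], genes_f)
  tab <- ranksig_cli(c("ora", "--genes", genes_f,
                       "--probe-map", file.path(out, "probe_map.tsv"),
                       "--gene-sets", file.path(out, "gene_sets.gmt"),
                       "--out", file.path(out, "ora.tsv")))
  expect_true(all(tab$p_adj >= tab$p_raw))
})
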