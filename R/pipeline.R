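#' Run the full discovery pipeline on one configuration
#'
#' Orchestrates: synthetic-cohort generation (or loading of user files) ->
#' candidate pool + genetic optimisation -> probe-label permutation test ->
#' biomarker extraction with per-probe differential statistics ->
#' over-representation analysis -> optional pathway-restricted ("reverse")
#' search -> heat-map and similarity-network exports, all governed by a
#' single seed. Artifacts are deterministic functions of (inputs, seed);
#' stage timings go to stderr only, so two runs of the same configuration
#' produce byte-identical artifact sets.
#'
#' @param config named list (or path to a JSON file) with elements:
#'   * `seed` — master seed (default 1);
#'   * `simulate` — list of [synthetic_config()] arguments, or `NULL` to
#'     load files;
#'   * `expression`, `labels_file`, `probe_map`, `gene_sets` — input paths
#'     (used when `simulate` is `NULL`); the labels file is a two-column TSV
#'     (sample, class);
#'   * `s_range`, `pool_size`, `pop_size`, `generations` — GA knobs;
#'   * `folds` (default 5), `weight_p` (default 1), `permutations`
#'     (default 100), `paper_mode` (default TRUE);
#'   * `restrict_set` — gene-set name for the reverse search (optional);
#'   * `out_dir` — output directory.
#' @return `run_manifest`: list with the configuration snapshot, seed,
#'   input digests, package version, artifact paths and headline results.
#' @export
run_full_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("missing input path: ", config)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(
    list(seed = 1L, simulate = NULL, expression = NULL, labels_file = NULL,
         probe_map = NULL, gene_sets = NULL, s_range = c(2L, 25L),
         pool_size = 100L, pop_size = 40L, generations = 30L, folds = 5L,
         weight_p = 1, permutations = 100L, paper_mode = TRUE,
         restrict_set = NULL, out_dir = "ranksig_run"),
    config)
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) message(sprintf("[%.1fs] ", proc.time()[["elapsed"]] - t0), ...)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  digests <- character(0)

  if (!is.null(cfg$simulate)) {
    say("simulate: generating synthetic cohort")
    sim_args <- cfg$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    cohort <- do.call(synthetic_config, sim_args)
    cohort <- generate_cohort(cohort)
    mat <- cohort$matrix; labels <- cohort$labels
    map <- cohort$probe_gene_map; sets <- cohort$gene_sets
  } else {
    for (f in c(cfg$expression, cfg$labels_file, cfg$probe_map, cfg$gene_sets))
      if (!is.null(f) && !file.exists(f)) stop("missing input path: ", f)
    say("load: reading inputs")
    mat <- average_replicate_probes(read_expression_matrix(cfg$expression))
    lab_df <- utils::read.table(cfg$labels_file, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
    labels <- cohort_labels(lab_df[[1L]], lab_df[[2L]])
    map <- if (is.null(cfg$probe_map)) NULL else read_probe_map(cfg$probe_map)
    sets <- if (is.null(cfg$gene_sets)) NULL else read_gmt(cfg$gene_sets)
    digests <- vapply(c(cfg$expression, cfg$labels_file, cfg$probe_map,
                        cfg$gene_sets),
                      function(f) unname(tools::md5sum(f)), character(1L))
  }

  ga <- ga_config(pop_size = cfg$pop_size, generations = cfg$generations,
                  s_range = cfg$s_range, pool_size = cfg$pool_size,
                  seed = cfg$seed)
  say("optimise: GA signature search + permutation test (B = ",
      cfg$permutations, ")")
  res <- run_signature_pipeline(mat, labels, map = map, ga = ga,
                                k = cfg$folds, p = cfg$weight_p,
                                B = cfg$permutations,
                                paper_mode = isTRUE(cfg$paper_mode))

  say("report: biomarker table, ORA, exports")
  utils::write.table(res$stats, file.path(cfg$out_dir, "biomarker.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ora <- NULL
  if (!is.null(sets) && !is.null(map) && length(res$genes)) {
    universe <- sort(unique(unlist(map, use.names = FALSE)))
    ora <- ora_enrichment(res$genes, sets, universe)
    utils::write.table(ora, file.path(cfg$out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  export_heatmap_data(mat, res$probes, labels,
                      path = file.path(cfg$out_dir, "heatmap_ranks.tsv"))
  sub <- mat[res$selected, , drop = FALSE]
  D <- distance_matrix(sub, res$s, cfg$weight_p)
  net <- export_similarity_network(D, labels,
                                   path = file.path(cfg$out_dir, "network"))

  restricted <- NULL
  if (!is.null(cfg$restrict_set)) {
    if (is.null(sets) || is.null(sets[[cfg$restrict_set]]))
      stop("restrict_set not found in the gene-set collection: ",
           cfg$restrict_set)
    say("reverse: pathway-restricted search on ", cfg$restrict_set)
    restricted <- pathway_restricted_search(
      mat, labels, sets[[cfg$restrict_set]]$genes, map, ga = ga,
      k = cfg$folds, p = cfg$weight_p, B = cfg$permutations)
  }

  manifest <- list(
    config = cfg[setdiff(names(cfg), "out_dir")],
    seed = cfg$seed,
    input_digests = as.list(digests),
    version = as.character(utils::packageVersion("ranksig")),
    results = list(
      n_probes = nrow(mat), n_samples = ncol(mat),
      signature_size = res$s, biomarker_size = length(res$probes),
      accuracy = res$accuracy, permutation_p = res$permutation_p,
      honest_accuracy = res$honest_accuracy,
      top_set = if (!is.null(ora)) ora$set[1L] else NULL,
      top_set_p_adj = if (!is.null(ora)) ora$p_adj[1L] else NULL,
      restricted_accuracy = if (!is.null(restricted)) restricted$accuracy else NULL,
      restricted_p = if (!is.null(restricted)) restricted$permutation_p else NULL))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  say("done")
  invisible(structure(c(manifest,
                        list(biomarker = res, ora = ora, network = net,
                             restricted = restricted)),
                      class = "run_manifest"))
}
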