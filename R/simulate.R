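#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the statistical structure of a two-colour log-ratio
#' microarray study of two extreme-phenotype groups of 10 samples: Gaussian
#' log-ratios, a few percent of probes differential with small effects
#' (|log2FC| drawn in 0.07--0.3 by default), gene sets with a shared latent
#' factor inducing within-pathway correlation, and one designated "enriched"
#' set receiving a fixed fraction of its genes among the differential probes.
#'
#' @param n_probes number of (post-averaging, unique) probes; default 4000,
#'   usable up to the full-array scale of 41001.
#' @param n_per_group samples per class; default 10.
#' @param n_diff_probes number of differential probes; default 100.
#' @param log2fc planted effect, oriented first-class-minus-second-class
#'   (sensitive minus resistant). `NULL` (default) draws magnitudes uniformly
#'   in `[0.07, 0.3]` with random signs; a scalar plants that magnitude with
#'   random signs; a vector of length `n_diff_probes` is used as-is (signed).
#' @param noise_sd within-sample Gaussian noise SD on the log2 scale;
#'   default 0.25.
#' @param rho within-gene-set correlation induced by a latent factor with
#'   loading `sqrt(rho)`; default 0.3, must lie in `[0, 1)`.
#' @param n_gene_sets,set_size_range pathway layout; defaults 20 sets of
#'   10--50 genes.
#' @param enriched_fraction fraction of the enriched set's genes whose probes
#'   are differential; default 0.6.
#' @param mapped_fraction fraction of probes with a gene mapping;
#'   default 0.65 (many array probes have no annotation).
#' @param probes_per_gene probe-to-gene multiplicity; default 1.
#' @param confound_age if `TRUE`, shift the resistant group's age upward by
#'   one SD so that matching logic can be stress-tested; default `FALSE`.
#' @param seed integer seed governing all randomness.
#' @return validated config list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_probes = 4000, n_per_group = 10,
                             n_diff_probes = 100, log2fc = NULL,
                             noise_sd = 0.25, rho = 0.3,
                             n_gene_sets = 20, set_size_range = c(10, 50),
                             enriched_fraction = 0.6, mapped_fraction = 0.65,
                             probes_per_gene = 1, confound_age = FALSE,
                             seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes),
              n_per_group = as.integer(n_per_group),
              n_diff_probes = as.integer(n_diff_probes), log2fc = log2fc,
              noise_sd = noise_sd, rho = rho,
              n_gene_sets = as.integer(n_gene_sets),
              set_size_range = as.integer(set_size_range),
              enriched_fraction = enriched_fraction,
              mapped_fraction = mapped_fraction,
              probes_per_gene = as.integer(probes_per_gene),
              confound_age = isTRUE(confound_age), seed = as.integer(seed))
  if (cfg$n_diff_probes > cfg$n_probes)
    stop("n_diff_probes must not exceed n_probes")
  if (!is.null(log2fc) && length(log2fc) > 1 &&
      length(log2fc) != cfg$n_diff_probes)
    stop("log2fc vector must have length n_diff_probes")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  if (cfg$rho < 0 || cfg$rho >= 1) stop("rho must lie in [0, 1)")
  if (length(cfg$set_size_range) != 2L ||
      cfg$set_size_range[1] > cfg$set_size_range[2] ||
      cfg$set_size_range[1] < 2L)
    stop("set_size_range must be an increasing pair >= 2")
  n_genes <- ceiling(cfg$mapped_fraction * cfg$n_probes / cfg$probes_per_gene)
  if (cfg$set_size_range[2] > n_genes)
    stop("inconsistent pathway layout: largest set exceeds the gene universe (",
         n_genes, " genes)")
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic two-group expression cohort
#'
#' Baseline per-probe means are Normal(0, 1); each sample adds Gaussian
#' noise of SD `noise_sd`, decomposed for gene-set members into a shared
#' per-set latent factor (loading `sqrt(rho)`) and an independent remainder,
#' so that total noise variance stays `noise_sd^2`. Differential probes are
#' shifted by the planted log2FC: the "resistant" (second) class is lowered
#' by the signed effect, so the observed first-minus-second log2FC equals
#' the planted value. The clinical table is drawn so that HOMA-IR separates
#' the two groups (sensitive about 0.5, resistant about 4, emulating the
#' 8-fold separation of an extreme-group design). Fully reproducible from
#' `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_cohort` with elements `matrix`
#'   (probe x sample), `labels` (two-level factor, `IS` then `IR`),
#'   `probe_gene_map`, `gene_sets` (GMT-style list), `clinical`
#'   (data.frame) and `truth` (differential probe ids with signed effects,
#'   enriched set name, group assignment).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  np <- config$n_probes; ng <- config$n_per_group
  probes <- sprintf("P%05d", seq_len(np))
  samples <- c(sprintf("IS_%02d", seq_len(ng)), sprintf("IR_%02d", seq_len(ng)))
  labels <- cohort_labels(samples, rep(c("IS", "IR"), each = ng),
                          class_order = c("IS", "IR"))

  # gene universe and probe map
  n_mapped <- round(config$mapped_fraction * np)
  n_genes <- ceiling(n_mapped / config$probes_per_gene)
  genes <- sprintf("G%05d", seq_len(n_genes))
  mapped_probes <- sort(sample(probes, n_mapped))
  gene_of_probe <- sample(rep_len(genes, n_mapped))
  map <- split(gene_of_probe, factor(mapped_probes, levels = mapped_probes))

  # gene sets; the first is the designated enriched set
  sz <- seq.int(config$set_size_range[1], config$set_size_range[2])
  sizes <- sz[sample.int(length(sz), config$n_gene_sets, replace = TRUE)]
  set_names <- sprintf("SET%03d", seq_len(config$n_gene_sets))
  gene_sets <- lapply(seq_len(config$n_gene_sets), function(i)
    list(description = if (i == 1L) "enriched" else "background",
         genes = sort(sample(genes, sizes[i]))))
  names(gene_sets) <- set_names

  # differential probes: seed the enriched set first, then fill at random
  nd <- config$n_diff_probes
  diff_probes <- character(0)
  if (nd > 0) {
    enr_genes <- gene_sets[[1L]]$genes
    k <- round(config$enriched_fraction * length(enr_genes))
    probe_by_gene <- split(mapped_probes,
                           factor(gene_of_probe, levels = genes))
    enr_core <- unlist(probe_by_gene[sample(enr_genes, k)], use.names = FALSE)
    enr_core <- enr_core[seq_len(min(length(enr_core), nd))]
    rest <- sample(setdiff(probes, enr_core), nd - length(enr_core))
    diff_probes <- sort(c(enr_core, rest))
  }
  effects <- numeric(0)
  if (nd > 0) {
    effects <- if (is.null(config$log2fc)) {
      runif(nd, 0.07, 0.3) * sample(c(-1, 1), nd, replace = TRUE)
    } else if (length(config$log2fc) == 1L) {
      abs(config$log2fc) * sample(c(-1, 1), nd, replace = TRUE)
    } else as.numeric(config$log2fc)
    names(effects) <- diff_probes
  }

  # per-probe latent-factor assignment: first gene set containing the gene
  set_of_gene <- rep(NA_integer_, n_genes)
  names(set_of_gene) <- genes
  for (i in rev(seq_along(gene_sets)))
    set_of_gene[gene_sets[[i]]$genes] <- i
  factor_of_probe <- rep(NA_integer_, np)
  names(factor_of_probe) <- probes
  factor_of_probe[mapped_probes] <- set_of_gene[gene_of_probe]

  mu <- rnorm(np)
  names(mu) <- probes
  sdn <- config$noise_sd
  vals <- matrix(0, np, 2 * ng, dimnames = list(probes, samples))
  in_set <- !is.na(factor_of_probe)
  for (j in seq_len(2 * ng)) {
    eps <- rnorm(np, sd = sdn)
    z <- rnorm(config$n_gene_sets)
    noise <- eps
    noise[in_set] <- sdn * (sqrt(config$rho) * z[factor_of_probe[in_set]] +
                            sqrt(1 - config$rho) * eps[in_set] / sdn)
    vals[, j] <- mu + noise
  }
  if (nd > 0)
    vals[diff_probes, labels == "IR"] <-
      vals[diff_probes, labels == "IR"] - effects

  clinical <- .simulate_clinical(samples, labels, config)

  structure(list(matrix = vals, labels = labels, probe_gene_map = map,
                 gene_sets = gene_sets, clinical = clinical,
                 truth = list(differential = effects,
                              enriched_set = if (nd > 0) set_names[1L] else NA_character_,
                              groups = labels)),
            class = "synthetic_cohort")
}

#' Generate an effect-free (null) cohort
#'
#' Identical to [generate_cohort()] with every planted effect forced to
#' zero; the truth records no differential probes.
#'
#' @inheritParams generate_cohort
#' @return as [generate_cohort()].
#' @export
generate_null_cohort <- function(config = synthetic_config()) {
  cfg <- config
  cfg$n_diff_probes <- 0L
  cfg$log2fc <- NULL
  out <- generate_cohort(cfg)
  out$truth$differential <- setNames(numeric(0), character(0))
  out
}

# Clinical covariates: age/sex/BMI independent of group unless confounding is
# requested; HOMA-IR targets drawn per group (sensitive ~ N(0.5, 0.1),
# resistant ~ lognormal with mean 4) and insulin back-computed from a normal
# fasting glucose so that homa_ir(glucose, insulin) reproduces the target.
.simulate_clinical <- function(samples, labels, config) {
  n <- length(samples)
  is_ir <- labels == "IR"
  age <- round(rnorm(n, 37, 8))
  if (config$confound_age) age <- age + ifelse(is_ir, 8, 0)
  age <- pmin(pmax(age, 20), 60)
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.65, 0.35))
  bmi <- round(rnorm(n, 22.4, 1.8), 1)
  bmi <- pmin(pmax(bmi, 18.5), 24.9)
  homa <- ifelse(is_ir,
                 rlnorm(n, meanlog = log(4) - 0.5 * 0.36, sdlog = 0.6),
                 pmax(rnorm(n, 0.5, 0.1), 0.2))
  glucose <- round(rnorm(n, 4.8, 0.35), 2)
  insulin <- round(homa * 22.5 / glucose, 2)
  data.frame(id = samples, sex = sex, age = age, bmi = bmi,
             glucose = glucose, insulin = insulin,
             homa_ir = round(glucose * insulin / 22.5, 3),
             group = as.character(labels), stringsAsFactors = FALSE)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic expression cohort: ", nrow(x$matrix), " probes x ",
      ncol(x$matrix), " samples (", paste(levels(x$labels), collapse = " vs "),
      ")\n", sep = "")
  cat("  differential probes: ", length(x$truth$differential),
      "; enriched set: ", x$truth$enriched_set, "\n", sep = "")
  invisible(x)
}
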