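# ranksig

Rank-based signature classification for two-group expression cohorts, with
cross-validation, probe-label permutation testing, genetic-algorithm
signature optimisation, biomarker extraction and pathway analysis — plus a
synthetic-cohort generator so the whole pipeline is testable offline.

## Who this is for

Analysts of small extreme-phenotype expression studies (e.g. 10 vs 10
insulin-sensitive vs insulin-resistant PBMC transcriptomes selected from
the tails of a HOMA-IR distribution, where
HOMA-IR = fasting glucose [mmol/l] × fasting insulin [mU/l] / 22.5).
With weak effects (|log2FC| ~ 0.1–0.3) and n = 10 per group, per-gene
testing has little power; classifying whole rank profiles and asking
whether classification *accuracy* beats a permutation null is often the
more answerable question.

## The method

For each sample the probes are ranked within the sample (1 = lowest);
sample *i* is summarised by its **rank signature** — the ordered sets of
its *s* highest- and *s* lowest-ranked probes. Signatures are compared all
against all with a weighted enrichment score ES ∈ [−1, 1] (running-sum
statistic over the ranked list; hit weight |rank − (N+1)/2|^p, miss
decrement 1/(N−|S|), score = signed maximum deviation):

    sim(i→j) = [ ES(up_i in profile_j) − ES(down_i in profile_j) ] / 2
    d(i, j)  = 1 − [ sim(i→j) + sim(j→i) ] / 2        ∈ [0, 2]

A held-out sample joins the class with the lowest mean distance. Accuracy
is estimated by stratified k-fold cross-validation; significance by a
per-sample probe-label permutation test with the add-one p-value
p = (r+1)/(B+1) (floor 1/(B+1): 0.0001 at B = 10000). A genetic algorithm
selects the probe subset and signature size; the **biomarker** is the
union of the probes appearing in at least one per-sample signature,
reported with per-probe log2 fold changes and exact Wilcoxon rank-sum
p-values, and fed into hypergeometric over-representation analysis with
step-down Bonferroni (Holm) correction. The same machinery restricted to
one gene set's probes ("reverse" mode) tests whether a single pathway
supports classification.

## Worked example

```r
library(ranksig)

cohort <- generate_cohort(synthetic_config(
  n_probes = 1000, n_diff_probes = 40, log2fc = 1, noise_sd = 0.25,
  seed = 7))
cohort
#> Synthetic expression cohort: 1000 probes x 20 samples (IS vs IR)
#>   differential probes: 40; enriched set: SET001

res <- run_signature_pipeline(cohort$matrix, cohort$labels,
                              map = cohort$probe_gene_map,
                              ga = ga_config(pool_size = 60, seed = 7),
                              k = 5, B = 100)
res
#> Rank-signature biomarker: 34 probes (29 mapped genes), s = 17
#>   CV accuracy 1.000; permutation p = 0.0099 (B = 100)

universe <- sort(unique(unlist(cohort$probe_gene_map)))
head(ora_enrichment(res$genes, cohort$gene_sets, universe), 3)
#>      set overlap set_size    p_raw    p_adj
#> 1 SET001      20       38 4.72e-21 9.45e-20
#> 2 SET013       3       28 1.23e-01 1.00e+00
#> 3 SET009       2       21 2.40e-01 1.00e+00
```

Reading the numbers: the cohort separates perfectly under 5-fold
cross-validation (accuracy 1.000), and that accuracy beats all B = 100
probe-label permutations, so p sits at the attainable floor
1/101 ≈ 0.0099. The 34-probe biomarker contains only planted differential
probes (precision 1.00, recall 0.85 against the generator's truth), and
the designated enriched set SET001 dominates the over-representation table
(Holm-adjusted p ≈ 9.4e-20); unrelated sets are non-significant.

A command-line wrapper covers the same steps
(`inst/cli/ranksig simulate|select-groups|classify|permtest|biomarker|ora|restrict|export|run-all`),
and `run_full_pipeline()` drives simulate → optimise → permute → biomarker
→ ORA → exports from a single JSON config with one master seed.

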