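---
title: "Rank-signature classification of expression cohorts: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-signature classification of expression cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ranksig)
```

## The problem and the model

`ranksig` addresses two-group classification of expression profiles when the
biological signal is weak and the sample size small — the typical situation
of an extreme-phenotype microarray design, e.g. insulin-sensitive versus
insulin-resistant PBMC transcriptomes selected from the tails of a HOMA-IR
distribution (HOMA-IR = fasting glucose [mmol/l] x fasting insulin [mU/l] /
22.5; `homa_ir()`, `select_extreme_groups()`).

The method works entirely on **within-sample ranks**, which makes every
downstream quantity invariant to strictly monotone per-sample distortions
(array effects, scale differences):

1. each sample's probes are ranked (ascending, average ties:
   `rank_transform()`);
2. a sample is summarised by its **rank signature**: the ordered sets of its
   `s` highest- and `s` lowest-ranked probes (`extract_signature()`);
3. sample *i* is compared to sample *j* by evaluating how extreme sample
   *i*'s signature falls in sample *j*'s ranking, using a weighted
   **enrichment score** (ES): walking *j*'s probes from highest to lowest
   rank, a probe of the query set adds its weight `|rank - (N+1)/2|^p`
   (normalised by the summed hit weights), a probe outside subtracts
   `1/(N-|S|)`; the ES is the signed maximum deviation of this running sum,
   in [-1, 1] (`enrichment_score()`). `p = 0` recovers the classic
   Kolmogorov–Smirnov form; the default `p = 1` weights hits by their
   centred-rank magnitude, so mid-ranking probes carry little evidence;
4. the directed similarity is `(ES(up_i in j) - ES(down_i in j)) / 2`, and
   the symmetrised distance `1 - (sim_ij + sim_ji)/2`, in [0, 2]
   (`signature_distance()`, `distance_matrix()`). A sample is at distance 0
   from itself (tie-free profiles) and at distance 2 from its exact rank
   reversal;
5. a held-out sample joins the class whose members sit at the lowest mean
   distance (`classify_sample()`), with stratified k-fold cross-validation
   (`cross_validate()`) and a probe-label permutation test
   (`permutation_test()`) assessing reliability;
6. a genetic algorithm (`ga_optimize()`) tunes which probes (from a
   candidate pool) enter the signatures and the signature size `s`; the
   **biomarker** is the union of the probes appearing in at least one
   per-sample signature (`biomarker_union()`), reported with per-probe log2
   fold changes and rank-sum p-values (`differential_stats()`) and
   interpreted by hypergeometric over-representation with step-down
   Bonferroni correction (`ora_enrichment()`). The same pipeline restricted
   to the probes of one gene set (`pathway_restricted_search()`) asks the
   reverse question: does this pathway alone support classification?

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `s` | signature size (probes per tail) | searched in [2, 25] | accuracy saturates over a broad range; see tie-breaking below |
| `p` | ES weight exponent | 1 | centred-rank weighting; 0 gives the unweighted KS form |
| `k` | CV folds | 5 | matches two groups of 10 (2 held out per class per fold) |
| `B` | permutations | 100 (tests); 10000 at study scale | add-one p floor `1/(B+1)`; 10000 reaches the 0.0001 floor |
| `pool_size` | candidate probes for the optimizer | 100 | top probes by absolute standardised rank-sum statistic |
| `pop_size`/`generations` | GA budget | 40 / 30 | converges on the synthetic benchmarks within seconds |

## Empirical p-values

`permutation_pvalue()` uses the add-one convention `p = (r+1)/(B+1)`, never
exactly zero; with `B = 10000` and an observed statistic beyond every null
the attainable floor is `1/10001`, which prints as `0.0001` at four
decimals. The permutation scheme shuffles, **within each sample**, the
assignment of values to probe labels. A single relabeling shared by all
samples leaves every distance unchanged (the distance depends only on rank
patterns, not probe identities), so the per-sample scheme is the only
non-degenerate reading of a "probe-label permutation".

## Genetic optimisation: fitness and tie-breaking

Cross-validated accuracy on 20 samples lives on a grid of 21 values and
saturates quickly: on a clearly separable cohort *most* probe subsets reach
accuracy 1.0, so accuracy alone cannot rank candidate signatures. The
comparator therefore breaks exact accuracy ties by, in order:

1. **mean per-probe discriminability** — the mean absolute standardised
   rank-sum statistic of the masked probes. Probes without marginal group
   separation drag this mean down and are pruned; at a strong planted
   effect every true probe saturates the statistic at its
   complete-separation maximum, so the mean cannot be improved by dropping
   a redundant true probe;
2. **coverage** — the larger probe mask. Among masks of equally
   discriminative probes the complete one wins, which is what makes the
   reported biomarker (a union of per-sample signatures) recover *all*
   redundant signal probes rather than an arbitrary minimal subset;
3. **the larger signature size `s`** — the biomarker is the union of
   per-sample signatures, so at equal accuracy a larger `s` yields the more
   complete, more reproducible union. Parsimony on the probe *set* is
   already enforced by (1)–(2), so no parsimony pressure on `s` is needed.

A deterministic memetic refinement (single-bit hill-climb plus a sweep over
admissible `s`; `ga_config(refine = )`) finishes the search, making the
selected signature a deterministic function of (data, seed).

Selection on all samples optimistically biases the selected subset's
cross-validated accuracy. The pipeline therefore reports significance from
a permutation test applied to the **stage input matrix** (all probes, or
all probes of a pathway restriction) at the selected `s`, never to the
selected subset: empirically, permuting the post-selection matrix declares
signal-free pathways significant (p <= 0.04 in 10/10 synthetic null
pathways), while the pre-selection statistic keeps them at p > 0.05 (10/10)
and still floors on true signal. `cross_validate_ga()` additionally offers
the fully nested ("honest") estimate, re-running pool selection and the GA
inside every training fold; `run_signature_pipeline(paper_mode = TRUE)`
reports selection-on-all-data fitness alongside, since published analyses
of this design are often ambiguous about which was used.

## The synthetic world

`generate_cohort()` emulates a two-colour log-ratio microarray cohort:
baseline per-probe means N(0, 1); per-sample Gaussian noise (default SD
0.25 on the log2 scale, the order of post-normalisation within-group
variability on such arrays); two groups of 10; differential probes
(default 100 of 4000) shifted by a planted log2 fold change, by default
drawn uniformly from ±[0.07, 0.3] — the magnitude range a weak early
transcriptomic signature exhibits — and configurable up to large effects
for stress tests; gene sets (default 20, sizes 10–50) whose member probes
share a latent factor with loading sqrt(rho), rho = 0.3; one designated
"enriched" set receiving 60% of its genes among the differential probes; a
clinical table whose HOMA-IR separates the groups roughly 8-fold. It does
**not** emulate probe-level dye bias, replicate-probe redundancy, heavy
tails, or batch structure — a green test establishes algorithmic
correctness and calibration under the stated model, not robustness to
those artefacts.

## Calibration of the permutation null — a known limitation

Per-sample probe-label permutation preserves each sample's value
distribution but destroys two structures real cohorts have: the shared
baseline probe means (which dominate every profile) and inter-probe
correlation. Permuted cohorts are therefore not distributed like real
effect-free cohorts, and the permutation p-values are *approximately* but
not exactly calibrated. Measured over 200 effect-free replicates (B = 100)
under the generator defaults, the type-I rate at 0.05 is 0.015 —
conservative, i.e. erring toward missing signal, not inventing it — and a
KS test detects the non-uniformity (p ≈ 0.003; still ≈ 0.009 with rho = 0,
implicating the shared means, the same mechanism behind the well-known
critique of gene-label permutation in enrichment testing). The acceptance
test asserts the ideal calibration bounds and is deliberately left failing
on those two sub-assertions rather than widened; mean null accuracy (0.527,
bound [0.35, 0.65]) and all signal-side criteria pass.

## Numerical choices and degenerate inputs

* ES running sums are evaluated only at hit boundaries (the sum is linear
  between hits); signed-magnitude ties resolve to the positive deviation,
  with a 1e-9 tolerance covering float drift of the accumulated sums.
* All-zero hit weights (every hit exactly at the centre rank, possible for
  odd N with p > 0) fall back to uniform weights.
* Ties at a signature cut are resolved by lexicographic probe id and
  flagged (`ties_at_cut`).
* Exact rank-sum p-values (both groups <= 10, tie-free) double the smaller
  tail of the exact U distribution, capped at 1; otherwise a tie-corrected
  normal approximation with continuity correction is used. At fixed group
  sizes the exact p-values lie on a discrete grid — identical p-values
  across probes are expected, not an error.
* Classification ties (equal mean distance) go to the first declared class
  and are flagged; the class order is always an explicit input.
* Greedy cohort matching restricts swaps to the extreme thirds of the
  HOMA-IR distribution, minimises summed standardised mean differences,
  treats a requested sex match as an exact count constraint, and is a
  declared reconstruction: the original study states *that* groups were
  matched, not how.
* BMI windows use strict inequalities at both ends, so `bmi_max = 25`
  excludes BMI >= 25 and `bmi_min = 25` requires BMI > 25.

## Known limitations

* The permutation null is conservative under realistic probe-mean and
  correlation structure (above).
* Two classes only, by design of the distance-to-class-mean rule.
* `paper_mode = TRUE` accuracy is optimistically biased; use
  `cross_validate_ga()` for honest error estimates.
* The ES weight exponent and the symmetrisation of the directed
  similarities are defaults where the source methodology is silent; both
  are exposed (`p`, and any affine rescaling of the distance leaves the
  argmin classification unchanged).
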