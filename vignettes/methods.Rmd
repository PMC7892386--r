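---
title: "Methods: curated gene effects in osteoarthritis models and network-based prioritisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curated gene effects in osteoarthritis models and network-based prioritisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oagenes)
```

## The problem

Hundreds of genes have been perturbed in animal models of osteoarthritis
(OA) — knockouts, transgenic overexpression, drugs, antibodies — with the
resulting joint-damage phenotype reported study by study. `oagenes`
provides the machinery to turn such a curated corpus of per-experiment
observations into per-gene effect labels, to quantify how reproducible
those labels are across studies, approaches and models, to relate them to
differential-expression (DE) data, and to prioritise new candidate genes
by their proximity to known effect genes in a protein–protein interaction
(PPI) network.

## Effect inference and consensus

Each observation records the direction of the modulation
(`activity_change`: increase or decrease of protein activity) and the
observed effect on OA severity. The per-experiment *inferred gene effect*
combines the two, analogous to the oncogene / tumour-suppressor
distinction:

| activity change | observed effect | inferred gene effect |
|---|---|---|
| decrease | detrimental | protective |
| decrease | protective | detrimental |
| increase | protective | protective |
| increase | detrimental | detrimental |
| any | no effect | no effect |
| any | mixed | mixed |

`infer_effect()` is total and antisymmetric: flipping the modulation
direction flips a directional inference.

`consensus_effect()` combines a gene's inferred effects: conflicting
directions give **ambiguous**; a single direction wins, with no-effect
observations *superseded* by any directional one; **mixed** survives only
when no directional label exists; **no effect** requires every observation
to report no effect.

Two kinds of judgement calls are made explicit as editable configuration
(`curation_config()`) rather than hidden in code:

* the vocabulary maps from free-text intervention / "effect on protein
  product" / model descriptions to the controlled enums (e.g. Removal,
  Inhibition, Knockdown → decrease; unmapped interventions default to
  exogenous because drug names form an open vocabulary while genetic
  interventions form a closed one);
* the definition of *consistency*: a gene is consistent when its
  directional inferred effects never contain both directions. Genes with
  only no-effect observations count as consistent (this follows from the
  supersede rule but is an edge case the corpus description leaves open),
  and mixed observations are excluded from consistency counting because
  they carry no direction.

`consistency_report()` computes four comparisons: genes studied two or
more times genetically; the same for exogenous modulations; genes studied
by both approaches (per-approach consensus labels compared by default; a
pooled-observation variant is available via `cross_approach_method`
because the corpus description does not state which was used); and genes
with unambiguous effects in both spontaneous and surgical models
(per-model consensus labels compared, ambiguous-within-model genes
excluded from the denominator).

A small transcription of published example tables ships with the package
(`printed_examples()`). The three TTR rows in it are flagged `anomalous`:
their printed inferred labels are inverted relative to the rule that every
other printed row follows (knockout with observed detrimental printed as
detrimental, overexpression with observed detrimental printed as
protective), consistent with a transposition at the source. They are
excluded from rule-reproduction checks rather than special-cased in code.

## Differential-expression integration

`significant_gene_sets()` applies the standard DE filter — absolute fold
change ≥ 1.5 (linear scale) and adjusted p ≤ 0.05, both boundaries
inclusive — after collapsing duplicate gene rows to the strongest change.
`map_to_human()` translates symbols through a user-supplied ortholog
table (many-to-one), dropping and counting unmapped symbols, and removes
miRNA identifiers by configurable prefix patterns, since the consensus
corpus covers protein-coding signalling and small-RNA datasets are not
comparable. A protein-coding restriction is applied from a user-supplied
gene list when available; none is bundled.

Overlap between a DE set and the effect-labelled genes is tested with the
one-sided Fisher exact test (the enrichment p equals the upper
hypergeometric tail, computed via `phyper`; the odds ratio is the sample
odds ratio with a 0.5 continuity addition only when a cell is zero).
Whether protective and detrimental genes are differentially represented
within a DE set is tested by a 2×2 χ² test of independence without
continuity correction (`effect_proportion_test()`); a zero margin makes
the test *untestable* (`p = NA`), never silently 1.

Benjamini–Hochberg correction is applied within two separate families,
matching how the results are reported: overlap tests across the datasets
of a run, and proportion tests across all dataset × direction cells
(`overlap_effect_matrix()`). The Fisher universe is per-dataset measured
genes by default; a global universe is available by flag, since the
original analysis does not state which was used.

## Network diffusion with restart

`diffuse()` scores every gene in the largest connected component of the
PPI network by the random-walk-with-restart fixed point

$$F = (1 - r)\,W F + r F_0,$$

where $W$ is the **column-normalised** adjacency matrix, $F_0$ the
uniform distribution over the seed genes (all genes with a consensus
effect on severity — protective, detrimental, ambiguous or mixed; the
no-effect genes are not seeds, and a flag restricts to directional labels
only), and $r$ the restart probability. Column normalisation is chosen
over the symmetric variant because it makes the scores a probability
distribution at every iteration (mass conservation), which the tests
exploit as an invariant. Defaults: $r = 0.3$ (the common
random-walk-with-restart default; cross-validation lets users tune it),
L1 tolerance $10^{-8}$, 1000 iterations maximum (non-convergence is
flagged, not hidden). A closed-form sparse solve of
$(I - (1-r)W)F = rF_0$ is available (`method = "exact"`) and the test
suite requires the two routes to agree to $10\times$ the tolerance.

`rank_genes()` ranks by descending score with average ranks for ties,
excluding the seeds themselves from the ranking domain so candidates
compete only with other non-seed genes.

## Cross-validated recovery and its statistics

`cross_validate()` repeatedly partitions the seeds into $k$ folds
(default 5, the full design being repeated independent partitions;
a repeated random-holdout design is available by flag), runs diffusion
from each retained set, and records the ranks of held-out seeds and of
all never-labelled nodes among all non-retained nodes — a held-out gene
competes with the unlabelled background, matching the "rank out of the
whole network" framing. Identical `rng_seed` gives bit-identical results.

Significance of the separation deserves care. Every rank recorded within
one fold comes from a single diffusion run, and the same held-out genes
recur across folds, so pooling all ranks into one two-sample rank test
overstates the effective sample size by orders of magnitude; we measured
null p-values of the pooled test ranging from $10^{-7}$ to 1 on networks
with no planted structure. `cv_separation_test()` therefore averages each
gene's rank over the folds in which it appears and applies the one-sided
Mann–Whitney test at the gene level, the independent sampling unit. On
null networks this statistic is calibrated (approximately uniform
p-values across independent replicates).

`rank_significance()` tests a small set of externally reported genes
against the random expectation: a one-sided Wilcoxon signed-rank test of
their ranks against the null median $(n+1)/2$, exact for ≤ 25 non-zero
differences (nine genes all ranking better than the median with distinct
magnitudes give exactly $2^{-9} \approx 0.001953$). Ranks exactly at the
null median carry no information and are dropped; a rank-sum variant is
available by flag because "the Wilcoxon test" is ambiguous between the
two.

`prioritise()` applies the published candidate filter: differentially
expressed in at least 3 human OA datasets, at least 4 direct PPI
neighbours among known OA genes, and not itself a known OA gene;
candidates are sorted by network rank and can carry a pass-through
drug-tractability label.

## Synthetic data: what it emulates and what it does not

The generators make every stage testable with known ground truth and no
downloads:

* `synth_observations()` emulates the curated corpus schema. Defaults
  reflect the corpus conditions: single-study genes the most common case
  (1 + Poisson(0.8) observations per gene), a genetic:exogenous mix of
  roughly 63:37, surgical and spontaneous models dominant, and a
  consistency rate of 0.7 (the corpus reports 69–83% across comparisons).
  Consistency is drawn **per gene**, with inconsistent genes alternating
  directions within each approach stratum; this makes the rate measured
  by `consistency_report()` over multi-study genes recover the parameter
  up to binomial error, which per-observation noise would not (a gene
  with $m$ observations would then be consistent with probability
  $q^m + (1-q)^m$).
* `synth_network()` grows a preferential-attachment graph (default 2000
  nodes, attachment 2) and plants a module (default 50 nodes) by adding
  each within-module edge with probability `intra_module_edge_boost`
  (default 0.3); boost 0 is the negative control in which the module is
  topologically invisible. One caveat the tests respect: under
  preferential attachment, node labels correlate with degree, so seed
  subsets must be drawn at random from the module — truncating the sorted
  member list selects high-degree nodes and biases recovery.
* `synth_de_tables()` generates DE *result* tables directly (uniform
  adjusted p for nulls, Beta-skewed for signals; fold changes past the
  1.5× threshold for signals) rather than simulating counts through a DE
  tool, because the pipeline consumes result tables. `enrichment_odds`
  multiplies a gene's odds of being a signal; odds 1 is the null
  calibration case.

What the synthetic data does **not** emulate: real PPI topology beyond
scale-free degree structure, correlated DE datasets, publication bias in
which genes get studied, or severity magnitudes. Passing tests therefore
demonstrate correctness of the machinery and recoverability under a clean
disease-module assumption, not performance on a specific real network.

## Problem sizes and determinism

The bundled checks run at desk scale, chosen so the full suite completes
in well under a minute of compute: 200 random graphs of ≤ 50 nodes for
the oracle-equivalence check, a 2000-node network with a 50-node module
and 40 seeds (5-fold, 5 repeats) for recovery, 20 repeats in the
acceptance script, and three independent 2000-node null networks for the
negative control (tested with a median-p rule, which drops the chance of
a spurious failure from the nominal 5% of a single calibrated test to
under 1%). All randomness flows through explicit integer seeds; the
generators save and restore the caller's RNG state.

## Known limitations

* The consensus scheme is deliberately coarse: it ignores effect sizes,
  tissue specificity and dosage, and treats "mixed" as a terminal label.
* Cross-approach consistency on consensus labels can differ from the
  pooled-observation variant when no-effect observations are superseded
  on one side only; both are exposed.
* The exact diffusion kernel and restart value used in published analyses
  of this kind vary; results are reported with the configuration that
  produced them, and $r$ should be tuned by cross-validation on the
  user's own network.
* Candidate ranks are network-version dependent; the filter thresholds
  (3 human DE datasets, 4 interactions) are exposed as parameters rather
  than treated as universal constants.
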