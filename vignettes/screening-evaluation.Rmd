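---
title: "Evaluating virtual screens and diagnosing benchmark bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating virtual screens and diagnosing benchmark bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenaudit)
library(dplyr)
```

## The problem

A virtual screen ranks a compound library against a protein target so that
true binders ("actives") appear before non-binders ("inactives" or decoys).
Docking produces several candidate poses per compound, often against several
receptor templates, each carrying one or more score channels — an empirical
docking energy (lower is better), a CNN pose probability in [0, 1], a
predicted affinity in pK units. Evaluating a scoring method therefore
involves three distinct steps, each with conventions that matter:

1. reduce per-pose, per-receptor scores to one prediction per
   (target, compound);
2. score the resulting ranking with early-recognition metrics and attach
   uncertainty;
3. ask *why* the method performs as it does — is it reading protein–ligand
   interactions, or exploiting ligand-only regularities baked into the
   benchmark?

`screenaudit` implements all three, plus a synthetic-data generator with
known ground truth so the whole pipeline can be validated end to end.

## Data model and conventions

Scores are ingested into a `screen_tbl` (one row per scored pose) and every
channel is canonicalized to *higher is better* at ingest: lower-is-better
channels (docking energies) are negated once. This removes per-call
direction flags from every downstream function — a single ranking convention
means a single place where sign errors can happen, and negating twice is the
identity, so round-tripping files is safe. Pose probabilities are checked
into [0, 1]; activity labels must be binary (`active`/`inactive`, `1`/`0`,
`TRUE`/`FALSE`) because every metric here is binary-classification based;
ambiguous labels are rejected rather than guessed.

Compounds that carry a label but no docked pose are ranked last (score
`-Inf`) with a warning: the conservative screening interpretation of a
failed docking. Ties are always broken deterministically — at the top-*k*
boundary by (score descending, compound id ascending), in pose selection by
(lower original pose rank, then receptor id) — reproducibility is preferred
over fractional-credit elegance, and users can pre-jitter scores if they
want randomized tie handling.

## Aggregation protocols

`aggregate_best()` takes the maximum canonicalized score over all poses and
receptors — the standard "best predicted score per (target, compound)"
protocol, with a flat max over receptors. `aggregate_worst()` takes the
minimum; contrasting the two is the pose-sensitivity diagnostic: a method
that still enriches actives when scored on its *worst* pose is drawing
mostly on ligand-only information. Two score combinations are provided:
`aggregate_product()` multiplies the pose probability by the predicted
affinity per pose (negative affinities clipped to zero so the product
preserves higher-is-better ordering; the source convention for negative pK
is undefined, and clipping keeps the ordering sensible) and then best-pose
aggregates; `affinity_at_best_pose()` reports the affinity of the
highest-pose-scored pose. We multiply per pose and then maximize rather
than multiplying the two aggregated maxima; the two differ only when the
best pose score and best affinity occur on different poses, and the
per-pose product is the one a docking pipeline can emit as a per-pose
output column.

## Metrics

* **ROC-AUC** via the Mann-Whitney identity with midrank ties: the
  probability a random active outranks a random inactive, half-credit for
  ties. Perfect ranking 1.0, uninformative 0.5.
* **Enrichment factor** EF(α) = (a/k)/(A/N), with k = ⌈αN⌉ compounds in
  the top fraction and a actives among them. The ceiling ⌈·⌉ guarantees
  k ≥ 1 for any non-empty library; the rounding convention is not fixed by
  common usage, so it is documented here and tested against a direct
  counting oracle.
* **Normalized EF** divides EF by the best achievable value
  (min(k, A)/k)/(A/N), giving [0, 1] comparable across libraries with
  different active/total ratios.

Uncertainty comes from a stratified percentile bootstrap (default
`n_boot = 10000`, level 0.95): actives and inactives are resampled
separately, preserving class counts so the metric is defined on every
resample, and all resampling is seeded. Coverage of the 95% AUC interval is
verified by simulation against the binormal ground truth (500 replicates in
the test suite, coverage required in [0.92, 0.98]).

Two comparison procedures are deliberately distinct:

* `compare_distributions()` — an *unpaired* two-sided Mann-Whitney U test on
  per-target metric values, the league-table question ("do these two
  methods' per-benchmark metric distributions differ?"). Exact enumeration
  tail probabilities when both samples have n ≤ 8 without ties; otherwise a
  tie-corrected, continuity-corrected normal approximation (for n = 8 the
  two agree to within 0.02 in p, which the suite checks).
* `significant_win_count()` — a *paired* per-target rule: compounds are
  resampled once per iteration and both methods are evaluated on the same
  resample, giving a bootstrap distribution of the metric difference; a
  target is a win when that interval excludes zero. This is the procedure
  behind "significantly better on X of N targets" statements. The paired
  design removes the shared sampling noise that an unpaired per-target test
  would double-count.

## Cross-docking pose evaluation

`build_crossdock_tasks()` forms one task per (ligand, non-cognate template)
pair; `good_pose_fraction()` reports the fraction of tasks whose top-n poses
by a channel include at least one pose within the RMSD threshold (2 Å
default — the conventional "good pose" cutoff), and `sampling_ceiling()` the
fraction with *any* good pose, the upper bound a perfect re-ranker could
reach. Fractions are averaged per target first and then across targets, so
a target with many templates does not dominate the panel average; each
(ligand, template) pair counts as its own task. RMSD is consumed as data —
computing symmetry-corrected RMSD belongs to the docking pipeline, not here.

## Ligand-only baselines and the bias audit

The descriptor sets are the "simple" features historically used to
construct property-matched benchmarks: six DUD-E-style properties
(molecular weight, H-bond acceptors, H-bond donors, rotatable bonds, logP,
net charge) and seventeen MUV-style features (element counts, atom counts,
chiral centers, ring systems, plus HBA/HBD/logP). The feature *names* do
not pin down conventions, so the package documents its choices: Lipinski
N/O acceptor counts; donors as N/O with ≥ 1 hydrogen; Crippen-type
atomic-contribution logP as implemented in OpenBabel; net formal charge;
ring systems as connected components of the ring-bond subgraph (fused and
spiro systems count once, via bridge detection on the bond graph); chiral
centers as the tetrahedral stereocenters carried by the canonical SMILES —
i.e. assigned stereo. Counting *potential* (unassigned) stereocenters would
require full symmetry perception, which the underlying toolkit does not
expose; with typical benchmark SMILES, which carry stereo annotations,
the assigned count is the faithful reading. ECFP4 fingerprints are the
OpenBabel implementation, folded from the native 4096 bits to a
configurable length (default 2048; the fold ORs the halves).

Six regression families (Lasso, k-NN, decision tree, random forest,
gradient-boosted trees, SVR) are fit to training affinities (pK) by
cross-validated grid search over small fixed grids shipped in
`inst/extdata/baseline_grids.yaml`, standardizing features for the
scale-sensitive families, refitting the winner on all data. Training rows
are canonically ordered by compound id before fold assignment, making the
fit invariant to input row order. The audit logic: screen the benchmark
with predicted affinity as the score; enrichment significantly above a
permutation null under *zero* planted descriptor shift would be a
methodological bug (type-I check), while enrichment growing with the
planted shift (power check) confirms the audit can detect property bias.
`best_baseline_per_target()` reports the per-target maximum over all
configurations — an upper bound for a ligand-only model given the ideal
family/descriptors/training set, intentionally not a fair single-model
comparison.

## Training-set similarity

`avg_max_similarity()` computes, for each benchmark active, the maximum
ECFP4 Tanimoto similarity to any training-pool compound, and averages these
maxima per target (actives only — affinity training sets contain no
inactives). Tanimoto of two empty fingerprints is defined as 0 to avoid
0/0. `similarity_performance_correlation()` then rank-correlates the
per-target similarity with per-target early enrichment across the pooled
benchmark targets (per-benchmark breakdowns can be computed by filtering
the input), using Spearman with midranks and a two-sided p.

## The synthetic generator

The generator's purpose is statistical, not chemical: it emulates the
*distributional* structure of a docked benchmark, with no pretence of valid
molecules (molecule-level code is tested on small hand-written SMILES
instead).

* **Scores**: equal-variance binormal — inactives N(0, 1), actives
  N(d, 1) per method — chosen precisely because it yields the closed-form
  expected AUC Φ(d/√2) used as the recovery oracle. Per-pose scores are the
  compound-level draw minus ordered non-negative offsets (exponential
  gaps), with offset zero on the first pose of the first receptor, so
  best-pose aggregation returns the compound draw *exactly* and the
  closed form applies to the end-to-end pipeline. A flat iid-per-pose
  model would break that oracle under max-aggregation.
* **Default separations** are calibrated once from the published median AUC
  levels of the method classes being emulated: `vina`-like and
  CNN-pose-like channels at d = 0.93 (AUC ≈ 0.745) and a CNN-affinity-like
  channel at d = 1.17 (AUC ≈ 0.795). Defaults of 15 targets and
  100/4900 actives/inactives per target give a LIT-PCBA-sized panel with
  5000 compounds per target; 9 poses per compound mirrors the conventional
  `num_modes` docking default.
* **Pose quality**: each compound (or cross-docking task) has a good pose
  (RMSD ~ U(0, 2)) with probability `p_good_pose`; its score rank is 1 with
  probability `score_rmsd_coupling`, otherwise uniform — coupling 1 means
  scoring and pose quality agree perfectly, 0 means they are independent.
  Bad poses draw RMSD ~ U(2, 10). Planted ranks are recorded in the truth
  object, so rank-success curves are checked exactly, not statistically.
* **Descriptors/training**: independent standard-normal features; actives
  shifted by `active_shift` along the training weight vector; training
  affinities pK = 6 + w·x + N(0, σ) on a realistic pK scale. The mean-shift
  structure is the simplest thing a DUD-E-style property model can exploit.
* **Fingerprints**: training-pool bits Bernoulli(`bit_density`, default
  0.02 ≈ 40 on-bits per 2048, a realistic ECFP density); per-target actives
  are bit-flip copies of random pool members at `flip_rate` (0 = verbatim,
  giving average max similarity exactly 1), making training similarity a
  controllable dial.

What passing recovery tests on this generator shows: the estimators,
aggregation protocols, interval procedures and audit logic are correct
under a model where their assumptions hold exactly. What it does not show:
robustness to real-data features the generator omits — correlated score
channels, heavy-tailed score distributions, analogue series and cliff
structure in chemistry space, assay label noise, and per-target
active/inactive imbalances beyond the configured counts.

## Numerical and design choices

* `k = ⌈αN⌉` for the top fraction; no fractional credit at the boundary.
* Bootstrap: percentile method (not BCa) — simple, stratification already
  guards the main failure mode, and its empirical coverage is verified.
* Mann-Whitney exact/approximate switch at n ≤ 8 per side without ties;
  continuity and tie corrections in the approximation.
* All randomness flows from explicit integer seeds; per-(target, method)
  bootstrap streams are derived by hashing the master seed with the group
  labels, so adding a method does not shift another method's resamples.
* Degenerate inputs: single-class targets, empty fingerprint sets, and
  constant vectors raise typed errors (`screenaudit_undefined_metric`,
  `screenaudit_domain_error`, ...) rather than returning NA.
* Problem sizes in the shipped tests (e.g. 500 coverage replicates with 500
  bootstrap resamples; 1000 random oracle instances at N ≤ 20) are chosen
  as the smallest panels at which the checked tolerances are meaningful.

## Known limitations

* No BEDROC/RIE-style weighted early-recognition metrics; no ROC plotting
  beyond the metric values.
* The bias audit bounds what *these* six families on *these* descriptor
  sets can achieve; it cannot prove the absence of subtler bias.
* Chiral-center counts reflect assigned stereocenters (see above).
* No pose generation, no RMSD computation, no protein structure parsing:
  the package consumes score tables, SMILES, and RMSDs as data.

## A compact end-to-end run

```{r example, eval = FALSE}
cfg   <- synthetic_config(n_targets = 5, seed = 42)
bench <- generate_benchmark(cfg)

bundle <- run_evaluation(bench$scores, n_boot = 1000, seed = 42)
bundle$summary

labels <- distinct(as_tibble(bench$scores)[, c("target", "compound", "label")])
audit <- run_bias_audit(bench$train, bench$descriptors, labels,
                        families = c("lasso", "random_forest"),
                        reference = bundle$metrics)
audit$best_per_target
```
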