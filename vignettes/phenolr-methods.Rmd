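---
title: "Phenotype likelihood-ratio models for gene classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype likelihood-ratio models for gene classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenolr)
```

## The problem and the model

In a developmental-disorder cohort, each diagnosed gene defines a small group
of individuals against a large heterogeneous background. `phenolr` asks, per
gene, whether the phenotype of that group is both consistent and distinct
enough to support the diagnosis, by building a one-vs-rest classifier for
each of four clinically available data types:

* **sex** — a nominal probability table;
* **growth** — five quantitative attributes: gestation (months) and
  birthweight, height, weight and head circumference as Z scores against an
  age/sex reference;
* **development** — four milestones in months: first walked, first words,
  social smile, sat independently;
* **HPO terms** — binary annotations over a selected set of informative
  phenotypic terms (IPTs) from a phenotype ontology.

Writing `M1` for "this gene is causal" and its complement for everyone else,
each classifier emits a log likelihood ratio
`log P(D | M1) / P(D | complement)` for its data type. Under naive Bayes the
evidence adds: with the class prior taken as the observed class frequency,

```
score = log(prior odds) + llr_sex + llr_growth + llr_dev + llr_hpo
```

is the log posterior odds, and `score > 0` classifies the individual to the
gene. The generalisation replaces the unit coefficients with five free
weights `w0..w4` (an intercept plus one exponent per data type), fitted per
gene by maximising F1. The weighted combination is defined in log space: the
multiplicative form with a positive constant would be positive everywhere,
so the "greater than 0" decision rule is only meaningful for the logarithm,
and `w0` is the additive intercept playing the prior's role.

### Per-data-type classifiers

**Nominal (sex).** A 2x2 table of `P(sex | class)`, with an additive
pseudocount (default 0.5 per cell) so no probability is 0 or 1. Missing sex
contributes a log LR of 0.

**Continuous (growth, development).** A Gaussian kernel density per feature
per class, evaluated as the exact kernel sum (no grid interpolation). The
bandwidth is the nrd0 rule of thumb, `0.9 min(sd, IQR/1.34) n^{-1/5}`,
multiplied by an adjustment factor whose default is **2**. Diagnosed groups
are small (10–30 individuals) and the raw rule-of-thumb bandwidth produces
spiky class densities whose ratios are dominated by individual
observations; doubling the bandwidth smooths the class model at the cost of
some sharpness. The factor is a configuration parameter and the default is
an explicit judgement call, not an estimate. Densities are floored at
`1e-12` before any ratio so tail queries cannot produce infinite log LRs.
Features with fewer than two non-missing values in either class are flagged
unusable and skipped with a warning; missing values contribute 0, mirroring
naive Bayes treatment of absent features. Gestation and milestone months
enter untransformed, on the same footing as Z scores.

**Binary (HPO terms).** A Bernoulli rate per IPT per class, smoothed with
the same pseudocount. Each term's signed contribution is retained so a
per-individual report can list the terms supporting (positive) and opposing
(negative) a diagnosis — the form a clinician would want to inspect.

## Informative phenotypic term selection

Annotation to an ontology term implies all its ancestors (the true-path
rule), so raw annotations at heterogeneous depths must be brought to a
common, informative level before they can serve as classifier features.
The selection procedure:

1. **Propagate** all annotations to ancestors and count, per term, the
   distinct individuals annotated — using the whole cohort irrespective of
   diagnosis. Because no diagnosis labels enter, the IPT set is computed
   once and deliberately *not* refitted inside cross-validation folds.
2. **Select top-down.** Every top-level term (child of the root) is an IPT
   unconditionally. From each top-level term, children are examined
   breadth-first: a child used by more than the upper bound of individuals
   is expanded into its own children; a child inside the bounds is retained
   as an IPT and not expanded; a child below the lower bound is dropped —
   its descendants can only be rarer after propagation, so further
   expansion is futile. Defaults are **2%** and **10%** of the cohort,
   inclusive at both ends.
3. **Single placement.** A term reachable from several top-level terms is
   placed under the first top-level term whose traversal reaches it. The
   traversal order (top-level terms in ontology declaration order, children
   in lexicographic term-ID order) exists purely to make the result
   deterministic; the selected *set* does not depend on it.
4. **Deduplicate nested IPTs.** When one IPT is an ancestor of another, an
   individual's annotation to the ancestor is deleted if it arises *only*
   through propagation from descendant IPTs; an annotation reaching the
   ancestor through a non-IPT descendant (or directly) is kept. This keeps
   one IPT from implying another within an individual's feature vector,
   which matters because naive Bayes would otherwise double-count the same
   clinical observation. The redundancy judgement needs the original,
   pre-propagation annotations — a propagated matrix makes every implied
   term look original — so `dedup_ipt_annotations()` takes the raw matrix
   and propagates internally.

For comparison, `tf_idf_ic_scores()` ranks terms per gene by the product of
within-gene term frequency, log inverse gene-document frequency and
information content (`-log` of the cohort-wide annotation fraction) — the
conventional information-retrieval baseline. IPTs are selected for moderate
cohort-wide frequency, so they typically sit well below the top of that
ranking; the two selections answer different questions.

## Weight optimization

`optimize_weights()` maximises F1 of the `score > 0` calls by a native
simulated-annealing maximizer: geometric temperature schedule, Gaussian
proposals whose scale shrinks with temperature, Metropolis acceptance, box
constraints by clamping. Hyperparameters (all configurable): evaluation
budget 2000, initial/final temperatures 0.3/1e-4 on the F1 scale, bounds
[-50, 50] for `w0` and [-10, 10] for `w1..w4` (symmetric: nothing forces a
data type's weight to be non-negative, and a consistently misleading data
type should be allowed a negative exponent). Three contracts are guaranteed
and tested:

* **keep-best** — the returned F1 is never below the F1 at the canonical
  start (`w0 = log prior odds`, unit weights), so the optimized combined
  model can never be worse than plain naive Bayes on training data;
* **determinism** — a fixed seed fixes the output exactly;
* **multi-start domination** — solutions of the four single-data-type
  optimizations seed the combined optimization, so the combined optimum
  dominates every single-source optimum on the same training data.

A weight vector producing no positive calls has F1 defined as 0: the
evidence never outweighed the prior, which with class priors of 1/20 or
less is a common and meaningful outcome, not an error. The HPO-only
ablation (`optimize_hpo_only()`) fixes `w1 = w2 = w3 = 0` and optimizes
only the intercept and the HPO weight with identical contracts.

## Evaluation

**Metrics.** Precision, recall, F1 (harmonic mean; recorded 0 with an
undefined-precision flag when there are no positive calls) and rank-based
(Mann–Whitney) AUC with half-credit ties. F1 measures decision quality at
the chosen threshold; AUC measures ranking quality irrespective of it.

**Leave-one-out cross-validation.** Each individual is scored under a model
refitted without them; the IPT feature set stays fixed (it uses no labels).
For combined-score metrics the weights are either optimized once on the
pooled table of held-out likelihoods (default) or reused from training.
True per-fold re-optimization would need, for every fold, the training
likelihoods under that fold's model — an N x N likelihood table per gene —
for a quantity that the pooled table already estimates; the pooled default
trades that quadratic cost for a small optimism that the null-calibration
test bounds.

A known behaviour worth naming: with small diagnosed groups, held-out log
LRs are *pessimistically* biased, most visibly for discrete features.
Removing a case from the case class shifts the class model away from that
case's own values, so under the null every held-out case scores slightly
below every held-out non-case; for sex — two values, no noise — this
drives the single-feature AUC far below 0.5 even with no signal. The
continuous and combined scores carry enough sampling noise that the
combined cross-validated AUC stays near chance on null data, which is what
the calibration test asserts (band 0.40–0.60 at a cohort of ~200).

**.632 bootstrap.** Because the gene class is a small minority, only recall
of the class of interest is bootstrap-estimated:
`0.368 * apparent + 0.632 * mean out-of-bag recall` over B resamples
(default B = 100; a deliberate convention, the estimator's variance is
stable well below that for these cohort sizes). Resamples with fewer than
two in-bag cases or no out-of-bag case are redrawn and counted.

**Generalization by quartiles.** Per gene, diagnosed individuals are
ordered by total combined likelihood and the weight-scaled per-type values
are reported at the quartile-1, median and quartile-3 individuals — poor,
typical and good fits. A data type *generalizes* when the median
individual's scaled value is positive: the model then supports the
diagnosis for a typical case, not only for its best-fitting members.

**Cohort summary.** Per-source medians, the Pearson correlation of F1 with
the number of diagnosed individuals (two-sided t approximation; reported as
undefined, not zero, under zero variance) and the count of genes at or
above a satisfactory AUC of 0.6.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the classifiers
assume: a large undiagnosed background (growth Z scores standard normal;
gestation and milestones from reference normals truncated at zero, since
months cannot be negative; sex uniform; each ontology leaf annotated
independently at a background probability, default 0.02) plus per-gene
diagnosed groups with planted additive shifts (Z units / months), a planted
sex ratio, and elevated per-term annotation probabilities. Annotations are
emitted at the annotated terms only — propagation is the pipeline's job.
Missingness removes whole growth or development blocks per individual
(default 5% each), matching how incomplete clinical records actually look
and exercising the completeness filter.

What it does **not** emulate — and therefore what passing tests cannot
show about real data: term co-occurrence structure (each term is drawn
independently, which is exactly the naive Bayes assumption, so the
generator cannot probe robustness to its violation); age structure or
ascertainment effects; real HPO usage frequencies or depth distribution;
correlated growth trajectories. Conclusions about real cohorts rest on the
method, not on these simulations.

The scenario library fixes six seeded conditions used by the acceptance
suite: growth-dominant, development-dominant, HPO-dominant, sex-biased
(95% female cases, the X-linked pattern), small-n-strong and null. Each
plants one gene's group over a background of 200 individuals on a shared
toy ontology (3 layers, branching 3, 10% of deep nodes with a second
parent; 40 terms). Group sizes are 20–25 — the scale of a typical per-gene
group in a diagnosed rare-disease cohort — except `small_n_strong`, which
uses exactly 10 cases with strong multi-type effects to probe the smallest
group size worth modelling; that scenario alone disables block missingness,
because its purpose is a model built from exactly ten complete records and
random block loss would silently shrink the group below the fitting floor.
These sizes keep every end-to-end check (including leave-one-out refits)
comfortably within an ordinary desktop run while leaving the planted
effects' detectability to the method rather than to brute sample size.

## Numerical and degenerate-input choices

* Bandwidth fallback for zero-spread samples: scale `max(|x1|, 1)` keeps
  the bandwidth positive and finite.
* Density floor `1e-12` before ratios; with a positive pseudocount no log
  LR is infinite for any input.
* Frequency bounds inclusive on both ends; ties in TF·IDF·IC rankings
  broken by term ID; BFS tie-breaks as above — all so that repeated runs
  are bit-identical.
* Obsolete ontology terms are dropped; annotations via alternate IDs are
  remapped to primary IDs; annotations to unknown IDs are rejected with
  named errors; terms that cannot reach the configured root (e.g.
  inheritance modifiers in a full ontology) are dropped with a logged
  count.
* All randomness (simulation, annealing, bootstrap) flows through explicit
  integer seeds; every pipeline run records seed, config hash and input
  checksums in its manifest, and a rerun reproduces deterministic outputs
  byte for byte.

## Known limitations

* Naive independence is the method: correlated features (height and
  weight; co-occurring terms) have their joint evidence over-counted.
* The IPT frequency bounds are cohort-relative; very small cohorts push
  the absolute bounds into a regime where few terms qualify and top-level
  terms dominate the feature set.
* The LOOCV pessimism described above means cross-validated single-feature
  AUCs for nominal data should not be read as calibrated chance levels.
* The per-fold weight re-optimization variant is intentionally not
  implemented; "pooled" and "train" modes bracket it in optimism.
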