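# phenolr

Phenotype-driven gene classification for developmental-disorder cohorts,
using integrated likelihood ratios.

## What problem this solves, and for whom

Diagnosing a rare developmental disorder from sequencing data usually ends
with a shortlist of plausible candidate genes, ranked with the help of
categorical clinical terms from the Human Phenotype Ontology (HPO). But a
clinical record holds more than terms: sex, quantitative growth measures
(birthweight, height, weight, head circumference as Z scores; gestation)
and developmental milestones (months to walking, first words, social
smile, sitting) are routinely collected and rarely modelled. `phenolr` is
for researchers and method developers working with phenotype-diagnosis
cohorts who want per-gene models that use *all* of that, quantify what each
data type contributes, and report per-individual evidence a clinician can
read.

## The model

For each gene `g`, individuals diagnosed with `g` form class `M1` and
everyone else the complement. Each data type `d` gets its own naive Bayes
classifier emitting a log likelihood ratio
`llr_d = log P(D_d | M1) / P(D_d | M1')`: a probability table for sex,
Gaussian kernel densities (nrd0 bandwidth, increased by an adjust factor)
per quantitative feature, and smoothed Bernoulli rates per informative
phenotypic term (IPT). Evidence is combined in log space with five weights

```
score = w0 + w1*llr_sex + w2*llr_growth + w3*llr_dev + w4*llr_hpo
```

and `score > 0` is a classification to the gene. With
`w0 = log(prior odds)` and unit weights this is exactly the naive Bayes
log posterior odds; the weights are otherwise optimized per gene by
simulated annealing on the F1 score, and an HPO-only ablation (`w0`, `w4`)
quantifies what the ontology terms alone achieve.

IPTs are selected from the whole cohort, irrespective of diagnosis, by a
top-down frequency-bounded walk of the ontology: top-level terms are always
kept; children used by 2%–10% of the cohort (after propagating annotations
to ancestors) are kept; busier children are expanded; rarer ones dropped.
Nested-IPT redundancy is removed per individual so one feature never
implies another. Evaluation covers training and leave-one-out
cross-validated F1/precision/recall/AUC, a .632 bootstrap of recall, and a
quartile-based generalization report. A seeded synthetic-cohort generator
with planted per-gene effects makes the whole pipeline testable without
access to managed clinical data.

## Worked example

Simulate a cohort whose planted gene is marked mainly by ontology terms,
select IPT features, fit the gene model and evaluate:

```r
library(phenolr)

lib   <- scenario_library(seed = 1)
built <- build_scenario(lib$hpo_dominant)          # 225 individuals, 25 cases
prep  <- prepare_ipt_features(built$ontology, built$cohort)
filt  <- filter_cohort(prep$cohort)                # inclusion rules
#> filter: kept 216/225 individuals; 1 modelable gene(s)

ev <- evaluate_gene(filt$cohort, "GENE_HPO", seed = 1, modes = "train")
ev$metrics[, c("source", "tp", "fp", "precision", "recall", "f1", "auc")]
#>               source tp fp precision recall    f1   auc
#> 1                sex  0  0     0.000  0.000 0.000 0.525
#> 2             growth  0  0     0.000  0.000 0.000 0.676
#> 3                dev  0  0     0.000  0.000 0.000 0.651
#> 4                hpo 17  1     0.944  0.739 0.829 0.988
#> 5           combined 18  1     0.947  0.783 0.857 0.987
#> 6 hpo_only_optimized 20  5     0.800  0.870 0.833 0.988
```

Read: sex, growth and development carry no usable signal here (no positive
calls, F1 = 0 — the evidence never outweighs the ~1/9 prior), the HPO
classifier finds 17 of 23 cases with one false positive, and the optimized
combination adds a true positive. The HPO-only ablation reaches a similar
F1 but at five false positives instead of one — the quantitative data are
what keep precision high.

Per-individual evidence, in the layout a clinician would review:

```r
m <- fit_gene_model(filt$cohort, "GENE_HPO")
evidence_report(m, filt$cohort, "IND_00201", weights = ev$weights)
#> $loglr
#>         sex      growth development         hpo
#>       -0.10       -0.08       -0.24        8.99
#> $supporting
#> HP:0000016 HP:0000010 HP:0000003 HP:0000011
#>       3.98       2.75       2.22       0.40
#> $opposing
#> HP:0000013 HP:0000015 HP:0000026 HP:0000012
#>      -0.14      -0.07      -0.06      -0.06
```

The whole chain — simulate, select IPTs, filter, fit, optimize, evaluate
(LOOCV and bootstrap included), report — also runs as one call writing TSV
and JSON artifacts plus a manifest:

```r
run_pipeline(list(scenario = "hpo_dominant", seed = 1), out_dir = "out")
```

or from a shell via the thin wrapper `inst/cli/phenolr.R`
(`run`, `simulate`, `select-ipts` subcommands).

Cohorts can equally come from files: an OBO ontology via `load_obo()` and
three TSVs (phenotypes, long-format annotations, diagnoses; UTF-8,
tab-separated, header row, `NA` for missing) via `load_cohort()`.

## Documentation

The methods vignette (`vignettes/phenolr-methods.Rmd`) describes the model
and its assumptions, every tunable with units and defaults, what the
synthetic generator does and does not emulate, the numerical conventions,
and known limitations.
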