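---
title: "Prioritizing bispecific antibody target pairs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing bispecific antibody target pairs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bspair)
```

## The problem

A bispecific antibody (BsAb) binds two antigens at once. Choosing *which*
two membrane proteins to pair is a central, expensive decision in BsAb
programs: a good pair should be active on the relevant tumor-infiltrating
cell populations (ideally co-expressed on the same cells), mechanistically
coherent, and tumor-restricted enough to be safe. `bspair` scores every
unordered pair from a curated candidate list by (i) computing a panel of
biologically motivated pair features from annotated single-cell RNA-seq
data, (ii) training models supervised by the ordinal clinical stage of
existing bispecific drugs, and (iii) rendering the result as a
natural-language analysis report via equal-frequency feature
discretization.

## Feature panel

For an unordered pair $(x, y)$ the five feature groups are:

* **Safety.** Per gene, $d = \overline{\mathrm{expr}}_{\text{tumor}} -
  \overline{\mathrm{expr}}_{\text{normal}}$ (pseudo-bulk means on the
  normalized scale); the pair score is the quasi-harmonic combination
  $\mathrm{score}_{\text{safe}} = d_x d_y / (d_x + d_y)$, higher = more
  tumor-restricted. When $|d_x + d_y| < 10^{-12}$, or $d_x$ and $d_y$ have
  strictly opposite signs (where the combination is not monotone in either
  argument), the score is recorded as 0 with a warning — the quantity is a
  "higher is safer" heuristic and has no meaningful value there.
* **Mechanism.** The number of pathways (GMT gene sets) containing both
  genes.
* **Gene embedding.** The Euclidean distance
  $d(x,y) = \sqrt{\sum_i (x_i - y_i)^2}$ between pre-trained gene vectors
  (Gene2Vec-style, dimensionality taken from the file, conventionally 200).
  Note this is a *distance*: small values mean similar genes, which is why
  the discretization labels run from "Very similar" at the low end.
* **Activity.** With threshold $T$, the positive proportion of a gene in a
  population is $P_{\text{gene}} = \tfrac1N \sum_i I(\mathrm{expr}_i > T)$
  (strictly greater). Each gene is evaluated over its top-$k$
  most-expressing populations (default $k = 2$, pooled cells); the pair
  summaries are `single_ratio_sum`, `single_ratio_min`, `single_ratio_max`,
  and the double-positive proportion
  $P_{g_1,g_2} = \tfrac1N \sum_i I(\mathrm{expr}_{g_1,i} > T)\,
  I(\mathrm{expr}_{g_2,i} > T)$, maximized over the union of the two
  genes' top populations (`double_ratio_max`). The same quantities are
  additionally emitted per configured *focus* population
  (`single_ratio_max@Treg`, `double_ratio@exhausted_CD8_T`, ...), the
  tumor-microenvironment cell types where checkpoint pairs actually act
  (defaults: exhausted CD8 T cells, Tregs, macrophages, epithelial cells).
* **Correlation.** The sample Pearson $r$ between the two genes' per-cell
  expression, pooled over all cells by default. A gene with zero variance
  in scope yields $r = 0$ with a warning.

### Expression scale and threshold

All features are computed after library-size normalization to 10,000
counts per cell followed by `log1p` (configurable back to raw counts).
The positivity threshold defaults to $T = 0$ on that scale, i.e. any
nonzero expression counts as positive — the natural choice for sparse
droplet-style data, and configurable where a stricter cutoff is wanted.

## Supervision and models

Drug records carry an ordinal clinical stage code 1–5 (1 = "Approved,
NDA/BLA" ... 5 = "Discontinued/pending"); smaller code = more advanced.
Several drugs can share one target pair, so pairs are labeled with their
*best* (minimum) stage; the binary positive class defaults to stage 1 only
(configurable to {1, 2} for sensitivity analyses). Because approved
bispecifics are rare, the headline model does not learn from binary labels
alone: preference pairs (winner, loser) are induced from every cross-stage
ordered combination, and a gradient-boosted tree ranker optimizes a
pairwise rank objective over them (relevance $5 - \text{stage}$, one
ranking query group per cross-validation fold).

The bench compares seven fixed configurations: logistic regression (ridge
penalty 0.1, ≤ 1000 iterations), a decision tree (minimum leaf 5, depth ≤
10), a random forest (100 trees), a gradient-boosting classifier (learning
rate 0.1, 100 trees; depth 3, the conventional default for that model
family), pointwise and pairwise gradient-boosted trees (learning rate 0.1,
100 trees, depth 10), and a deep neural network (five dense layers
256/128/64/32/1). The neural kind requires a deep-learning backend and is
excluded from the default bench when none is installed; with few positive
samples tree ensembles are the stronger family here in any case. The
pairwise ranker sets `min_child_weight = 0`: pairwise-loss hessians are
far below 1 per sample, and the usual minimum of 1 would forbid any split
on small ranking groups.

Evaluation is stratified five-fold cross-validation with AUC (rank-sum
formulation, half credit for ties) of held-out scores against the binary
label; the pairwise model's scores are real-valued ranking scores, not
calibrated probabilities, which is immaterial to AUC. Feature importance
is *split frequency* — how often a feature is chosen as a split node
across the ensemble — computed from the pointwise gradient-boosted
classifier, whose conservative split policy makes the counts far less
noisy than the free-splitting ranker's. Ablations add feature groups
cumulatively (double-positive → safety → mechanism → embedding →
single-cell summaries → grouped per-cell-type features) with identical
folds and seed throughout.

## Discretization and reports

For reporting, the six headline features (embedding distance, safety
score, Pearson r, `single_ratio_max`, `double_ratio_max`, pathway
co-occurrence) are cut into up to five equal-frequency bins fitted on the
current candidate set's feature distribution (quantile type 7, left-open
right-closed intervals, unbounded extremes). Under heavy ties duplicate
quantile edges are merged and labels are dropped from the extremes inward;
a constant feature collapses to a single middle-labeled bin with a
warning. A frozen reference scheme with published edges ships as a
plain-text fixture (`inst/extdata/reference_bins.json`) and serves as a
regression target; live schemes are always re-fit because the edges are
data-derived. The prompt assembled for a language-model client contains
both targets, each feature's label plus a one-line glossary meaning, the
model score, and the pair's rank among all scored candidates; the default
client is an offline deterministic template renderer, and any function
`f(prompt, bundle) -> text` can be plugged in (failures fall back to the
offline renderer with a flagged provenance field). No network code exists
in the package.

## The synthetic study generator

Real supervision requires proprietary-scale single-cell cohorts and a
curated drug table, so the package ships a generator that emulates all
five inputs with *planted, graded* signal:

* Baseline counts are negative-binomial (dispersion `nb_size = 2`) with
  gene- and cell-type-specific means; each gene has a "home" population
  with 4× elevated expression, and each entry is zeroed with dropout
  probability 0.3 — the minimal realistic noise model for droplet data.
* Every labeled pair carries a strength $s \sim U(0,1)$ scaling three
  pair-level channels: a shared Bernoulli co-activation factor in a
  designated focus population (Poisson counts with mean
  `delta_coexpr * s = 3s` added to both genes in the same cells), an
  embedding pull moving both gene vectors a fraction $\min(1, 0.8s)$
  toward their midpoint, and up to 5 jointly assigned pathways
  (`round(5s)`). Embedding pulls are applied weakest-to-strongest so the
  strongest relationships dominate the final geometry when genes belong
  to several pairs (600 pairs over 223 genes give a mean gene degree of
  ~5.4).
* Safety is gene-level, like the feature itself: each gene's quality
  $u \sim U(0,1)$ scales extra tumor-cell counts (mean `delta_safe * u =
  2u`).
* The latent druggability of a pair is the standardized *sum of its
  planted effects*: $s$ counted once per active pair-level channel plus
  the genes' mean safety quality when the tumor shift is active. Channels
  with a zero effect size drop out of the latent, so single-channel
  configurations plant stage signal only in the data they actually
  modify. Stages are the latent's quintiles; each drug's stage is then
  replaced by a uniform random stage with probability `stage_noise = 0.1`.
* Defaults mirror the study conditions end to end: 3,000 cells across six
  cell types (the four focus types plus B cells and fibroblasts), 223
  candidate genes (24,753 pairs), 600 labeled pairs, and a 791-drug
  cohort whose stage texts come verbatim from the stage vocabulary.

What the generator does **not** emulate: real cohort scale (tens to
hundreds of thousands of cells), batch and patient effects, realistic
gene–gene correlation structure beyond the planted factors, cell-type
abundance shifts between tumor and normal tissue, and real embedding
geometry. Passing tests therefore demonstrate that the pipeline recovers
*planted* ordinal structure under realistic sparsity and label noise —
not that any particular real-data AUC would be attained.

## Numerical and design choices

* Gene symbols are matched case-sensitively after whitespace trimming; an
  alias map hook ships empty (HGNC symbols and protein names are often
  mixed in drug tables).
* Pair canonicalization and all sorting use C-locale collation, so
  results do not depend on the session locale. Top-population ties break
  lexicographically.
* Missing features (gene absent from the embedding table or pathway
  database, a tissue unrepresented) are the `NA` sentinel; tree models
  consume it natively, other models receive training-median imputation
  stored on the fitted model.
* Cells with a missing tissue label are kept for activity features and
  excluded from safety only.
* Binning-scheme JSON prints doubles with 17 significant digits so the
  serialization round-trips bit-exactly.
* Fold assignment deals each class round-robin with a rotation that
  continues across classes: class balance per fold within one sample, and
  total fold sizes within one of each other.
* All randomness (fold assignment, subsampling, every generator) is a
  pure function of the supplied seeds; boosting runs single-threaded for
  bit-reproducibility.

## Test problem sizes

The test suite validates every formula against independently coded
brute-force oracles on random matrices up to 50 cells × 10 genes (exact to
1e−12), and exercises the end-to-end ranking recovery at the default
study conditions (3,000 cells, 223 genes, 600 labeled pairs) across ten
generator seeds, the cumulative ablation across five seeds, and the
importance check on reduced instances (1,000 cells, 80 genes, 300 pairs)
across ten seeds — sizes chosen to keep the full suite around two minutes
on a laptop-class core while leaving the study conditions themselves
untouched.

## Limitations

Supervision by clinical stage conflates biological quality with
historical development priorities; the candidate list bounds what can be
proposed; pooled-cell Pearson correlation mixes between- and
within-population co-expression; the safety contrast requires matched
tumor/normal annotation and ignores non-transcriptional toxicity; and the
offline report renderer provides structure, not literature retrieval —
attach an external LLM client for that. Tri- and tetra-specific
combinations are out of scope.
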