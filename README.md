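# bspair

Prioritizing target pairs for bispecific antibodies (BsAbs) from annotated
single-cell RNA-seq data, with pairwise learning-to-rank supervision from
clinical-stage labels and natural-language report generation.

## The problem

A bispecific antibody binds two antigens simultaneously. Which two membrane
proteins to pair is a costly early decision: the pair should be active on
the tumor-microenvironment populations that matter (ideally co-expressed on
the same cells), mechanistically coherent, and tumor-restricted enough to
be safe. Approved bispecifics are rare, so pointwise supervised learning is
starved of positive labels — but hundreds of bispecific programs carry an
*ordinal* clinical stage (approved → phase 3 → phase 1/2 → preclinical →
discontinued), and relative comparisons between stages multiply the usable
training signal.

`bspair` implements that idea end to end:

1. **Features** — five groups per unordered gene pair `(x, y)`:
   - *safety*: per gene `d = mean tumor expr − mean normal expr`
     (pseudo-bulk, normalized scale); pair score `d_x·d_y/(d_x + d_y)`,
     higher = more tumor-restricted;
   - *mechanism*: number of pathways (GMT gene sets) containing both genes;
   - *gene embedding*: Euclidean distance `√Σ(x_i − y_i)²` between
     pre-trained gene vectors (small = similar);
   - *activity*: threshold-based positive proportions
     `P_gene = Σ I(expr > T)/N` and the double-positive proportion
     `P_g1,g2 = Σ I(expr_g1 > T)·I(expr_g2 > T)/N`, evaluated over each
     gene's top-k most-expressing populations and over configured focus
     populations (exhausted CD8 T cells, Tregs, macrophages, epithelial);
   - *correlation*: Pearson r of the two genes' per-cell expression.
2. **Models** — a bench of seven fixed configurations (ridge logistic
   regression, decision tree, random forest, gradient boosting, deep net
   (optional), and pointwise/pairwise gradient-boosted trees), evaluated by
   stratified five-fold cross-validated AUC. The headline model is the
   **pairwise** gradient-boosted ranker trained on preference pairs induced
   by the stage ordering. Split-frequency importances and cumulative
   feature-group ablations are first-class outputs.
3. **Reports** — headline features are discretized into up to five
   equal-frequency bins with ordered language labels ("Very similar" …
   "Very dissimilar"), assembled into a deterministic retrieval-augmented
   prompt, and rendered offline (or via any pluggable LLM client).

A synthetic-data generator (`sim_config()` / `simulate_study()`) emulates
all five inputs — annotated tumor/normal cell matrix, gene embeddings,
pathway GMT, candidate gene list, 791-drug clinical-progress table — with
planted, graded signal, so the whole pipeline is testable without any
external download.

## Worked example

```r
library(bspair)

study   <- simulate_study(sim_config(seed = 42))      # the default study conditions
labels  <- aggregate_pair_labels(study$drugs)         # 600 pairs, best stage each
ctx     <- feature_context(study$matrix, study$pathways, study$embeddings, run_config())
features <- build_feature_table(labels[, c("gene_a", "gene_b")], ctx)
dataset <- build_dataset(labels, features, cv_folds = 5, seed = 42)

crossvalidate(model_spec("gbtree_pairwise"), dataset)
#> cv_result: gbtree_pairwise mean AUC 0.8983 ( folds: 0.934 0.935 0.807 0.926 0.889 )

model  <- train(model_spec("gbtree_pairwise"), dataset)
head(rank_candidates(model, features), 3)
#>   gene_a gene_b    score rank
#> 1  MP005  MP079 4.540810    1
#> 2  MP107  MP118 4.522407    2
#> 3  MP124  MP161 4.498376    3

head(feature_frequency_importance(train(model_spec("gbtree_pointwise"), dataset)), 3)
#>              feature count      share
#> 1 embedding_distance   254 0.15347432
#> 2       safety_score   130 0.07854985
#> 3 single_ratio_max@epithelial 108 0.06525680
```

The cross-validated AUC of ~0.90 says the ranker recovers the planted
druggability ordering from the features despite 10% stage-label noise; the
importance table says embedding proximity and the tumor/normal safety
contrast drive the splits, with per-population activity next. A report for
the top pair:

```r
scheme <- fit_binning_scheme(features)
row    <- features[pair_key(features) == "MP005|MP079", ]
bundle <- prompt_bundle(c("MP005", "MP079"), discretize_features(row, scheme),
                        score = 4.54, rank = 1, n_candidates = 600)
render_report(bundle)
#> # Bispecific target-pair analysis: MP005 + MP079
#> ...
#> ## Machine learning model analysis
#> - embedding_distance: Very similar. Euclidean distance between the two targets' ...
#> - safety_score: Unsafe. Combined tumor-minus-normal expression contrast ...
```

A thin command-line wrapper over the same functions lives at
`inst/cli/bspair.R` (`simulate`, `featurize`, `train`, `rank`, `report`).

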