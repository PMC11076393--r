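# brute-force concordant-pair AUC oracle with half credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# hand-build a pair_dataset from a feature matrix and labels
toy_dataset <- function(x, binary, stage = ifelse(binary == 1, 1L, 4L),
                        folds = 2L, seed = 1L) {
  n <- nrow(x)
  labels <- data.frame(gene_a = sprintf("A%03d", 1:n),
                       gene_b = sprintf("B%03d", 1:n),
                       best_stage = stage, binary = binary,
                       n_drugs = 1L)
  ft <- cbind(labels[, c("gene_a", "gene_b")],
              as.data.frame(x, stringsAsFactors = FALSE))
  build_dataset(labels, ft, cv_folds = folds, seed = seed)
}

test_that("rank-sum AUC equals the concordant-pair oracle (with ties)", {
  expect_equal(compute_auc(c(.9, .8, .4, .2), c(1, 0, 1, 0)), 0.75)
  expect_equal(compute_auc(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)
  set.seed(71)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    expect_equal(compute_auc(s, y), oracle_auc(s, y), tolerance = 1e-12)
  }
  expect_error(compute_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("rank-sum AUC agrees with the pROC reference implementation", {
  set.seed(72)
  y <- rbinom(80, 1, 0.5)
  s <- rnorm(80) + y
  expect_equal(compute_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("pointwise models separate a linearly separable toy exactly", {
  set.seed(73)
  x <- cbind(f1 = c(rnorm(20, 3), rnorm(20, -3)), f2 = rnorm(40))
  y <- rep(c(1L, 0L), each = 20)
  ds <- toy_dataset(x, y)
  for (kind in c("gbtree_pointwise", "logistic_regression", "decision_tree")) {
    m <- train(model_spec(kind), ds)
    expect_equal(compute_auc(predict_scores(m, ds$x), y), 1)
  }
  # single-class pointwise input errors
  ds_one <- toy_dataset(x[1:20, ], rep(1L, 20))
  expect_error(train(model_spec("gbtree_pointwise"), ds_one), "both classes")
})

test_that("the pairwise ranker orders a minimal preference correctly", {
  x <- matrix(c(5, 1, 0, 0), 2, 2,
              dimnames = list(NULL, c("f1", "f2")))
  ds <- toy_dataset(x, binary = c(1L, 0L), stage = c(1L, 4L), folds = 2L)
  expect_warning(m <- train(model_spec("gbtree_pairwise", nrounds = 20L), ds),
                 "singleton")
  s <- predict_scores(m, ds$x)
  expect_gt(s[ds$labels$best_stage == 1L], s[ds$labels$best_stage == 4L])
})

test_that("cross-validation scores held-out folds and skips degenerate ones", {
  set.seed(74)
  y <- rep(c(1L, 0L), each = 15)
  x <- cbind(f1 = 2 * y, f2 = rnorm(30))
  ds <- toy_dataset(x, y, folds = 5L)
  cv <- crossvalidate(model_spec("gbtree_pointwise"), ds)
  expect_length(cv$per_fold_auc, 5)
  expect_equal(cv$per_fold_auc, rep(1, 5))
  expect_equal(cv$mean_auc, 1)
  # degenerate fold: all positives concentrated, one fold with a single class
  ds2 <- toy_dataset(x, y, folds = 5L)
  ds2$fold <- c(rep(1:5, 5), rep(1L, 5))
  ds2$fold[y == 1] <- rep(1:5, 3)
  ds2$fold[y == 0] <- c(rep(1:4, 3), 1, 1, 1)  # fold 5 has no negatives
  expect_warning(cv2 <- crossvalidate(model_spec("gbtree_pointwise"), ds2),
                 "lacks both classes")
  expect_true(is.na(cv2$per_fold_auc[5]))
  expect_equal(cv2$mean_auc, mean(cv2$per_fold_auc[1:4]))
})

test_that("the whole bench is reproducible for a fixed seed", {
  ds <- small_dataset()
  cv_a <- crossvalidate(model_spec("gbtree_pairwise"), ds)
  cv_b <- crossvalidate(model_spec("gbtree_pairwise"), ds)
  expect_identical(cv_a$per_fold_auc, cv_b$per_fold_auc)
  imp_a <- feature_frequency_importance(train(model_spec("gbtree_pairwise"), ds))
  imp_b <- feature_frequency_importance(train(model_spec("gbtree_pairwise"), ds))
  expect_identical(imp_a, imp_b)
  rf_a <- feature_frequency_importance(train(model_spec("random_forest"), ds))
  rf_b <- feature_frequency_importance(train(model_spec("random_forest"), ds))
  expect_identical(rf_a, rf_b)
})

test_that("split-frequency importance tallies tree dumps exactly", {
  set.seed(75)
  x <- cbind(f1 = c(rnorm(20, 3), rnorm(20, -3)), f2 = rnorm(40))
  y <- rep(c(1L, 0L), each = 20)
  ds <- toy_dataset(x, y)
  # a single shallow tree must split once, on the informative feature
  m1 <- train(model_spec("decision_tree", maxdepth = 1L), ds)
  imp1 <- feature_frequency_importance(m1)
  expect_identical(imp1$feature[1], "f1")
  expect_equal(imp1$count, c(1L, 0L))
  expect_equal(imp1$share, c(1, 0))
  # xgboost counts equal an independent tally of the text dump
  m2 <- train(model_spec("gbtree_pointwise", nrounds = 10L), ds)
  imp2 <- feature_frequency_importance(m2)
  dump <- xgboost::xgb.dump(m2$fit, with_stats = FALSE)
  for (f in c("f1", "f2")) {
    n_dump <- sum(grepl(paste0("\\[", f, "<"), dump))
    expect_equal(imp2$count[imp2$feature == f], n_dump)
  }
  expect_equal(sum(imp2$share), 1)
  # non-tree models are unsupported
  m3 <- train(model_spec("logistic_regression"), ds)
  expect_error(feature_frequency_importance(m3), "tree-based")
})

test_that("the neural kind reports its missing backend", {
  ds <- small_dataset()
  expect_error(train(model_spec("neural_net"), ds), "backend")
})

test_that("cumulative ablation is consistent with direct cross-validation", {
  ds <- small_dataset()
  ab <- ablation_run(ds, spec = model_spec("gbtree_pairwise"))
  expect_length(ab, 6)
  expect_identical(names(ab)[1], "double_positive")
  # first prefix == direct CV restricted to that group's columns
  direct <- crossvalidate(model_spec("gbtree_pairwise"),
                          bspair:::subset_features(ds, "double_ratio_max"))
  expect_identical(ab$double_positive$per_fold_auc, direct$per_fold_auc)
  expect_error(ablation_run(ds, group_order = "nonsense"), "unknown feature group")
})

test_that("candidate ranking sorts stably with canonical tie-breaks", {
  set.seed(76)
  x <- cbind(f1 = c(3, 2, 1), f2 = c(0, 0, 0))
  ds <- toy_dataset(x, binary = c(1L, 0L, 0L), stage = c(1L, 3L, 4L))
  m <- train(model_spec("gbtree_pointwise", nrounds = 5L), ds)
  cand <- data.frame(gene_a = c("X1", "X2", "X3"), gene_b = c("Y", "Y", "Y"),
                     f1 = c(1, 3, 2), f2 = 0)
  ranked <- rank_candidates(m, cand)
  expect_equal(ranked$rank, 1:3)
  expect_true(all(diff(ranked$score) <= 0))
  # exact ties: canonical pair order breaks them
  cand2 <- data.frame(gene_a = c("X2", "X1"), gene_b = "Y", f1 = 2, f2 = 0)
  r2 <- rank_candidates(m, cand2)
  expect_identical(r2$gene_a, c("X1", "X2"))
  # column mismatch is named
  expect_error(rank_candidates(m, data.frame(gene_a = "A", gene_b = "B",
                                             f1 = 1, f9 = 2)), "f9")
})
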