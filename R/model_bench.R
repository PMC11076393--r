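#' Benchmark model specifications
#'
#' The seven model configurations compared by the bench, with their fixed
#' hyperparameters:
#'
#' * `logistic_regression` — ridge (L2) penalty 0.1, up to 1000 iterations.
#' * `decision_tree` — minimum leaf size 5, maximum depth 10.
#' * `random_forest` — 100 trees.
#' * `gradient_boosting` — learning rate 0.1, 100 trees (depth 3).
#' * `neural_net` — five dense layers (256, 128, 64, 32, 1); requires a
#'   deep-learning backend and is skipped from the default bench when none
#'   is installed.
#' * `gbtree_pointwise` — gradient-boosted trees, cross-entropy loss,
#'   learning rate 0.1, 100 trees, maximum depth 10.
#' * `gbtree_pairwise` — same trees with a pairwise rank objective over
#'   preference pairs induced by the ordinal stage labels (one query group
#'   per training fold); the headline model.
#'
#' @param kind One of the seven kinds above.
#' @param ... Hyperparameter overrides.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(kind = c("gbtree_pairwise", "gbtree_pointwise",
                                "gradient_boosting", "random_forest",
                                "decision_tree", "logistic_regression",
                                "neural_net"), ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    logistic_regression = list(lambda = 0.1, maxit = 1000L),
    decision_tree = list(minbucket = 5L, maxdepth = 10L),
    random_forest = list(ntree = 100L),
    gradient_boosting = list(eta = 0.1, nrounds = 100L, max_depth = 3L),
    neural_net = list(layers = c(256L, 128L, 64L, 32L, 1L), dropout = 0.3,
                      epochs = 200L),
    gbtree_pointwise = list(eta = 0.1, nrounds = 100L, max_depth = 10L),
    gbtree_pairwise = list(eta = 0.1, nrounds = 100L, max_depth = 10L,
                           min_child_weight = 0)
  )
  over <- list(...)
  defaults[names(over)] <- over
  structure(list(kind = kind, hyperparams = defaults), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  hp <- paste(names(x$hyperparams),
              vapply(x$hyperparams, function(v) paste(v, collapse = "/"), ""),
              sep = "=", collapse = ", ")
  cat("model_spec:", x$kind, "(", hp, ")\n")
  invisible(x)
}

# kinds that tolerate NA features natively (tree-based with surrogate/default
# directions); the others get median imputation learned on the training rows
handles_na <- function(kind) {
  kind %in% c("gbtree_pairwise", "gbtree_pointwise", "gradient_boosting",
              "decision_tree")
}

impute_medians <- function(x, medians = NULL) {
  if (is.null(medians)) {
    medians <- apply(x, 2L, stats::median, na.rm = TRUE)
    medians[is.na(medians)] <- 0
  }
  for (j in seq_len(ncol(x))) {
    x[is.na(x[, j]), j] <- medians[j]
  }
  list(x = x, medians = medians)
}

#' Train one benchmark model
#'
#' Fits the given specification on (a subset of) a [build_dataset()]
#' dataset. Pointwise kinds optimize a cross-entropy objective on the binary
#' label and require both classes; the pairwise kind optimizes a rank
#' objective with relevance `5 - stage_code` (more advanced = higher) and
#' one ranking query group per training fold. Deterministic for a fixed
#' dataset seed (single-threaded boosting).
#'
#' @param spec A [model_spec()].
#' @param dataset A `pair_dataset`.
#' @param rows Optional integer row subset to train on (used by CV).
#' @return An object of class `trained_model` carrying the fit, the feature
#'   names, the imputation medians (when used) and the seed.
#' @export
train <- function(spec, dataset, rows = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(dataset, "pair_dataset"))
  if (is.null(rows)) rows <- seq_len(nrow(dataset$x))
  x <- dataset$x[rows, , drop = FALSE]
  y <- dataset$labels$binary[rows]
  stage <- dataset$labels$best_stage[rows]
  fold <- dataset$fold[rows]
  hp <- spec$hyperparams
  medians <- NULL
  if (!handles_na(spec$kind) && anyNA(x)) {
    imp <- impute_medians(x)
    x <- imp$x
    medians <- imp$medians
  }
  if (spec$kind != "gbtree_pairwise" && length(unique(y)) < 2L) {
    stop("pointwise training needs both classes present", call. = FALSE)
  }
  set.seed(dataset$seed)
  fit <- switch(spec$kind,
    logistic_regression = glmnet::glmnet(
      x, y, family = "binomial", alpha = 0, lambda = hp$lambda,
      maxit = hp$maxit, standardize = TRUE),
    decision_tree = rpart::rpart(
      y ~ ., data = data.frame(y = factor(y), x, check.names = FALSE),
      method = "class",
      control = rpart::rpart.control(minbucket = hp$minbucket,
                                     maxdepth = hp$maxdepth, cp = 0,
                                     xval = 0)),
    random_forest = randomForest::randomForest(
      x = x, y = factor(y, levels = c(0, 1)), ntree = hp$ntree),
    gradient_boosting = xgb_fit(x, y, objective = "binary:logistic",
                                eta = hp$eta, nrounds = hp$nrounds,
                                max_depth = hp$max_depth,
                                seed = dataset$seed),
    gbtree_pointwise = xgb_fit(x, y, objective = "binary:logistic",
                               eta = hp$eta, nrounds = hp$nrounds,
                               max_depth = hp$max_depth,
                               seed = dataset$seed),
    gbtree_pairwise = {
      if (nrow(x) < 2L || length(unique(stage)) < 2L) {
        stop("pairwise training needs >= 2 pairs with >= 2 distinct stages",
             call. = FALSE)
      }
      ord <- order(fold)
      group <- as.integer(table(fold[ord]))
      if (all(group < 2L)) {
        warning("all ranking groups are singletons; training as one group")
        group <- length(ord)
      }
      xgb_fit(x[ord, , drop = FALSE], 5L - stage[ord],
              objective = "rank:pairwise", eta = hp$eta,
              nrounds = hp$nrounds, max_depth = hp$max_depth,
              seed = dataset$seed, group = group,
              min_child_weight = hp$min_child_weight)
    },
    neural_net = stop(
      "neural_net needs a deep-learning backend (keras/torch), which is not ",
      "installed; this kind is optional and excluded from the default bench",
      call. = FALSE)
  )
  structure(list(kind = spec$kind, spec = spec, fit = fit,
                 feature_names = colnames(dataset$x),
                 medians = medians, seed = dataset$seed),
            class = "trained_model")
}

xgb_fit <- function(x, y, objective, eta, nrounds, max_depth, seed,
                    group = NULL, min_child_weight = NULL) {
  d <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  if (!is.null(group)) xgboost::setinfo(d, "group", group)
  params <- list(objective = objective, eta = eta, max_depth = max_depth,
                 nthread = 1, seed = seed)
  # pairwise gradients carry per-sample hessians well below 1; the default
  # minimum child weight would forbid any split on very small groups
  if (!is.null(min_child_weight)) params$min_child_weight <- min_child_weight
  xgboost::xgb.train(params = params, data = d, nrounds = nrounds,
                     verbose = 0)
}

#' @export
print.trained_model <- function(x, ...) {
  cat("trained_model:", x$kind, "on", length(x$feature_names), "features\n")
  invisible(x)
}

#' Score pairs with a trained model
#'
#' Pointwise kinds return predicted probabilities; the pairwise kind returns
#' real-valued ranking scores (not calibrated probabilities).
#'
#' @param model A `trained_model`.
#' @param x Numeric feature matrix with exactly the training columns.
#' @return Numeric score vector.
#' @export
predict_scores <- function(model, x) {
  diff_cols <- c(setdiff(model$feature_names, colnames(x)),
                 setdiff(colnames(x), model$feature_names))
  if (length(diff_cols)) {
    stop("feature columns differ from training: ",
         paste(diff_cols, collapse = ", "), call. = FALSE)
  }
  x <- x[, model$feature_names, drop = FALSE]
  if (!is.null(model$medians)) x <- impute_medians(x, model$medians)$x
  switch(model$kind,
    logistic_regression = as.numeric(
      stats::predict(model$fit, newx = x, type = "response")),
    decision_tree = stats::predict(
      model$fit, newdata = as.data.frame(x, check.names = FALSE),
      type = "prob")[, "1"],
    random_forest = stats::predict(model$fit, newdata = x,
                                   type = "prob")[, "1"],
    stats::predict(model$fit, xgboost::xgb.DMatrix(x, nthread = 1))
  )
}

#' Area under the ROC curve
#'
#' Rank-sum (Mann-Whitney) formulation with half credit for tied scores;
#' identical to counting concordant score/label pairs.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1), both classes present.
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC needs both classes present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated evaluation of one model specification
#'
#' Trains on each fold complement and computes the held-out AUC of the
#' scores against the binary labels. Folds lacking both classes are skipped
#' with a warning and the mean is taken over valid folds; the concatenated
#' held-out scores additionally yield a pooled AUC.
#'
#' @param spec A [model_spec()].
#' @param dataset A `pair_dataset` with folds assigned.
#' @return An object of class `cv_result`: `per_fold_auc`, `mean_auc`,
#'   `pooled_auc`, `scores` (held-out, dataset order), `spec`, `seed`.
#' @export
crossvalidate <- function(spec, dataset) {
  folds <- sort(unique(dataset$fold))
  per_fold <- rep(NA_real_, length(folds))
  scores <- rep(NA_real_, nrow(dataset$x))
  for (i in seq_along(folds)) {
    hold <- which(dataset$fold == folds[i])
    y <- dataset$labels$binary[hold]
    model <- train(spec, dataset, rows = setdiff(seq_len(nrow(dataset$x)), hold))
    s <- predict_scores(model, dataset$x[hold, , drop = FALSE])
    scores[hold] <- s
    if (length(unique(y)) < 2L) {
      warning("fold ", folds[i], " lacks both classes; skipped from the mean")
      next
    }
    per_fold[i] <- compute_auc(s, y)
  }
  valid <- !is.na(per_fold)
  structure(list(per_fold_auc = per_fold,
                 mean_auc = mean(per_fold[valid]),
                 pooled_auc = compute_auc(scores, dataset$labels$binary),
                 scores = scores, spec = spec, seed = dataset$seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result:", x$spec$kind, "mean AUC",
      sprintf("%.4f", x$mean_auc), "( folds:",
      paste(sprintf("%.3f", x$per_fold_auc), collapse = " "), ")\n")
  invisible(x)
}

#' Split-frequency feature importance
#'
#' Counts how often each feature serves as a split node across the trees of
#' a tree-based model — the "feature frequency" notion of importance.
#' Non-tree kinds (logistic, neural) are unsupported.
#'
#' @param model A `trained_model` of a tree-based kind.
#' @return A data.frame (`feature`, `count`, `share`) over all training
#'   features, sorted by decreasing count; shares sum to 1 over features
#'   with nonzero count.
#' @export
feature_frequency_importance <- function(model) {
  counts <- stats::setNames(rep(0L, length(model$feature_names)),
                            model$feature_names)
  if (model$kind %in% c("gbtree_pairwise", "gbtree_pointwise",
                        "gradient_boosting")) {
    tree <- xgboost::xgb.model.dt.tree(model = model$fit)
    used <- tree$Feature[tree$Feature != "Leaf"]
    tab <- table(used)
    counts[names(tab)] <- as.integer(tab)
  } else if (model$kind == "random_forest") {
    counts[] <- randomForest::varUsed(model$fit, count = TRUE)
  } else if (model$kind == "decision_tree") {
    used <- as.character(model$fit$frame$var)
    used <- used[used != "<leaf>"]
    tab <- table(used)
    counts[names(tab)] <- as.integer(tab)
  } else {
    stop("split-frequency importance needs a tree-based model (got ",
         model$kind, ")", call. = FALSE)
  }
  total <- sum(counts)
  out <- data.frame(feature = names(counts), count = as.integer(counts),
                    share = if (total > 0) counts / total else 0,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$feature), ]
  rownames(out) <- NULL
  out
}

# restrict a dataset to a feature subset, keeping labels/folds/seed
subset_features <- function(dataset, cols) {
  miss <- setdiff(cols, colnames(dataset$x))
  if (length(miss)) {
    stop("unknown feature column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dataset$x <- dataset$x[, cols, drop = FALSE]
  dataset$feature_names <- cols
  dataset
}

#' Cumulative feature-group ablation
#'
#' Re-runs cross-validation on a growing prefix of feature groups, with
#' identical folds and seed throughout, mirroring the protocol of
#' sequentially incorporating each group and retraining. Default order:
#' double-positive proportion, safety, mechanism, gene embedding,
#' single-cell expression, grouped cell-type expression.
#'
#' @param dataset A `pair_dataset`.
#' @param group_order Character vector of group names (see
#'   [feature_groups()]); groups with no columns present are skipped with a
#'   message.
#' @param spec A [model_spec()].
#' @return Named list of `cv_result`, one per cumulative prefix.
#' @export
ablation_run <- function(dataset,
                         group_order = c("double_positive", "safety",
                                         "mechanism", "embedding",
                                         "single_cell_expression",
                                         "grouped_cell_type"),
                         spec = model_spec("gbtree_pairwise")) {
  groups <- feature_groups(dataset$feature_names)
  unknown <- setdiff(group_order, names(groups))
  if (length(unknown)) {
    stop("unknown feature group(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cols <- character()
  out <- list()
  for (g in group_order) {
    if (length(groups[[g]]) == 0) {
      message("feature group '", g, "' has no columns; skipped")
      next
    }
    cols <- c(cols, groups[[g]])
    out[[g]] <- crossvalidate(spec, subset_features(dataset, cols))
  }
  out
}

#' Rank candidate pairs by model score
#'
#' Scores every candidate feature row and returns a stable descending
#' ranking; exact score ties are broken by canonical pair order, ranks are
#' 1-based.
#'
#' @param model A `trained_model`.
#' @param candidate_features Feature data.frame (`gene_a`, `gene_b`, feature
#'   columns matching training).
#' @return A data.frame: `gene_a`, `gene_b`, `score`, `rank`.
#' @export
rank_candidates <- function(model, candidate_features) {
  feat_cols <- setdiff(names(candidate_features), c("gene_a", "gene_b"))
  x <- as.matrix(candidate_features[, feat_cols, drop = FALSE])
  score <- predict_scores(model, x)
  out <- data.frame(gene_a = candidate_features$gene_a,
                    gene_b = candidate_features$gene_b,
                    score = score, stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene_a, out$gene_b, method = "radix"), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
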