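#' @title Pair feature engineering
#' @description
#' Five feature groups computed for an unordered target pair from an
#' annotated single-cell expression matrix, a pathway database and a gene
#' embedding table:
#'
#' * **Safety**: quasi-harmonic mean `d_x * d_y / (d_x + d_y)` of the two
#'   genes' tumor-minus-normal pseudo-bulk mean expression differences;
#'   higher = safer (more tumor-restricted).
#' * **Mechanism**: number of pathways containing both genes.
#' * **Gene embedding**: Euclidean distance between the genes' embedding
#'   vectors (small = similar).
#' * **Target activity**: threshold-based single- and double-positive cell
#'   proportions within each gene's most expressing populations, plus
#'   per-population variants for configured focus cell types.
#' * **Expression correlation**: Pearson correlation of the two genes'
#'   per-cell expression.
#' @name feature_engine
NULL

# normalize a pair argument to a canonical length-2 character vector
as_pair <- function(pair) {
  if (is.data.frame(pair)) {
    stopifnot(nrow(pair) == 1)
    pair <- c(pair$gene_a, pair$gene_b)
  }
  stopifnot(length(pair) == 2)
  p <- gene_pair(pair[1L], pair[2L])
  c(p$gene_a, p$gene_b)
}

check_gene <- function(mat, gene) {
  if (!gene %in% mat$genes) {
    stop("gene '", gene, "' not in expression matrix", call. = FALSE)
  }
}

#' Pseudo-bulk mean expression of a gene in one tissue
#'
#' Arithmetic mean of the gene's normalized expression over all cells of the
#' requested tissue (`"tumor"` or `"normal"`). Cells with a missing tissue
#' label are excluded.
#'
#' @param mat A [cell_matrix()].
#' @param gene Gene symbol.
#' @param tissue `"tumor"` or `"normal"`.
#' @param cfg A [run_config()] (controls the normalization scale).
#' @return A single number.
#' @export
pseudo_bulk_mean <- function(mat, gene, tissue, cfg = run_config()) {
  tissue <- match.arg(tissue, c("tumor", "normal"))
  check_gene(mat, gene)
  cells <- which(!is.na(mat$meta$tissue) & mat$meta$tissue == tissue)
  if (length(cells) == 0) {
    stop("no cells with tissue '", tissue,
         "'; skip the safety feature for this matrix", call. = FALSE)
  }
  x <- normalize_expression(mat, cfg$normalization)
  mean(x[cells, gene])
}

#' Tumor-versus-normal safety score of a target pair
#'
#' For each gene, `d = mean tumor expression - mean normal expression`
#' (pseudo-bulk, normalized scale). The pair score is the quasi-harmonic
#' combination `d_x * d_y / (d_x + d_y)`; higher values indicate a more
#' tumor-restricted — hence safer — pair. Degenerate configurations
#' (`|d_x + d_y| < 1e-12`, or `d_x` and `d_y` of strictly opposite sign,
#' where the combination is not monotone in either difference) return 0 with
#' a warning.
#'
#' @param mat A [cell_matrix()] with both tissues represented.
#' @param pair A canonical pair (data.frame row or 2 symbols).
#' @param cfg A [run_config()].
#' @return A single number; symmetric in the pair.
#' @export
compute_safety_score <- function(mat, pair, cfg = run_config()) {
  p <- as_pair(pair)
  d <- vapply(p, function(g) {
    pseudo_bulk_mean(mat, g, "tumor", cfg) -
      pseudo_bulk_mean(mat, g, "normal", cfg)
  }, 0)
  unname(safety_from_diffs(d[1L], d[2L]))
}

# the pair-level combination, shared with the vectorized featurizer
safety_from_diffs <- function(dx, dy, warn = TRUE) {
  if (abs(dx + dy) < 1e-12) {
    if (warn) warning("degenerate safety denominator (d_x + d_y ~ 0); returning 0")
    return(0)
  }
  if (dx * dy < 0) {
    if (warn) warning("opposite-sign expression differences; safety score set to 0")
    return(0)
  }
  dx * dy / (dx + dy)
}

#' Pathway co-occurrence count of a pair
#'
#' Number of pathways in the database that contain both genes. Genes absent
#' from every pathway simply contribute 0.
#'
#' @param pair A canonical pair.
#' @param db A `pathway_db` (see [read_gmt()]).
#' @return Non-negative integer.
#' @export
compute_cooccurrence <- function(pair, db) {
  stopifnot(inherits(db, "pathway_db"), length(db$pathways) >= 1)
  p <- as_pair(pair)
  sum(vapply(db$pathways, function(g) all(p %in% g), TRUE))
}

#' Euclidean embedding distance of a pair
#'
#' `sqrt(sum((x_i - y_i)^2))` over the genes' embedding vectors. Small
#' distances mean similar embedding context. A gene missing from the table
#' yields the missing-feature sentinel `NA` with a warning.
#'
#' @param pair A canonical pair.
#' @param emb A `gene_embedding` (see [read_embeddings()]).
#' @return Non-negative number, or `NA_real_` if a gene is absent.
#' @export
compute_embedding_distance <- function(pair, emb) {
  stopifnot(inherits(emb, "gene_embedding"))
  p <- as_pair(pair)
  miss <- setdiff(p, rownames(emb$vectors))
  if (length(miss)) {
    warning("gene(s) absent from embedding table: ",
            paste(miss, collapse = ", "), "; recording NA")
    return(NA_real_)
  }
  sqrt(sum((emb$vectors[p[1L], ] - emb$vectors[p[2L], ])^2))
}

#' Positive proportion of a gene within one cell population
#'
#' Fraction of the population's cells whose normalized expression is
#' strictly greater than the threshold `T`.
#'
#' @param mat A [cell_matrix()].
#' @param gene Gene symbol.
#' @param cell_type Population (cell type) name.
#' @param threshold Threshold `T`; defaults to the config's
#'   `activity_threshold`.
#' @param cfg A [run_config()].
#' @return A number in \[0, 1\].
#' @export
positive_proportion <- function(mat, gene, cell_type,
                                threshold = cfg$activity_threshold,
                                cfg = run_config()) {
  check_gene(mat, gene)
  cells <- which(mat$meta$cell_type == cell_type)
  if (length(cells) == 0) {
    stop("no cells of type '", cell_type, "'", call. = FALSE)
  }
  x <- normalize_expression(mat, cfg$normalization)
  mean(x[cells, gene] > threshold)
}

#' Double-positive proportion of a pair within one cell population
#'
#' Fraction of the population's cells where *both* genes exceed the
#' threshold; always at most the smaller of the two single-positive
#' proportions.
#'
#' @inheritParams positive_proportion
#' @param pair A canonical pair.
#' @return A number in \[0, 1\].
#' @export
double_positive_proportion <- function(mat, pair, cell_type,
                                       threshold = cfg$activity_threshold,
                                       cfg = run_config()) {
  p <- as_pair(pair)
  check_gene(mat, p[1L]); check_gene(mat, p[2L])
  cells <- which(mat$meta$cell_type == cell_type)
  if (length(cells) == 0) {
    stop("no cells of type '", cell_type, "'", call. = FALSE)
  }
  x <- normalize_expression(mat, cfg$normalization)
  mean(x[cells, p[1L]] > threshold & x[cells, p[2L]] > threshold)
}

#' Most expressing cell populations for a gene
#'
#' The `k` cell types with highest mean normalized expression of the gene;
#' exact ties are broken lexicographically by cell-type name for
#' determinism. With fewer than `k` populations present, all are returned
#' with a warning.
#'
#' @param mat A [cell_matrix()].
#' @param gene Gene symbol.
#' @param k Number of populations (default from config).
#' @param cfg A [run_config()].
#' @return Character vector of cell types, highest mean first.
#' @export
select_top_populations <- function(mat, gene, k = cfg$top_k_populations,
                                   cfg = run_config()) {
  check_gene(mat, gene)
  x <- normalize_expression(mat, cfg$normalization)
  types <- sort_c(unique(mat$meta$cell_type))
  means <- vapply(types, function(ct) {
    mean(x[mat$meta$cell_type == ct, gene])
  }, 0)
  if (length(types) < k) {
    warning("only ", length(types), " population(s) available (k = ", k, ")")
    k <- length(types)
  }
  types[order(-means, types)][seq_len(k)]
}

#' Pearson correlation of a pair's per-cell expression
#'
#' Sample Pearson r between the two genes' normalized expression across
#' cells; `scope = "all"` pools every cell (default), or give one cell type.
#' A gene with zero variance in scope yields 0 with a warning.
#'
#' @param mat A [cell_matrix()].
#' @param pair A canonical pair.
#' @param scope `"all"` or a cell-type name.
#' @param cfg A [run_config()].
#' @return A number in \[-1, 1\].
#' @export
compute_pearson <- function(mat, pair, scope = "all", cfg = run_config()) {
  p <- as_pair(pair)
  check_gene(mat, p[1L]); check_gene(mat, p[2L])
  cells <- if (identical(scope, "all")) seq_len(nrow(mat$counts)) else
    which(mat$meta$cell_type == scope)
  if (length(cells) < 3) stop("need >= 3 cells in scope", call. = FALSE)
  x <- normalize_expression(mat, cfg$normalization)
  a <- as.numeric(x[cells, p[1L]])
  b <- as.numeric(x[cells, p[2L]])
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero expression variance in scope; Pearson r recorded as 0")
    return(0)
  }
  stats::cor(a, b)
}

#' Precompute a featurization context
#'
#' Normalizes the matrix once and caches per-population means, positive
#' proportions, tissue means, embedding rows and pathway incidence, so that
#' [build_feature_table()] over thousands of pairs stays fast. All
#' feature-level functions operate on the same definitions.
#'
#' @param mat A [cell_matrix()].
#' @param db A `pathway_db` or NULL.
#' @param emb A `gene_embedding` or NULL.
#' @param cfg A [run_config()].
#' @return An object of class `feature_context`.
#' @export
feature_context <- function(mat, db = NULL, emb = NULL, cfg = run_config()) {
  x <- normalize_expression(mat, cfg$normalization)
  thr <- cfg$activity_threshold
  type <- mat$meta$cell_type
  types <- sort_c(unique(type))
  cells_by_type <- lapply(stats::setNames(types, types),
                          function(ct) which(type == ct))
  n_by_type <- vapply(cells_by_type, length, 0L)
  # population x gene summaries via sparse cross-products
  ind <- Matrix::sparseMatrix(
    i = match(type, types), j = seq_along(type), x = 1,
    dims = c(length(types), length(type)), dimnames = list(types, NULL))
  mean_by_type <- as.matrix((ind / n_by_type) %*% x)
  pos <- x > thr
  pos_by_type <- as.matrix((ind / n_by_type) %*% pos)
  colnames(mean_by_type) <- colnames(pos_by_type) <- mat$genes
  # top-k populations per gene, lexicographic tie-break
  k <- min(cfg$top_k_populations, length(types))
  if (k < cfg$top_k_populations) {
    warning("only ", length(types), " population(s) available (k = ",
            cfg$top_k_populations, ")")
  }
  top_pops <- apply(mean_by_type, 2L, function(m) {
    types[order(-m, types)][seq_len(k)]
  }, simplify = FALSE)
  tumor <- which(!is.na(mat$meta$tissue) & mat$meta$tissue == "tumor")
  normal <- which(!is.na(mat$meta$tissue) & mat$meta$tissue == "normal")
  tissue_diff <- if (length(tumor) && length(normal)) {
    as.numeric(Matrix::colMeans(x[tumor, , drop = FALSE]) -
               Matrix::colMeans(x[normal, , drop = FALSE]))
  } else {
    message("a tissue is unrepresented; safety scores will be NA")
    rep(NA_real_, length(mat$genes))
  }
  names(tissue_diff) <- mat$genes
  focus <- intersect(cfg$focus_cell_types, types)
  structure(list(
    x = x, pos = pos, genes = mat$genes, types = types,
    cells_by_type = cells_by_type, n_by_type = n_by_type,
    mean_by_type = mean_by_type, pos_by_type = pos_by_type,
    top_pops = top_pops, tissue_diff = tissue_diff, focus = focus,
    db = db, emb = emb, cfg = cfg
  ), class = "feature_context")
}

# pooled positive proportion of one gene over a set of populations
pooled_positive <- function(ctx, gene, pops) {
  cells <- unlist(ctx$cells_by_type[pops], use.names = FALSE)
  mean(ctx$pos[cells, gene])
}

#' Activity features of a pair
#'
#' For each gene, the positive proportion is evaluated over the cells of its
#' own top-k most expressing populations (pooled); the pair-level summaries
#' are `single_ratio_sum` (P_a + P_b), `single_ratio_min`, and
#' `single_ratio_max`. The double-positive proportion is evaluated in every
#' population appearing in either gene's top-k set and reported per
#' population maximum as `double_ratio_max`. For each configured focus cell
#' type present in the data, per-population variants
#' `single_ratio_sum@type`, `single_ratio_min@type`, `single_ratio_max@type`
#' and `double_ratio@type` are also emitted, so the feature name list is
#' identical across all pairs of one run.
#'
#' @param mat A [cell_matrix()] or a prebuilt [feature_context()].
#' @param pair A canonical pair.
#' @param cfg A [run_config()] (ignored when a context is supplied).
#' @return Named numeric vector of activity features.
#' @export
compute_activity_features <- function(mat, pair, cfg = run_config()) {
  ctx <- if (inherits(mat, "feature_context")) mat else
    feature_context(mat, cfg = cfg)
  p <- as_pair(pair)
  check_gene(list(genes = ctx$genes), p[1L])
  check_gene(list(genes = ctx$genes), p[2L])
  activity_from_context(ctx, p[1L], p[2L])
}

activity_from_context <- function(ctx, ga, gb) {
  pa <- pooled_positive(ctx, ga, ctx$top_pops[[ga]])
  pb <- pooled_positive(ctx, gb, ctx$top_pops[[gb]])
  eval_pops <- sort_c(unique(c(ctx$top_pops[[ga]], ctx$top_pops[[gb]])))
  va <- ctx$pos[, ga]
  vb <- ctx$pos[, gb]
  both <- va & vb
  doubles <- vapply(eval_pops, function(ct) {
    mean(both[ctx$cells_by_type[[ct]]])
  }, 0)
  out <- c(single_ratio_sum = pa + pb,
           single_ratio_min = min(pa, pb),
           single_ratio_max = max(pa, pb),
           double_ratio_max = max(doubles))
  for (ct in ctx$focus) {
    fa <- ctx$pos_by_type[ct, ga]
    fb <- ctx$pos_by_type[ct, gb]
    grp <- c(fa + fb, min(fa, fb), max(fa, fb),
             mean(both[ctx$cells_by_type[[ct]]]))
    names(grp) <- paste0(c("single_ratio_sum@", "single_ratio_min@",
                           "single_ratio_max@", "double_ratio@"), ct)
    out <- c(out, grp)
  }
  out
}

pearson_from_context <- function(ctx, ga, gb) {
  a <- as.numeric(ctx$x[, ga])
  b <- as.numeric(ctx$x[, gb])
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

cooccurrence_from_context <- function(ctx, ga, gb) {
  if (is.null(ctx$db)) return(NA_real_)
  sum(vapply(ctx$db$pathways, function(g) ga %in% g && gb %in% g, TRUE))
}

distance_from_context <- function(ctx, ga, gb) {
  if (is.null(ctx$emb)) return(NA_real_)
  v <- ctx$emb$vectors
  if (!(ga %in% rownames(v)) || !(gb %in% rownames(v))) return(NA_real_)
  sqrt(sum((v[ga, ] - v[gb, ])^2))
}

#' Build the full feature vector of one pair
#'
#' Assembles all five feature groups into one named vector. Features whose
#' resource is missing (gene absent from the embedding table, no pathway
#' database, a tissue unrepresented) carry the `NA` sentinel without
#' affecting the other features; the name list is identical for every pair
#' of a run.
#'
#' @param pair A canonical pair.
#' @param mat A [cell_matrix()] or prebuilt [feature_context()].
#' @param db A `pathway_db` or NULL.
#' @param emb A `gene_embedding` or NULL.
#' @param cfg A [run_config()].
#' @return Named numeric feature vector.
#' @export
build_feature_vector <- function(pair, mat, db = NULL, emb = NULL,
                                 cfg = run_config()) {
  ctx <- if (inherits(mat, "feature_context")) mat else
    feature_context(mat, db = db, emb = emb, cfg = cfg)
  p <- as_pair(pair)
  check_gene(list(genes = ctx$genes), p[1L])
  check_gene(list(genes = ctx$genes), p[2L])
  ga <- p[1L]; gb <- p[2L]
  dx <- ctx$tissue_diff[ga]
  dy <- ctx$tissue_diff[gb]
  safety <- if (anyNA(c(dx, dy))) NA_real_ else
    safety_from_diffs(dx, dy, warn = FALSE)
  c(safety_score = unname(safety),
    cooccurrence_count = cooccurrence_from_context(ctx, ga, gb),
    embedding_distance = distance_from_context(ctx, ga, gb),
    pearson_r = pearson_from_context(ctx, ga, gb),
    activity_from_context(ctx, ga, gb))
}

#' Build the feature table for many pairs
#'
#' One row per pair, fixed column order; the workhorse behind featurization.
#'
#' @param pairs A canonical pair data.frame (`gene_a`, `gene_b`).
#' @inheritParams build_feature_vector
#' @return A data.frame: `gene_a`, `gene_b`, then one column per feature.
#' @export
build_feature_table <- function(pairs, mat, db = NULL, emb = NULL,
                                cfg = run_config()) {
  ctx <- if (inherits(mat, "feature_context")) mat else
    feature_context(mat, db = db, emb = emb, cfg = cfg)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    build_feature_vector(c(pairs$gene_a[i], pairs$gene_b[i]), ctx, cfg = ctx$cfg)
  })
  feats <- do.call(rbind, rows)
  out <- cbind(pairs[, c("gene_a", "gene_b")],
               as.data.frame(feats, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Feature-group membership of feature names
#'
#' Maps feature columns to the named groups used in ablation studies, in the
#' canonical cumulative order: double-positive proportion, safety,
#' mechanism, gene embedding, single-cell expression summaries, and grouped
#' (per-cell-type) expression features.
#'
#' @param feature_names Character vector of feature column names.
#' @return Named list of character vectors (possibly empty), in group order.
#' @export
feature_groups <- function(feature_names) {
  grouped <- grep("@", feature_names, value = TRUE, fixed = TRUE)
  list(
    double_positive = intersect("double_ratio_max", feature_names),
    safety = intersect("safety_score", feature_names),
    mechanism = intersect("cooccurrence_count", feature_names),
    embedding = intersect("embedding_distance", feature_names),
    single_cell_expression = intersect(
      c("single_ratio_sum", "single_ratio_min", "single_ratio_max",
        "pearson_r"), feature_names),
    grouped_cell_type = grouped
  )
}
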