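small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_cells = 600L, n_genes = 40L, n_labeled_pairs = 80L,
         n_drugs = 120L, seed = 17L),
    list(...))
  do.call(sim_config, args)
}

test_that("every generator is a pure function of its configuration", {
  cfg <- small_cfg()
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_equal(as.matrix(a$matrix$counts), as.matrix(b$matrix$counts))
  expect_identical(a$embeddings$vectors, b$embeddings$vectors)
  expect_identical(a$pathways$pathways, b$pathways$pathways)
  expect_identical(a$drugs, b$drugs)
  # standalone generators agree with the orchestrator
  expect_identical(simulate_embeddings(cfg)$vectors, a$embeddings$vectors)
  expect_identical(simulate_drug_table(cfg), a$drugs)
})

test_that("generated stage text is closed under the stage parser", {
  drugs <- simulate_drug_table(small_cfg())
  expect_false(anyNA(parse_stage(drugs$stage_text)))
  expect_identical(parse_stage(drugs$stage_text), drugs$stage_code)
})

test_that("without stage noise, stages follow the latent ordering exactly", {
  cfg <- small_cfg(stage_noise = 0)
  st <- simulate_study(cfg)
  key <- pair_key(st$drugs)
  tkey <- pair_key(st$truth$pairs)
  expect_identical(st$drugs$stage_code, st$truth$stage_clean[match(key, tkey)])
  # latent order and stage order agree (smaller code = larger latent)
  expect_true(all(tapply(st$truth$latent, st$truth$stage_clean, min)[
    as.character(1:4)] >=
    tapply(st$truth$latent, st$truth$stage_clean, max)[as.character(2:5)]))
})

test_that("planted embedding proximity strengthens with the pull parameter", {
  pair_dist <- function(emb, a, b) sqrt(sum((emb$vectors[a, ] - emb$vectors[b, ])^2))
  dists <- sapply(c(0, 0.4, 5), function(d) {
    emb <- simulate_embeddings(small_cfg(delta_emb = d))
    des <- bspair:::planted_design(small_cfg(delta_emb = d))
    strong <- which(des$strength > 0.8)
    mean(mapply(pair_dist, des$pairs$gene_a[strong], des$pairs$gene_b[strong],
                MoreArgs = list(emb = emb)))
  })
  expect_true(all(diff(dists) < 0))
  # infinite-pull limit: the strongest pair (pulled last) collapses exactly
  emb <- simulate_embeddings(small_cfg(delta_emb = 5))
  des <- bspair:::planted_design(small_cfg(delta_emb = 5))
  top <- which.max(des$strength)
  expect_lt(pair_dist(emb, des$pairs$gene_a[top], des$pairs$gene_b[top]), 1e-8)
})

test_that("null effect sizes leave no planted signal behind", {
  cfg <- small_cfg(delta_safe = 0, delta_coexpr = 0, delta_emb = 0,
                   n_shared_pathways = 0L, n_cells = 1500L)
  st <- simulate_study(cfg)
  ctx <- feature_context(st$matrix, st$pathways, st$embeddings, run_config())
  ft <- build_feature_table(st$truth$pairs, ctx)
  # tumor-minus-normal differences center near zero
  expect_lt(abs(mean(ctx$tissue_diff)), 0.05)
  # co-expression absent: pooled Pearson r stays small
  expect_lt(stats::quantile(abs(ft$pearson_r), 0.95), 0.1)
  # shared pathways at background rate: E = n_pathways * rate^2
  expected_bg <- cfg$n_pathways * cfg$pathway_bg_rate^2
  expect_lt(mean(ft$cooccurrence_count), expected_bg + 3 * sqrt(expected_bg))
})

test_that("planted co-expression exceeds a permuted-label control", {
  # permuting one gene's expression within the designated population keeps
  # both marginal positivity rates but destroys the planted co-activation
  cfg <- small_cfg(delta_coexpr = 20, dropout = 0.1, n_cells = 1200L)
  st <- simulate_study(cfg)
  des <- st$truth
  top <- which.max(des$strength)
  ga <- des$pairs$gene_a[top]
  gb <- des$pairs$gene_b[top]
  ct <- des$coexpr_pop[top]
  x <- normalize_expression(st$matrix, "cpm_log1p")
  cells <- which(st$matrix$meta$cell_type == ct)
  xa <- as.numeric(x[cells, ga])
  xb <- as.numeric(x[cells, gb])
  # threshold at the joint median so positivity is not saturated
  thr <- stats::median(c(xa, xb))
  m <- double_positive_proportion(st$matrix, c(ga, gb), ct, threshold = thr)
  pa <- xa > thr
  pb <- xb > thr
  expect_equal(m, mean(pa & pb))
  set.seed(99)
  null_dist <- replicate(200, mean(pa & sample(pb)))
  expect_gt(m, stats::quantile(null_dist, 0.975))
})

test_that("simulated studies round-trip through the on-disk formats", {
  st <- simulate_study(small_cfg())
  dir <- withr::local_tempdir()
  paths <- write_sim_study(st, dir)
  m <- read_expression(paths$matrix, paths$genes, paths$cells, paths$meta)
  expect_equal(as.matrix(m$counts), as.matrix(st$matrix$counts))
  expect_identical(m$meta, st$matrix$meta)
  drugs <- read_drug_table(paths$drugs)
  expect_equal(nrow(drugs), nrow(st$drugs))
  expect_identical(drugs$stage_code, st$drugs$stage_code)
  db <- read_gmt(paths$gmt)
  expect_identical(db$pathways, st$pathways$pathways)
  emb <- read_embeddings(paths$embeddings)
  expect_equal(emb$vectors, st$embeddings$vectors, tolerance = 1e-15)
  expect_identical(read_gene_list(paths$gene_list), st$gene_list)
})

test_that("model scores respond monotonically to each planted effect size", {
  aucs <- sapply(c(0, 3), function(d) {
    cfg <- small_cfg(delta_emb = 0, delta_coexpr = 0, n_shared_pathways = 0L,
                     delta_safe = d, stage_noise = 0)
    st <- simulate_study(cfg)
    labels <- aggregate_pair_labels(st$drugs)
    ft <- build_feature_table(
      labels[, c("gene_a", "gene_b")],
      feature_context(st$matrix, st$pathways, st$embeddings, run_config()))
    ds <- build_dataset(labels, ft, cv_folds = 5, seed = 17)
    crossvalidate(model_spec("gbtree_pairwise"), ds)$mean_auc
  })
  expect_gt(aucs[2], aucs[1])
})
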