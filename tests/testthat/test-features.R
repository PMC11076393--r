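test_that("pseudo-bulk means average over the requested tissue only", {
  m <- tiny_matrix()
  # GA tumor cells: c1, c2, c4 with raw counts 1, 2, 0
  expect_equal(pseudo_bulk_mean(m, "GA", "tumor", cfg_counts), 1)
  expect_equal(pseudo_bulk_mean(m, "GA", "normal", cfg_counts), 4)
  expect_equal(pseudo_bulk_mean(m, "GC", "tumor", cfg_counts), 0)
  only_tumor <- cell_matrix(
    matrix(1, 2, 1, dimnames = list(c("c1", "c2"), "G")),
    data.frame(cell_id = c("c1", "c2"), cell_type = "t",
               tissue = "tumor", patient = "p"))
  expect_error(pseudo_bulk_mean(only_tumor, "G", "normal"), "skip")
})

test_that("safety score is the quasi-harmonic mean with guarded degeneracies", {
  expect_equal(bspair:::safety_from_diffs(2, 2), 1)
  expect_equal(bspair:::safety_from_diffs(0, 5), 0)
  expect_equal(bspair:::safety_from_diffs(3, 6), oracle_safety(3, 6))
  expect_equal(oracle_safety(3, 6), 2)
  expect_warning(z <- bspair:::safety_from_diffs(1, -1), "degenerate")
  expect_equal(z, 0)
  expect_warning(z2 <- bspair:::safety_from_diffs(-1, 3), "opposite")
  expect_equal(z2, 0)
  # matrix-level: symmetric in the pair
  m <- random_matrix(30, 4, seed = 8)
  s1 <- compute_safety_score(m, c("g01", "g03"), cfg_counts)
  s2 <- compute_safety_score(m, c("g03", "g01"), cfg_counts)
  expect_identical(s1, s2)
})

test_that("pathway co-occurrence counts pathways holding both genes", {
  db <- pathway_db(list(P1 = c("A", "B", "C"), P2 = c("A", "B"),
                        P3 = c("B", "C")))
  expect_equal(compute_cooccurrence(c("A", "B"), db), 2)
  expect_equal(compute_cooccurrence(c("A", "Z"), db), 0)
  expect_equal(compute_cooccurrence(c("X", "Z"), db), 0)
  set.seed(12)
  for (i in 1:10) {
    sets <- lapply(1:6, function(j) sample(LETTERS[1:8], sample(2:5, 1)))
    names(sets) <- paste0("P", 1:6)
    db <- pathway_db(sets)
    expect_equal(compute_cooccurrence(c("A", "B"), db),
                 oracle_cooccurrence("A", "B", sets))
  }
})

test_that("embedding distance is Euclidean, symmetric, and metric", {
  emb <- gene_embedding(matrix(c(0, 0, 3, 4, 0, 0), 3, 2, byrow = TRUE,
                               dimnames = list(c("A", "B", "C"), NULL)))
  expect_equal(compute_embedding_distance(c("A", "B"), emb), 5)
  expect_equal(compute_embedding_distance(c("A", "C"), emb), 0)
  set.seed(13)
  for (i in 1:10) {
    v <- matrix(rnorm(30), 3, 10, dimnames = list(c("A", "B", "C"), NULL))
    e <- gene_embedding(v)
    dab <- compute_embedding_distance(c("A", "B"), e)
    expect_equal(dab, oracle_euclid(v["A", ], v["B", ]), tolerance = 1e-12)
    expect_identical(dab, compute_embedding_distance(c("B", "A"), e))
    dac <- compute_embedding_distance(c("A", "C"), e)
    dbc <- compute_embedding_distance(c("B", "C"), e)
    expect_lte(dab, dac + dbc + 1e-12)
  }
  expect_warning(z <- compute_embedding_distance(c("A", "Z"), emb), "absent")
  expect_true(is.na(z))
})

test_that("positive proportions count strict threshold exceedance", {
  m <- tiny_matrix()
  # Tcell GA raw values: 1, 2, 3
  expect_equal(positive_proportion(m, "GA", "Tcell", 0, cfg_counts), 1)
  expect_equal(positive_proportion(m, "GA", "Tcell", 99, cfg_counts), 0)
  expect_equal(positive_proportion(m, "GA", "Tcell", 1, cfg_counts), 2 / 3)
  # strictness at the boundary
  expect_equal(positive_proportion(m, "GA", "Tcell", 3, cfg_counts), 0)
  expect_error(positive_proportion(m, "GA", "NKcell", 0, cfg_counts),
               "no cells")
})

test_that("positive proportion is monotone non-increasing in the threshold", {
  set.seed(14)
  for (i in 1:5) {
    m <- random_matrix(40, 5, seed = 100 + i)
    thresholds <- sort(runif(6, 0, 5))
    p <- vapply(thresholds, function(t) {
      positive_proportion(m, "g02", "ct1", t, cfg_counts)
    }, 0)
    expect_true(all(diff(p) <= 0))
  }
})

test_that("double-positive proportion is bounded by both singles", {
  counts <- matrix(c(1, 0, 1, 0,   # gx positive in cells 1,3
                     0, 1, 0, 1),  # gy positive in cells 2,4
                   4, 2, dimnames = list(paste0("c", 1:4), c("gx", "gy")))
  meta <- data.frame(cell_id = paste0("c", 1:4), cell_type = "t",
                     tissue = "tumor", patient = "p")
  m <- cell_matrix(counts, meta)
  expect_equal(double_positive_proportion(m, c("gx", "gy"), "t", 0, cfg_counts), 0)
  # absorbing case: one gene positive everywhere
  counts2 <- counts; counts2[, 1] <- 1
  m2 <- cell_matrix(counts2, meta)
  expect_equal(double_positive_proportion(m2, c("gx", "gy"), "t", 0, cfg_counts),
               positive_proportion(m2, "gy", "t", 0, cfg_counts))
  # random fixtures: joint count oracle and the min-single bound
  for (i in 1:10) {
    m3 <- random_matrix(20, 2, seed = 200 + i, n_types = 1)
    thr <- sample(0:3, 1)
    d <- double_positive_proportion(m3, c("g01", "g02"), "ct1", thr, cfg_counts)
    raw <- as.matrix(m3$counts)
    expect_equal(d, sum(raw[, 1] > thr & raw[, 2] > thr) / nrow(raw))
    p1 <- positive_proportion(m3, "g01", "ct1", thr, cfg_counts)
    p2 <- positive_proportion(m3, "g02", "ct1", thr, cfg_counts)
    expect_lte(d, min(p1, p2))
  }
})

test_that("top populations are ranked by mean expression with lexicographic ties", {
  counts <- matrix(c(5, 5, 0, 0, 1, 1,
                     1, 1, 1, 1, 1, 1), 6, 2,
                   dimnames = list(paste0("c", 1:6), c("gd", "gt")))
  meta <- data.frame(cell_id = paste0("c", 1:6),
                     cell_type = rep(c("Tcell", "Bcell", "Epi"), each = 2),
                     tissue = "tumor", patient = "p")
  m <- cell_matrix(counts, meta)
  expect_identical(select_top_populations(m, "gd", 2, cfg_counts),
                   c("Tcell", "Epi"))
  # gt is flat: full lexicographic tie-break
  expect_identical(select_top_populations(m, "gt", 2, cfg_counts),
                   c("Bcell", "Epi"))
  expect_warning(all3 <- select_top_populations(m, "gd", 5, cfg_counts),
                 "only 3")
  expect_length(all3, 3)
  # oracle sort on a random 4-population fixture
  m4 <- random_matrix(40, 3, seed = 77, n_types = 4)
  got <- select_top_populations(m4, "g01", 4, cfg_counts)
  raw <- as.matrix(m4$counts)
  means <- tapply(raw[, "g01"], m4$meta$cell_type, mean)
  expect_identical(got, names(sort(means, decreasing = TRUE)))
})

test_that("Pearson r matches the textbook formula and its invariances", {
  counts <- matrix(c(1, 2, 3, 3, 2, 1), 3, 2,
                   dimnames = list(paste0("c", 1:3), c("gx", "gy")))
  meta <- data.frame(cell_id = paste0("c", 1:3), cell_type = "t",
                     tissue = "tumor", patient = "p")
  m <- cell_matrix(counts, meta)
  expect_equal(compute_pearson(m, c("gx", "gy"), cfg = cfg_counts), -1)
  counts[, 2] <- counts[, 1]
  # identical columns are disallowed as a pair of distinct genes, so scale one
  counts[, 2] <- 2 * counts[, 1] + 1
  m2 <- cell_matrix(counts, meta)
  expect_equal(compute_pearson(m2, c("gx", "gy"), cfg = cfg_counts), 1)
  # random fixture vs independent oracle, and affine invariance
  m3 <- random_matrix(10, 2, seed = 301, n_types = 1)
  raw <- as.matrix(m3$counts)
  r <- compute_pearson(m3, c("g01", "g02"), cfg = cfg_counts)
  expect_equal(r, oracle_pearson(raw[, 1], raw[, 2]), tolerance = 1e-12)
  shifted <- raw; shifted[, 1] <- 3 * shifted[, 1] + 2
  m4 <- cell_matrix(shifted, m3$meta)
  expect_equal(compute_pearson(m4, c("g01", "g02"), cfg = cfg_counts), r,
               tolerance = 1e-12)
  # zero variance guard
  flat <- raw; flat[, 1] <- 2
  m5 <- cell_matrix(flat, m3$meta)
  expect_warning(z <- compute_pearson(m5, c("g01", "g02"), cfg = cfg_counts),
                 "zero")
  expect_equal(z, 0)
})

test_that("full feature vectors are deterministic with isolated sentinels", {
  m <- random_matrix(40, 6, seed = 55)
  db <- pathway_db(list(P1 = c("g01", "g02", "g03"), P2 = c("g01", "g02")))
  set.seed(56)
  emb <- gene_embedding(matrix(rnorm(5 * 8), 5, 8,
                               dimnames = list(sprintf("g%02d", 1:5), NULL)))
  cfg <- run_config(focus_cell_types = c("ct1", "ct2"))
  v1 <- build_feature_vector(c("g01", "g02"), m, db, emb, cfg)
  v2 <- build_feature_vector(c("g02", "g01"), m, db, emb, cfg)
  expect_identical(v1, v2)
  # component agreement
  expect_equal(unname(v1["safety_score"]),
               compute_safety_score(m, c("g01", "g02"), cfg))
  expect_equal(unname(v1["cooccurrence_count"]), 2)
  expect_equal(unname(v1["embedding_distance"]),
               compute_embedding_distance(c("g01", "g02"), emb))
  expect_equal(unname(v1["pearson_r"]),
               compute_pearson(m, c("g01", "g02"), cfg = cfg))
  # g06 is absent from embeddings only
  v3 <- build_feature_vector(c("g01", "g06"), m, db, emb, cfg)
  expect_true(is.na(v3["embedding_distance"]))
  expect_false(anyNA(v3[setdiff(names(v3), "embedding_distance")]))
  # identical feature-name layout across pairs
  expect_identical(names(v1), names(v3))
})

test_that("activity features vanish when nothing exceeds the threshold", {
  m <- random_matrix(30, 3, seed = 66)
  cfg <- run_config(activity_threshold = 1e6,
                    focus_cell_types = c("ct1", "ct2", "ct3"))
  act <- compute_activity_features(m, c("g01", "g02"), cfg)
  expect_true(all(act == 0))
  # order statistics hold on a nontrivial threshold
  cfg2 <- run_config(focus_cell_types = "ct1")
  act2 <- compute_activity_features(m, c("g01", "g02"), cfg2)
  expect_lte(act2[["single_ratio_min"]], act2[["single_ratio_max"]])
  expect_lte(act2[["double_ratio_max"]], act2[["single_ratio_max"]])
})
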