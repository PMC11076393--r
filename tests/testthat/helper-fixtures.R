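# fixtures built in code; raw-count configs keep hand computations exact

cfg_counts <- run_config(normalization = "counts")

# tiny hand-made matrix: 6 cells (2 cell types, both tissues) x 3 genes
tiny_matrix <- function() {
  counts <- matrix(
    c(1, 2, 3, 0, 4, 5,    # GA
      3, 2, 1, 1, 0, 2,    # GB
      0, 0, 0, 0, 0, 0),   # GC, silent
    nrow = 6, ncol = 3,
    dimnames = list(paste0("c", 1:6), c("GA", "GB", "GC")))
  meta <- data.frame(
    cell_id = paste0("c", 1:6),
    cell_type = c("Tcell", "Tcell", "Tcell", "Epi", "Epi", "Epi"),
    tissue = c("tumor", "tumor", "normal", "tumor", "normal", "normal"),
    patient = "p1", stringsAsFactors = FALSE)
  cell_matrix(counts, meta)
}

# random annotated matrix for property tests
random_matrix <- function(n_cells, n_genes, seed, n_types = 3) {
  set.seed(seed)
  counts <- matrix(rpois(n_cells * n_genes, 2), n_cells, n_genes,
                   dimnames = list(sprintf("c%03d", seq_len(n_cells)),
                                   sprintf("g%02d", seq_len(n_genes))))
  meta <- data.frame(
    cell_id = rownames(counts),
    cell_type = sample(paste0("ct", seq_len(n_types)), n_cells, replace = TRUE),
    tissue = sample(c("tumor", "normal"), n_cells, replace = TRUE),
    patient = sample(c("p1", "p2"), n_cells, replace = TRUE),
    stringsAsFactors = FALSE)
  # guarantee every type and both tissues occur
  meta$cell_type[seq_len(n_types)] <- paste0("ct", seq_len(n_types))
  meta$tissue[1:2] <- c("tumor", "normal")
  cell_matrix(counts, meta)
}

# independent dense-arithmetic normalization (oracle path)
oracle_normalize <- function(m, normalization = "cpm_log1p") {
  m <- as.matrix(m)
  if (normalization == "counts") return(m)
  lib <- rowSums(m)
  scaled <- m
  for (i in seq_len(nrow(m))) {
    scaled[i, ] <- if (lib[i] > 0) log1p(m[i, ] * 1e4 / lib[i]) else 0
  }
  scaled
}

oracle_safety <- function(dx, dy) {
  if (abs(dx + dy) < 1e-12 || dx * dy < 0) return(0)
  dx * dy / (dx + dy)
}

oracle_euclid <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - y[i])^2
  sqrt(s)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  num / (sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2)))
}

oracle_cooccurrence <- function(a, b, sets) {
  hits <- 0
  for (s in sets) if (a %in% s && b %in% s) hits <- hits + 1
  hits
}

# small cached synthetic study shared across tests
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(sim_config(
        n_cells = 800L, n_genes = 50L, n_labeled_pairs = 120L,
        n_drugs = 160L, seed = 11L))
    }
    cache
  }
})

small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- small_study()
      labels <- aggregate_pair_labels(st$drugs)
      ft <- build_feature_table(
        labels[, c("gene_a", "gene_b")],
        feature_context(st$matrix, st$pathways, st$embeddings, run_config()))
      cache <<- build_dataset(labels, ft, cv_folds = 5, seed = 11)
    }
    cache
  }
})
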