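#' Synthetic study configuration
#'
#' Parameters of the planted-signal generator that emulates the five inputs
#' of the pipeline: an annotated tumor/normal single-cell matrix, a gene
#' embedding table, pathway gene sets, a candidate membrane-protein list and
#' a drug clinical-progress table. Every labeled pair carries a graded
#' planted strength `s ~ U(0, 1)` that scales all four effect channels
#' (co-expression, tumor-specific shift, embedding proximity, shared
#' pathways). The tumor-specificity (safety) channel is gene-level, as in
#' the scoring method itself: each gene carries a quality `u ~ U(0, 1)`
#' scaling its planted tumor-cell expression shift. The latent druggability
#' of a labeled pair is the standardized sum of its planted effects — the
#' pair strength `s` counted once per active pair-level channel
#' (co-expression, embedding proximity, shared pathways) plus the genes'
#' mean safety quality when the safety shift is active; a channel whose
#' effect size is zero contributes nothing. Clinical stages are assigned by
#' latent quintile, then corrupted with probability `stage_noise`.
#'
#' @param n_cells,n_genes Matrix dimensions.
#' @param cell_types Named numeric vector of cell-type mixing proportions
#'   (must sum to 1).
#' @param tumor_fraction Fraction of cells from tumor tissue.
#' @param n_patients Number of patients cells are attributed to.
#' @param n_labeled_pairs Number of candidate pairs that receive drug
#'   records (and planted strengths).
#' @param n_drugs Number of drug records; the default emulates a 791-drug
#'   clinical-progress cohort.
#' @param stage_noise Probability that a drug's stage is replaced by a
#'   uniform random stage, breaking the latent ordering.
#' @param nb_size Negative-binomial dispersion (size) of baseline counts.
#' @param dropout Probability that any count is zeroed (dropout noise).
#' @param delta_coexpr Mean added counts (Poisson) per co-activated cell for
#'   a planted pair at full strength, in its designated population.
#' @param coexpr_populations Cell types eligible as a planted pair's
#'   co-expression population (the tumor-microenvironment populations where
#'   real checkpoint pairs co-express).
#' @param delta_safe Mean added tumor-cell counts per gene at full safety
#'   quality (tumor-specificity shift).
#' @param delta_emb Embedding pull: at strength `s`, both vectors move a
#'   fraction `min(1, delta_emb * s)` toward their midpoint.
#' @param n_shared_pathways Maximum number of jointly assigned pathways for
#'   a planted pair (scaled by strength).
#' @param n_pathways,pathway_bg_rate Pathway count and background membership
#'   probability per gene.
#' @param emb_dim Embedding dimensionality (Gene2Vec convention: 200).
#' @param seed Integer master seed; every generated artifact is a pure
#'   function of this configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cells = 3000L, n_genes = 223L,
                       cell_types = c(exhausted_CD8_T = 0.15, Treg = 0.10,
                                      macrophage = 0.15, epithelial = 0.25,
                                      B_cell = 0.10, fibroblast = 0.25),
                       tumor_fraction = 0.6, n_patients = 8L,
                       n_labeled_pairs = 600L, n_drugs = 791L,
                       stage_noise = 0.1,
                       nb_size = 2, dropout = 0.3,
                       delta_coexpr = 3,
                       coexpr_populations = c("exhausted_CD8_T", "Treg",
                                              "macrophage", "epithelial"),
                       delta_safe = 2, delta_emb = 0.8,
                       n_shared_pathways = 5L, n_pathways = 50L,
                       pathway_bg_rate = 0.05,
                       emb_dim = 200L, seed = 42L) {
  stopifnot(abs(sum(cell_types) - 1) < 1e-8, all(cell_types > 0),
            stage_noise >= 0, stage_noise <= 1,
            delta_coexpr >= 0, delta_safe >= 0, delta_emb >= 0,
            all(coexpr_populations %in% names(cell_types)),
            dropout >= 0, dropout < 1, n_genes >= 4,
            n_labeled_pairs <= choose(n_genes, 2))
  structure(as.list(environment()), class = "sim_config")
}

# derived sub-seed per generator stage; stays well below 2^31
sub_seed <- function(seed, k) {
  (abs(as.integer(seed)) %% 1000003L) * 2017L + k * 7919L
}

# the planted design shared by all generators: pure function of the config
planted_design <- function(cfg) {
  set.seed(sub_seed(cfg$seed, 1L))
  genes <- sprintf("MP%03d", seq_len(cfg$n_genes))
  candidates <- enumerate_candidates(genes)
  labeled <- sort(sample.int(nrow(candidates), cfg$n_labeled_pairs))
  pairs <- candidates[labeled, , drop = FALSE]
  strength <- stats::runif(cfg$n_labeled_pairs)
  gene_quality <- stats::setNames(stats::runif(cfg$n_genes), genes)
  pair_safety <- (gene_quality[pairs$gene_a] + gene_quality[pairs$gene_b]) / 2
  # sum of planted effects: strength counts once per active pair-level
  # channel, safety quality once when the tumor shift is active
  n_pair_channels <- (cfg$delta_coexpr > 0) + (cfg$delta_emb > 0) +
    (cfg$n_shared_pathways > 0)
  effect_sum <- n_pair_channels * strength +
    (cfg$delta_safe > 0) * pair_safety
  if (stats::sd(effect_sum) == 0) effect_sum <- strength  # no active channel
  latent <- as.numeric(scale(effect_sum))
  coexpr_pop <- sample(cfg$coexpr_populations, cfg$n_labeled_pairs,
                       replace = TRUE)
  r <- rank(-latent, ties.method = "first")
  stage_clean <- as.integer(ceiling(r * 5 / length(r)))
  list(genes = genes, candidates = candidates, pairs = pairs,
       strength = strength, gene_quality = gene_quality,
       pair_safety = unname(pair_safety), latent = latent,
       coexpr_pop = coexpr_pop, stage_clean = stage_clean)
}

#' Simulate an annotated cell-by-gene matrix with planted signal
#'
#' Baseline counts are negative-binomial with gene- and cell-type-specific
#' means (each gene has a "home" population with elevated expression).
#' Planted pairs receive a shared Bernoulli co-activation factor in their
#' designated tumor-microenvironment population (strength-scaled Poisson
#' counts added to both genes in the same cells); each gene receives extra
#' tumor-cell counts scaled by its safety quality (tumor specificity).
#' Dropout noise zeroes each entry independently. Deterministic per
#' configuration.
#'
#' @param cfg A [sim_config()].
#' @return List with `matrix` (a [cell_matrix()]) and `truth` (the planted
#'   design: pairs, strengths, latent, designated populations, stages).
#' @export
simulate_cell_matrix <- function(cfg) {
  design <- planted_design(cfg)
  set.seed(sub_seed(cfg$seed, 2L))
  n <- cfg$n_cells
  g <- cfg$n_genes
  types <- names(cfg$cell_types)
  # deterministic composition, shuffled assignment
  n_by_type <- diff(round(cumsum(c(0, cfg$cell_types)) * n))
  n_by_type[length(n_by_type)] <- n - sum(n_by_type[-length(n_by_type)])
  type <- sample(rep(types, times = n_by_type))
  tissue <- sample(c("tumor", "normal"), n, replace = TRUE,
                   prob = c(cfg$tumor_fraction, 1 - cfg$tumor_fraction))
  patient <- sample(sprintf("PT%02d", seq_len(cfg$n_patients)), n,
                    replace = TRUE)
  # gene-by-type mean structure: baseline x lognormal type wobble,
  # plus a 4x boost in each gene's home population
  mu_gene <- exp(stats::rnorm(g, log(0.3), 1))
  M <- outer(rep(1, length(types)), mu_gene) *
    exp(matrix(stats::rnorm(length(types) * g, 0, 0.5), length(types), g))
  home <- sample.int(length(types), g, replace = TRUE)
  M[cbind(home, seq_len(g))] <- M[cbind(home, seq_len(g))] * 4
  rownames(M) <- types
  type_idx <- match(type, types)
  counts <- matrix(stats::rnbinom(n * g, mu = M[type_idx, ], size = cfg$nb_size),
                   n, g)
  # planted co-activation: one shared Bernoulli factor per pair
  for (i in seq_len(nrow(design$pairs))) {
    s <- design$strength[i]
    if (cfg$delta_coexpr * s <= 0) next
    cells <- which(type == design$coexpr_pop[i])
    z <- cells[stats::rbinom(length(cells), 1L, 0.5) == 1L]
    if (length(z) == 0) next
    ja <- match(design$pairs$gene_a[i], design$genes)
    jb <- match(design$pairs$gene_b[i], design$genes)
    lam <- cfg$delta_coexpr * s
    counts[z, ja] <- counts[z, ja] + stats::rpois(length(z), lam)
    counts[z, jb] <- counts[z, jb] + stats::rpois(length(z), lam)
  }
  # gene-level planted tumor-specificity shift
  shift <- cfg$delta_safe * design$gene_quality
  tumor_cells <- which(tissue == "tumor")
  for (j in which(shift > 0)) {
    counts[tumor_cells, j] <- counts[tumor_cells, j] +
      stats::rpois(length(tumor_cells), shift[j])
  }
  if (cfg$dropout > 0) {
    keep <- matrix(stats::rbinom(n * g, 1L, 1 - cfg$dropout), n, g)
    counts <- counts * keep
  }
  dimnames(counts) <- list(sprintf("C%05d", seq_len(n)), design$genes)
  meta <- data.frame(cell_id = rownames(counts), cell_type = type,
                     tissue = tissue, patient = patient,
                     stringsAsFactors = FALSE)
  list(matrix = cell_matrix(counts, meta), truth = design)
}

#' Simulate a gene-embedding table with planted proximity
#'
#' Isotropic Gaussian vectors; both vectors of a planted pair are pulled a
#' strength-scaled fraction of the way toward their midpoint, so planted
#' distances shrink monotonically in strength (reaching 0 in the infinite
#' pull limit). Pulls are applied in increasing strength order, so the
#' strongest relationships dominate the final geometry when genes belong to
#' several pairs.
#'
#' @param cfg A [sim_config()].
#' @return A `gene_embedding`.
#' @export
simulate_embeddings <- function(cfg) {
  design <- planted_design(cfg)
  set.seed(sub_seed(cfg$seed, 3L))
  V <- matrix(stats::rnorm(cfg$n_genes * cfg$emb_dim), cfg$n_genes,
              cfg$emb_dim, dimnames = list(design$genes, NULL))
  for (i in order(design$strength)) {
    alpha <- min(1, cfg$delta_emb * design$strength[i])
    if (alpha <= 0) next
    a <- design$pairs$gene_a[i]
    b <- design$pairs$gene_b[i]
    m <- (V[a, ] + V[b, ]) / 2
    V[a, ] <- V[a, ] + alpha * (m - V[a, ])
    V[b, ] <- V[b, ] + alpha * (m - V[b, ])
  }
  gene_embedding(V)
}

#' Simulate a pathway database with planted co-membership
#'
#' Background membership is independent per gene and pathway; each planted
#' pair is additionally co-assigned to a strength-scaled number of shared
#' pathways.
#'
#' @param cfg A [sim_config()].
#' @return A `pathway_db`.
#' @export
simulate_pathways <- function(cfg) {
  design <- planted_design(cfg)
  set.seed(sub_seed(cfg$seed, 4L))
  ids <- sprintf("PW%03d", seq_len(cfg$n_pathways))
  member <- matrix(stats::rbinom(cfg$n_genes * cfg$n_pathways, 1L,
                                 cfg$pathway_bg_rate) == 1L,
                   cfg$n_genes, cfg$n_pathways,
                   dimnames = list(design$genes, ids))
  for (i in seq_len(nrow(design$pairs))) {
    k <- round(cfg$n_shared_pathways * design$strength[i])
    if (k < 1) next
    pw <- sample.int(cfg$n_pathways, k)
    member[design$pairs$gene_a[i], pw] <- TRUE
    member[design$pairs$gene_b[i], pw] <- TRUE
  }
  sets <- lapply(stats::setNames(ids, ids),
                 function(p) design$genes[member[, p]])
  keep <- vapply(sets, length, 0L) > 0L
  pathway_db(sets[keep], source = "synthetic")
}

#' Simulate a drug clinical-progress table
#'
#' Assigns each drug a labeled pair (every labeled pair receives at least
#' one drug when `n_drugs >= n_labeled_pairs`); the drug's stage is the
#' pair's latent-quintile stage, replaced by a uniform random stage with
#' probability `stage_noise`. Stage text strings come verbatim from
#' [stage_vocabulary()].
#'
#' @param cfg A [sim_config()].
#' @param feature_latents Optional numeric override of the per-pair latent
#'   druggability (length `n_labeled_pairs`); stages are then re-derived
#'   from its quintiles.
#' @return A drug-record data.frame as from [read_drug_table()].
#' @export
simulate_drug_table <- function(cfg, feature_latents = NULL) {
  design <- planted_design(cfg)
  stage_clean <- design$stage_clean
  if (!is.null(feature_latents)) {
    stopifnot(length(feature_latents) == nrow(design$pairs))
    r <- rank(-feature_latents, ties.method = "first")
    stage_clean <- as.integer(ceiling(r * 5 / length(r)))
  }
  set.seed(sub_seed(cfg$seed, 5L))
  n_lab <- nrow(design$pairs)
  pair_idx <- if (cfg$n_drugs >= n_lab) {
    c(seq_len(n_lab), sample.int(n_lab, cfg$n_drugs - n_lab, replace = TRUE))
  } else {
    sample.int(n_lab, cfg$n_drugs)
  }
  stage <- stage_clean[pair_idx]
  flip <- stats::runif(cfg$n_drugs) < cfg$stage_noise
  stage[flip] <- sample.int(5L, sum(flip), replace = TRUE)
  vocab <- stage_vocabulary()
  data.frame(drug_id = sprintf("BD%04d", seq_len(cfg$n_drugs)),
             gene_a = design$pairs$gene_a[pair_idx],
             gene_b = design$pairs$gene_b[pair_idx],
             stage_text = names(vocab)[stage],
             stage_code = as.integer(stage),
             stringsAsFactors = FALSE)
}

#' Simulate the complete synthetic study
#'
#' Orchestrates all generators under one configuration; the individual
#' generators share the same planted design, so standalone calls agree with
#' this function.
#'
#' @param cfg A [sim_config()].
#' @return List: `matrix` ([cell_matrix()]), `embeddings`, `pathways`,
#'   `drugs`, `gene_list`, `truth` (planted design), `config`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  cm <- simulate_cell_matrix(cfg)
  list(matrix = cm$matrix,
       embeddings = simulate_embeddings(cfg),
       pathways = simulate_pathways(cfg),
       drugs = simulate_drug_table(cfg),
       gene_list = cm$truth$genes,
       truth = cm$truth,
       config = cfg)
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Emits exactly the files the readers consume: MatrixMarket matrix with
#' gene/cell index files and metadata TSV, embedding TSV, pathway GMT,
#' candidate gene list and drug table TSV.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory.
#' @return Invisibly, the named list of paths written.
#' @export
write_sim_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_expression(study$matrix, dir)
  paths$embeddings <- file.path(dir, "embeddings.tsv")
  write_embeddings(study$embeddings, paths$embeddings)
  paths$gmt <- file.path(dir, "pathways.gmt")
  write_gmt(study$pathways, paths$gmt)
  paths$gene_list <- file.path(dir, "candidates.txt")
  writeLines(study$gene_list, paths$gene_list)
  paths$drugs <- file.path(dir, "drugs.tsv")
  write_drug_table(study$drugs, paths$drugs)
  invisible(paths)
}
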