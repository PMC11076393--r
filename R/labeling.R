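#' Clinical-stage vocabulary
#'
#' The five ordinal clinical-progress categories and their codes. Lower code
#' means more advanced: 1 = "Approved, NDA/BLA" down to 5 =
#' "Discontinued/pending".
#'
#' @return Named integer vector, names are the canonical stage strings.
#' @export
stage_vocabulary <- function() {
  c("Approved, NDA/BLA" = 1L,
    "Phase 3, 2/3" = 2L,
    "Phase 1, 2" = 3L,
    "Preclinical, IND application" = 4L,
    "Discontinued/pending" = 5L)
}

#' Parse clinical-progress text into a stage code
#'
#' Case-insensitive keyword mapping onto the five ordinal codes of
#' [stage_vocabulary()]. Matching is ordered so that e.g. "Phase 3, 2/3"
#' resolves to code 2, not to the phase-1/2 code.
#'
#' @param text Character vector of stage descriptions.
#' @param strict If TRUE (default), unrecognized text is an error naming the
#'   string; if FALSE it yields NA.
#' @return Integer vector of codes in 1..5 (NA where unparseable and
#'   `strict = FALSE`).
#' @examples
#' parse_stage(c("Approved, NDA/BLA", "Phase 3, 2/3", "Discontinued/pending"))
#' @export
parse_stage <- function(text, strict = TRUE) {
  s <- tolower(trimws(as.character(text)))
  out <- rep(NA_integer_, length(s))
  rules <- list(c("approved|nda|bla", 1L), c("phase\\s*3", 2L),
                c("phase\\s*[12]", 3L), c("preclinical|\\bind\\b", 4L),
                c("discontinued|pending", 5L))
  for (rule in rules) {
    todo <- which(is.na(out))
    out[todo[grepl(rule[1L], s[todo])]] <- as.integer(rule[2L])
  }
  out[!nzchar(s)] <- NA_integer_
  if (strict && anyNA(out)) {
    stop("unrecognized clinical-progress text: '",
         text[which(is.na(out))[1L]], "'", call. = FALSE)
  }
  out
}

#' Aggregate drug records into per-pair labels
#'
#' Several drugs can share one target pair; each distinct canonical pair gets
#' one label whose `best_stage` is the minimum (most advanced) stage code
#' among its drugs, with the drug count retained. The binary label marks
#' pairs whose best stage falls in `positive_stages` (default: approved
#' only, code 1).
#'
#' Duplicate `drug_id`s with conflicting target pairs keep the most advanced
#' record, with a warning.
#'
#' @param records Drug records (see [read_drug_table()]).
#' @param positive_stages Integer stage codes counted as the positive class.
#' @return A data.frame of pair labels: `gene_a`, `gene_b`, `best_stage`,
#'   `binary`, `n_drugs`, sorted canonically.
#' @export
aggregate_pair_labels <- function(records, positive_stages = 1L) {
  stopifnot(nrow(records) >= 1)
  dup <- duplicated(records$drug_id) | duplicated(records$drug_id, fromLast = TRUE)
  if (any(dup)) {
    conflicting <- unique(records$drug_id[dup])
    multi_target <- vapply(conflicting, function(id) {
      rows <- records[records$drug_id == id, ]
      length(unique(pair_key(rows))) > 1L
    }, TRUE)
    if (any(multi_target)) {
      warning("drug id(s) with conflicting targets, keeping most advanced: ",
              paste(conflicting[multi_target], collapse = ", "))
      keep <- rep(TRUE, nrow(records))
      for (id in conflicting[multi_target]) {
        rows <- which(records$drug_id == id)
        best <- rows[which.min(records$stage_code[rows])]
        keep[setdiff(rows, best)] <- FALSE
      }
      records <- records[keep, , drop = FALSE]
    }
  }
  key <- pair_key(records)
  best <- tapply(records$stage_code, key, min)
  n <- tapply(records$stage_code, key, length)
  keys <- sort_c(unique(key))
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- data.frame(
    gene_a = vapply(parts, `[[`, "", 1L),
    gene_b = vapply(parts, `[[`, "", 2L),
    best_stage = as.integer(best[keys]),
    n_drugs = as.integer(n[keys]),
    stringsAsFactors = FALSE
  )
  out$binary <- as.integer(out$best_stage %in% positive_stages)
  out[, c("gene_a", "gene_b", "best_stage", "binary", "n_drugs")]
}

#' Build preference pairs from ordinal labels
#'
#' Every ordered (winner, loser) combination across distinct stages: the
#' winner's stage code is strictly smaller (more advanced). With `max_pairs`
#' finite, the full set is subsampled deterministically under `seed`.
#'
#' @param labels Pair labels from [aggregate_pair_labels()].
#' @param max_pairs Optional cap on the number of preference pairs.
#' @param seed Integer seed for subsampling.
#' @return A data.frame: `winner_a`, `winner_b`, `loser_a`, `loser_b`,
#'   `winner_stage`, `loser_stage`. Empty (with a warning) if all labels
#'   share one stage.
#' @export
make_preference_pairs <- function(labels, max_pairs = Inf, seed = 1L) {
  stopifnot(nrow(labels) >= 2)
  empty <- data.frame(winner_a = character(), winner_b = character(),
                      loser_a = character(), loser_b = character(),
                      winner_stage = integer(), loser_stage = integer(),
                      stringsAsFactors = FALSE)
  if (length(unique(labels$best_stage)) < 2L) {
    warning("all pairs share one clinical stage; no preference information")
    return(empty)
  }
  idx <- expand.grid(w = seq_len(nrow(labels)), l = seq_len(nrow(labels)))
  idx <- idx[labels$best_stage[idx$w] < labels$best_stage[idx$l], , drop = FALSE]
  out <- data.frame(
    winner_a = labels$gene_a[idx$w], winner_b = labels$gene_b[idx$w],
    loser_a = labels$gene_a[idx$l], loser_b = labels$gene_b[idx$l],
    winner_stage = labels$best_stage[idx$w],
    loser_stage = labels$best_stage[idx$l],
    stringsAsFactors = FALSE
  )
  out <- out[order_c(out$winner_a, out$winner_b, out$loser_a, out$loser_b), ]
  rownames(out) <- NULL
  if (is.finite(max_pairs) && nrow(out) > max_pairs) {
    set.seed(seed)
    out <- out[sort(sample.int(nrow(out), max_pairs)), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Assemble a model-ready dataset from labels and features
#'
#' Row-aligns the feature table to the labeled pairs, attaches ordinal and
#' binary targets, and assigns stratified cross-validation folds (stratified
#' on the binary label) deterministically from the seed. Unlabeled candidate
#' pairs are never part of the design matrix; they are scored downstream
#' only.
#'
#' @param labels Pair labels from [aggregate_pair_labels()].
#' @param feature_table Feature data.frame from [build_feature_table()]; must
#'   contain a row for every labeled pair.
#' @param cv_folds Number of folds (>= 2).
#' @param seed Integer seed for fold assignment.
#' @return An object of class `pair_dataset`: list with `x` (numeric matrix,
#'   rownames = pair keys), `labels` (canonically sorted), `fold` (integer
#'   fold ids), `cv_folds`, `seed`, `feature_names`.
#' @export
build_dataset <- function(labels, feature_table, cv_folds = 5L, seed = 1L) {
  labels <- labels[order_c(labels$gene_a, labels$gene_b), , drop = FALSE]
  rownames(labels) <- NULL
  fkey <- pair_key(feature_table)
  lkey <- pair_key(labels)
  miss <- setdiff(lkey, fkey)
  if (length(miss)) {
    stop("labeled pair(s) missing from feature table: ",
         paste(utils::head(miss, 5L), collapse = ", "),
         if (length(miss) > 5L) " ..." else "", call. = FALSE)
  }
  feat_cols <- setdiff(names(feature_table), c("gene_a", "gene_b"))
  x <- as.matrix(feature_table[match(lkey, fkey), feat_cols, drop = FALSE])
  rownames(x) <- lkey
  fold <- assign_folds(labels$binary, cv_folds, seed)
  structure(list(x = x, labels = labels, fold = fold,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed),
                 feature_names = feat_cols),
            class = "pair_dataset")
}

# stratified fold assignment: within each class, shuffle then deal
# round-robin; the rotation continues across classes so total fold sizes
# stay balanced as well
assign_folds <- function(binary, cv_folds, seed) {
  fold <- integer(length(binary))
  set.seed(seed)
  start <- 0L
  for (cls in sort(unique(binary))) {
    idx <- which(binary == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((start + seq_along(idx) - 1L) %% cv_folds) + 1L
    start <- start + length(idx)
  }
  fold
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat("pair_dataset:", nrow(x$x), "labeled pairs x", ncol(x$x), "features;",
      sum(x$labels$binary), "positive;", x$cv_folds, "folds (seed",
      paste0(x$seed, ")\n"))
  invisible(x)
}

#' Write pair labels as TSV
#' @param labels Labels from [aggregate_pair_labels()].
#' @param path Output path.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
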