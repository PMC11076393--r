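#' Pipeline configuration
#'
#' Bundles the tunable parameters shared across featurization, model
#' benchmarking and reporting.
#'
#' @param activity_threshold Non-negative expression threshold `T` on the
#'   normalized scale above which a cell counts as positive for a gene
#'   (strictly greater). Default 0: any nonzero normalized expression is
#'   positive.
#' @param top_k_populations How many of a gene's most-expressing cell
#'   populations are pooled for its activity features. Default 2.
#' @param n_bins Number of equal-frequency bins used when discretizing
#'   features into language; at most 5.
#' @param cv_folds Number of cross-validation folds (>= 2). Default 5.
#' @param seed Integer seed governing fold assignment and any subsampling.
#' @param model_kind One of the benchmark model kinds, see [model_spec()].
#' @param normalization `"cpm_log1p"` (library-size normalization to 10,000
#'   counts per cell, then log1p; default) or `"counts"` (raw values).
#' @param focus_cell_types Cell populations of particular interest in the
#'   tumor microenvironment for which per-population activity features are
#'   always emitted, in addition to each gene's own top-k populations.
#' @return An object of class `run_config`.
#' @export
run_config <- function(activity_threshold = 0,
                       top_k_populations = 2L,
                       n_bins = 5L,
                       cv_folds = 5L,
                       seed = 1L,
                       model_kind = "gbtree_pairwise",
                       normalization = c("cpm_log1p", "counts"),
                       focus_cell_types = c("exhausted_CD8_T", "Treg",
                                            "macrophage", "epithelial")) {
  normalization <- match.arg(normalization)
  stopifnot(is.numeric(activity_threshold), activity_threshold >= 0,
            top_k_populations >= 1, cv_folds >= 2)
  if (n_bins < 1 || n_bins > 5) {
    stop("n_bins must be between 1 and 5", call. = FALSE)
  }
  structure(list(
    activity_threshold = as.numeric(activity_threshold),
    top_k_populations = as.integer(top_k_populations),
    n_bins = as.integer(n_bins),
    cv_folds = as.integer(cv_folds),
    seed = as.integer(seed),
    model_kind = model_kind,
    normalization = normalization,
    focus_cell_types = as.character(focus_cell_types)
  ), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config: T =", x$activity_threshold,
      "| top-k populations =", x$top_k_populations,
      "| folds =", x$cv_folds,
      "| normalization =", x$normalization,
      "| model =", x$model_kind, "\n")
  invisible(x)
}
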