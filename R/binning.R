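#' Equal-frequency discretization of features into language
#'
#' Continuous features are cut into up to five equal-frequency bins (quantile
#' edges), each bin carrying an ordered natural-language label, so that a
#' numeric feature value can be communicated to a language model as e.g.
#' "Moderately high". Edges are re-fit on each run's candidate feature
#' distribution. Note that the gene-embedding feature is a *distance*: small
#' values mean similar genes, so its label order runs from "Very similar"
#' upward.
#'
#' @name interpret_report
NULL

#' Fit one equal-frequency binning entry
#'
#' Interior edges are the `i/n_bins` quantiles (type 7) of the observed
#' values, defining left-open, right-closed intervals that cover the whole
#' real line (the outer intervals are unbounded). Under heavy ties duplicate
#' edges are merged and the label list is truncated from the extremes
#' inward; a constant feature collapses to a single bin labeled with the
#' middle label, with a warning.
#'
#' @param values Numeric vector of observed feature values (NAs dropped).
#' @param n_bins Number of bins, 1 to 5.
#' @param labels Ordered label strings, one per intended bin.
#' @param direction_note One-line reading aid stored with the entry.
#' @return A `bin_entry`: list with `edges` (interior edges, ascending),
#'   `labels`, `direction_note`.
#' @export
fit_equal_frequency_bins <- function(values, n_bins = 5L, labels,
                                     direction_note = "") {
  stopifnot(n_bins >= 1, n_bins <= 5, length(labels) == n_bins)
  v <- values[!is.na(values)]
  if (length(v) == 0) stop("no finite values to bin", call. = FALSE)
  if (length(unique(v)) == 1L) {
    warning("constant feature; single bin with the middle label")
    mid <- labels[ceiling(n_bins / 2)]
    return(bin_entry(numeric(0), mid, direction_note))
  }
  probs <- seq_len(n_bins - 1L) / n_bins
  edges <- unique(as.numeric(stats::quantile(v, probs, type = 7, names = FALSE)))
  n_kept <- length(edges) + 1L
  if (n_kept < n_bins) {
    drop_front <- floor((n_bins - n_kept) / 2)
    labels <- labels[seq.int(drop_front + 1L, drop_front + n_kept)]
  }
  bin_entry(edges, labels, direction_note)
}

bin_entry <- function(edges, labels, direction_note = "") {
  stopifnot(length(labels) == length(edges) + 1L,
            !is.unsorted(edges, strictly = TRUE))
  structure(list(edges = as.numeric(edges), labels = as.character(labels),
                 direction_note = direction_note), class = "bin_entry")
}

#' Default label vocabularies for the headline features
#'
#' @param feature Feature name.
#' @return Character vector of 5 ordered labels.
#' @export
default_label_vocabulary <- function(feature) {
  switch(feature,
    embedding_distance = c("Very similar", "Somewhat similar", "Similar",
                           "Dissimilar", "Very dissimilar"),
    safety_score = c("Unsafe", "Moderately low safety", "Safe",
                     "Moderately high safety", "High safety"),
    pearson_r = c("Strongly negative correlation",
                  "Weakly negative correlation", "Uncorrelated",
                  "Weakly positive correlation",
                  "Strongly positive correlation"),
    c("Low", "Moderately low", "Moderate", "Moderately high", "High")
  )
}

default_direction_note <- function(feature) {
  switch(feature,
    embedding_distance = "Euclidean distance between gene embeddings; smaller means more similar",
    safety_score = "tumor-minus-normal expression contrast; higher means safer",
    pearson_r = "Pearson correlation of per-cell expression",
    cooccurrence_count = "number of pathways containing both targets",
    "higher means more"
  )
}

#' Fit a binning scheme over the headline features
#'
#' @param feature_table Feature data.frame from [build_feature_table()]
#'   (ideally over the whole candidate set, so labels describe a pair's
#'   standing among all candidates).
#' @param features Which feature columns to discretize; default: the six
#'   headline features.
#' @param n_bins Bins per feature (<= 5).
#' @return A `binning_scheme`: named list of `bin_entry`.
#' @export
fit_binning_scheme <- function(feature_table,
                               features = headline_features(),
                               n_bins = 5L) {
  miss <- setdiff(features, names(feature_table))
  if (length(miss)) {
    stop("feature(s) not in table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  entries <- lapply(features, function(f) {
    fit_equal_frequency_bins(feature_table[[f]], n_bins,
                             default_label_vocabulary(f),
                             default_direction_note(f))
  })
  names(entries) <- features
  structure(entries, class = "binning_scheme")
}

#' The six headline features passed to the report stage
#' @return Character vector of feature names.
#' @export
headline_features <- function() {
  c("embedding_distance", "safety_score", "pearson_r",
    "single_ratio_max", "double_ratio_max", "cooccurrence_count")
}

#' Map a feature value to its natural-language label
#'
#' Intervals are left-open and right-closed; values beyond the outer edges
#' take the extreme labels (the outer intervals are unbounded).
#'
#' @param value Numeric value(s).
#' @param scheme A `binning_scheme`.
#' @param feature Feature name present in the scheme.
#' @return Character label(s).
#' @export
discretize_to_language <- function(value, scheme, feature) {
  if (!feature %in% names(scheme)) {
    stop("no binning fitted for feature '", feature, "'", call. = FALSE)
  }
  entry <- scheme[[feature]]
  idx <- vapply(value, function(v) sum(v > entry$edges) + 1L, 0L)
  entry$labels[idx]
}

#' @export
print.binning_scheme <- function(x, ...) {
  for (f in names(x)) {
    cat(f, ": ", length(x[[f]]$labels), " bins | edges: ",
        paste(signif(x[[f]]$edges, 4), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Serialize / restore a binning scheme as JSON (bit-exact)
#'
#' @param scheme A `binning_scheme`.
#' @param path JSON file path.
#' @return `write_binning_scheme()` the path, invisibly;
#'   `read_binning_scheme()` the scheme.
#' @export
write_binning_scheme <- function(scheme, path) {
  # edges are printed with 17 significant digits so doubles survive the
  # round trip exactly (jsonlite caps at 15)
  esc <- function(s) gsub("\"", "\\\\\"", s)
  entry_json <- vapply(names(scheme), function(f) {
    e <- scheme[[f]]
    edges <- paste(sprintf("%.17g", e$edges), collapse = ", ")
    labels <- paste(sprintf("\"%s\"", esc(e$labels)), collapse = ", ")
    sprintf("  \"%s\": {\n    \"edges\": [%s],\n    \"labels\": [%s],\n    \"direction_note\": \"%s\"\n  }",
            esc(f), edges, labels, esc(e$direction_note))
  }, "")
  writeLines(paste0("{\n", paste(entry_json, collapse = ",\n"), "\n}"), path)
  invisible(path)
}

#' @rdname write_binning_scheme
#' @export
read_binning_scheme <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- lapply(raw, function(e) {
    bin_entry(as.numeric(e$edges), as.character(e$labels),
              if (is.null(e$direction_note)) "" else e$direction_note)
  })
  structure(entries, class = "binning_scheme")
}

#' Published reference discretization scheme
#'
#' The frozen reference bin edges and label vocabularies for the five
#' discretized headline features, shipped as a plain-text fixture. These
#' edges were derived on the reference candidate-set distribution; in normal
#' use schemes are re-fit on the current run's candidates with
#' [fit_binning_scheme()] and this fixture serves as a stable regression
#' reference.
#'
#' @return A `binning_scheme`.
#' @export
reference_binning_scheme <- function() {
  read_binning_scheme(system.file("extdata", "reference_bins.json",
                                  package = "bspair", mustWork = TRUE))
}
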