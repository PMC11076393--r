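#' Default one-line glossary for the headline features
#'
#' Short meanings included in the prompt so the language model can argue
#' about each discretized feature.
#'
#' @param features Feature names.
#' @return Named character vector.
#' @export
default_feature_glossary <- function(features = headline_features()) {
  glossary <- c(
    embedding_distance = "Euclidean distance between the two targets' gene-embedding vectors; small distances mean the genes share expression context and likely function.",
    safety_score = "Combined tumor-minus-normal expression contrast of the two targets; higher values mean expression is more tumor-restricted, hence safer.",
    pearson_r = "Pearson correlation of the two targets' expression across single cells; positive values mean the targets tend to be expressed in the same cells.",
    single_ratio_max = "The larger of the two targets' single-positive cell proportions within their most expressing populations; measures overall target activity.",
    double_ratio_max = "Highest proportion of cells expressing both targets above threshold in any evaluated population; measures co-expression on the same cells.",
    cooccurrence_count = "Number of curated pathways containing both targets; shared pathways suggest a common mechanism of action."
  )
  miss <- setdiff(features, names(glossary))
  if (length(miss)) {
    stop("no default glossary for feature(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  glossary[features]
}

#' Bundle everything the report stage needs for one pair
#'
#' @param pair A canonical pair.
#' @param nl_features Named character vector: headline feature ->
#'   natural-language label (from [discretize_to_language()]).
#' @param score Model prediction score for the pair.
#' @param rank 1-based rank of the pair among all scored candidates.
#' @param n_candidates Number of scored candidates.
#' @param glossary Named character vector: feature -> one-line meaning; must
#'   cover every feature in `nl_features`.
#' @param template_id Identifier of the prompt template.
#' @return An object of class `prompt_bundle`.
#' @export
prompt_bundle <- function(pair, nl_features, score, rank, n_candidates,
                          glossary = default_feature_glossary(names(nl_features)),
                          template_id = "default-v1") {
  p <- as_pair(pair)
  stopifnot(length(nl_features) >= 1, !is.null(names(nl_features)))
  miss <- setdiff(names(nl_features), names(glossary))
  if (length(miss)) {
    stop("glossary entry missing for feature(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  stopifnot(rank >= 1, rank <= n_candidates)
  structure(list(gene_a = p[1L], gene_b = p[2L],
                 nl_features = nl_features,
                 score = as.numeric(score), rank = as.integer(rank),
                 n_candidates = as.integer(n_candidates),
                 glossary = glossary[names(nl_features)],
                 template_id = template_id),
            class = "prompt_bundle")
}

#' Discretize a pair's feature row into natural-language labels
#'
#' @param feature_row One row of a feature table (data.frame or named
#'   vector) for the pair.
#' @param scheme A fitted `binning_scheme`.
#' @return Named character vector, one label per scheme feature.
#' @export
discretize_features <- function(feature_row, scheme) {
  if (is.data.frame(feature_row)) {
    stopifnot(nrow(feature_row) == 1)
    feature_row <- unlist(feature_row[setdiff(names(feature_row),
                                              c("gene_a", "gene_b"))])
  }
  vapply(names(scheme), function(f) {
    discretize_to_language(as.numeric(feature_row[[f]]), scheme, f)
  }, "")
}

#' Assemble the deterministic analysis prompt
#'
#' Produces the retrieval-augmented prompt text: both targets, each headline
#' feature's language label with its glossary meaning, the model score and
#' rank among all candidates, and an instruction block requesting per-target
#' clinical context plus a combined conclusion. Byte-identical for identical
#' bundles.
#'
#' @param bundle A [prompt_bundle()].
#' @return A single character string.
#' @export
assemble_prompt <- function(bundle) {
  stopifnot(inherits(bundle, "prompt_bundle"))
  feat_lines <- vapply(names(bundle$nl_features), function(f) {
    sprintf("- %s: %s. (%s)", f, bundle$nl_features[[f]],
            bundle$glossary[[f]])
  }, "")
  paste0(
    "You are assisting the design of a bispecific antibody. Assess the ",
    "target pair ", bundle$gene_a, " + ", bundle$gene_b, ".\n\n",
    "Machine learning evidence (features discretized among all candidate ",
    "pairs):\n",
    paste(feat_lines, collapse = "\n"), "\n\n",
    "Machine learning model prediction score: ",
    format(bundle$score, trim = TRUE), ". Ranked ",
    format(bundle$rank, big.mark = ","), " out of ",
    format(bundle$n_candidates, big.mark = ","), " candidates.\n\n",
    "Instructions:\n",
    "1. Summarize the clinical progress of therapies against ",
    bundle$gene_a, ", citing recent results.\n",
    "2. Summarize the clinical progress of therapies against ",
    bundle$gene_b, ", citing recent results.\n",
    "3. Discuss each machine learning feature above and what it implies ",
    "for combining the two targets.\n",
    "4. Conclude whether the pair is a promising bispecific combination, ",
    "weighing efficacy and safety.\n",
    "[template ", bundle$template_id, "]\n")
}

#' Offline template report renderer
#'
#' The default, network-free "LLM client": ignores the prompt text and
#' renders a structured markdown report directly from the bundle, with
#' per-target sections, a model-analysis bullet list and a conclusion.
#'
#' @return A client function `f(prompt, bundle)` returning report text.
#' @export
offline_llm_client <- function() {
  function(prompt, bundle) {
    feat_lines <- vapply(names(bundle$nl_features), function(f) {
      sprintf("- %s: %s. %s", f, bundle$nl_features[[f]],
              bundle$glossary[[f]])
    }, "")
    paste0(
      "# Bispecific target-pair analysis: ", bundle$gene_a, " + ",
      bundle$gene_b, "\n\n",
      "## ", bundle$gene_a, "\n",
      "Clinical progress: consult the cited trial literature for ",
      bundle$gene_a, "-directed therapies (offline rendering; no ",
      "retrieval performed).\n\n",
      "## ", bundle$gene_b, "\n",
      "Clinical progress: consult the cited trial literature for ",
      bundle$gene_b, "-directed therapies (offline rendering; no ",
      "retrieval performed).\n\n",
      "## Machine learning model analysis\n",
      paste(feat_lines, collapse = "\n"), "\n",
      "- Machine learning model prediction score: ",
      format(bundle$score, trim = TRUE), ". Ranked ",
      format(bundle$rank, big.mark = ","), " out of ",
      format(bundle$n_candidates, big.mark = ","), " candidates.\n\n",
      "## Conclusion\n",
      "The model ranks ", bundle$gene_a, " + ", bundle$gene_b, " ",
      format(bundle$rank, big.mark = ","), " of ",
      format(bundle$n_candidates, big.mark = ","),
      " candidate pairs (score ", format(bundle$score, trim = TRUE),
      "). Feature standing — ",
      paste(sprintf("%s: %s", names(bundle$nl_features),
                    unname(bundle$nl_features)), collapse = "; "),
      ". Weigh the safety standing against the activity evidence before ",
      "advancing this combination.\n")
  }
}

#' Render the final analysis report
#'
#' Sends the assembled prompt to the configured client (any function
#' `f(prompt, bundle) -> text`, e.g. a wrapper around a hosted LLM). If the
#' client fails, falls back to the offline template renderer and flags the
#' provenance.
#'
#' @param bundle A [prompt_bundle()].
#' @param client A client function; default [offline_llm_client()].
#' @return An object of class `pair_report`: list with `body`, `prompt`,
#'   `provenance` (client id, fallback flag, template id).
#' @export
render_report <- function(bundle, client = offline_llm_client()) {
  prompt <- assemble_prompt(bundle)
  fallback <- FALSE
  body <- tryCatch(client(prompt, bundle), error = function(e) {
    warning("LLM client failed (", conditionMessage(e),
            "); falling back to offline rendering")
    fallback <<- TRUE
    offline_llm_client()(prompt, bundle)
  })
  structure(list(body = body, prompt = prompt,
                 provenance = list(
                   client = if (fallback) "offline_fallback" else "client",
                   offline_fallback = fallback,
                   template_id = bundle$template_id)),
            class = "pair_report")
}

#' @export
print.pair_report <- function(x, ...) {
  cat(x$body)
  invisible(x)
}
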