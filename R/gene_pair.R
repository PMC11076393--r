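#' Canonical unordered gene pairs
#'
#' A target pair is an unordered pair of distinct gene symbols — the two
#' binding arms of a bispecific antibody. Pairs are stored canonically with
#' `gene_a < gene_b` (lexicographic, C locale) so that `gene_pair("B","A")`
#' and `gene_pair("A","B")` are identical. Symbols are matched case-sensitively
#' after whitespace trimming; an alias map hook is available via
#' [apply_gene_aliases()] and ships empty.
#'
#' @param gene_a,gene_b Character vectors of gene symbols (recycled to a
#'   common length).
#' @return A data.frame with columns `gene_a`, `gene_b` in canonical order.
#' @examples
#' gene_pair("CTLA4", "CD274")
#' @export
gene_pair <- function(gene_a, gene_b) {
  a <- trimws(as.character(gene_a))
  b <- trimws(as.character(gene_b))
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    stop("gene symbols must be non-empty strings", call. = FALSE)
  }
  if (any(a == b)) {
    bad <- a[a == b][1L]
    stop("a target pair needs two distinct genes (got '", bad, "' twice)",
         call. = FALSE)
  }
  swap <- cmp_gt(a, b)
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE)
}

# locale-independent string comparison (C collation)
cmp_gt <- function(a, b) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  a > b
}

#' @rdname gene_pair
#' @param pairs A pair data.frame as returned by [gene_pair()].
#' @return `pair_key()`: character keys `"A|B"` identifying each canonical pair.
#' @export
pair_key <- function(pairs) {
  paste(pairs$gene_a, pairs$gene_b, sep = "|")
}

#' Apply a gene-symbol alias map
#'
#' Hook for reconciling symbol dialects (e.g. protein names like PD-L1 versus
#' HGNC symbols like CD274). The default alias map is empty: symbols pass
#' through untouched.
#'
#' @param genes Character vector of symbols.
#' @param aliases Named character vector mapping alias -> canonical symbol.
#' @return Character vector with aliases replaced.
#' @export
apply_gene_aliases <- function(genes, aliases = character()) {
  if (length(aliases) == 0) return(genes)
  hit <- genes %in% names(aliases)
  genes[hit] <- unname(aliases[genes[hit]])
  genes
}

#' Enumerate all candidate target pairs from a gene list
#'
#' Forms every unordered pair from a curated candidate list (typically a few
#' hundred common membrane proteins), in deterministic lexicographic order:
#' `m` genes give `m(m-1)/2` pairs.
#'
#' @param gene_list Character vector of unique gene symbols, length >= 2.
#' @return A canonical pair data.frame with `choose(m, 2)` rows.
#' @examples
#' enumerate_candidates(c("A", "B", "C"))
#' @export
enumerate_candidates <- function(gene_list) {
  genes <- trimws(as.character(gene_list))
  if (length(genes) < 2) {
    stop("need at least 2 genes to form candidate pairs", call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    stop("duplicate genes in candidate list: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  genes <- sort_c(genes)
  idx <- utils::combn(length(genes), 2)
  data.frame(gene_a = genes[idx[1L, ]], gene_b = genes[idx[2L, ]],
             stringsAsFactors = FALSE)
}

# sort under C collation for reproducibility across locales
sort_c <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  sort(x, method = "radix")
}

order_c <- function(...) {
  order(..., method = "radix")
}
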