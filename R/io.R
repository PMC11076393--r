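#' Read a candidate gene list
#'
#' One gene symbol per line; blank lines ignored.
#'
#' @param path File path.
#' @return Character vector of symbols in file order.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x[nzchar(trimws(x))])
  if (length(x) == 0) stop("gene list '", path, "' is empty", call. = FALSE)
  x
}

#' Read pathway gene sets in GMT format
#'
#' Each tab-separated line is `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within one pathway are de-duplicated; lines with no genes
#' are skipped with a warning.
#'
#' @param path Path to a GMT file.
#' @return A `pathway_db` object: list with `pathways` (named list of
#'   character gene sets) and `source`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 0L) < 3L
  if (any(short)) {
    warning(sum(short), " GMT line(s) with no genes skipped")
    fields <- fields[!short]
  }
  if (length(fields) == 0) stop("GMT file '", path, "' has no usable pathways",
                                call. = FALSE)
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate pathway ids in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(trimws(f[-(1:2)])))
  sets <- lapply(sets, function(g) g[nzchar(g)])
  empty <- vapply(sets, length, 0L) == 0L
  if (any(empty)) {
    warning(sum(empty), " empty pathway(s) skipped")
    sets <- sets[!empty]
    ids <- ids[!empty]
  }
  names(sets) <- ids
  pathway_db(sets, source = path)
}

#' Construct a pathway database
#'
#' @param pathways Named list of character gene sets (non-empty, unique ids).
#' @param source Free-text provenance.
#' @return A `pathway_db` object.
#' @export
pathway_db <- function(pathways, source = "unknown") {
  stopifnot(is.list(pathways), !is.null(names(pathways)))
  if (anyDuplicated(names(pathways))) stop("pathway ids must be unique",
                                           call. = FALSE)
  if (any(vapply(pathways, length, 0L) == 0L)) {
    stop("pathway gene sets must be non-empty", call. = FALSE)
  }
  structure(list(pathways = lapply(pathways, unique), source = source),
            class = "pathway_db")
}

#' Write pathway gene sets in GMT format
#' @param db A `pathway_db`.
#' @param path Output path.
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(names(db$pathways), function(id) {
    paste(c(id, db$source, db$pathways[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-embedding table
#'
#' Tab-separated: gene symbol followed by `n` floats per line (Gene2Vec-style;
#' the dimensionality is whatever the file provides, commonly 200). Rows of
#' inconsistent length are a format error.
#'
#' @param path Path to the embedding TSV.
#' @return A `gene_embedding` object: list with `vectors` (genes x dim numeric
#'   matrix, rownames = symbols) and `dim`.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("embedding file '", path, "' is empty",
                               call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  lens <- vapply(fields, length, 0L)
  if (length(unique(lens)) != 1L) {
    stop("ragged embedding rows: lengths ", paste(unique(lens), collapse = ", "),
         call. = FALSE)
  }
  if (lens[1L] < 2L) stop("embedding rows need a gene plus >= 1 value",
                          call. = FALSE)
  genes <- vapply(fields, `[[`, "", 1L)
  vals <- t(vapply(fields, function(f) as.numeric(f[-1L]),
                   numeric(lens[1L] - 1L)))
  if (anyNA(vals)) stop("non-numeric embedding values", call. = FALSE)
  rownames(vals) <- trimws(genes)
  gene_embedding(vals)
}

#' Construct a gene-embedding table
#' @param vectors Genes x dim numeric matrix with gene symbols as rownames.
#' @return A `gene_embedding` object.
#' @export
gene_embedding <- function(vectors) {
  stopifnot(is.matrix(vectors), is.numeric(vectors), ncol(vectors) >= 1,
            !is.null(rownames(vectors)))
  if (anyDuplicated(rownames(vectors))) {
    stop("duplicate genes in embedding table", call. = FALSE)
  }
  structure(list(vectors = vectors, dim = ncol(vectors)),
            class = "gene_embedding")
}

#' Write a gene-embedding table as TSV
#' @param emb A `gene_embedding`.
#' @param path Output path.
#' @export
write_embeddings <- function(emb, path) {
  lines <- vapply(seq_len(nrow(emb$vectors)), function(i) {
    paste(c(rownames(emb$vectors)[i],
            format(emb$vectors[i, ], digits = 17, trim = TRUE,
                   scientific = FALSE)), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a drug clinical-progress table
#'
#' Accepts TSV/CSV (by extension) or XLSX (requires the readxl package).
#' Required columns: `drug`, `target_a`, `target_b`, `clinical_progress`.
#' Each usable row becomes one drug record with an ordinal stage code 1-5
#' assigned by [parse_stage()]. Rows whose two targets coincide or whose
#' stage text is unrecognized are rejected; rejections are counted, messaged,
#' and attached as attribute `"rejected"`.
#'
#' @param path Path to the table.
#' @return A data.frame of drug records: `drug_id`, `gene_a`, `gene_b`
#'   (canonical order), `stage_text`, `stage_code`.
#' @export
read_drug_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  tab <- switch(ext,
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("reading .xlsx requires the readxl package; convert to TSV instead",
             call. = FALSE)
      }
      as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
    },
    csv = utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  )
  required <- c("drug", "target_a", "target_b", "clinical_progress")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("drug table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  drug_records(tab)
}

# validate rows and assemble canonical drug records
drug_records <- function(tab) {
  rejected <- data.frame(row = integer(), reason = character(),
                         stringsAsFactors = FALSE)
  a <- trimws(as.character(tab$target_a))
  b <- trimws(as.character(tab$target_b))
  stage <- parse_stage(as.character(tab$clinical_progress), strict = FALSE)
  same <- a == b
  bad_stage <- is.na(stage) & !same
  keep <- !same & !bad_stage
  if (any(same)) {
    rejected <- rbind(rejected, data.frame(
      row = which(same), reason = "target_a == target_b"))
  }
  if (any(bad_stage)) {
    rejected <- rbind(rejected, data.frame(
      row = which(bad_stage),
      reason = paste0("unrecognized stage '",
                      tab$clinical_progress[bad_stage], "'")))
  }
  if (nrow(rejected)) {
    message("rejected ", nrow(rejected), " drug-table row(s)")
  }
  pairs <- gene_pair(a[keep], b[keep])
  out <- data.frame(drug_id = as.character(tab$drug)[keep],
                    gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                    stage_text = as.character(tab$clinical_progress)[keep],
                    stage_code = stage[keep],
                    stringsAsFactors = FALSE)
  attr(out, "rejected") <- rejected
  out
}

#' Write a drug clinical-progress table as TSV
#' @param records Drug records as from [read_drug_table()].
#' @param path Output path.
#' @export
write_drug_table <- function(records, path) {
  utils::write.table(
    data.frame(drug = records$drug_id, target_a = records$gene_a,
               target_b = records$gene_b, clinical_progress = records$stage_text),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a feature table as TSV
#' @param features Feature data.frame from [build_feature_table()].
#' @param path Output path.
#' @export
write_feature_table <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
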