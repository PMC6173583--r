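#' Expression study container
#'
#' Bundles a genes x samples expression matrix with per-sample metadata; the
#' unit of all expression computation in the package. Metadata rows align 1:1
#' with matrix columns.
#'
#' @param expr Numeric matrix, genes in rows (unique rownames), samples in
#'   columns (colnames).
#' @param sample_meta Data frame with one row per sample. Must contain a
#'   `sample_id` column matching `colnames(expr)`; conventional columns are
#'   `study_id`, `condition`, `severity`, `timepoint_days`, `platform`.
#' @return An object of class `expression_study`: a list with elements `expr`
#'   and `sample_meta` (a tibble).
#' @export
expression_study <- function(expr, sample_meta = NULL) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort("`expr` must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(expr))) abort("`expr` must have gene rownames")
  if (anyDuplicated(rownames(expr))) abort("duplicated gene ids in `expr`")
  if (is.null(colnames(expr))) {
    colnames(expr) <- sprintf("sample%03d", seq_len(ncol(expr)))
  }
  if (is.null(sample_meta)) {
    sample_meta <- tibble::tibble(sample_id = colnames(expr))
  }
  sample_meta <- tibble::as_tibble(sample_meta)
  if (!"sample_id" %in% names(sample_meta)) {
    abort("`sample_meta` must contain a `sample_id` column")
  }
  if (nrow(sample_meta) != ncol(expr) ||
      !all(sample_meta$sample_id == colnames(expr))) {
    abort("`sample_meta` rows must align 1:1 with `expr` columns")
  }
  structure(list(expr = expr, sample_meta = sample_meta),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %d genes x %d samples\n",
              nrow(x$expr), ncol(x$expr)))
  extra <- setdiff(names(x$sample_meta), "sample_id")
  if (length(extra)) cat("metadata:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$expr)

#' Read / write an expression study as plain TSV
#'
#' The expression file has genes as rows with a leading `gene` column and one
#' column per sample; the metadata file has one row per sample.
#'
#' @param path,meta_path File paths for the expression matrix and the
#'   sample-metadata table.
#' @param study An `expression_study`.
#' @return `read_expression_tsv()` returns an `expression_study`;
#'   `write_expression_tsv()` returns `study` invisibly.
#' @export
read_expression_tsv <- function(path, meta_path = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  expr <- as.matrix(df[, -1, drop = FALSE])
  rownames(expr) <- df[[1]]
  meta <- if (!is.null(meta_path)) {
    tibble::as_tibble(utils::read.delim(meta_path, check.names = FALSE))
  } else NULL
  expression_study(expr, meta)
}

#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(study, path, meta_path = NULL) {
  df <- data.frame(gene = rownames(study$expr), study$expr,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path)) {
    utils::write.table(as.data.frame(study$sample_meta), meta_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(study)
}

#' Read / write gene sets in GMT format
#'
#' GMT is the tab-delimited gene-set format: one set per line as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path File path.
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @return `read_gmt()` returns a named list of character vectors with a
#'   `descriptions` attribute; `write_gmt()` returns `sets` invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, "", 1)
  attr(sets, "descriptions") <-
    setNames(vapply(parts, `[`, "", 2), names(sets))
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% attr(sets, "descriptions") %||%
    setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[[i]], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(sets)
}
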