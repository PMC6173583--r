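#' Majority-vote ortholog mapping
#'
#' Maps source-species gene accessions to human genes by consensus across
#' several ortholog databases: for each source id, considering only the
#' databases that contain an entry for it, a human gene is accepted iff it is
#' proposed by at least half of them (ceiling). If two or more distinct human
#' genes meet the bar the id is ambiguous and left unmapped.
#'
#' @param source_ids Character vector of source accessions.
#' @param tables List of ortholog tables; each is a list with elements
#'   `database_name` and `mapping` (a named list: source id -> character
#'   vector of human gene ids).
#' @return A tibble with columns `source_id`, `human_gene` (`NA` when
#'   unmappable or ambiguous) and `n_databases` (databases with an entry).
#' @export
map_orthologs_majority <- function(source_ids, tables) {
  if (length(tables) < 1) abort("at least one ortholog table is required")
  dbnames <- vapply(tables, function(t) t$database_name, "")
  if (anyDuplicated(dbnames)) abort("ortholog database names must be unique")
  purrr::map_dfr(unique(source_ids), function(id) {
    hits <- purrr::compact(lapply(tables, function(t) t$mapping[[id]]))
    d <- length(hits)
    if (d == 0) {
      return(tibble::tibble(source_id = id, human_gene = NA_character_,
                            n_databases = 0L))
    }
    # one vote per database per human gene
    votes <- table(unlist(lapply(hits, unique)))
    bar <- ceiling(d / 2)
    winners <- names(votes)[votes >= bar]
    gene <- if (length(winners) == 1) winners else NA_character_
    tibble::tibble(source_id = id, human_gene = gene, n_databases = d)
  })
}

#' Parse a literature-curated gene table
#'
#' Reads curation records (one per gene per study) and derives the unique
#' human gene set. Non-human accessions are mapped through
#' [map_orthologs_majority()]; unmappable rows are dropped with a message.
#' Direction vocabulary is fixed to up/down/phospho.
#'
#' @param path A TSV file path, or a data frame already in the schema.
#'   Required columns: `gene`, `species`, `direction`, `technique`, `model`,
#'   `timepoint`, `study_id`.
#' @param ortholog_tables Optional list of ortholog tables (see
#'   [map_orthologs_majority()]); required if any record is non-human.
#' @return An object of class `curated_gene_set`: a list with `records`
#'   (tibble, with a `human_gene` column), `genes` (unique mapped human gene
#'   ids), `study_counts` (named integer vector of distinct studies per
#'   gene), and `summary` (one-row tibble of the curation counts).
#' @export
parse_curated_table <- function(path, ortholog_tables = NULL) {
  records <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    tibble::as_tibble(utils::read.delim(path, check.names = FALSE,
                                        colClasses = "character"))
  }
  required <- c("gene", "species", "direction", "technique", "model",
                "timepoint", "study_id")
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    abort(sprintf("curated table is missing required column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "scinet_parse_error")
  }
  bad_dir <- setdiff(unique(records$direction), c("up", "down", "phospho"))
  if (length(bad_dir)) {
    abort(sprintf("unknown direction value(s): %s",
                  paste(bad_dir, collapse = ", ")),
          class = "scinet_parse_error")
  }

  records$human_gene <- records$gene
  nonhuman <- records$species != "human"
  if (any(nonhuman)) {
    if (is.null(ortholog_tables)) {
      abort("non-human records present but no ortholog tables supplied",
            class = "scinet_parse_error")
    }
    map <- map_orthologs_majority(unique(records$gene[nonhuman]),
                                  ortholog_tables)
    idx <- match(records$gene[nonhuman], map$source_id)
    records$human_gene[nonhuman] <- map$human_gene[idx]
    n_drop <- sum(is.na(records$human_gene[nonhuman]))
    if (n_drop > 0) {
      message(sprintf("dropping %d record(s) without a consensus ortholog",
                      n_drop))
    }
  }
  mapped <- records[!is.na(records$human_gene), , drop = FALSE]
  if (nrow(mapped) == 0) {
    abort("no records could be mapped to human genes",
          class = "scinet_empty_error")
  }

  genes <- sort(unique(mapped$human_gene))
  study_counts <- vapply(
    split(mapped$study_id, mapped$human_gene),
    function(x) length(unique(x)), integer(1))[genes]
  dir_genes <- function(d) length(unique(mapped$human_gene[mapped$direction == d]))
  summary <- tibble::tibble(
    n_genes = length(genes),
    n_up = dir_genes("up"),
    n_down = dir_genes("down"),
    n_phospho = dir_genes("phospho"),
    n_multi_study = sum(study_counts > 1),
    n_records = nrow(mapped)
  )
  structure(list(records = mapped, genes = genes,
                 study_counts = study_counts, summary = summary),
            class = "curated_gene_set")
}

#' @export
print.curated_gene_set <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "<curated_gene_set> %d unique human genes from %d records\n",
    "  %d up / %d down / %d phospho; %d associated by more than one study\n"),
    s$n_genes, s$n_records, s$n_up, s$n_down, s$n_phospho, s$n_multi_study))
  invisible(x)
}

#' Write a curated gene set back to the ingest TSV schema
#' @param curated A `curated_gene_set`.
#' @param path Output file.
#' @export
write_curated_table <- function(curated, path) {
  cols <- c("gene", "species", "direction", "technique", "model",
            "timepoint", "study_id")
  utils::write.table(as.data.frame(curated$records[, cols]), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(curated)
}

#' Expression filtering on minimum abundance
#'
#' Retains genes whose value exceeds `min_value` (strictly) in at least
#' `min_individuals` samples.
#'
#' @param study An [expression_study()].
#' @param min_value Abundance threshold (exclusive).
#' @param min_individuals Minimum number of samples above threshold.
#' @return A filtered [expression_study()].
#' @export
filter_expression <- function(study, min_value = 0.1, min_individuals = 10) {
  keep <- rowSums(study$expr > min_value) >= min_individuals
  if (!any(keep)) {
    abort("no genes pass the expression filter",
          class = "scinet_empty_error")
  }
  expression_study(study$expr[keep, , drop = FALSE], study$sample_meta)
}

#' Quantile normalisation of samples
#'
#' Transforms each sample to the average empirical distribution across all
#' samples: after the transform, the sorted values of every sample equal the
#' per-rank mean of the sorted input columns. Ties within a sample receive
#' the mean of their target quantiles.
#'
#' @param study An [expression_study()].
#' @return An [expression_study()] with normalised columns.
#' @export
quantile_normalize_samples <- function(study) {
  x <- study$expr
  if (ncol(x) < 2) {
    warn("single sample: quantile normalisation is the identity")
    return(study)
  }
  target <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) {
    ord <- order(col)
    grp <- cumsum(c(TRUE, diff(col[ord]) != 0))
    res <- numeric(length(col))
    res[ord] <- stats::ave(target, grp)
    res
  })
  dimnames(out) <- dimnames(x)
  expression_study(out, study$sample_meta)
}

#' Rank-based inverse normal transform per gene
#'
#' Replaces each gene row by standard-normal quantiles of its mid-ranks:
#' `qnorm((rank - 0.5) / n)`, with ranks averaged on ties. Constant rows
#' become all zeros with a warning.
#'
#' @param study An [expression_study()] with at least 3 samples.
#' @return An [expression_study()].
#' @export
inverse_normal_transform_genes <- function(study) {
  x <- study$expr
  if (ncol(x) < 3) abort("at least 3 samples are required")
  n <- ncol(x)
  const <- apply(x, 1, function(r) max(r) == min(r))
  if (any(const)) {
    warn(sprintf("%d constant gene row(s) set to zero", sum(const)))
  }
  out <- t(apply(x, 1, function(r) {
    if (max(r) == min(r)) return(rep(0, n))
    qnorm((rank(r, ties.method = "average") - 0.5) / n)
  }))
  dimnames(out) <- dimnames(x)
  expression_study(out, study$sample_meta)
}

#' Collapse duplicate probes to genes by the element-wise median
#'
#' @param study An [expression_study()] whose rows are probes.
#' @param id_map Named character vector mapping row ids (names) to gene ids
#'   (values). Rows not covered are dropped.
#' @return An [expression_study()] with one row per gene.
#' @export
collapse_duplicates_median <- function(study, id_map) {
  rows <- intersect(rownames(study$expr), names(id_map))
  if (length(rows) == 0) abort("id_map covers no rows of the matrix")
  x <- study$expr[rows, , drop = FALSE]
  groups <- split(seq_len(nrow(x)), id_map[rows])
  out <- t(vapply(groups, function(idx) {
    apply(x[idx, , drop = FALSE], 2, median)
  }, numeric(ncol(x))))
  rownames(out) <- names(groups)
  colnames(out) <- colnames(x)
  expression_study(out, study$sample_meta)
}

#' Full expression preprocessing
#'
#' Filtering, sample quantile normalisation and per-gene inverse normal
#' transform, in that order.
#'
#' @inheritParams filter_expression
#' @return A preprocessed [expression_study()].
#' @export
preprocess_expression <- function(study, min_value = 0.1,
                                  min_individuals = 10) {
  study |>
    filter_expression(min_value, min_individuals) |>
    quantile_normalize_samples() |>
    inverse_normal_transform_genes()
}
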