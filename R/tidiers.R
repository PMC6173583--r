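#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a module partition
#'
#' @param x A `module_partition`.
#' @param ... Unused.
#' @return A tibble with one row per gene: `gene`, `module`, and (when kME
#'   is available) `kme`, the gene's correlation with its own module
#'   eigengene (`NA` for unassigned genes).
#' @export
tidy.module_partition <- function(x, ...) {
  out <- tibble::tibble(gene = names(x$labels), module = unname(x$labels))
  if (!is.null(x$kme)) {
    out$kme <- vapply(seq_len(nrow(out)), function(i) {
      m <- out$module[i]
      if (m == 0) return(NA_real_)
      x$kme[out$gene[i], paste0("ME", m)]
    }, numeric(1))
  }
  out
}

#' @rdname tidy.module_partition
#' @return `glance()` returns a one-row tibble: `n_genes`, `n_modules`,
#'   `n_assigned`, `beta`, `method`, `mean_prop_var_explained`.
#' @export
glance.module_partition <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$labels),
    n_modules = length(x$module_sizes),
    n_assigned = sum(x$labels > 0),
    beta = x$beta,
    method = x$method,
    mean_prop_var_explained = if (is.null(x$prop_var_explained)) NA_real_
    else mean(x$prop_var_explained))
}

#' Tidy a null-ensemble test result
#'
#' @param x A `null_ensemble`.
#' @param ... Unused.
#' @return A one-row tibble: statistic name, observed value, null mean and
#'   sd, `n_null`, `empirical_p`.
#' @export
tidy.null_ensemble <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, observed = x$observed,
                 null_mean = mean(x$null_values),
                 null_sd = sd(x$null_values),
                 n_null = x$n_null, empirical_p = x$empirical_p)
}

#' Tidy a preservation result
#'
#' @param x A `preservation_result`.
#' @param ... Unused.
#' @return The per-module summary tibble (observed statistics, Z scores,
#'   `z_density`, `z_connectivity`, `z_summary`).
#' @export
tidy.preservation_result <- function(x, ...) x$summary

#' @rdname tidy.preservation_result
#' @return `glance()` returns a one-row tibble: module counts in the strong
#'   (>10), moderate (5-10) and absent (<2) preservation bands.
#' @export
glance.preservation_result <- function(x, ...) {
  z <- x$summary$z_summary
  tibble::tibble(n_modules = length(z), n_perm = x$n_perm,
                 method = x$method,
                 n_strong = sum(z > 10), n_moderate = sum(z > 5 & z <= 10),
                 n_absent = sum(z < 2))
}

#' Tidy a severity result
#'
#' @param x A `severity_result`.
#' @param ... Unused.
#' @return Per-module tibble joining score enrichment and eigengene-severity
#'   correlation.
#' @export
tidy.severity_result <- function(x, ...) {
  dplyr::left_join(x$module_enrichment, x$eigengene_severity, by = "module")
}

#' Tidy a classifier result
#'
#' @param x A `classifier_result`.
#' @param ... Unused.
#' @return The per-sample prediction tibble.
#' @export
tidy.classifier_result <- function(x, ...) x$predictions

#' @rdname tidy.classifier_result
#' @return `glance()` returns a one-row tibble with the LOOCV accuracy and
#'   the number of features and samples.
#' @export
glance.classifier_result <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 n_features = length(x$features),
                 n_samples = nrow(x$predictions))
}

#' @rdname tidy.module_partition
#' @export
glance.curated_gene_set <- function(x, ...) x$summary
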