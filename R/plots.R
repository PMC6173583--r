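#' Plot a null-ensemble test
#'
#' Histogram of the null distribution with the observed statistic as a
#' dashed vertical line (the conventional randomized-interactome display).
#'
#' @param object A `null_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.null_ensemble <- function(object, ...) {
  df <- tibble::tibble(value = object$null_values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = object$statistic, y = "null networks",
                  title = sprintf("observed %.4g, empirical p = %.3g",
                                  object$observed, object$empirical_p)) +
    ggplot2::theme_minimal()
}

#' Plot module preservation Zsummary
#'
#' Zsummary per module against module size, with the conventional evidence
#' bands (2, 5, 10) as horizontal lines.
#'
#' @param object A `preservation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.preservation_result <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$n_genes, y = .data$z_summary,
                               label = .data$module)) +
    ggplot2::geom_hline(yintercept = c(2, 5, 10), linetype = "dotted",
                        colour = c("red", "orange", "darkgreen")) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = "module size", y = "Zsummary") +
    ggplot2::theme_minimal()
}

#' Plot module eigengenes across samples
#'
#' @param object A `module_partition`.
#' @param ... Unused.
#' @return A ggplot tile plot of eigengene values (modules x samples).
#' @export
autoplot.module_partition <- function(object, ...) {
  if (is.null(object$eigengenes)) abort("partition has no eigengenes")
  df <- as.data.frame(object$eigengenes)
  df$module <- rownames(object$eigengenes)
  long <- tidyr::pivot_longer(df, -"module", names_to = "sample",
                              values_to = "eigengene")
  long$sample <- factor(long$sample, levels = colnames(object$eigengenes))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$module,
                                     fill = .data$eigengene)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "sample", y = NULL)
}

#' Plot per-study and consensus module differential expression
#'
#' Tile plot of signed significance (`-log10` adjusted p, signed by
#' direction) per study and module, the consensus column last.
#'
#' @param de A tibble from [module_de()].
#' @param consensus Optional tibble from [consensus_calls()].
#' @return A ggplot object.
#' @export
plot_module_de <- function(de, consensus = NULL) {
  df <- de |>
    dplyr::mutate(signed = dplyr::case_when(
      .data$direction == "up" ~ -log10(pmax(.data$p_up_adj, 1e-300)),
      .data$direction == "down" ~ log10(pmax(.data$p_down_adj, 1e-300)),
      TRUE ~ 0))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$study_id,
                                        y = factor(.data$module),
                                        fill = .data$signed)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  name = "signed -log10 p") +
    ggplot2::labs(x = NULL, y = "module") +
    ggplot2::theme_minimal()
  if (!is.null(consensus)) {
    p <- p + ggplot2::geom_text(
      data = dplyr::mutate(consensus, study_id = "consensus", signed = 0),
      ggplot2::aes(label = sub("_(up|down)", "", .data$consensus)),
      size = 2.5)
  }
  p
}

#' Plot eigengene versus injury severity
#'
#' @param severity_result A `severity_result`.
#' @param study The [expression_study()] it was computed from.
#' @param partition The `module_partition` used.
#' @param module Module to display (default: maximal `|rho|`).
#' @return A ggplot scatter of the module eigengene against severity.
#' @export
plot_eigengene_severity <- function(severity_result, study, partition,
                                    module = NULL) {
  es <- severity_result$eigengene_severity
  module <- module %||% es$module[which.max(abs(es$rho))]
  me <- module_eigengenes(study, partition_labels(partition))$eigengenes
  df <- tibble::tibble(severity = study$sample_meta$severity,
                       eigengene = me[paste0("ME", module), ])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$severity,
                                   y = .data$eigengene)) +
    ggplot2::geom_jitter(width = diff(range(df$severity)) / 50, height = 0) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red") +
    ggplot2::labs(x = "injury severity", y = sprintf("M%s eigengene", module),
                  title = sprintf("Spearman rho = %.2f, p = %.2g",
                                  es$rho[es$module == module],
                                  es$p_value[es$module == module])) +
    ggplot2::theme_minimal()
}
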