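#' Per-gene differential statistics for one study
#'
#' For a two-group contrast, the pooled-variance two-sample t statistic
#' (positive = higher in the first group) with its two-sided p-value; for a
#' continuous covariate (e.g. injury severity), the Spearman correlation with
#' a t-approximation p-value.
#'
#' @param study An [expression_study()].
#' @param contrast Either `"condition"` (two-group) or the name of a numeric
#'   metadata column (continuous covariate).
#' @param groups For a group contrast, the two levels compared, as
#'   `c(numerator, denominator)` (default injured vs sham).
#' @return A tibble: `gene`, `statistic`, `p_value`, `kind`
#'   (`"t"`/`"spearman_rho"`), `study_id`, `contrast`.
#' @export
gene_statistics <- function(study, contrast = "condition",
                            groups = c("injured", "sham")) {
  meta <- study$sample_meta
  x <- study$expr
  study_id <- if ("study_id" %in% names(meta)) {
    unique(meta$study_id)[1]
  } else NA_character_
  if (contrast == "condition") {
    i1 <- which(meta$condition == groups[1])
    i2 <- which(meta$condition == groups[2])
    if (length(i1) < 2 || length(i2) < 2) {
      abort("each contrast level needs at least 2 samples")
    }
    res <- t(apply(x, 1, function(r) pooled_t(r[i1], r[i2])))
    kind <- "t"
    desc <- paste(groups, collapse = "_vs_")
  } else {
    covariate <- meta[[contrast]]
    if (is.null(covariate) || !is.numeric(covariate)) {
      abort(sprintf("metadata column `%s` must exist and be numeric", contrast))
    }
    if (length(unique(covariate)) < 2) {
      abort(sprintf("`%s` is constant across samples", contrast))
    }
    res <- t(apply(x, 1, function(r) spearman_stat(r, covariate)))
    kind <- "spearman_rho"
    desc <- contrast
  }
  tibble::tibble(gene = rownames(x), statistic = unname(res[, 1]),
                 p_value = unname(res[, 2]), kind = kind,
                 study_id = study_id, contrast = desc)
}

pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  if (sp2 == 0) return(c(0, 1))
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  c(tt, 2 * pt(-abs(tt), df = n1 + n2 - 2))
}

spearman_stat <- function(x, y) {
  if (max(x) == min(x)) return(c(0, 1))
  rho <- cor(x, y, method = "spearman")
  n <- length(x)
  if (abs(rho) >= 1) return(c(rho, 0))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  c(rho, 2 * pt(-abs(tt), df = n - 2))
}

#' Mean-rank gene-set enrichment test
#'
#' Wilcoxon rank-sum comparison of the per-gene statistics of set genes
#' against all other genes. `alternative = "up"` tests whether set genes tend
#' to have larger statistics. Exact enumeration is used when both groups have
#' at most 10 members and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param stats A tibble from [gene_statistics()] (columns `gene`,
#'   `statistic`), or a named numeric vector of statistics.
#' @param gene_set Character vector of set gene ids.
#' @param alternative `"up"` or `"down"`.
#' @return One-sided p-value.
#' @export
mean_rank_set_test <- function(stats, gene_set,
                               alternative = c("up", "down")) {
  alternative <- match.arg(alternative)
  values <- if (is.data.frame(stats)) {
    setNames(stats$statistic, stats$gene)
  } else stats
  in_set <- names(values) %in% gene_set
  if (sum(in_set) < 1 || sum(in_set) == length(values)) {
    abort("gene set must overlap the universe and leave a complement")
  }
  v <- if (alternative == "up") values else -values
  r <- rank(v)
  n1 <- sum(in_set); n2 <- length(v) - n1
  w <- sum(r[in_set]) - n1 * (n1 + 1) / 2  # Mann-Whitney U
  ties <- any(duplicated(v))
  if (!ties && n1 <= 10 && n2 <= 10) {
    return(pwilcox(w - 1, n1, n2, lower.tail = FALSE))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(v)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - mu - 0.5) / sqrt(sigma2)
  pnorm(z, lower.tail = FALSE)
}

#' Module-level differential expression across studies
#'
#' For each study, ranks genes by their injured-vs-sham statistic and runs
#' [mean_rank_set_test()] for up- and downregulation of every module, with
#' Bonferroni correction over modules x 2 directions within the study. A
#' direction is called at adjusted p < `alpha`.
#'
#' @param studies A list of [expression_study()] objects.
#' @param partition A `module_partition` (reference labels), or a named
#'   integer label vector.
#' @param alpha Significance level on the Bonferroni-adjusted p (default
#'   0.05).
#' @param groups Contrast levels passed to [gene_statistics()].
#' @return A tibble with one row per study x module: `p_up`, `p_down`,
#'   adjusted values, and `direction` (`"up"`, `"down"` or `"none"`).
#' @export
module_de <- function(studies, partition, alpha = 0.05,
                      groups = c("injured", "sham")) {
  labels <- partition_labels(partition)
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods) == 0) abort("no modules in the partition")
  purrr::map_dfr(studies, function(study) {
    stats <- gene_statistics(study, "condition", groups = groups)
    values <- setNames(stats$statistic, stats$gene)
    m_tests <- 2 * length(mods)
    purrr::map_dfr(mods, function(m) {
      genes <- names(labels)[labels == m]
      p_up <- mean_rank_set_test(values, genes, "up")
      p_down <- mean_rank_set_test(values, genes, "down")
      tibble::tibble(study_id = stats$study_id[1], module = m,
                     p_up = p_up, p_down = p_down,
                     p_up_adj = min(1, p_up * m_tests),
                     p_down_adj = min(1, p_down * m_tests),
                     n_tests = m_tests)
    })
  }) |>
    dplyr::mutate(direction = dplyr::case_when(
      .data$p_up_adj < alpha & .data$p_up_adj <= .data$p_down_adj ~ "up",
      .data$p_down_adj < alpha ~ "down",
      TRUE ~ "none"))
}

partition_labels <- function(partition) {
  if (inherits(partition, "module_partition")) partition$labels else partition
}

#' Consensus module calls across studies
#'
#' `consensus_up`/`consensus_down`: significant in the same direction in all
#' studies; `majority_up`/`majority_down`: in all but one; otherwise `none`.
#'
#' @param de A tibble from [module_de()] (columns `study_id`, `module`,
#'   `direction`).
#' @return A tibble: `module`, `n_studies`, `n_up`, `n_down`, `consensus`.
#' @export
consensus_calls <- function(de) {
  n_studies <- length(unique(de$study_id))
  if (n_studies < 2) abort("consensus requires at least 2 studies")
  de |>
    dplyr::group_by(.data$module) |>
    dplyr::summarise(n_studies = dplyr::n(),
                     n_up = sum(.data$direction == "up"),
                     n_down = sum(.data$direction == "down"),
                     .groups = "drop") |>
    dplyr::mutate(consensus = dplyr::case_when(
      .data$n_up == .data$n_studies ~ "consensus_up",
      .data$n_down == .data$n_studies ~ "consensus_down",
      .data$n_up == .data$n_studies - 1 ~ "majority_up",
      .data$n_down == .data$n_studies - 1 ~ "majority_down",
      TRUE ~ "none"))
}

#' Module differential expression stratified by timepoint
#'
#' Runs [module_de()] within each post-injury timepoint (sham samples at the
#' same timepoint form the control group) and flags modules whose consensus
#' direction flips between the earliest and the latest timepoint.
#'
#' @inheritParams module_de
#' @param timepoints Timepoints (days) to analyse; default all observed.
#' @return A list with `by_timepoint` (tibble of per-timepoint module DE with
#'   consensus), and `flips` (tibble: module, direction_earliest,
#'   direction_latest, flipped).
#' @export
temporal_profiles <- function(studies, partition, timepoints = NULL,
                              alpha = 0.05) {
  has_tp <- vapply(studies, function(s)
    "timepoint_days" %in% names(s$sample_meta) &&
      !all(is.na(s$sample_meta$timepoint_days)), logical(1))
  if (!all(has_tp)) abort("all studies need `timepoint_days` metadata")
  observed <- sort(unique(unlist(lapply(studies, function(s)
    s$sample_meta$timepoint_days))))
  timepoints <- timepoints %||% observed

  by_tp <- purrr::map_dfr(timepoints, function(tp) {
    subs <- purrr::compact(lapply(studies, function(s) {
      keep <- s$sample_meta$timepoint_days == tp
      if (sum(keep & s$sample_meta$condition == "injured") < 2 ||
          sum(keep & s$sample_meta$condition == "sham") < 2) {
        message(sprintf("study %s: timepoint %s stratum too small; skipped",
                        s$sample_meta$study_id[1], format(tp)))
        return(NULL)
      }
      expression_study(s$expr[, keep, drop = FALSE],
                       s$sample_meta[keep, , drop = FALSE])
    }))
    if (length(subs) < 2) return(NULL)
    de <- module_de(subs, partition, alpha = alpha)
    cons <- consensus_calls(de)
    dplyr::mutate(dplyr::left_join(de, cons[, c("module", "consensus")],
                                   by = "module"),
                  timepoint_days = tp)
  })
  direction_of <- function(label) {
    dplyr::case_when(label %in% c("consensus_up", "majority_up") ~ "up",
                     label %in% c("consensus_down", "majority_down") ~ "down",
                     TRUE ~ "none")
  }
  tps <- sort(unique(by_tp$timepoint_days))
  flips <- by_tp |>
    dplyr::filter(.data$timepoint_days %in% c(tps[1], tps[length(tps)])) |>
    dplyr::distinct(.data$module, .data$timepoint_days, .data$consensus) |>
    dplyr::mutate(when = ifelse(.data$timepoint_days == tps[1],
                                "earliest", "latest")) |>
    dplyr::select("module", "when", "consensus") |>
    tidyr::pivot_wider(names_from = "when", values_from = "consensus") |>
    dplyr::mutate(direction_earliest = direction_of(.data$earliest),
                  direction_latest = direction_of(.data$latest),
                  flipped = .data$direction_earliest != "none" &
                    .data$direction_latest != "none" &
                    .data$direction_earliest != .data$direction_latest) |>
    dplyr::select("module", "direction_earliest", "direction_latest",
                  "flipped")
  list(by_timepoint = by_tp, flips = flips)
}

#' Severity-dependent expression scores
#'
#' Per gene, the Spearman correlation of expression with injury severity and
#' the score `s = rho * (-log10 p)`; per module, mean-rank enrichment of the
#' scores for severity-correlated (`up`) and anti-correlated (`down`) genes
#' with Bonferroni correction over modules x 2, and the Spearman correlation
#' of the module eigengene (computed in this study under the reference
#' labels) with severity.
#'
#' @param study An [expression_study()] with a numeric `severity` metadata
#'   column taking >= 3 distinct levels or >= 8 samples.
#' @param partition A `module_partition` or named label vector.
#' @return An object of class `severity_result`: a list of tibbles
#'   `gene_scores` (gene, rho, p_value, score), `module_enrichment` (module,
#'   p_correlated, p_anticorrelated, adjusted values), and
#'   `eigengene_severity` (module, rho, p_value).
#' @export
severity_scores <- function(study, partition) {
  sev <- study$sample_meta$severity
  if (is.null(sev) || length(unique(sev)) < 2) {
    abort("severity metadata is missing or constant")
  }
  if (length(unique(sev)) < 3 && length(sev) < 8) {
    abort("need >= 3 severity levels or >= 8 samples")
  }
  labels <- partition_labels(partition)
  labels <- labels[intersect(names(labels), rownames(study$expr))]

  per_gene <- t(apply(study$expr, 1, spearman_stat, y = sev))
  gene_scores <- tibble::tibble(
    gene = rownames(study$expr),
    rho = unname(per_gene[, 1]), p_value = unname(per_gene[, 2]),
    score = unname(per_gene[, 1] * (-log10(pmax(per_gene[, 2], 1e-300)))))
  scores <- setNames(gene_scores$score, gene_scores$gene)

  mods <- sort(unique(labels[labels > 0]))
  m_tests <- 2 * length(mods)
  module_enrichment <- purrr::map_dfr(mods, function(m) {
    genes <- names(labels)[labels == m]
    p_cor <- mean_rank_set_test(scores, genes, "up")
    p_anti <- mean_rank_set_test(scores, genes, "down")
    tibble::tibble(module = m, p_correlated = p_cor,
                   p_anticorrelated = p_anti,
                   p_correlated_adj = min(1, p_cor * m_tests),
                   p_anticorrelated_adj = min(1, p_anti * m_tests),
                   n_tests = m_tests)
  })

  me <- module_eigengenes(study, labels)$eigengenes
  eigengene_severity <- purrr::map_dfr(seq_len(nrow(me)), function(i) {
    ct <- suppressWarnings(cor.test(me[i, ], sev, method = "spearman"))
    tibble::tibble(module = mods[i], rho = unname(ct$estimate),
                   p_value = ct$p.value)
  })
  structure(list(gene_scores = gene_scores,
                 module_enrichment = module_enrichment,
                 eigengene_severity = eigengene_severity),
            class = "severity_result")
}

#' @export
print.severity_result <- function(x, ...) {
  cat("<severity_result>\n")
  print(dplyr::left_join(x$module_enrichment[, c("module", "p_correlated_adj",
                                                 "p_anticorrelated_adj")],
                         x$eigengene_severity, by = "module"))
  invisible(x)
}

#' Curated-set enrichment of modules
#'
#' One-sided (greater) Fisher's exact test on the 2x2 table of module
#' membership against curated-set membership, per module, with Bonferroni
#' correction over modules.
#'
#' @param partition A `module_partition` or named label vector.
#' @param curated Character vector of curated gene ids, or a
#'   `curated_gene_set`.
#' @param universe Character vector of universe gene ids (default: all
#'   labelled genes).
#' @return A tibble: module, counts of the 2x2 table, `p_value`, `p_adj`.
#' @export
curated_enrichment <- function(partition, curated, universe = NULL) {
  labels <- partition_labels(partition)
  if (inherits(curated, "curated_gene_set")) curated <- curated$genes
  universe <- universe %||% names(labels)
  labels <- labels[intersect(names(labels), universe)]
  curated <- intersect(curated, universe)
  if (length(curated) == 0) abort("curated set has no overlap with universe")
  mods <- sort(unique(labels[labels > 0]))
  res <- purrr::map_dfr(mods, function(m) {
    in_mod <- names(labels)[labels == m]
    if (length(in_mod) == 0) return(NULL)
    a <- length(intersect(in_mod, curated))
    b <- length(in_mod) - a
    c_ <- length(curated) - a
    d <- length(universe) - a - b - c_
    p <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                     alternative = "greater")$p.value
    tibble::tibble(module = m, n_module = length(in_mod),
                   n_overlap = a, n_curated = length(curated),
                   n_universe = length(universe), p_value = p)
  })
  res$p_adj <- pmin(1, res$p_value * nrow(res))
  res
}

#' Robustness of curated-set enrichment to seed removal and noise addition
#'
#' For each perturbation fraction, repeatedly removes that fraction of the
#' curated set (or adds that fraction of random universe genes) and
#' recomputes the Bonferroni-corrected Fisher enrichment. The breakdown
#' fraction per module is the largest fraction at which the median adjusted
#' p stays below `alpha`.
#'
#' @inheritParams curated_enrichment
#' @param removal_grid,addition_grid Perturbation fractions in `[0, 1]`.
#' @param n_boot Bootstraps per fraction (default 100).
#' @param rng_seed Integer seed.
#' @param alpha Significance level (default 0.05).
#' @return A list with `curves` (tibble: mode, fraction, module, median
#'   adjusted p) and `breakdown` (tibble: module, mode,
#'   breakdown_fraction).
#' @export
enrichment_robustness <- function(partition, curated, universe = NULL,
                                  removal_grid = seq(0, 0.9, by = 0.1),
                                  addition_grid = seq(0, 1, by = 0.25),
                                  n_boot = 100, rng_seed = NULL,
                                  alpha = 0.05) {
  if (any(c(removal_grid, addition_grid) < 0) ||
      any(removal_grid > 1)) {
    abort("perturbation grids must lie in [0, 1] (additions may exceed 1)")
  }
  labels <- partition_labels(partition)
  if (inherits(curated, "curated_gene_set")) curated <- curated$genes
  universe <- universe %||% names(labels)
  curated <- intersect(curated, universe)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- length(curated)

  one_mode <- function(mode, grid) {
    purrr::map_dfr(grid, function(f) {
      k <- floor(f * n)
      ps <- purrr::map_dfr(seq_len(n_boot), function(b) {
        set <- if (mode == "removal") {
          if (k >= n) return(NULL)
          setdiff(curated, sample(curated, k))
        } else {
          unique(c(curated, sample(setdiff(universe, curated), k)))
        }
        if (length(set) == 0) return(NULL)
        dplyr::mutate(curated_enrichment(labels, set, universe),
                      bootstrap = b)
      })
      if (nrow(ps) == 0) {
        return(tibble::tibble(mode = mode, fraction = f,
                              module = sort(unique(labels[labels > 0])),
                              median_p_adj = NA_real_))
      }
      ps |>
        dplyr::group_by(.data$module) |>
        dplyr::summarise(median_p_adj = median(.data$p_adj),
                         .groups = "drop") |>
        dplyr::mutate(mode = mode, fraction = f)
    })
  }
  curves <- dplyr::bind_rows(one_mode("removal", removal_grid),
                             one_mode("addition", addition_grid))
  breakdown <- curves |>
    dplyr::group_by(.data$module, .data$mode) |>
    dplyr::summarise(breakdown_fraction = {
      sig <- .data$fraction[!is.na(.data$median_p_adj) &
                              .data$median_p_adj < alpha]
      if (length(sig)) max(sig) else NA_real_
    }, .groups = "drop")
  list(curves = curves, breakdown = breakdown)
}

#' Reversal of the consensus injury signature under treatment
#'
#' Tests whether consensus modules move in the opposite direction in a
#' treatment contrast: per consensus module, a one-sided
#' [mean_rank_set_test()] with the alternative fixed by the reversal
#' hypothesis (a consensus-up module is tested for downregulation under
#' treatment, and vice versa), plus a one-tailed Wilcoxon rank-sum test on
#' the module eigengene sample scores between the two groups.
#'
#' @param treated_study,control_study [expression_study()] objects sharing a
#'   gene universe, or a single combined study with a `condition` column
#'   (pass it as `treated_study` and leave `control_study` `NULL`, with
#'   `groups` naming the treated and control levels).
#' @param partition A `module_partition` or named label vector.
#' @param consensus A tibble from [consensus_calls()].
#' @param groups Condition levels as `c(treated, control)`.
#' @param alpha Significance level on the Bonferroni-adjusted reversal p.
#' @return A tibble with one row per consensus module: consensus label,
#'   reversal alternative, `p_reversal` (+ adjusted), eigengene Wilcoxon p,
#'   and `reversed`; plus an attribute `n_reversed`.
#' @export
reversal_test <- function(treated_study, control_study = NULL, partition,
                          consensus, groups = c("treated", "control"),
                          alpha = 0.05) {
  if (!is.null(control_study)) {
    shared <- intersect(rownames(treated_study$expr),
                        rownames(control_study$expr))
    expr <- cbind(treated_study$expr[shared, , drop = FALSE],
                  control_study$expr[shared, , drop = FALSE])
    colnames(expr) <- make.unique(colnames(expr))
    meta <- tibble::tibble(
      sample_id = colnames(expr),
      study_id = "reversal",
      condition = rep(groups, c(ncol(treated_study$expr),
                                ncol(control_study$expr))))
    combined <- expression_study(expr, meta)
  } else {
    combined <- treated_study
  }
  if (!all(groups %in% combined$sample_meta$condition)) {
    abort("treatment/control group labels missing from metadata")
  }
  labels <- partition_labels(partition)
  labels <- labels[intersect(names(labels), rownames(combined$expr))]
  cons <- dplyr::filter(consensus, grepl("^consensus", .data$consensus))
  if (nrow(cons) == 0) abort("no consensus modules to test")

  stats <- gene_statistics(combined, "condition", groups = groups)
  values <- setNames(stats$statistic, stats$gene)
  me <- module_eigengenes(combined, labels)$eigengenes
  treated_idx <- combined$sample_meta$condition == groups[1]
  control_idx <- combined$sample_meta$condition == groups[2]

  m_tests <- nrow(cons)
  res <- purrr::map_dfr(seq_len(nrow(cons)), function(i) {
    m <- cons$module[i]
    injured_dir <- if (cons$consensus[i] == "consensus_up") "up" else "down"
    reversal_alt <- if (injured_dir == "up") "down" else "up"
    genes <- names(labels)[labels == m]
    p_rev <- mean_rank_set_test(values, genes, reversal_alt)
    eg <- me[paste0("ME", m), ]
    wt <- wilcox.test(eg[treated_idx], eg[control_idx],
                      alternative = if (reversal_alt == "down") "less"
                      else "greater")
    tibble::tibble(module = m, consensus = cons$consensus[i],
                   reversal_alternative = reversal_alt,
                   p_reversal = p_rev,
                   p_reversal_adj = min(1, p_rev * m_tests),
                   p_eigengene_wilcoxon = wt$p.value)
  })
  res$reversed <- res$p_reversal_adj < alpha
  attr(res, "n_reversed") <- sum(res$reversed)
  res
}
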