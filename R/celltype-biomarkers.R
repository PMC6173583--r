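#' Cell-type specificity index
#'
#' A rank-mean specificity index: for gene g and cell type c, the average
#' over all other cell types c' of the rank of `log2((e_gc + eps) /
#' (e_gc' + eps))` among all genes (rank 1 = most enriched in c relative to
#' c'). Low SI marks genes specifically expressed in c. The permutation
#' p-value shuffles gene labels independently within each pairwise
#' comparison and is the add-one lower tail of the observed SI.
#'
#' @param profiles Genes x cell-types matrix of non-negative mean
#'   expression, or a list with element `celltype_profiles` (as produced by
#'   [generate_annotations()]).
#' @param n_perm Permutations for the p-value (default 1000).
#' @param eps Pseudocount in the fold ratio (default 1).
#' @param rng_seed Integer seed.
#' @return A tibble: `gene`, `cell_type`, `si` (scaled to \[0, 1\] by the
#'   number of genes), `p_si`.
#' @export
specificity_index <- function(profiles, n_perm = 1000, eps = 1,
                              rng_seed = NULL) {
  if (is.list(profiles) && !is.null(profiles$celltype_profiles)) {
    profiles <- profiles$celltype_profiles
  }
  if (ncol(profiles) < 2) abort("need at least 2 cell types")
  n_genes <- nrow(profiles)
  types <- colnames(profiles)
  if (!is.null(rng_seed)) set.seed(rng_seed)

  si <- matrix(NA_real_, n_genes, length(types),
               dimnames = list(rownames(profiles), types))
  null_si <- array(0, c(n_perm, n_genes, length(types)))
  for (ci in seq_along(types)) {
    others <- setdiff(seq_along(types), ci)
    rank_sum <- numeric(n_genes)
    null_sum <- matrix(0, n_perm, n_genes)
    for (cj in others) {
      fold <- log2((profiles[, ci] + eps) / (profiles[, cj] + eps))
      r <- rank(-fold, ties.method = "average")
      rank_sum <- rank_sum + r
      if (n_perm > 0) {
        for (p in seq_len(n_perm)) {
          null_sum[p, ] <- null_sum[p, ] + sample(r)
        }
      }
    }
    si[, ci] <- rank_sum / length(others)
    if (n_perm > 0) null_si[, , ci] <- null_sum / length(others)
  }

  p_si <- if (n_perm > 0) {
    as.numeric(vapply(seq_along(types), function(ci) {
      vapply(seq_len(n_genes), function(g) {
        (1 + sum(null_si[, g, ci] <= si[g, ci])) / (1 + n_perm)
      }, numeric(1))
    }, numeric(n_genes)))
  } else NA_real_
  tibble::tibble(gene = rep(rownames(profiles), length(types)),
                 cell_type = rep(types, each = n_genes),
                 si = as.numeric(si) / n_genes,
                 p_si = p_si)
}

#' Cell-type enrichment of modules
#'
#' Fisher's exact test (one-sided, greater) of module membership against
#' cell-type-specific genes (`p_si < threshold`), per module x cell type x
#' threshold, with Bonferroni correction over modules x cell types within
#' each threshold.
#'
#' @param partition A `module_partition` or named label vector.
#' @param psi A tibble from [specificity_index()].
#' @param thresholds Specificity p-value cutoffs.
#' @return A tibble: module, cell_type, threshold, marker/overlap counts,
#'   `p_value`, `p_adj`.
#' @export
celltype_module_enrichment <- function(partition, psi,
                                       thresholds = c(0.05, 0.01, 0.001,
                                                      0.0001)) {
  labels <- partition_labels(partition)
  universe <- intersect(names(labels), unique(psi$gene))
  labels <- labels[universe]
  mods <- sort(unique(labels[labels > 0]))
  types <- unique(psi$cell_type)
  purrr::map_dfr(thresholds, function(th) {
    m_tests <- length(mods) * length(types)
    res <- purrr::map_dfr(types, function(ct) {
      markers <- psi$gene[psi$cell_type == ct & psi$p_si < th]
      markers <- intersect(markers, universe)
      if (length(markers) == 0) {
        message(sprintf("no markers for %s at threshold %g; skipped", ct, th))
        return(NULL)
      }
      purrr::map_dfr(mods, function(m) {
        in_mod <- names(labels)[labels == m]
        a <- length(intersect(in_mod, markers))
        b <- length(in_mod) - a
        c_ <- length(markers) - a
        d <- length(universe) - a - b - c_
        p <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                         alternative = "greater")$p.value
        tibble::tibble(module = m, cell_type = ct, threshold = th,
                       n_markers = length(markers), n_overlap = a,
                       p_value = p)
      })
    })
    if (nrow(res) == 0) return(NULL)
    res$p_adj <- pmin(1, res$p_value * m_tests)
    res
  })
}

#' Select module hub genes by kME
#'
#' The most connected genes of a module: the `ceiling(top_frac * size)`
#' members with the highest correlation to the module eigengene in the
#' reference data, deterministic tie-break by gene id.
#'
#' @param partition A `module_partition` with kME computed.
#' @param module Module number.
#' @param top_frac Fraction of members selected (default 0.10).
#' @return Character vector of hub gene ids.
#' @export
select_hubs <- function(partition, module, top_frac = 0.10) {
  if (!inherits(partition, "module_partition") || is.null(partition$kme)) {
    abort("`partition` must be a module_partition with kME")
  }
  members <- names(partition$labels)[partition$labels == module]
  if (length(members) == 0) abort(sprintf("module %s has no members",
                                          format(module)))
  if (length(members) < 10) {
    warn("module smaller than 10 genes: returning its single top hub")
    n_hub <- 1L
  } else {
    n_hub <- as.integer(ceiling(top_frac * length(members)))
  }
  k <- partition$kme[members, paste0("ME", module)]
  ord <- order(-k, members)
  members[ord][seq_len(n_hub)]
}

#' Linear discriminant analysis with leave-one-out cross-validation
#'
#' Two-class LDA with pooled covariance and equal priors, trained on all but
#' one sample and predicting the held-out sample, for every sample. A
#' singular pooled covariance is ridge-regularised by `1e-6 * trace` with a
#' warning.
#'
#' @param study An [expression_study()] (samples taken from columns), or a
#'   samples x features numeric matrix.
#' @param features Feature (gene) ids; ignored when a plain matrix is given.
#' @param class_labels Vector of two class labels, one per sample; samples
#'   with `NA` labels are dropped.
#' @return An object of class `classifier_result`: a list with `accuracy`,
#'   `predictions` (tibble: sample, truth, predicted), `classes`,
#'   `features`.
#' @export
lda_loocv <- function(study, features = NULL, class_labels) {
  x <- if (inherits(study, "expression_study")) {
    t(study$expr[features, , drop = FALSE])
  } else {
    as.matrix(study)
  }
  keep <- !is.na(class_labels)
  x <- x[keep, , drop = FALSE]
  cls <- as.character(class_labels[keep])
  classes <- sort(unique(cls))
  if (length(classes) != 2) abort("exactly 2 classes are required")
  if (any(table(cls) < 2)) abort("each class needs at least 2 samples")

  preds <- vapply(seq_len(nrow(x)), function(i) {
    lda_predict(x[-i, , drop = FALSE], cls[-i], x[i, ], classes)
  }, "")
  acc <- mean(preds == cls)
  structure(list(
    accuracy = acc,
    predictions = tibble::tibble(
      sample = rownames(x) %||% as.character(seq_len(nrow(x))),
      truth = cls, predicted = preds),
    classes = classes,
    features = features %||% colnames(x)
  ), class = "classifier_result")
}

# Pooled-covariance, equal-prior two-class linear discriminant.
lda_predict <- function(train, cls, newdata, classes) {
  x1 <- train[cls == classes[1], , drop = FALSE]
  x2 <- train[cls == classes[2], , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  n1 <- nrow(x1); n2 <- nrow(x2)
  s <- (crossprod(sweep(x1, 2, m1)) + crossprod(sweep(x2, 2, m2))) /
    (n1 + n2 - 2)
  w <- tryCatch(solve(s, m1 - m2), error = function(e) NULL)
  if (is.null(w) || rcond_low(s)) {
    lambda <- 1e-6 * sum(diag(s))
    if (lambda <= 0) lambda <- 1e-8
    warn("singular pooled covariance: ridge-regularised")
    w <- solve(s + lambda * diag(ncol(s)), m1 - m2)
  }
  score <- sum(w * (newdata - (m1 + m2) / 2))
  if (score > 0) classes[1] else classes[2]
}

rcond_low <- function(s) {
  rc <- tryCatch(rcond(s), error = function(e) 0)
  rc < 1e-12
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf("<classifier_result> LOOCV accuracy %.3f (%s vs %s, %d feature(s))\n",
              x$accuracy, x$classes[1], x$classes[2], length(x$features)))
  invisible(x)
}

#' Association between hubness and biomarker accuracy
#'
#' Spearman correlation between reference kME (hubness) and per-gene LOOCV
#' classification accuracy.
#'
#' @param kme_ref Named numeric vector of reference kME values.
#' @param accuracies Named numeric vector of per-gene LOOCV accuracies.
#' @return A tibble: `rho`, `p_value`, `n_genes` (`rho` is `NA` when either
#'   vector is constant).
#' @export
hubness_accuracy_correlation <- function(kme_ref, accuracies) {
  shared <- intersect(names(kme_ref), names(accuracies))
  if (length(shared) < 10) abort("need >= 10 genes with both values")
  a <- kme_ref[shared]; b <- accuracies[shared]
  if (max(b) == min(b) || max(a) == min(a)) {
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_,
                          n_genes = length(shared)))
  }
  ct <- suppressWarnings(cor.test(a, b, method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n_genes = length(shared))
}

#' Per-gene biomarker accuracy for a set of genes
#'
#' Runs single-feature [lda_loocv()] for each gene.
#'
#' @param study An [expression_study()].
#' @param genes Gene ids.
#' @param class_labels Two-class label vector (NA samples dropped).
#' @return A tibble: `gene`, `accuracy`.
#' @export
per_gene_accuracy <- function(study, genes, class_labels) {
  genes <- intersect(genes, rownames(study$expr))
  purrr::map_dfr(genes, function(g) {
    tibble::tibble(gene = g,
                   accuracy = lda_loocv(study, g, class_labels)$accuracy)
  })
}
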