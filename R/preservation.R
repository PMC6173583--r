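#' Align two studies on their shared gene universe
#'
#' @param ref_study,test_study [expression_study()] objects.
#' @param min_shared Minimum number of shared genes (default 30).
#' @return A list with both studies restricted to the shared genes, in a
#'   consistent (sorted) order, and `genes`, the shared ids.
#' @export
match_universe <- function(ref_study, test_study, min_shared = 30) {
  shared <- sort(intersect(rownames(ref_study$expr),
                           rownames(test_study$expr)))
  if (length(shared) < min_shared) {
    abort(sprintf("only %d shared genes (need >= %d)", length(shared),
                  min_shared))
  }
  list(ref = expression_study(ref_study$expr[shared, , drop = FALSE],
                              ref_study$sample_meta),
       test = expression_study(test_study$expr[shared, , drop = FALSE],
                               test_study$sample_meta),
       genes = shared)
}

# Correlation/adjacency pair for one dataset, used repeatedly by the
# preservation statistics.
preservation_context <- function(study, method, beta) {
  cm <- switch(method,
               bicor = unclass(bicor(study)),
               spearman = unclass(cor_matrix(study, "spearman")),
               abort("`method` must be 'bicor' or 'spearman'"))
  list(cor = cm, adj = adjacency_signed(cm, beta), study = study)
}

# Seven observed statistics for one gene set (module), given precomputed
# reference and test contexts. Density class: mean_cor, mean_adj,
# prop_var_explained, mean_kme (test data); connectivity class: cor_kim,
# cor_kme, cor_cor (reference vs test agreement over member genes).
module_preservation_stats <- function(genes, ref_ctx, test_ctx) {
  lt <- function(m) m[lower.tri(m)]
  rc <- ref_ctx$cor[genes, genes, drop = FALSE]
  tc <- test_ctx$cor[genes, genes, drop = FALSE]
  ra <- ref_ctx$adj[genes, genes, drop = FALSE]
  ta <- test_ctx$adj[genes, genes, drop = FALSE]

  me_test <- module_eigengenes(test_ctx$study,
                               setNames(rep(1L, length(genes)), genes))
  kme_test_own <- as.numeric(
    kme(expression_study(test_ctx$study$expr[genes, , drop = FALSE],
                         test_ctx$study$sample_meta),
        me_test$eigengenes))
  me_ref <- module_eigengenes(ref_ctx$study,
                              setNames(rep(1L, length(genes)), genes))
  kme_ref_own <- as.numeric(
    kme(expression_study(ref_ctx$study$expr[genes, , drop = FALSE],
                         ref_ctx$study$sample_meta),
        me_ref$eigengenes))

  kim <- function(a) rowSums(a) - 1  # intramodular connectivity
  c(mean_cor = mean(lt(tc)),
    mean_adj = mean(lt(ta)),
    prop_var_explained = unname(me_test$prop_var_explained[1]),
    mean_kme = mean(kme_test_own),
    cor_kim = cor(kim(ra), kim(ta)),
    cor_kme = cor(kme_ref_own, kme_test_own),
    cor_cor = cor(lt(rc), lt(tc)))
}

#' Observed module preservation statistics
#'
#' Evaluates, in the test data under the reference module labels, the
#' density statistics (mean intra-module correlation, mean signed adjacency,
#' proportion of variance explained by the module eigengene, mean kME) and
#' the connectivity statistics (correlation of intramodular connectivity,
#' kME, and vectorized intra-module correlation between reference and test).
#'
#' @param ref_labels Named integer module labels from the reference network.
#' @param ref_study,test_study [expression_study()] objects (aligned with
#'   [match_universe()] internally).
#' @param method Correlation method: `"bicor"` (transcriptomic) or
#'   `"spearman"` (proteomic).
#' @param beta Soft power for the signed adjacency (the reference network's
#'   fit; default 5).
#' @return A tibble with one row per module and the seven statistics.
#' @export
preservation_statistics <- function(ref_labels, ref_study, test_study,
                                    method = c("bicor", "spearman"),
                                    beta = 5) {
  method <- match.arg(method)
  uni <- match_universe(ref_study, test_study)
  ref_ctx <- preservation_context(uni$ref, method, beta)
  test_ctx <- preservation_context(uni$test, method, beta)
  mods <- sort(unique(ref_labels[ref_labels > 0]))
  purrr::map_dfr(mods, function(m) {
    genes <- intersect(names(ref_labels)[ref_labels == m], uni$genes)
    if (length(genes) < 3) {
      message(sprintf("module %d has < 3 genes in the shared universe; skipped", m))
      return(NULL)
    }
    stats <- module_preservation_stats(genes, ref_ctx, test_ctx)
    dplyr::bind_cols(tibble::tibble(module = m, n_genes = length(genes)),
                     tibble::as_tibble(as.list(stats)))
  })
}

#' Permutation Zsummary module preservation
#'
#' The permutation null reassigns module labels uniformly at random over the
#' shared gene universe, preserving module sizes; each statistic's Z score is
#' `(observed - mean_perm) / sd_perm`. `Zdensity` is the median Z over the
#' four density statistics, `Zconnectivity` the median over the three
#' connectivity statistics, and `Zsummary` their mean. Conventional bands:
#' above 10 strong, 5-10 moderate, below 2 no evidence of preservation.
#'
#' @inheritParams preservation_statistics
#' @param n_perm Number of label permutations (default 100).
#' @param rng_seed Integer seed for the permutations.
#' @return An object of class `preservation_result`: a list with `summary`
#'   (tibble: module, n_genes, observed statistics, per-statistic Z,
#'   z_density, z_connectivity, z_summary), `n_perm`, and `method`.
#' @export
zsummary <- function(ref_labels, ref_study, test_study, n_perm = 100,
                     rng_seed = NULL, method = c("bicor", "spearman"),
                     beta = 5) {
  method <- match.arg(method)
  uni <- match_universe(ref_study, test_study)
  ref_ctx <- preservation_context(uni$ref, method, beta)
  test_ctx <- preservation_context(uni$test, method, beta)
  # canonical gene order so results are invariant to input ordering
  universe <- uni$genes
  mods <- sort(unique(ref_labels[ref_labels > 0]))
  member_sets <- lapply(mods, function(m) {
    intersect(names(ref_labels)[ref_labels == m], universe)
  })
  keep <- lengths(member_sets) >= 3
  mods <- mods[keep]; member_sets <- member_sets[keep]
  if (length(mods) == 0) abort("no module has >= 3 genes in the shared universe")

  observed <- t(vapply(member_sets, module_preservation_stats,
                       numeric(7), ref_ctx, test_ctx))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  perms <- array(NA_real_, c(n_perm, length(mods), 7))
  for (p in seq_len(n_perm)) {
    shuffled <- sample(universe)
    offset <- 0L
    for (i in seq_along(mods)) {
      size <- length(member_sets[[i]])
      genes <- shuffled[(offset + 1):(offset + size)]
      offset <- offset + size
      perms[p, i, ] <- module_preservation_stats(genes, ref_ctx, test_ctx)
    }
  }

  stat_names <- colnames(observed)
  density_stats <- c("mean_cor", "mean_adj", "prop_var_explained", "mean_kme")
  conn_stats <- c("cor_kim", "cor_kme", "cor_cor")
  rows <- purrr::map_dfr(seq_along(mods), function(i) {
    mu <- apply(perms[, i, , drop = FALSE], 3, mean)
    sdev <- apply(perms[, i, , drop = FALSE], 3, sd)
    z <- (observed[i, ] - mu) / sdev
    z[!is.finite(z)] <- NA  # sd_perm = 0: omitted from the medians
    names(z) <- stat_names
    zd <- median(z[density_stats], na.rm = TRUE)
    zc <- median(z[conn_stats], na.rm = TRUE)
    obs <- as.list(observed[i, ])
    names(obs) <- stat_names
    zl <- as.list(z)
    names(zl) <- paste0("z_", stat_names)
    dplyr::bind_cols(
      tibble::tibble(module = mods[i], n_genes = length(member_sets[[i]])),
      tibble::as_tibble(obs), tibble::as_tibble(zl),
      tibble::tibble(z_density = zd, z_connectivity = zc,
                     z_summary = (zd + zc) / 2))
  })
  structure(list(summary = rows, n_perm = n_perm, method = method),
            class = "preservation_result")
}

#' @export
print.preservation_result <- function(x, ...) {
  cat(sprintf("<preservation_result> %d module(s), %d permutations, %s correlation\n",
              nrow(x$summary), x$n_perm, x$method))
  print(x$summary[, c("module", "n_genes", "z_density", "z_connectivity",
                      "z_summary")])
  invisible(x)
}
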