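#' Biweight midcorrelation between gene expression profiles
#'
#' Robust correlation: each sample is weighted by `w = (1 - u^2)^2` for
#' `u = (x - med(x)) / (9 * MAD(x))` (weight zero when `|u| >= 1`), so values
#' far from the median contribute little. With `max_p_outliers`, the `u`
#' denominator is inflated on each side of the median where needed so that at
#' most that proportion of samples receives zero weight per side. Genes with
#' zero MAD fall back to Pearson weighting.
#'
#' @param study An [expression_study()] (or a genes x samples matrix) with at
#'   least 4 samples.
#' @param max_p_outliers Maximum proportion of samples treated as outliers on
#'   either side of the median (default 0.05).
#' @return A genes x genes correlation matrix of class `cor_matrix` with a
#'   `method` attribute `"bicor"`; symmetric, unit diagonal, values in
#'   `[-1, 1]`.
#' @export
bicor <- function(study, max_p_outliers = 0.05) {
  x <- if (inherits(study, "expression_study")) study$expr else study
  if (ncol(x) < 4) abort("bicor requires at least 4 samples")
  xt <- t(apply(x, 1, bicor_transform, max_p_outliers = max_p_outliers))
  r <- tcrossprod(xt)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- list(rownames(x), rownames(x))
  structure(r, method = "bicor", class = c("cor_matrix", class(r)))
}

# Median-centred, outlier-weighted, unit-norm row used in the bicor cross
# product; Pearson standardisation when MAD is zero.
bicor_transform <- function(x, max_p_outliers = 0.05) {
  med <- median(x)
  madx <- mad(x, constant = 1)
  if (madx == 0) {
    centred <- x - mean(x)
    nrm <- sqrt(sum(centred^2))
    if (nrm == 0) return(rep(0, length(x)))
    return(centred / nrm)
  }
  u <- (x - med) / (9 * madx)
  if (max_p_outliers < 0.5) {
    q <- quantile(u, c(max_p_outliers, 1 - max_p_outliers), names = FALSE)
    if (q[1] < -1) u[u < 0] <- u[u < 0] / abs(q[1])
    if (q[2] > 1) u[u > 0] <- u[u > 0] / q[2]
  }
  w <- (1 - u^2)^2 * (abs(u) < 1)
  centred <- (x - med) * w
  nrm <- sqrt(sum(centred^2))
  if (nrm == 0) return(rep(0, length(x)))
  centred / nrm
}

#' Correlation matrix with a method tag
#'
#' Pearson or Spearman correlation across samples, in the same container as
#' [bicor()].
#'
#' @inheritParams bicor
#' @param method `"pearson"` or `"spearman"`.
#' @return A `cor_matrix`.
#' @export
cor_matrix <- function(study, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- if (inherits(study, "expression_study")) study$expr else study
  r <- cor(t(x), method = method)
  r[is.na(r)] <- 0
  diag(r) <- 1
  structure(r, method = method, class = c("cor_matrix", class(r)))
}

#' Signed adjacency from a correlation matrix
#'
#' `a_ij = ((1 + cor_ij) / 2) ^ beta`, mapping correlation -1 to adjacency 0
#' and +1 to 1, so anti-correlated genes are far apart in the network.
#'
#' @param cor A correlation matrix.
#' @param beta Soft-thresholding power (>= 1).
#' @return An adjacency matrix in `[0, 1]` with unit diagonal.
#' @export
adjacency_signed <- function(cor, beta) {
  if (beta < 1) abort("`beta` must be >= 1")
  a <- ((1 + unclass(cor)) / 2)^beta
  diag(a) <- 1
  a
}

#' Soft-threshold selection by the scale-free topology criterion
#'
#' For each candidate power the signed adjacency is formed and the
#' connectivity distribution is regressed as `log10 p(k)` on `log10 k` over
#' equal-width connectivity bins (empty bins skipped). The fit index is the
#' regression R-squared, sign-adjusted so that a positive slope yields a
#' negative value; the chosen power is the minimum candidate whose fit
#' exceeds `r2_cut`. If none qualifies, the power with the maximum fit is
#' returned and flagged.
#'
#' @param cor A correlation matrix.
#' @param candidates Candidate powers (default 1..20).
#' @param r2_cut Scale-free fit threshold (default 0.8).
#' @param n_bins Number of connectivity bins (default 10).
#' @return A list of class `soft_threshold`: `fit` (tibble: beta,
#'   scale_free_r2, mean_connectivity), `beta` (chosen power), and
#'   `criterion_met` (logical).
#' @export
pick_soft_threshold <- function(cor, candidates = 1:20, r2_cut = 0.8,
                                n_bins = 10) {
  cm <- unclass(cor)
  if (max(cm[upper.tri(cm)]) == min(cm[upper.tri(cm)])) {
    abort("degenerate (constant) correlation matrix")
  }
  fit <- purrr::map_dfr(candidates, function(beta) {
    a <- adjacency_signed(cm, beta)
    k <- rowSums(a) - 1
    tibble::tibble(beta = beta,
                   scale_free_r2 = scale_free_fit(k, n_bins),
                   mean_connectivity = mean(k))
  })
  ok <- fit$beta[fit$scale_free_r2 > r2_cut]
  if (length(ok) > 0) {
    beta <- min(ok); met <- TRUE
  } else {
    beta <- fit$beta[which.max(fit$scale_free_r2)]; met <- FALSE
    warn(sprintf("no candidate power reached scale-free R^2 > %.2f; using beta = %d (max R^2)",
                 r2_cut, beta))
  }
  structure(list(fit = fit, beta = beta, criterion_met = met),
            class = "soft_threshold")
}

# Signed scale-free fit: R^2 of log10 p(k) ~ log10 k over equal-width bins,
# negated when the slope is positive.
scale_free_fit <- function(k, n_bins = 10) {
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- vapply(split(k, bin), function(v) mean(v), numeric(1))
  keep <- counts > 0 & !is.na(mids) & mids > 0
  if (sum(keep) < 3) return(0)
  xs <- log10(mids[keep])
  ys <- log10(counts[keep] / length(k))
  f <- stats::lm(ys ~ xs)
  r2 <- summary(f)$r.squared
  slope <- unname(stats::coef(f)[2])
  if (is.na(slope)) return(0)
  -sign(slope) * r2
}

#' @export
print.soft_threshold <- function(x, ...) {
  cat(sprintf("<soft_threshold> beta = %d (scale-free criterion %s)\n",
              x$beta, if (x$criterion_met) "met" else "NOT met"))
  invisible(x)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with the
#' sum over `u != i, j` and `k` the off-diagonal row sums; similarity
#' combines direct adjacency with shared neighbourhoods. `TOM_ii = 1`.
#'
#' @param adj A square adjacency matrix from [adjacency_signed()] (unit
#'   diagonal, values in `[0, 1]`).
#' @return The TOM matrix, symmetric with values in `[0, 1]`.
#' @export
tom_similarity <- function(adj) {
  if (nrow(adj) != ncol(adj)) abort("adjacency matrix must be square")
  a <- unclass(adj)
  k <- rowSums(a) - 1
  num <- a %*% a - 2 * a  # removes u = i and u = j terms (diag(a) = 1)
  num <- num + a
  kmin <- outer(k, k, pmin)
  tom <- num / (kmin + 1 - a)
  diag(tom) <- 1
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect coexpression modules by adaptive tree cut
#'
#' Genes are clustered by average-linkage hierarchical clustering of the TOM
#' dissimilarity `1 - TOM`. The dendrogram is cut just below its top joins
#' (at `cut_frac` of the maximum merge height) and each resulting branch is
#' accepted as a module only if it is cohesive: member genes must have mean
#' intra-branch TOM of at least `cohesion_z` standard deviations above the
#' overall mean TOM, non-cohesive leaves are pruned, and the branch must
#' retain at least `min_size` genes. Everything else gets label 0
#' (unassigned). Modules are numbered 1..K by decreasing size.
#'
#' @param tom A TOM similarity matrix.
#' @param min_size Minimum module size (default 20).
#' @param cut_frac Static cut height as a fraction of the maximum merge
#'   height (default 0.99).
#' @param cohesion_z Cohesion threshold in global TOM standard deviations
#'   (default 0.5).
#' @return A named integer vector of module labels (0 = unassigned).
#' @export
cluster_modules <- function(tom, min_size = 20, cut_frac = 0.99,
                            cohesion_z = 0.5) {
  genes <- rownames(tom) %||% sprintf("g%04d", seq_len(nrow(tom)))
  if (nrow(tom) < min_size) {
    warn("fewer genes than `min_size`; returning a single unassigned partition")
    return(setNames(rep(0L, nrow(tom)), genes))
  }
  hc <- hclust(as.dist(1 - tom), method = "average")
  raw <- cutree(hc, h = cut_frac * max(hc$height))
  off <- tom[upper.tri(tom)]
  threshold <- mean(off) + cohesion_z * sd(off)

  labels <- setNames(rep(0L, nrow(tom)), genes)
  accepted <- list()
  for (cl in unique(raw)) {
    members <- which(raw == cl)
    if (length(members) < min_size) next
    sub <- tom[members, members, drop = FALSE]
    repeat {
      cohesion <- (rowSums(sub) - 1) / (ncol(sub) - 1)
      drop <- which(cohesion < threshold)
      if (length(drop) == 0 || ncol(sub) - length(drop) < 2) break
      sub <- sub[-drop, -drop, drop = FALSE]
      members <- members[-drop]
      if (length(drop) == 0) break
    }
    if (length(members) < min_size) next
    if (mean(sub[upper.tri(sub)]) < threshold) next
    accepted[[length(accepted) + 1]] <- members
  }
  if (length(accepted) > 0) {
    accepted <- accepted[order(-lengths(accepted))]
    for (i in seq_along(accepted)) labels[accepted[[i]]] <- i
  }
  labels
}

#' Module eigengenes and explained variance
#'
#' The eigengene of a module is the first right singular vector (first
#' principal component over samples) of the standardized member-gene
#' submatrix, unit norm, with sign chosen so its mean correlation with member
#' genes is non-negative. The proportion of variance explained is the first
#' squared singular value over the total.
#'
#' @param study An [expression_study()].
#' @param labels Named integer module labels (0 ignored).
#' @return A list with `eigengenes` (modules x samples matrix, rows named
#'   `ME<m>`) and `prop_var_explained` (named numeric vector).
#' @export
module_eigengenes <- function(study, labels) {
  x <- study$expr
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods) == 0) abort("no modules in `labels`")
  eig <- matrix(NA_real_, length(mods), ncol(x),
                dimnames = list(paste0("ME", mods), colnames(x)))
  pve <- setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    genes <- names(labels)[labels == mods[i]]
    genes <- intersect(genes, rownames(x))
    if (length(genes) < 2) abort(sprintf("module %d has fewer than 2 genes",
                                         mods[i]))
    sub <- x[genes, , drop = FALSE]
    sub <- t(scale(t(sub)))
    sub[!is.finite(sub)] <- 0
    sv <- svd(sub, nu = 0, nv = 1)
    v <- sv$v[, 1]
    mean_cor <- mean(suppressWarnings(cor(v, t(sub))), na.rm = TRUE)
    if (is.finite(mean_cor) && mean_cor < 0) v <- -v
    eig[i, ] <- v
    pve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = eig, prop_var_explained = pve)
}

#' Module membership (kME)
#'
#' Correlation of each gene's expression with each module eigengene.
#'
#' @param study An [expression_study()].
#' @param eigengenes Modules x samples eigengene matrix.
#' @param method Correlation method (default Pearson; Spearman for proteomic
#'   data).
#' @return A genes x modules matrix of kME values in `[-1, 1]`; constant
#'   genes get 0 with a warning.
#' @export
kme <- function(study, eigengenes, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- study$expr
  const <- apply(x, 1, function(r) max(r) == min(r))
  if (any(const)) warn(sprintf("%d constant gene(s): kME set to 0",
                               sum(const)))
  k <- suppressWarnings(cor(t(x), t(eigengenes), method = method))
  k[is.na(k)] <- 0
  k
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the closest pair of modules whose eigengene
#' dissimilarity `1 - cor` is below `cut_height`, recomputing eigengenes
#' after every merge, until no pair qualifies. Modules are renumbered by
#' decreasing size.
#'
#' @param labels Named integer module labels.
#' @param study The [expression_study()] the labels refer to.
#' @param cut_height Eigengene dissimilarity threshold (default 0.2).
#' @return A named integer vector of merged labels.
#' @export
merge_close_modules <- function(labels, study, cut_height = 0.2) {
  repeat {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2) break
    me <- module_eigengenes(study, labels)$eigengenes
    cc <- cor(t(me))
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if ((1 - max(cc)) >= cut_height) break
    from <- mods[max(best)]; into <- mods[min(best)]
    labels[labels == from] <- into
  }
  relabel_by_size(labels)
}

relabel_by_size <- function(labels) {
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods) == 0) return(labels)
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
  new <- setNames(rank(-sizes, ties.method = "first"), mods)
  out <- labels
  out[labels > 0] <- as.integer(new[as.character(labels[labels > 0])])
  out
}

#' Eigengene meta-network
#'
#' Pairwise Spearman correlations among module eigengenes, with an
#' average-linkage dendrogram of `1 - rho`.
#'
#' @param eigengenes Modules x samples eigengene matrix (>= 2 modules).
#' @return A list with `cor` (Spearman correlation matrix) and `dendrogram`
#'   (an `hclust` object).
#' @export
eigengene_network <- function(eigengenes) {
  if (nrow(eigengenes) < 2) abort("need at least 2 modules")
  rho <- cor(t(eigengenes), method = "spearman")
  list(cor = rho, dendrogram = hclust(as.dist(1 - rho), method = "average"))
}

#' Full signed coexpression network analysis
#'
#' Runs the whole pipeline on a preprocessed expression study: biweight
#' midcorrelation, soft-threshold selection by the scale-free criterion,
#' signed adjacency, TOM, adaptive tree cut, eigengene-based module merging,
#' eigengenes and kME.
#'
#' @param study A preprocessed [expression_study()].
#' @param beta Soft power; `NULL` (default) selects it by
#'   [pick_soft_threshold()].
#' @param min_size Minimum module size (default 20).
#' @param cut_height Eigengene merge height (default 0.2).
#' @param method Correlation method: `"bicor"` (default), `"pearson"` or
#'   `"spearman"`.
#' @param r2_cut Scale-free fit threshold for automatic beta selection.
#' @return An object of class `module_partition`: a list with `labels`,
#'   `module_sizes`, `eigengenes` (modules x samples), `kme` (genes x
#'   modules), `prop_var_explained`, `beta`, `method`, `soft_threshold`.
#' @export
build_coexpression_network <- function(study, beta = NULL, min_size = 20,
                                       cut_height = 0.2,
                                       method = c("bicor", "pearson",
                                                  "spearman"),
                                       r2_cut = 0.8) {
  method <- match.arg(method)
  cm <- if (method == "bicor") bicor(study) else cor_matrix(study, method)
  st <- NULL
  if (is.null(beta)) {
    st <- pick_soft_threshold(cm, r2_cut = r2_cut)
    beta <- st$beta
  }
  adj <- adjacency_signed(cm, beta)
  tom <- tom_similarity(adj)
  labels <- cluster_modules(tom, min_size = min_size)
  if (any(labels > 0)) {
    labels <- merge_close_modules(labels, study, cut_height = cut_height)
  }
  module_partition(study, labels, beta = beta, method = method,
                   soft_threshold = st)
}

#' Construct a module partition from labels
#'
#' @param study The [expression_study()] the labels refer to.
#' @param labels Named integer labels (0 = unassigned).
#' @param beta Soft power used for the underlying network (recorded).
#' @param method Correlation method tag.
#' @param soft_threshold Optional [pick_soft_threshold()] result.
#' @return A `module_partition` object.
#' @export
module_partition <- function(study, labels, beta = NA, method = "bicor",
                             soft_threshold = NULL) {
  labels <- labels[rownames(study$expr)]
  mods <- sort(unique(labels[labels > 0]))
  eig <- NULL; pve <- NULL; km <- NULL
  if (length(mods) > 0) {
    me <- module_eigengenes(study, labels)
    eig <- me$eigengenes
    pve <- me$prop_var_explained
    km <- kme(study, eig,
              method = if (method == "spearman") "spearman" else "pearson")
  }
  structure(list(
    labels = labels,
    module_sizes = if (length(mods)) setNames(
      vapply(mods, function(m) sum(labels == m), integer(1)), mods)
    else integer(0),
    eigengenes = eig, kme = km, prop_var_explained = pve,
    beta = beta, method = method, soft_threshold = soft_threshold
  ), class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d modules over %d genes (%d unassigned), beta = %s\n",
              length(x$module_sizes), length(x$labels),
              sum(x$labels == 0), format(x$beta)))
  if (length(x$module_sizes)) {
    cat("sizes:", paste(x$module_sizes, collapse = ", "), "\n")
  }
  invisible(x)
}
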