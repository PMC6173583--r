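#' Build an interaction network from an edge list
#'
#' @param edges A two-column data frame (or matrix) of gene-id endpoints, or
#'   a TSV path readable by [read_edge_list()].
#' @return A simple undirected [igraph::igraph] with named vertices;
#'   self-loops and duplicate edges are removed.
#' @export
interaction_network <- function(edges) {
  if (is.character(edges) && length(edges) == 1) {
    edges <- utils::read.delim(edges, colClasses = "character")
  }
  edges <- as.data.frame(edges)[, 1:2]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Read / write an interactome edge list as TSV
#'
#' Written edges have lexicographically ordered endpoints.
#'
#' @param path File path.
#' @param net An igraph network.
#' @export
read_edge_list <- function(path) interaction_network(path)

#' @rdname read_edge_list
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net)
  el <- t(apply(el, 1, sort))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  utils::write.table(data.frame(gene_a = el[, 1], gene_b = el[, 2]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(net)
}

# Restrict a gene set to network nodes, with a message for dropped ids.
match_nodes <- function(net, genes) {
  present <- intersect(genes, igraph::V(net)$name)
  dropped <- length(genes) - length(present)
  if (dropped > 0) message(sprintf("%d gene(s) not in the network, dropped",
                                   dropped))
  if (length(present) == 0) {
    abort("gene set has no overlap with network nodes",
          class = "scinet_empty_error")
  }
  present
}

#' Number of interactions within a gene set
#'
#' @param net An igraph network with named vertices.
#' @param genes Character vector of gene ids (ids absent from the network are
#'   dropped with a message).
#' @return Count of edges with both endpoints in the set.
#' @export
count_set_interactions <- function(net, genes) {
  genes <- match_nodes(net, genes)
  igraph::ecount(igraph::induced_subgraph(net, genes))
}

#' Largest connected component of the induced subgraph
#'
#' @inheritParams count_set_interactions
#' @return Size (node count) of the largest connected component among the
#'   set genes.
#' @export
largest_component_size <- function(net, genes) {
  genes <- match_nodes(net, genes)
  sub <- igraph::induced_subgraph(net, genes)
  max(igraph::components(sub)$csize)
}

#' Degree-preserving network randomisation
#'
#' Double-edge-swap randomisation: repeatedly exchanges endpoint pairs of two
#' edges, rejecting swaps that would create self-loops or duplicate edges, so
#' the degree sequence is exactly preserved.
#'
#' @param net An igraph network.
#' @param n_swaps Target number of successful swaps (default `10 * |E|`).
#'   Swap proposals that would create a self-loop or duplicate edge are
#'   rejected, and rejections are frequent on heavy-tailed simple graphs, so
#'   three proposals are attempted per requested swap.
#' @param rng_seed Integer seed.
#' @return A rewired igraph network with the same degree sequence. If no
#'   legal swap exists the input is returned with a warning.
#' @export
rewire_degree_preserving <- function(net, n_swaps = NULL, rng_seed = NULL) {
  if (igraph::ecount(net) < 2) abort("network must have at least 2 edges")
  n_swaps <- n_swaps %||% (10 * igraph::ecount(net))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  out <- igraph::rewire(net, igraph::keeping_degseq(loops = FALSE,
                                                    niter = 3 * n_swaps))
  if (igraph::identical_graphs(igraph::as_undirected(out),
                               igraph::as_undirected(net)) &&
      edge_key_set_equal(out, net)) {
    # distinguish "no legal swap" from the (vanishing) chance of a fixed point
    if (!has_legal_swap(net)) warn("no legal degree-preserving swap exists; returning input")
  }
  out
}

edge_key_set_equal <- function(a, b) {
  key <- function(g) {
    el <- igraph::as_edgelist(g)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  identical(key(a), key(b))
}

# A legal double-edge swap exists unless every pair of edges shares an
# endpoint or both alternative pairings already exist. Checked exhaustively
# only for tiny graphs; larger graphs are assumed swappable.
has_legal_swap <- function(net) {
  m <- igraph::ecount(net)
  if (m > 50) return(TRUE)
  el <- igraph::as_edgelist(net)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      a <- el[i, ]; b <- el[j, ]
      if (length(intersect(a, b)) > 0) next
      ok1 <- net[a[1], b[1]] == 0 && net[a[2], b[2]] == 0
      ok2 <- net[a[1], b[2]] == 0 && net[a[2], b[1]] == 0
      if (ok1 || ok2) return(TRUE)
    }
  }
  FALSE
}

# Shared engine for null-ensemble tests on rewired networks.
null_ensemble_rewired <- function(net, genes, statistic, n_null, rng_seed,
                                  stat_name) {
  genes <- match_nodes(net, genes)
  observed <- statistic(net, genes)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  nulls <- vapply(seq_len(n_null), function(i) {
    g <- igraph::rewire(net, igraph::keeping_degseq(
      loops = FALSE, niter = 30 * igraph::ecount(net)))
    statistic(g, genes)
  }, numeric(1))
  null_ensemble(observed, nulls, stat_name)
}

#' Null-ensemble result container
#'
#' Holds an observed network statistic, its null distribution, and the
#' add-one empirical p-value `(1 + #\{null >= obs\}) / (1 + N)`, which is
#' never zero and lies in `[1/(N+1), 1]`.
#'
#' @param observed Observed statistic.
#' @param null_values Numeric vector of null statistics.
#' @param statistic Name of the statistic.
#' @return An object of class `null_ensemble`.
#' @export
null_ensemble <- function(observed, null_values, statistic = "statistic") {
  structure(list(observed = observed,
                 null_values = null_values,
                 empirical_p = empirical_p(observed, null_values),
                 n_null = length(null_values),
                 statistic = statistic),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %s: observed %.4g, null mean %.4g (N = %d), empirical p = %.4g\n",
              x$statistic, x$observed, mean(x$null_values), x$n_null,
              x$empirical_p))
  invisible(x)
}

#' Interaction enrichment of a gene set
#'
#' Compares the number of interactions among set genes to the same count on
#' degree-preserving rewired networks (one-sided, greater).
#'
#' @inheritParams count_set_interactions
#' @param n_null Number of rewired null networks.
#' @param rng_seed Integer seed.
#' @return A [null_ensemble()].
#' @export
interaction_enrichment <- function(net, genes, n_null = 1000,
                                   rng_seed = NULL) {
  null_ensemble_rewired(net, genes, count_set_interactions, n_null, rng_seed,
                        "set_interactions")
}

#' Largest-connected-component significance of a gene set
#'
#' @inheritParams interaction_enrichment
#' @return A [null_ensemble()] for the LCC size against rewired networks.
#' @export
lcc_significance <- function(net, genes, n_null = 1000, rng_seed = NULL) {
  null_ensemble_rewired(net, genes, largest_component_size, n_null, rng_seed,
                        "lcc_size")
}

# Distinct unordered pairs of `genes` sharing at least one set in `sets`.
count_shared_pairs <- function(sets, genes) {
  genes <- unique(genes)
  if (length(genes) < 2) return(0L)
  inc <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  if (is.null(dim(inc))) inc <- matrix(inc, nrow = length(genes))
  shared <- tcrossprod(inc * 1)  # pairwise co-membership counts
  sum(shared[upper.tri(shared)] > 0)
}

#' Co-complex participation test
#'
#' Observed statistic: number of unordered gene pairs from the set sharing at
#' least one protein complex. Nulls draw uniform random sets of the same size
#' from the complex universe (union of complex members).
#'
#' @param complexes Named list of gene vectors (e.g. from [read_gmt()]).
#' @param genes Gene set.
#' @param n_draws Number of random null sets.
#' @param rng_seed Integer seed.
#' @return A [null_ensemble()].
#' @export
cocomplex_test <- function(complexes, genes, n_draws = 1000,
                           rng_seed = NULL) {
  if (length(complexes) == 0) abort("`complexes` must be non-empty")
  universe <- unique(unlist(complexes))
  set_in <- intersect(genes, universe)
  if (length(genes) > length(universe)) {
    abort("gene set larger than the complex universe")
  }
  observed <- count_shared_pairs(complexes, genes)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  nulls <- vapply(seq_len(n_draws), function(i) {
    count_shared_pairs(complexes, sample(universe, length(set_in)))
  }, numeric(1))
  null_ensemble(observed, nulls, "cocomplex_pairs")
}

#' Shared-annotation enrichment at breadth cutoffs
#'
#' For each annotation category and breadth cutoff, the observed statistic is
#' the mean over gene pairs of the number of shared terms, restricted to
#' terms annotated to at most `cutoff` genes; nulls use random gene sets of
#' equal size drawn from the annotation universe.
#'
#' @param annotations An `annotation_set` (see [generate_annotations()]), or
#'   a list with `terms` (named list of gene vectors) and `term_meta`
#'   (tibble with columns `term`, `category`).
#' @param genes Gene set.
#' @param breadth_cutoffs Numeric vector of maximum term sizes (use `Inf`
#'   for no restriction).
#' @param n_null Number of random null sets per (category, cutoff).
#' @param rng_seed Integer seed.
#' @return A tibble with one row per (category, cutoff): observed mean
#'   shared-term count, empirical p, and null summary.
#' @export
shared_annotation_test <- function(annotations, genes,
                                   breadth_cutoffs = c(100, 1000, Inf),
                                   n_null = 1000, rng_seed = NULL) {
  if (length(breadth_cutoffs) == 0) abort("`breadth_cutoffs` must be non-empty")
  terms <- annotations$terms
  meta <- annotations$term_meta
  universe <- unique(unlist(terms))
  set_in <- intersect(genes, universe)
  if (length(set_in) < 2) abort("fewer than 2 set genes have annotations")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  grid <- tidyr::expand_grid(category = unique(meta$category),
                             cutoff = breadth_cutoffs)
  purrr::pmap_dfr(grid, function(category, cutoff) {
    sizes <- lengths(terms)
    use <- terms[meta$category == category & sizes <= cutoff]
    observed <- mean_shared_terms(use, set_in)
    nulls <- vapply(seq_len(n_null), function(i) {
      mean_shared_terms(use, sample(universe, length(set_in)))
    }, numeric(1))
    tibble::tibble(category = category, cutoff = cutoff,
                   observed = observed,
                   empirical_p = empirical_p(observed, nulls),
                   null_mean = mean(nulls), null_sd = sd(nulls),
                   n_null = n_null)
  })
}

# Mean over unordered gene pairs of the number of shared terms.
mean_shared_terms <- function(terms, genes) {
  if (length(terms) == 0 || length(genes) < 2) return(0)
  inc <- vapply(terms, function(s) genes %in% s,
                logical(length(genes)))  # genes x terms
  if (is.null(dim(inc))) inc <- matrix(inc, nrow = length(genes))
  shared <- inc %*% t(inc)  # pairwise shared-term counts
  n <- length(genes)
  sum(shared[upper.tri(shared)]) / (n * (n - 1) / 2)
}

#' DIAMOnD disease-gene ranking
#'
#' Iteratively grows a seed set by adding, at each step, the non-seed node
#' with the most significant hypergeometric connectivity to the current seed
#' set: drawing `k` neighbours (the node's degree) from all `N` nodes of
#' which `s` are seeds, the p-value is the upper tail at the observed number
#' of seed neighbours `k_s`. Ties are broken by higher `k_s`, then
#' lexicographic node id. The added node joins the seed set.
#'
#' @param net An igraph network.
#' @param seeds Seed gene ids (must be network nodes).
#' @param n_iter Number of nodes to rank.
#' @return A tibble with columns `iteration`, `gene`, `k_s`, `degree`,
#'   `connectivity_p`. May be shorter than `n_iter` if no candidate remains
#'   connected to the seed set.
#' @export
diamond_rank <- function(net, seeds, n_iter) {
  if (n_iter < 1) abort("`n_iter` must be at least 1")
  nodes <- igraph::V(net)$name
  seeds <- intersect(seeds, nodes)
  if (length(seeds) == 0) abort("no seeds present in the network")
  n_total <- length(nodes)
  adj <- igraph::as_adj_list(net)
  names(adj) <- nodes
  neighbours <- lapply(adj, function(v) nodes[as.integer(v)])
  degree <- lengths(neighbours)
  in_seed <- setNames(nodes %in% seeds, nodes)
  ks <- vapply(neighbours, function(nb) sum(in_seed[nb]), numeric(1))

  out <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    cand <- nodes[!in_seed & ks > 0]
    if (length(cand) == 0) {
      message(sprintf("no connected candidate left after %d iteration(s)",
                      it - 1))
      out <- out[seq_len(it - 1)]
      break
    }
    s0 <- sum(in_seed)
    p <- phyper(ks[cand] - 1, s0, n_total - s0, degree[cand],
                lower.tail = FALSE)
    ord <- order(p, -ks[cand], cand)
    best <- cand[ord[1]]
    out[[it]] <- tibble::tibble(iteration = it, gene = best,
                                k_s = ks[[best]], degree = degree[[best]],
                                connectivity_p = p[[ord[1]]])
    in_seed[best] <- TRUE
    nb <- neighbours[[best]]
    ks[nb] <- ks[nb] + 1
  }
  dplyr::bind_rows(out)
}

#' DIAMOnD recovery of withheld genes
#'
#' Per bootstrap, withholds a fraction of the gene set, runs [diamond_rank()]
#' seeded with the remainder, and records the cumulative fraction of withheld
#' genes recovered by iteration. A control arm uses random seed sets of equal
#' size recovering random targets. Recovery-rank distributions of the two
#' arms are compared by a two-sample Kolmogorov-Smirnov test (unrecovered
#' targets are assigned rank `n_iter + 1`).
#'
#' @param net An igraph network.
#' @param genes Gene set.
#' @param withhold_frac Fraction withheld per bootstrap (must give >= 1 gene).
#' @param n_iter DIAMOnD iterations per bootstrap.
#' @param n_boot Number of bootstraps per arm.
#' @param rng_seed Integer seed.
#' @return A list with `curves` (tibble: arm, bootstrap, iteration,
#'   frac_recovered), `ks_statistic`, `ks_p`.
#' @export
diamond_recovery <- function(net, genes, withhold_frac = 0.2, n_iter = 1000,
                             n_boot = 1000, rng_seed = NULL) {
  genes <- match_nodes(net, genes)
  if (length(genes) < 5) abort("need at least 5 genes")
  n_hold <- floor(withhold_frac * length(genes))
  if (n_hold < 1) abort("`withhold_frac` leaves nothing to recover")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  nodes <- igraph::V(net)$name

  run_arm <- function(arm) {
    purrr::map(seq_len(n_boot), function(b) {
      if (arm == "seed") {
        held <- sample(genes, n_hold)
        seed_set <- setdiff(genes, held)
      } else {
        seed_set <- sample(nodes, length(genes) - n_hold)
        held <- sample(setdiff(nodes, seed_set), n_hold)
      }
      ranked <- diamond_rank(net, seed_set, n_iter)
      hit <- match(held, ranked$gene)
      ranks <- ifelse(is.na(hit), n_iter + 1, hit)
      rec <- vapply(seq_len(n_iter), function(i) mean(ranks <= i),
                    numeric(1))
      list(curve = tibble::tibble(arm = arm, bootstrap = b,
                                  iteration = seq_len(n_iter),
                                  frac_recovered = rec),
           ranks = ranks)
    })
  }
  seed_runs <- run_arm("seed")
  ctrl_runs <- run_arm("control")
  ranks_seed <- unlist(lapply(seed_runs, `[[`, "ranks"))
  ranks_ctrl <- unlist(lapply(ctrl_runs, `[[`, "ranks"))
  ks <- suppressWarnings(ks.test(ranks_seed, ranks_ctrl,
                                 alternative = "greater"))
  list(curves = dplyr::bind_rows(c(lapply(seed_runs, `[[`, "curve"),
                                   lapply(ctrl_runs, `[[`, "curve"))),
       ks_statistic = unname(ks$statistic),
       ks_p = ks$p.value)
}
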