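# Independent brute-force oracles shared across test files. Each one
# recomputes a statistic from its definition, without reusing package code.

# O(n^2) edge counting within a set.
oracle_set_interactions <- function(net, genes) {
  genes <- intersect(genes, igraph::V(net)$name)
  total <- 0L
  for (i in seq_along(genes)) {
    for (j in seq_len(i - 1L)) {
      if (net[genes[i], genes[j]] != 0) total <- total + 1L
    }
  }
  total
}

# BFS component enumeration on the induced subgraph.
oracle_lcc <- function(net, genes) {
  genes <- intersect(genes, igraph::V(net)$name)
  adj <- lapply(setNames(genes, genes), function(g) {
    intersect(igraph::V(net)$name[
      as.integer(igraph::neighbors(net, g))], genes)
  })
  unseen <- genes
  best <- 0L
  while (length(unseen)) {
    queue <- unseen[1]
    comp <- character(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, setdiff(adj[[v]], comp))
    }
    unseen <- setdiff(unseen, comp)
    best <- max(best, length(comp))
  }
  best
}

# Step-by-step DIAMOnD with explicit hypergeometric tail sums.
oracle_diamond <- function(net, seeds, n_iter) {
  nodes <- igraph::V(net)$name
  seeds <- intersect(seeds, nodes)
  picked <- character(0)
  for (it in seq_len(n_iter)) {
    current <- c(seeds, picked)
    cand <- setdiff(nodes, current)
    stats <- lapply(cand, function(v) {
      nb <- nodes[as.integer(igraph::neighbors(net, v))]
      k <- length(nb)
      ks <- length(intersect(nb, current))
      if (ks == 0) return(NULL)
      s0 <- length(current)
      n_tot <- length(nodes)
      p <- sum(vapply(ks:k, function(i) {
        choose(s0, i) * choose(n_tot - s0, k - i) / choose(n_tot, k)
      }, numeric(1)))
      list(gene = v, ks = ks, p = p)
    })
    stats <- purrr::compact(stats)
    if (length(stats) == 0) break
    df <- dplyr::bind_rows(lapply(stats, tibble::as_tibble))
    df <- df[order(df$p, -df$ks, df$gene), ]
    picked <- c(picked, df$gene[1])
  }
  picked
}

# Triple-loop TOM.
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - 1
  out <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      num <- a[i, j]
      for (u in seq_len(n)) {
        if (u != i && u != j) num <- num + a[i, u] * a[u, j]
      }
      out[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  out
}

# Exact one-sided Wilcoxon tail by enumeration over all assignments.
oracle_wilcoxon_up <- function(values, in_set) {
  n1 <- sum(in_set)
  r <- rank(values)
  obs <- sum(r[in_set])
  combos <- combn(length(values), n1)
  tails <- sum(apply(combos, 2, function(idx) sum(r[idx]) >= obs))
  tails / ncol(combos)
}

# Hypergeometric upper tail by direct summation over 2x2 tables.
oracle_fisher_greater <- function(a, b, c_, d) {
  total <- a + b + c_ + d
  sum(vapply(a:min(a + b, a + c_), function(x) {
    choose(a + c_, x) * choose(b + d, a + b - x) / choose(total, a + b)
  }, numeric(1)))
}

# Brute-force specificity index on a small profile matrix.
oracle_si <- function(profiles, eps = 1) {
  n <- nrow(profiles)
  types <- colnames(profiles)
  out <- matrix(NA_real_, n, length(types),
                dimnames = list(rownames(profiles), types))
  for (ci in seq_along(types)) {
    ranks <- sapply(setdiff(seq_along(types), ci), function(cj) {
      fold <- log2((profiles[, ci] + eps) / (profiles[, cj] + eps))
      rank(-fold, ties.method = "average")
    })
    out[, ci] <- rowMeans(ranks) / n
  }
  out
}
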