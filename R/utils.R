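#' @importFrom rlang %||% abort warn .data
#' @importFrom stats cor cor.test median qnorm pnorm phyper pt sd quantile
#'   setNames rnorm runif rbinom complete.cases ks.test wilcox.test fisher.test
#'   hclust cutree as.dist p.adjust t.test var mad pwilcox rpois
#' @importFrom utils head combn
NULL

`%||%` <- rlang::`%||%`

#' Adjusted Rand index between two partitions
#'
#' Measures agreement between two labelings of the same items, corrected for
#' chance; 1 means identical partitions, 0 is the expected value for random
#' labelings.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return A single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Add-one (Davison-Hinkley) empirical p for a one-sided "greater" test.
empirical_p <- function(observed, null_values) {
  (1 + sum(null_values >= observed)) / (1 + length(null_values))
}

# Derive a per-object RNG seed from a base seed so that generating one output
# never perturbs the stream of another. Kept below 2^31.
derive_seed <- function(rng_seed, offset) {
  (as.integer(rng_seed) %% 1000000L) * 2000L + as.integer(offset)
}

# Bonferroni with the family size recorded as an attribute.
bonferroni <- function(p, m = length(p)) {
  out <- pmin(1, p * m)
  attr(out, "n_tests") <- m
  out
}

assert_config_field <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    abort(sprintf("invalid simulation config: field `%s` %s", field, msg),
          class = "scinet_config_error")
  }
}
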