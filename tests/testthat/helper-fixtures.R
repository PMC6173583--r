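# Shared fixtures: compact configurations and small deterministic objects.

# Small, fast configuration for structural tests.
small_config <- function(...) {
  args <- list(
    n_genes = 120, module_sizes = c(30, 25, 20),
    n_samples_ref = 40, n_test_studies = 3, samples_per_study = 24,
    de_effect = c(2, -2, 2), severity_coupled_module = 2,
    time_flip_module = 3, curated_size = 40, curated_target_modules = 1,
    interactome_n_genes = 400, interactome_mean_degree = 4
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# Null configuration: no coexpression signal, no differential effects, no
# planted interactome structure, random annotations.
null_config <- function(...) {
  small_config(module_signal = 0, de_effect = 0,
               planted_subgraph_density = 0, annotation_concordance = 0,
               severity_coupled_module = NA, time_flip_module = NA, ...)
}

# Tiny deterministic expression study.
toy_study <- function(n_genes = 10, n_samples = 12, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", 1:n_genes),
                              sprintf("s%02d", 1:n_samples)))
  expression_study(x)
}

# Deterministic small graph from an edge list given as a 2-column matrix.
graph_from_pairs <- function(...) {
  el <- matrix(c(...), ncol = 2, byrow = TRUE)
  igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
}
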