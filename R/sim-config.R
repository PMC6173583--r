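#' Simulation configuration
#'
#' Defines the study conditions the synthetic-data generators emulate: a
#' healthy reference cohort with planted coexpression modules, several
#' injured-vs-sham test studies sharing that module structure, one
#' graded-severity experiment, a heavy-tailed interactome with a densely
#' interconnected planted neighbourhood, GO-like annotations, protein
#' complexes, cell-type profiles, and a literature-curated gene set with a
#' controlled false-positive rate.
#'
#' @param n_genes Total number of genes (modules plus background).
#' @param module_sizes Integer vector of planted module sizes; their sum must
#'   not exceed `n_genes`.
#' @param n_samples_ref Samples in the healthy reference cohort (default 71,
#'   the size of a typical post-mortem spinal-cord RNA-seq cohort).
#' @param n_test_studies Number of injured-vs-sham studies for the
#'   meta-analysis (default 5).
#' @param samples_per_study Samples per test study, split evenly between sham
#'   and injured and cycled across `timepoints`.
#' @param module_signal Per-module latent-factor loading strength in \[0, 1\]
#'   (recycled across modules). Per-gene loadings are drawn uniformly from
#'   0.4-1.2 times this value, giving each module a hub-to-periphery
#'   membership continuum as in real coexpression networks.
#' @param noise_sd Standard deviation of i.i.d. Gaussian measurement noise.
#' @param severity_levels Strictly increasing injury severities; 0 is sham
#'   (default 0/100/200, the kdyn impact forces of a contusion model).
#' @param severity_coupled_module Index of the module whose eigengene mean
#'   scales linearly with severity in the graded-severity study, or `NA`.
#' @param severity_samples_per_level Animals per severity group in the
#'   graded-severity study (default 5, a typical prospective contusion
#'   design).
#' @param time_flip_module Index of the module whose injury effect reverses
#'   sign from the earliest to the latest timepoint (acute-down/chronic-up),
#'   or `NA`.
#' @param de_effect Per-module signed eigengene shift in injured samples.
#' @param timepoints Post-injury sampling days (default 1/3/7/28: acute,
#'   subacute, intermediate, chronic).
#' @param curated_size Number of unique genes in the synthetic curated set.
#' @param curated_target_modules Modules from which curated true positives are
#'   drawn.
#' @param seed_gene_fraction Fraction of the curated set drawn from target
#'   modules (true positives).
#' @param fp_rate Fraction of the curated set drawn uniformly at random
#'   (false positives); `seed_gene_fraction + fp_rate` must not exceed 1, and
#'   any remainder is also drawn uniformly.
#' @param interactome_degree_exponent Power-law exponent of the interactome
#'   degree distribution (default 2.5).
#' @param interactome_mean_degree Mean degree of the interactome.
#' @param interactome_n_genes Total interactome nodes (default 3000): the
#'   expression genes plus genome-background genes, so a curated set is a
#'   small fraction of the network as in a real genome-scale interactome.
#' @param planted_subgraph_density Edge density planted among curated true
#'   positives, in \[0, 1\].
#' @param annotation_concordance Fraction of annotation terms/complexes
#'   aligned with planted structure; 0 gives fully random annotations.
#' @param marker_fold Expression fold-change of marker-module genes in the
#'   designated cell type.
#' @param celltype_marker_module Module whose genes are markers of
#'   `marker_celltype`.
#' @param marker_celltype Name of the designated cell type.
#' @param celltypes Cell-type names for the synthetic profiles.
#' @param rng_seed Integer seed; fully determines all generator outputs. Each
#'   generator draws from its own stream derived from this seed, so adding
#'   outputs never perturbs existing ones.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 400,
                       module_sizes = c(60, 50, 40, 30, 20),
                       n_samples_ref = 71,
                       n_test_studies = 5,
                       samples_per_study = 32,
                       module_signal = 0.9,
                       noise_sd = 0.2,
                       severity_levels = c(0, 100, 200),
                       severity_coupled_module = 4,
                       severity_samples_per_level = 5,
                       time_flip_module = 5,
                       de_effect = c(2, -2, 2, 10, 2),
                       timepoints = c(1, 3, 7, 28),
                       curated_size = 80,
                       curated_target_modules = c(1, 3),
                       seed_gene_fraction = 0.7,
                       fp_rate = 0.3,
                       interactome_degree_exponent = 2.5,
                       interactome_mean_degree = 6,
                       interactome_n_genes = 3000,
                       planted_subgraph_density = 0.2,
                       annotation_concordance = 0.8,
                       marker_fold = 8,
                       celltype_marker_module = 1,
                       marker_celltype = "microglia",
                       celltypes = c("neuron", "astrocyte", "microglia",
                                     "oligodendrocyte", "endothelial"),
                       rng_seed = 1L) {
  k <- length(module_sizes)
  module_signal <- rep_len(module_signal, k)
  de_effect <- rep_len(de_effect, k)
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  k <- length(cfg$module_sizes)
  assert_config_field(is.numeric(cfg$n_genes) && length(cfg$n_genes) == 1 &&
                        cfg$n_genes >= 1, "n_genes", "must be a positive count")
  assert_config_field(k >= 1 && all(cfg$module_sizes >= 1),
                      "module_sizes", "must be positive counts")
  assert_config_field(sum(cfg$module_sizes) <= cfg$n_genes,
                      "module_sizes", "must sum to at most n_genes")
  assert_config_field(cfg$n_samples_ref >= 4, "n_samples_ref",
                      "must be at least 4")
  assert_config_field(cfg$n_test_studies >= 1, "n_test_studies",
                      "must be at least 1")
  assert_config_field(cfg$samples_per_study >= 4, "samples_per_study",
                      "must be at least 4")
  assert_config_field(all(cfg$module_signal >= 0 & cfg$module_signal <= 1),
                      "module_signal", "must lie in [0, 1]")
  assert_config_field(is.numeric(cfg$noise_sd) && cfg$noise_sd > 0,
                      "noise_sd", "must be a positive real")
  assert_config_field(length(cfg$severity_levels) >= 2 &&
                        all(diff(cfg$severity_levels) > 0),
                      "severity_levels", "must be strictly increasing")
  assert_config_field(is.na(cfg$severity_coupled_module) ||
                        (cfg$severity_coupled_module %in% seq_len(k)),
                      "severity_coupled_module",
                      "must index a planted module or be NA")
  assert_config_field(cfg$severity_samples_per_level >= 2,
                      "severity_samples_per_level", "must be at least 2")
  assert_config_field(is.na(cfg$time_flip_module) ||
                        (cfg$time_flip_module %in% seq_len(k)),
                      "time_flip_module",
                      "must index a planted module or be NA")
  assert_config_field(all(cfg$timepoints > 0) &&
                        !is.unsorted(cfg$timepoints, strictly = TRUE),
                      "timepoints", "must be strictly increasing day counts")
  assert_config_field(cfg$curated_size >= 1, "curated_size",
                      "must be a positive count")
  assert_config_field(all(cfg$curated_target_modules %in% seq_len(k)),
                      "curated_target_modules", "must index planted modules")
  assert_config_field(cfg$seed_gene_fraction >= 0 &&
                        cfg$seed_gene_fraction <= 1,
                      "seed_gene_fraction", "must lie in [0, 1]")
  assert_config_field(cfg$fp_rate >= 0 && cfg$fp_rate <= 1,
                      "fp_rate", "must lie in [0, 1]")
  assert_config_field(cfg$seed_gene_fraction + cfg$fp_rate <= 1,
                      "fp_rate", "plus seed_gene_fraction must not exceed 1")
  assert_config_field(cfg$interactome_degree_exponent > 0,
                      "interactome_degree_exponent", "must be positive")
  assert_config_field(cfg$interactome_mean_degree > 0,
                      "interactome_mean_degree", "must be positive")
  assert_config_field(cfg$interactome_n_genes >= cfg$n_genes,
                      "interactome_n_genes", "must be at least n_genes")
  assert_config_field(cfg$planted_subgraph_density >= 0 &&
                        cfg$planted_subgraph_density <= 1,
                      "planted_subgraph_density", "must lie in [0, 1]")
  assert_config_field(cfg$annotation_concordance >= 0 &&
                        cfg$annotation_concordance <= 1,
                      "annotation_concordance", "must lie in [0, 1]")
  assert_config_field(cfg$marker_fold > 0, "marker_fold", "must be positive")
  assert_config_field(length(cfg$celltypes) >= 2, "celltypes",
                      "must name at least two cell types")
  assert_config_field(is.numeric(cfg$rng_seed) && length(cfg$rng_seed) == 1 &&
                        !is.na(cfg$rng_seed),
                      "rng_seed", "must be a single integer")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> %d genes, %d planted modules (%s), %d reference samples,\n",
    "  %d test studies x %d samples, severities %s, timepoints %s, seed %d\n"),
    x$n_genes, length(x$module_sizes),
    paste(x$module_sizes, collapse = "/"),
    x$n_samples_ref, x$n_test_studies, x$samples_per_study,
    paste(x$severity_levels, collapse = "/"),
    paste(x$timepoints, collapse = "/"), as.integer(x$rng_seed)))
  invisible(x)
}
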