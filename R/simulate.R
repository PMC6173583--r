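#' Generate the reference expression study and the ground truth
#'
#' Draws expression from a single-latent-factor model per module: for gene g
#' in module m and sample s, `x_gs = lambda_g * e_ms + eps_gs`, with `e_m`
#' i.i.d. standard normal per sample, `eps` i.i.d. `N(0, noise_sd^2)`, and
#' `lambda_g` a jittered version of `module_signal` (0 for background genes).
#' The returned truth records everything later stages are tested against:
#' module labels, loadings, curated true positives, and the designated
#' severity, time-flip and marker modules.
#'
#' @param config A [sim_config()].
#' @return A list with elements `study` (an [expression_study()]) and `truth`
#'   (class `synthetic_truth`).
#' @export
generate_reference_expression <- function(config) {
  config <- validate_sim_config(config)
  set.seed(derive_seed(config$rng_seed, 1L))
  n <- config$n_genes
  k <- length(config$module_sizes)
  genes <- sprintf("g%04d", seq_len(n))
  labels <- setNames(rep(0L, n), genes)
  idx <- 1L
  for (m in seq_len(k)) {
    labels[idx:(idx + config$module_sizes[m] - 1L)] <- m
    idx <- idx + config$module_sizes[m]
  }
  loadings <- setNames(numeric(n), genes)
  for (m in seq_len(k)) {
    members <- labels == m
    loadings[members] <-
      config$module_signal[m] * runif(sum(members), 0.4, 1.2)
  }
  target_pool <- genes[labels %in% config$curated_target_modules]
  n_tp <- min(round(config$seed_gene_fraction * config$curated_size),
              length(target_pool))
  curated_true <- sort(sample(target_pool, n_tp))

  truth <- structure(list(
    module_labels = labels,
    loadings = loadings,
    curated_true = curated_true,
    target_modules = config$curated_target_modules,
    severity_module = config$severity_coupled_module,
    time_flip_module = config$time_flip_module,
    de_direction = sign(config$de_effect),
    marker_module = config$celltype_marker_module,
    marker_celltype = config$marker_celltype,
    config = config
  ), class = "synthetic_truth")

  expr <- draw_factor_expression(config, truth, config$n_samples_ref,
                                 shift = NULL)
  meta <- tibble::tibble(
    sample_id = colnames(expr), study_id = "reference",
    condition = "control", severity = 0,
    timepoint_days = NA_real_, platform = "rnaseq"
  )
  list(study = expression_study(expr, meta), truth = truth)
}

# Draw one genes x samples matrix from the factor model. `shift` is an
# optional k x n_samples matrix of per-module eigengene mean shifts; module
# factors are residualized against the design (the severity vector) before
# the shift is added, so the planted effects are the only design-aligned
# signal and chance factor-design correlation does not masquerade as
# differential expression at desk-scale sample sizes.
draw_factor_expression <- function(config, truth, n_samples, shift = NULL,
                                   sample_prefix = "s", design = NULL) {
  n <- config$n_genes
  k <- length(config$module_sizes)
  e <- matrix(rnorm(k * n_samples), k, n_samples)
  if (!is.null(design) && sd(design) > 0) {
    e <- t(apply(e, 1, function(row) stats::resid(stats::lm(row ~ design))))
  }
  if (!is.null(shift)) e <- e + shift
  expr <- matrix(rnorm(n * n_samples, sd = config$noise_sd), n, n_samples)
  member <- truth$module_labels > 0
  expr[member, ] <- expr[member, , drop = FALSE] +
    truth$loadings[member] * e[truth$module_labels[member], , drop = FALSE]
  rownames(expr) <- names(truth$module_labels)
  colnames(expr) <- sprintf("%s%03d", sample_prefix, seq_len(n_samples))
  expr
}

#' Generate injured-vs-sham test studies sharing the planted module structure
#'
#' Each study redraws module eigengenes and noise but keeps the reference
#' loadings. Injured samples receive a mean shift of `de_effect[m]` on the
#' module-m eigengene, scaled by `severity / max(severity_levels)`; in these
#' meta-analysis studies all injured samples sit at the maximal severity, so
#' the contrast is injured vs sham (the graded-severity design is provided by
#' [generate_severity_study()]). The effect of `time_flip_module` is further
#' multiplied by a factor running linearly from -1 at the earliest timepoint
#' to +1 at the latest, emulating an acute-down/chronic-up module.
#'
#' @param config A [sim_config()].
#' @param truth The `synthetic_truth` from [generate_reference_expression()].
#' @return A list of `n_test_studies` [expression_study()] objects.
#' @export
generate_test_studies <- function(config, truth) {
  config <- validate_sim_config(config)
  if (config$n_test_studies < 1) {
    abort("invalid simulation config: field `n_test_studies` must be >= 1",
          class = "scinet_config_error")
  }
  set.seed(derive_seed(config$rng_seed, 2L))
  lapply(seq_len(config$n_test_studies), function(s) {
    draw_test_study(config, truth, sprintf("study%02d", s))
  })
}

draw_test_study <- function(config, truth, study_id) {
  ns <- config$samples_per_study
  k <- length(config$module_sizes)
  n_inj <- ns %/% 2L
  condition <- rep(c("sham", "injured"), c(ns - n_inj, n_inj))
  max_sev <- max(config$severity_levels)
  severity <- ifelse(condition == "injured", max_sev, 0)
  timepoint <- rep_len(config$timepoints, ns)
  shift <- matrix(0, k, ns)
  for (m in seq_len(k)) {
    eff <- config$de_effect[m] * severity / max_sev
    if (!is.na(truth$time_flip_module) && m == truth$time_flip_module) {
      mult <- flip_multiplier(timepoint, config$timepoints)
      eff <- eff * mult
    }
    shift[m, ] <- eff
  }
  expr <- draw_factor_expression(config, truth, ns,
                                 shift = shift,
                                 sample_prefix = paste0(study_id, "_s"),
                                 design = severity)
  meta <- tibble::tibble(
    sample_id = colnames(expr), study_id = study_id,
    condition = condition, severity = severity,
    timepoint_days = as.numeric(timepoint), platform = "microarray"
  )
  expression_study(expr, meta)
}

# Linear ramp from -1 (earliest timepoint) to +1 (latest).
flip_multiplier <- function(timepoint, timepoints) {
  ranks <- match(timepoint, sort(unique(timepoints)))
  nt <- length(unique(timepoints))
  if (nt == 1) return(rep(1, length(timepoint)))
  -1 + 2 * (ranks - 1) / (nt - 1)
}

#' Generate the graded-severity study
#'
#' Emulates a dedicated severity experiment (sham plus each non-zero severity
#' level, balanced groups, a single post-injury timepoint): only the
#' severity-coupled module responds, with an eigengene mean shift of
#' `de_effect[severity_coupled_module] * severity / max(severity)` so the
#' coupling is linear in severity.
#'
#' @inheritParams generate_test_studies
#' @param timepoint_days Day at which all samples are taken (default 7).
#' @return An [expression_study()].
#' @export
generate_severity_study <- function(config, truth, timepoint_days = 7) {
  config <- validate_sim_config(config)
  if (is.na(config$severity_coupled_module)) {
    abort("invalid simulation config: field `severity_coupled_module` must index a module to generate a severity study",
          class = "scinet_config_error")
  }
  set.seed(derive_seed(config$rng_seed, 6L))
  levels <- config$severity_levels
  per_level <- config$severity_samples_per_level
  severity <- rep(levels, each = per_level)
  ns <- length(severity)
  k <- length(config$module_sizes)
  cm <- config$severity_coupled_module
  shift <- matrix(0, k, ns)
  shift[cm, ] <- config$de_effect[cm] * severity / max(levels)
  expr <- draw_factor_expression(config, truth, ns, shift = shift,
                                 sample_prefix = "sev_s", design = severity)
  meta <- tibble::tibble(
    sample_id = colnames(expr), study_id = "severity",
    condition = ifelse(severity == 0, "sham", "injured"),
    severity = severity, timepoint_days = timepoint_days,
    platform = "rnaseq"
  )
  expression_study(expr, meta)
}

#' Generate a synthetic interactome with a planted dense neighbourhood
#'
#' Samples a simple undirected graph over all genes with a heavy-tailed
#' (power-law, configuration-model style) degree distribution, mixes it with
#' a degree-preserving edge-swap burn-in, then adds edges among the curated
#' true positives until their induced density reaches
#' `planted_subgraph_density`.
#'
#' @inheritParams generate_test_studies
#' @return An [igraph::igraph] object with vertex names equal to gene ids.
#' @export
generate_interactome <- function(config, truth) {
  config <- validate_sim_config(config)
  set.seed(derive_seed(config$rng_seed, 3L))
  n <- config$interactome_n_genes
  m_edges <- round(config$interactome_mean_degree * n / 2)
  g <- igraph::sample_fitness_pl(n, m_edges,
                                 exponent.out = config$interactome_degree_exponent)
  extra <- n - config$n_genes
  igraph::V(g)$name <- c(names(truth$module_labels),
                         if (extra > 0) sprintf("x%04d", seq_len(extra)))
  g <- igraph::rewire(g, igraph::keeping_degseq(niter = 30 * igraph::ecount(g)))
  dens <- config$planted_subgraph_density
  tp <- truth$curated_true
  if (dens > 0 && length(tp) >= 2) {
    pairs <- t(combn(tp, 2))
    target <- ceiling(dens * nrow(pairs))
    if (target > nrow(pairs)) {
      abort("invalid simulation config: field `planted_subgraph_density` infeasible for subgraph size",
            class = "scinet_config_error")
    }
    sub <- igraph::induced_subgraph(g, tp)
    have <- igraph::ecount(sub)
    need <- target - have
    if (need > 0) {
      present <- apply(pairs, 1, function(p) {
        g[p[1], p[2]] != 0
      })
      missing <- pairs[!present, , drop = FALSE]
      add <- missing[sample(nrow(missing), need), , drop = FALSE]
      g <- igraph::add_edges(g, as.vector(t(add)))
    }
  }
  igraph::simplify(g)
}

#' Generate synthetic annotations, complexes and cell-type profiles
#'
#' Terms span three breadth classes (small 5-20, medium 30-80, large 120-200
#' genes) in three ontology-like categories. A fraction
#' `annotation_concordance` of small/medium terms is module-concordant (80%
#' of members drawn from one planted module); complexes are likewise enriched
#' for curated true positives. Cell-type profiles are log-normal baselines
#' with the marker module's genes elevated `marker_fold`-fold in the
#' designated cell type.
#'
#' @inheritParams generate_test_studies
#' @param n_terms_per_category Number of terms per ontology category.
#' @param n_complexes Number of protein complexes.
#' @return A list of class `annotation_set` with elements `terms` (named list
#'   of gene vectors), `term_meta` (tibble: term, category, breadth_class,
#'   size), `complexes` (named list), `celltype_profiles` (genes x cell-types
#'   matrix), and `marker` (list with `module` and `cell_type`).
#' @export
generate_annotations <- function(config, truth, n_terms_per_category = 30,
                                 n_complexes = 60) {
  config <- validate_sim_config(config)
  set.seed(derive_seed(config$rng_seed, 4L))
  genes <- names(truth$module_labels)
  k <- length(config$module_sizes)
  breadth <- list(small = c(5, 20), medium = c(30, 80), large = c(120, 200))
  cap <- max(30, config$n_genes %/% 2)
  breadth$large <- c(min(breadth$large[1], cap - 10), min(breadth$large[2], cap))
  # term sizes can never exceed the gene universe
  breadth <- lapply(breadth, function(r) pmax(2, pmin(r, config$n_genes)))

  terms <- list()
  meta <- list()
  for (cat in c("BP", "CC", "MF")) {
    for (i in seq_len(n_terms_per_category)) {
      cls <- names(breadth)[1 + (i - 1) %% 3]
      rng <- breadth[[cls]]
      size <- sample(rng[1]:rng[2], 1)
      concordant <- cls != "large" &&
        runif(1) < config$annotation_concordance
      if (concordant) {
        m <- sample(seq_len(k), 1)
        members <- genes[truth$module_labels == m]
        n_in <- min(round(0.8 * size), length(members))
        n_in <- max(n_in, size - (length(genes) - length(members)))
        set <- c(sample(members, n_in),
                 sample(setdiff(genes, members), size - n_in))
      } else {
        set <- sample(genes, size)
      }
      id <- sprintf("%s%03d", cat, i)
      terms[[id]] <- sort(set)
      meta[[id]] <- tibble::tibble(term = id, category = cat,
                                   breadth_class = cls, size = size,
                                   class_min = rng[1], class_max = rng[2])
    }
  }

  complexes <- list()
  tp <- truth$curated_true
  for (i in seq_len(n_complexes)) {
    size <- sample(3:10, 1)
    if (runif(1) < config$annotation_concordance && length(tp) >= 2) {
      n_in <- min(max(2, round(0.6 * size)), length(tp))
      set <- c(sample(tp, n_in), sample(setdiff(genes, tp), size - n_in))
    } else {
      set <- sample(genes, size)
    }
    complexes[[sprintf("CPX%03d", i)]] <- sort(set)
  }

  profiles <- matrix(
    exp(rnorm(length(genes) * length(config$celltypes), mean = 2, sd = 1)),
    nrow = length(genes),
    dimnames = list(genes, config$celltypes))
  marker_genes <- genes[truth$module_labels == truth$marker_module]
  profiles[marker_genes, truth$marker_celltype] <-
    profiles[marker_genes, truth$marker_celltype] * config$marker_fold

  structure(list(
    terms = terms,
    term_meta = dplyr::bind_rows(meta),
    complexes = complexes,
    celltype_profiles = profiles,
    marker = list(module = truth$marker_module,
                  cell_type = truth$marker_celltype)
  ), class = "annotation_set")
}

#' Generate a synthetic literature-curated gene set
#'
#' Builds curation records (source accession, species, direction, technique,
#' injury model, timepoint, study id) for `curated_size` unique human genes:
#' the true positives recorded in the truth, `fp_rate` uniform false
#' positives, and any remainder also drawn uniformly. Non-human records carry
#' species-prefixed accessions together with ortholog tables (three synthetic
#' databases, each missing ~10% of entries) so the majority-vote mapping is
#' exercised on ingest.
#'
#' @inheritParams generate_test_studies
#' @return A list of class `curated_sim` with elements `records` (tibble in
#'   the ingest schema), `genes` (unique human gene ids), `truth_flags`
#'   (tibble: gene, is_true_positive), and `ortholog_tables`.
#' @export
generate_curated_set <- function(config, truth) {
  config <- validate_sim_config(config)
  set.seed(derive_seed(config$rng_seed, 5L))
  genes <- names(truth$module_labels)
  tp <- truth$curated_true
  n <- config$curated_size
  n_fp <- round(config$fp_rate * n)
  n_rest <- n - length(tp) - n_fp
  pool <- setdiff(genes, tp)
  random_part <- sample(pool, n_fp + max(0, n_rest))
  curated <- c(tp, random_part)
  flags <- tibble::tibble(gene = curated,
                          is_true_positive = curated %in% tp)

  species_pool <- c("rat", "mouse", "rabbit", "human")
  study_pool <- sprintf("PMID%05d", sample(10000:99999, 20))
  records <- purrr::map_dfr(curated, function(g) {
    n_rec <- min(1L + rpois(1, 0.35), 4L)
    studies <- sample(study_pool, n_rec)
    dir_gene <- sample(c("up", "down", "phospho"), 1,
                       prob = c(0.70, 0.26, 0.04))
    purrr::map_dfr(studies, function(st) {
      sp <- sample(species_pool, 1, prob = c(0.45, 0.35, 0.05, 0.15))
      tibble::tibble(
        gene = if (sp == "human") g else paste0(sp, "_", g),
        species = sp,
        direction = dir_gene,
        technique = sample(c("western blot", "qPCR",
                             "immunohistochemistry", "ELISA"), 1),
        model = sample(c("contusion", "transection", "compression"), 1),
        timepoint = sample(c("1d", "3d", "7d", "28d"), 1),
        study_id = st
      )
    })
  })

  nonhuman <- unique(records$gene[records$species != "human"])
  tables <- lapply(c("dbA", "dbB", "dbC"), function(db) {
    keep <- runif(length(nonhuman)) > 0.1
    ids <- nonhuman[keep]
    list(database_name = db,
         mapping = setNames(as.list(sub("^[a-z]+_", "", ids)), ids))
  })

  structure(list(records = records,
                 genes = sort(unique(curated)),
                 truth_flags = flags,
                 ortholog_tables = tables),
            class = "curated_sim")
}

#' Run all generators for one configuration
#'
#' @param config A [sim_config()].
#' @return A list with elements `reference`, `truth`, `studies`,
#'   `severity_study`, `interactome`, `annotations`, `curated`.
#' @export
simulate_sci <- function(config = sim_config()) {
  ref <- generate_reference_expression(config)
  list(
    reference = ref$study,
    truth = ref$truth,
    studies = generate_test_studies(config, ref$truth),
    severity_study = generate_severity_study(config, ref$truth),
    interactome = generate_interactome(config, ref$truth),
    annotations = generate_annotations(config, ref$truth),
    curated = generate_curated_set(config, ref$truth)
  )
}

#' Write a full simulation to plain-text files
#'
#' Expression and metadata as TSV, interactome as a two-column edge list with
#' lexicographically ordered endpoints, annotations/complexes as GMT,
#' cell-type profiles and the curated table as TSV, truth as JSON.
#'
#' @param sim Output of [simulate_sci()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_expression_tsv(sim$reference, fp("reference_expr.tsv"),
                       fp("reference_meta.tsv"))
  for (i in seq_along(sim$studies)) {
    write_expression_tsv(sim$studies[[i]],
                         fp(sprintf("study%02d_expr.tsv", i)),
                         fp(sprintf("study%02d_meta.tsv", i)))
  }
  write_expression_tsv(sim$severity_study, fp("severity_expr.tsv"),
                       fp("severity_meta.tsv"))
  write_edge_list(sim$interactome, fp("interactome_edges.tsv"))
  write_gmt(sim$annotations$terms, fp("annotations.gmt"))
  write_gmt(sim$annotations$complexes, fp("complexes.gmt"))
  utils::write.table(
    data.frame(gene = rownames(sim$annotations$celltype_profiles),
               sim$annotations$celltype_profiles, check.names = FALSE),
    fp("celltype_profiles.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(sim$curated$records),
                     fp("curated_set.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- sim$truth
  jsonlite::write_json(
    list(module_labels = as.list(truth$module_labels),
         curated_true = truth$curated_true,
         severity_module = truth$severity_module,
         time_flip_module = truth$time_flip_module,
         de_direction = truth$de_direction),
    fp("truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
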