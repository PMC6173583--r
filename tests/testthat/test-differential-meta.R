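test_that("group statistics match the textbook pooled t-test", {
  st <- toy_study(15, 20, seed = 2)
  st$sample_meta$condition <- rep(c("injured", "sham"), each = 10)
  st$sample_meta$study_id <- "s"
  gs <- gene_statistics(st, "condition")
  for (g in sample(rownames(st$expr), 5)) {
    tt <- t.test(st$expr[g, 1:10], st$expr[g, 11:20], var.equal = TRUE)
    expect_equal(gs$statistic[gs$gene == g], unname(tt$statistic),
                 tolerance = 1e-10)
    expect_equal(gs$p_value[gs$gene == g], tt$p.value, tolerance = 1e-10)
  }
  # identical group means and variances give statistic 0, p 1
  x <- rbind(flat = rep(c(1, 2, 3, 4), 4), other = rnorm(16))
  colnames(x) <- sprintf("s%02d", 1:16)
  st0 <- expression_study(x)
  st0$sample_meta$condition <- rep(c("injured", "sham"), each = 8)
  gs0 <- gene_statistics(st0, "condition")
  expect_equal(gs0$statistic[gs0$gene == "flat"], 0)
  expect_equal(gs0$p_value[gs0$gene == "flat"], 1)
  expect_error(gene_statistics(st0, "condition", groups = c("a", "b")),
               "2 samples")
})

test_that("a planted two-SD shift is detected at the analytic power", {
  set.seed(7)
  n_rep <- 60
  hits <- replicate(n_rep, {
    x <- matrix(rnorm(20), 1, dimnames = list("g", sprintf("s%02d", 1:20)))
    x[1, 1:10] <- x[1, 1:10] + 2
    st <- expression_study(x)
    st$sample_meta$condition <- rep(c("injured", "sham"), each = 10)
    gene_statistics(st, "condition")$p_value < 0.01
  })
  # closed-form power of the two-sided pooled t-test at alpha = 0.01,
  # n = 10 per group, noncentrality 2 / sqrt(2/10)
  ncp <- 2 / sqrt(2 / 10)
  crit <- qt(0.995, df = 18)
  power <- pt(-crit, df = 18, ncp = ncp) + pt(crit, df = 18, ncp = ncp,
                                              lower.tail = FALSE)
  se <- sqrt(power * (1 - power) / n_rep)
  expect_lt(abs(mean(hits) - power), 3 * se + 0.01)
  expect_gt(mean(hits), 0.85)
})

test_that("mean-rank set test agrees with exhaustive enumeration", {
  set.seed(11)
  values <- setNames(rnorm(12), sprintf("g%02d", 1:12))
  top4 <- names(sort(values, decreasing = TRUE))[1:4]
  p <- mean_rank_set_test(values, top4, "up")
  expect_equal(p, oracle_wilcoxon_up(values, names(values) %in% top4),
               tolerance = 1e-12)
  expect_equal(p, 1 / choose(12, 4), tolerance = 1e-12)
  # arbitrary sets also match the enumeration oracle
  for (i in 1:5) {
    set <- sample(names(values), 5)
    expect_equal(mean_rank_set_test(values, set, "up"),
                 oracle_wilcoxon_up(values, names(values) %in% set),
                 tolerance = 1e-12)
  }
  expect_error(mean_rank_set_test(values, character(0)), "overlap")
})

test_that("mean-rank set test matches limma geneSetTest at scale", {
  skip_if_not_installed("limma")
  set.seed(12)
  values <- setNames(rnorm(500), sprintf("g%03d", 1:500))
  set <- sample(names(values), 40)
  idx <- names(values) %in% set
  expect_equal(mean_rank_set_test(values, set, "up"),
               limma::geneSetTest(idx, values, alternative = "up",
                                  ranks.only = TRUE),
               tolerance = 0.01)
  expect_equal(mean_rank_set_test(values, set, "down"),
               limma::geneSetTest(idx, values, alternative = "down",
                                  ranks.only = TRUE),
               tolerance = 0.01)
})

test_that("up and down one-sided p-values are complementary", {
  set.seed(13)
  values <- setNames(rnorm(200), sprintf("g%03d", 1:200))
  set <- sample(names(values), 25)
  p_up <- mean_rank_set_test(values, set, "up")
  p_down <- mean_rank_set_test(values, set, "down")
  expect_lt(abs(p_up + p_down - 1), 0.02)
})

test_that("module DE calls planted directions across all studies", {
  cfg <- small_config()
  ref <- generate_reference_expression(cfg)
  studies <- generate_test_studies(cfg, ref$truth)
  de <- module_de(studies, ref$truth$module_labels)
  expect_equal(nrow(de), 3 * 3)
  expect_true(all(de$n_tests == 6))
  # planted: module 1 up, module 2 down in every study
  expect_true(all(de$direction[de$module == 1] == "up"))
  expect_true(all(de$direction[de$module == 2] == "down"))
  cons <- consensus_calls(de)
  expect_equal(cons$consensus[cons$module == 1], "consensus_up")
  expect_equal(cons$consensus[cons$module == 2], "consensus_down")
})

test_that("consensus labels follow the all/all-but-one rule", {
  fake <- function(dirs) {
    tibble::tibble(study_id = sprintf("s%d", seq_along(dirs)), module = 1,
                   direction = dirs)
  }
  expect_equal(consensus_calls(fake(rep("up", 5)))$consensus, "consensus_up")
  expect_equal(consensus_calls(fake(c(rep("up", 4), "none")))$consensus,
               "majority_up")
  expect_equal(consensus_calls(fake(c(rep("down", 3), "none", "none")))$consensus,
               "none")
  expect_equal(consensus_calls(fake(rep("down", 4)))$consensus,
               "consensus_down")
  # permutation-invariant in study order
  de <- fake(c("up", "none", "up", "up", "up"))
  expect_equal(consensus_calls(de)$consensus,
               consensus_calls(de[sample(5), ])$consensus)
  expect_error(consensus_calls(fake("up")), "2 studies")
})

test_that("temporal stratification flags the planted sign-flipping module", {
  cfg <- small_config(samples_per_study = 48)
  ref <- generate_reference_expression(cfg)
  studies <- generate_test_studies(cfg, ref$truth)
  tp <- suppressMessages(temporal_profiles(studies,
                                           ref$truth$module_labels))
  flips <- tp$flips
  expect_true(flips$flipped[flips$module == cfg$time_flip_module])
  expect_false(any(flips$flipped[flips$module != cfg$time_flip_module]))
  # studies without timepoints error
  s0 <- studies[[1]]
  s0$sample_meta$timepoint_days <- NA_real_
  expect_error(temporal_profiles(list(s0, studies[[2]]),
                                 ref$truth$module_labels), "timepoint")
})

test_that("severity scores have the defining sign and product structure", {
  # modules are a small fraction of the universe, as in genome-scale data,
  # so one strongly scored module cannot tilt the rank-test complement
  cfg <- small_config(n_genes = 300, module_sizes = c(25, 25, 25),
                      severity_samples_per_level = 10,
                      de_effect = c(2, -3, 2))
  ref <- generate_reference_expression(cfg)
  sev <- generate_severity_study(cfg, ref$truth)
  res <- severity_scores(sev, ref$truth$module_labels)
  gs <- res$gene_scores
  expect_equal(gs$score, gs$rho * (-log10(pmax(gs$p_value, 1e-300))),
               tolerance = 1e-12)
  expect_true(all(sign(gs$score) == sign(gs$rho) | gs$score == 0))

  # the coupled module (2, planted negative) is the sole anticorrelated
  # enrichment, and its eigengene has the maximal |rho|
  enr <- res$module_enrichment
  expect_lt(enr$p_anticorrelated_adj[enr$module == 2], 0.05)
  expect_true(all(enr$p_anticorrelated_adj[enr$module != 2] > 0.05))
  expect_true(all(enr$p_correlated_adj > 0.05))
  es <- res$eigengene_severity
  expect_equal(es$module[which.max(abs(es$rho))], 2)
  expect_error(severity_scores(ref$study, ref$truth$module_labels),
               "severity")
})

test_that("curated enrichment equals the hypergeometric tail sum", {
  # the 2x2 table (10, 40, 90, 4860) from a 5000-gene universe
  p_oracle <- oracle_fisher_greater(10, 40, 90, 4860)
  genes <- sprintf("g%04d", 1:5000)
  labels <- setNames(c(rep(1L, 50), rep(0L, 4950)), genes)
  curated <- c(genes[1:10], genes[51:140])
  res <- curated_enrichment(labels, curated, genes)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-10)
  expect_equal(res$n_overlap, 10)

  # curated set equal to the module gives the minimal possible p
  res_min <- curated_enrichment(labels, genes[1:50], genes)
  expect_equal(res_min$p_value,
               oracle_fisher_greater(50, 0, 0, 4950), tolerance = 1e-10)
  # disjoint curated set: p well above 0.5
  res_dis <- curated_enrichment(labels, genes[100:149], genes)
  expect_gte(res_dis$p_value, 0.5)
})

test_that("curated enrichment flags the planted target module end-to-end", {
  cfg <- small_config()
  ref <- generate_reference_expression(cfg)
  cur <- generate_curated_set(cfg, ref$truth)
  res <- curated_enrichment(ref$truth$module_labels, cur$genes)
  expect_lt(res$p_adj[res$module == 1], 0.05)     # target module
  expect_gt(min(res$p_adj[res$module != 1]), 0.05)
})

test_that("enrichment robustness reproduces the unperturbed test at f = 0", {
  cfg <- small_config()
  ref <- generate_reference_expression(cfg)
  cur <- generate_curated_set(cfg, ref$truth)
  labels <- ref$truth$module_labels
  base <- curated_enrichment(labels, cur$genes)
  rob <- enrichment_robustness(labels, cur$genes,
                               removal_grid = c(0, 0.5),
                               addition_grid = 0, n_boot = 5, rng_seed = 1)
  f0 <- rob$curves[rob$curves$fraction == 0 & rob$curves$mode == "removal", ]
  expect_equal(f0$median_p_adj[f0$module == 1],
               base$p_adj[base$module == 1], tolerance = 1e-12)
  # full removal is undefined and reported as NA
  rob1 <- enrichment_robustness(labels, cur$genes, removal_grid = 1,
                                addition_grid = numeric(0), n_boot = 3,
                                rng_seed = 1)
  expect_true(all(is.na(rob1$curves$median_p_adj)))
})

test_that("stronger planted enrichment survives more seed removal", {
  cfg <- small_config()
  ref <- generate_reference_expression(cfg)
  labels <- ref$truth$module_labels
  m1 <- names(labels)[labels == 1]
  other <- setdiff(names(labels), m1)
  set.seed(5)
  strength <- vapply(c(18, 24, 30), function(n_in) {
    cur <- c(sample(m1, n_in), sample(other, 40 - n_in))
    rob <- enrichment_robustness(labels, cur,
                                 removal_grid = seq(0, 0.9, 0.15),
                                 addition_grid = numeric(0),
                                 n_boot = 20, rng_seed = 2)
    bd <- rob$breakdown
    bd$breakdown_fraction[bd$module == 1 & bd$mode == "removal"]
  }, numeric(1))
  expect_true(all(diff(strength) >= 0))
  expect_gt(strength[3], strength[1])
})

test_that("a negated treatment reverses every consensus module", {
  cfg <- small_config()
  ref <- generate_reference_expression(cfg)
  studies <- generate_test_studies(cfg, ref$truth)
  de <- module_de(studies, ref$truth$module_labels)
  cons <- consensus_calls(de)

  # treatment constructed as the negation of the planted injury effect
  neg_cfg <- small_config(de_effect = -cfg$de_effect, rng_seed = 77)
  neg_study <- generate_test_studies(neg_cfg, ref$truth)[[1]]
  meta <- neg_study$sample_meta
  meta$condition <- ifelse(meta$condition == "injured", "treated", "control")
  treat <- expression_study(neg_study$expr, meta)

  rev_res <- reversal_test(treat, NULL, ref$truth$module_labels, cons,
                           groups = c("treated", "control"))
  expect_true(all(rev_res$reversed))
  expect_equal(attr(rev_res, "n_reversed"), nrow(rev_res))
  # eigengene Wilcoxon agrees with the base implementation run one-sidedly
  m <- rev_res$module[1]
  me <- module_eigengenes(treat, ref$truth$module_labels)$eigengenes
  idx <- treat$sample_meta$condition == "treated"
  alt <- if (rev_res$reversal_alternative[1] == "down") "less" else "greater"
  expect_equal(rev_res$p_eigengene_wilcoxon[1],
               wilcox.test(me[paste0("ME", m), idx],
                           me[paste0("ME", m), !idx],
                           alternative = alt)$p.value,
               tolerance = 1e-12)
})

test_that("an inert treatment shows chance-level concordance", {
  cfg <- small_config()
  ref <- generate_reference_expression(cfg)
  studies <- generate_test_studies(cfg, ref$truth)
  cons <- consensus_calls(module_de(studies, ref$truth$module_labels))
  null_cfg <- small_config(de_effect = 0, rng_seed = 55)
  inert <- generate_test_studies(null_cfg, ref$truth)[[1]]
  meta <- inert$sample_meta
  meta$condition <- ifelse(meta$condition == "injured", "treated", "control")
  inert <- expression_study(inert$expr, meta)
  rev_res <- reversal_test(inert, NULL, ref$truth$module_labels, cons,
                           groups = c("treated", "control"))
  expect_lte(attr(rev_res, "n_reversed"), 1)
})

test_that("eigengene Wilcoxon matches exhaustive small-sample enumeration", {
  set.seed(17)
  a <- rnorm(5); b <- rnorm(6) + 1
  # enumeration: all assignments of the pooled values into groups
  pooled <- c(a, b)
  r <- rank(pooled)
  obs <- sum(r[1:5])
  combos <- combn(11, 5)
  p_exact <- mean(apply(combos, 2, function(idx) sum(r[idx]) <= obs))
  expect_equal(wilcox.test(a, b, alternative = "less")$p.value, p_exact,
               tolerance = 1e-12)
})

test_that("Bonferroni adjustment records and applies the family size", {
  p <- c(0.01, 0.2, 0.9)
  adj <- scinet:::bonferroni(p, m = 6)
  expect_equal(unclass(adj), pmin(1, p * 6), ignore_attr = TRUE)
  expect_equal(attr(adj, "n_tests"), 6)
})
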