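test_that("bicor has the defining correlation properties", {
  set.seed(1)
  x <- rnorm(50)
  m <- rbind(a = x, b = x, c = -x)
  colnames(m) <- sprintf("s%02d", 1:50)
  r <- bicor(expression_study(m))
  expect_equal(unname(r["a", "b"]), 1, tolerance = 1e-12)
  expect_equal(unname(r["a", "c"]), -1, tolerance = 1e-12)
  expect_true(isSymmetric(unclass(r)))
  expect_true(all(r >= -1 & r <= 1))
  expect_error(bicor(expression_study(m[, 1:3])), "4 samples")
})

test_that("bicor converges to Pearson on clean bivariate normal data", {
  set.seed(4)
  diffs <- replicate(20, {
    z <- rnorm(100)
    a <- 0.6 * z + sqrt(1 - 0.36) * rnorm(100)
    m <- rbind(x = z, y = a)
    colnames(m) <- sprintf("s%03d", 1:100)
    abs(bicor(expression_study(m))["x", "y"] - cor(z, a))
  })
  expect_lt(max(diffs), 0.05)
})

test_that("bicor is robust to a single extreme outlier where Pearson is not", {
  set.seed(6)
  z <- rnorm(60)
  a <- 0.9 * z + sqrt(1 - 0.81) * rnorm(60)
  clean_p <- cor(z, a)
  a_cont <- a
  a_cont[1] <- 100 * max(abs(a))
  m <- rbind(x = z, y = a_cont)
  colnames(m) <- sprintf("s%02d", 1:60)
  b_cont <- bicor(expression_study(m))["x", "y"]
  expect_gt(abs(cor(z, a_cont) - clean_p), 0.3)  # Pearson is wrecked
  expect_lt(abs(b_cont - clean_p), 0.1)          # bicor barely moves
})

test_that("zero-MAD genes fall back to Pearson weighting", {
  # both rows have MAD 0 but are not constant: biweight weights would vanish,
  # so both must fall back to Pearson standardisation
  x <- c(rep(0, 30), 1:10)
  y <- 2 * x
  y[40] <- y[40] + 0.5
  m <- rbind(x = x, y = y)
  colnames(m) <- sprintf("s%02d", 1:40)
  r <- bicor(expression_study(m))
  expect_equal(unname(r["x", "y"]), cor(x, y), tolerance = 1e-12)
  expect_gt(r["x", "y"], 0.99)
})

test_that("signed adjacency follows its closed form and monotonicity", {
  cm <- matrix(c(1, 0, 0, 1), 2)
  expect_equal(adjacency_signed(cm, 5)[1, 2], 0.5^5)
  cm2 <- matrix(c(1, 1, 1, 1), 2)
  expect_equal(adjacency_signed(cm2, 7)[1, 2], 1)
  cm3 <- matrix(c(1, -1, -1, 1), 2)
  expect_equal(adjacency_signed(cm3, 3)[1, 2], 0)
  cors <- seq(-1, 1, by = 0.1)
  a <- ((1 + cors) / 2)^4
  expect_true(all(diff(a) > 0))
  expect_error(adjacency_signed(cm, 0.5), "beta")
})

test_that("TOM matches direct evaluation and a triple-loop oracle", {
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  tom <- tom_similarity(a)
  expect_equal(tom[1, 2], (0.25 + 0.5) / (1 + 1 - 0.5))
  # identical neighbourhoods and a_ij = 1 give TOM = 1
  a2 <- matrix(1, 3, 3)
  expect_equal(tom_similarity(a2)[1, 2], 1)
  set.seed(11)
  for (n in c(4, 6, 8)) {
    cm <- cor(matrix(rnorm(n * 20), 20, n))
    a <- adjacency_signed(cm, 3)
    expect_lt(max(abs(tom_similarity(a) - oracle_tom(a))), 1e-12)
  }
  tom_r <- tom_similarity(adjacency_signed(cor(matrix(rnorm(120), 20, 6)), 2))
  expect_true(isSymmetric(tom_r))
  expect_true(all(tom_r >= 0 & tom_r <= 1))
})

test_that("soft-threshold selection reproduces an independent binned fit", {
  cfg <- small_config()
  ref <- generate_reference_expression(cfg)
  cm <- bicor(ref$study)
  st <- suppressWarnings(pick_soft_threshold(cm, candidates = 1:12))
  # independent re-implementation of the binned regression
  oracle_fit <- function(cm, beta, n_bins = 10) {
    a <- ((1 + unclass(cm)) / 2)^beta
    diag(a) <- 1
    k <- rowSums(a) - 1
    br <- seq(min(k), max(k), length.out = n_bins + 1)
    bin <- cut(k, br, include.lowest = TRUE)
    cnt <- as.integer(table(bin))
    mid <- tapply(k, bin, mean)
    keep <- cnt > 0 & !is.na(mid) & mid > 0
    f <- stats::lm(log10(cnt[keep] / length(k)) ~ log10(mid[keep]))
    unname(-sign(coef(f)[2]) * summary(f)$r.squared)
  }
  for (b in c(1, 4, 8, 12)) {
    expect_equal(st$fit$scale_free_r2[st$fit$beta == b],
                 oracle_fit(cm, b), tolerance = 1e-10)
  }
  # mean connectivity decreases with beta
  expect_true(all(diff(st$fit$mean_connectivity) < 0))
  # r2_cut = 0 selects the smallest candidate
  expect_equal(pick_soft_threshold(cm, candidates = 1:5, r2_cut = -1)$beta, 1)
  expect_error(pick_soft_threshold(matrix(1, 4, 4)), "degenerate")
})

test_that("planted correlation blocks are recovered as modules", {
  set.seed(21)
  n_per <- 30; n_s <- 60
  e1 <- rnorm(n_s); e2 <- rnorm(n_s)
  block <- function(e, pre) {
    m <- t(sapply(seq_len(n_per), function(i) e + rnorm(n_s, sd = 0.33)))
    rownames(m) <- sprintf("%s%02d", pre, seq_len(n_per))
    m
  }
  x <- rbind(block(e1, "a"), block(e2, "b"))
  colnames(x) <- sprintf("s%02d", seq_len(n_s))
  tom <- tom_similarity(adjacency_signed(bicor(expression_study(x)), 5))
  labels <- cluster_modules(tom, min_size = 20)
  expect_equal(length(unique(labels[labels > 0])), 2)
  expect_equal(adjusted_rand_index(labels,
                                   rep(1:2, each = n_per)), 1)
  expect_true(all(table(labels[labels > 0]) >= 20))
})

test_that("pure noise yields (nearly) no module assignments", {
  set.seed(22)
  x <- matrix(rnorm(200 * 50), 200, 50,
              dimnames = list(sprintf("g%03d", 1:200),
                              sprintf("s%02d", 1:50)))
  tom <- tom_similarity(adjacency_signed(bicor(expression_study(x)), 5))
  labels <- cluster_modules(tom, min_size = 20)
  expect_lt(mean(labels > 0), 0.05)
})

test_that("eigengenes recover a rank-1 factor exactly", {
  set.seed(31)
  e <- rnorm(30)
  lambda <- runif(8, 0.5, 1.5)
  x <- outer(lambda, e)
  dimnames(x) <- list(sprintf("g%02d", 1:8), sprintf("s%02d", 1:30))
  st <- expression_study(x)
  me <- module_eigengenes(st, setNames(rep(1L, 8), rownames(x)))
  expect_equal(me$prop_var_explained[["ME1"]], 1, tolerance = 1e-12)
  expect_equal(abs(cor(me$eigengenes["ME1", ], e)), 1, tolerance = 1e-12)
  expect_equal(sqrt(sum(me$eigengenes["ME1", ]^2)), 1, tolerance = 1e-12)
  # sign convention: mean member correlation is positive
  expect_gt(mean(cor(me$eigengenes["ME1", ], t(st$expr))), 0)
})

test_that("eigengene computation agrees with a dense SVD oracle", {
  st <- toy_study(12, 25, seed = 41)
  labels <- setNames(rep(c(1L, 2L), each = 6), rownames(st$expr))
  me <- module_eigengenes(st, labels)
  for (m in 1:2) {
    sub <- t(scale(t(st$expr[labels == m, ])))
    sv <- svd(sub)
    v <- sv$v[, 1]
    if (mean(cor(v, t(sub))) < 0) v <- -v
    expect_equal(unname(me$eigengenes[paste0("ME", m), ]), unname(v),
                 tolerance = 1e-10)
    expect_equal(me$prop_var_explained[[paste0("ME", m)]],
                 sv$d[1]^2 / sum(sv$d^2), tolerance = 1e-12)
  }
  # a random module explains roughly 1/min(n_genes, n_samples) of variance
  expect_lt(me$prop_var_explained[["ME1"]], 0.5)
  expect_error(module_eigengenes(st, setNames(c(1L, rep(0L, 11)),
                                              rownames(st$expr))),
               "fewer than 2")
})

test_that("kME matches direct correlation with the eigengene", {
  set.seed(51)
  e <- rnorm(40)
  x <- rbind(pos = e, neg = -e + rnorm(40, sd = 0.1),
             noise = rnorm(40))
  colnames(x) <- sprintf("s%02d", 1:40)
  st <- expression_study(x)
  eig <- matrix(e / sqrt(sum(e^2)), 1, dimnames = list("ME1", colnames(x)))
  k <- kme(st, eig)
  expect_equal(unname(k["pos", 1]), 1, tolerance = 1e-12)
  expect_lt(k["neg", 1], -0.9)
  expect_equal(unname(k["noise", 1]), cor(x["noise", ], e),
               tolerance = 1e-12)
  # constant gene warns and gets kME 0
  x2 <- rbind(x, flat = rep(1, 40))
  expect_warning(k2 <- kme(expression_study(x2), eig), "constant")
  expect_equal(unname(k2["flat", 1]), 0)
})

test_that("modules from a shared latent factor are merged", {
  set.seed(61)
  e <- rnorm(50)
  x <- t(sapply(1:40, function(i) 0.9 * e + rnorm(50, sd = 0.3)))
  rownames(x) <- sprintf("g%02d", 1:40)
  colnames(x) <- sprintf("s%02d", 1:50)
  st <- expression_study(x)
  split_labels <- setNames(rep(c(1L, 2L), each = 20), rownames(x))
  merged <- merge_close_modules(split_labels, st, cut_height = 0.2)
  expect_equal(length(unique(merged[merged > 0])), 1)
  # orthogonal factors stay separate, and merging is idempotent
  e2 <- rnorm(50)
  y <- rbind(t(sapply(1:20, function(i) e + rnorm(50, sd = 0.2))),
             t(sapply(1:20, function(i) e2 + rnorm(50, sd = 0.2))))
  dimnames(y) <- dimnames(x)
  st2 <- expression_study(y)
  kept <- merge_close_modules(split_labels, st2, cut_height = 0.2)
  expect_equal(length(unique(kept[kept > 0])), 2)
  expect_identical(merge_close_modules(kept, st2, cut_height = 0.2), kept)
})

test_that("eigengene meta-network reflects shared latent structure", {
  set.seed(71)
  shared <- rnorm(60); own <- rnorm(60)
  e1 <- shared
  e2 <- 0.8 * shared + sqrt(1 - 0.64) * own
  e3 <- rnorm(60)
  eg <- rbind(ME1 = e1, ME2 = e2, ME3 = e3)
  colnames(eg) <- sprintf("s%02d", 1:60)
  en <- eigengene_network(eg)
  expect_true(isSymmetric(en$cor))
  expect_equal(unname(diag(en$cor)), rep(1, 3))
  expect_gt(en$cor["ME1", "ME2"], 0.5)
  expect_lt(abs(en$cor["ME1", "ME3"]), 0.4)
  expect_s3_class(en$dendrogram, "hclust")
  expect_error(eigengene_network(eg[1, , drop = FALSE]), "2 modules")
})

test_that("the full pipeline recovers planted modules with high ARI", {
  cfg <- small_config(module_signal = 0.9, noise_sd = 0.2)
  ref <- generate_reference_expression(cfg)
  part <- suppressWarnings(build_coexpression_network(ref$study))
  expect_gte(adjusted_rand_index(part$labels, ref$truth$module_labels), 0.9)
  expect_true(all(part$module_sizes >= 20))
  # eigengene sign convention holds for every module
  for (m in names(part$module_sizes)) {
    members <- names(part$labels)[part$labels == as.integer(m)]
    expect_gte(mean(part$kme[members, paste0("ME", m)]), 0)
  }
  expect_true(all(part$prop_var_explained >= 0 &
                    part$prop_var_explained <= 1))
})

test_that("adjusted Rand index agrees with mclust", {
  skip_if_not_installed("mclust")
  set.seed(81)
  for (i in 1:5) {
    a <- sample(0:3, 60, replace = TRUE)
    b <- sample(0:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})
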