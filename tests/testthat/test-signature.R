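# Per-gene statistics, selection gates, cross-validation, weighting, QC.

test_that("log2 fold change follows the pseudocount formula", {
  expect_equal(log2_fold_change(c(7, 7), c(1, 1)), 2)          # log2(8/2)
  expect_equal(log2_fold_change(1:5, 1:5), 0)                  # symmetry
  a <- rexp(4) * 10; b <- rexp(6) * 10
  expect_equal(log2_fold_change(a, b), -log2_fold_change(b, a))
  expect_error(log2_fold_change(numeric(0), 1), "empty")
})

test_that("Welch t-test matches reference values and conventions", {
  res <- welch_t(c(10, 12, 14), c(20, 22, 24))
  expect_equal(res$t_stat, -6.1237, tolerance = 1e-4)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 0.0036, tolerance = 0.01)
  # identical groups: no effect
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)
  # both groups constant with equal means: p = 1 by convention
  expect_equal(welch_t(c(5, 5), c(5, 5))$p_value, 1)
  expect_error(welch_t(c(5, 5), c(7, 7)), "constant")
  # scale invariance of the statistic
  expect_equal(welch_t(c(10, 12, 14) * 10, c(20, 22, 24) * 10)$t_stat,
               res$t_stat)
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
})

test_that("BH adjustment reproduces the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.002)),
               c(0.02, 0.04, 0.04, 0.008))
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("roc_auc equals brute-force pair counting, ties counted half", {
  expect_equal(roc_auc(c(5, 6, 7), c(1, 2, 3)), 1)
  expect_equal(roc_auc(c(1, 3), c(2, 4)), 0.25)
  expect_equal(roc_auc(c(2, 3), c(1, 2)), 0.875)
  set.seed(42)
  for (nd in c(1, 3, 5, 8)) for (nh in c(1, 4, 8)) {
    d <- sample(1:6, nd, replace = TRUE)   # coarse grid forces ties
    h <- sample(1:6, nh, replace = TRUE)
    expect_equal(roc_auc(d, h), brute_force_auc(d, h))
  }
})

test_that("roc_auc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  d <- rnorm(15, 1); h <- rnorm(12)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = rep(c(1, 0), c(15, 12)), predictor = c(d, h),
    direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(d, h), ref)
})

test_that("preliminary selection is the intersection of its three gates", {
  stats <- data.frame(
    gene = c("pass", "lowfc", "flip"),
    log2fc = c(0.8, 0.5, -0.9),
    t_stat = 0, p_value = 0.01,
    fdr = c(0.01, 0.001, 0.04),
    auc = c(0.75, 0.99, 0.29))   # 0.29 oriented -> 0.71
  expect_setequal(select_preliminary_tds(stats), c("pass", "flip"))
  # removing any gate only enlarges the selection
  set.seed(1)
  rnd <- data.frame(gene = paste0("g", 1:200),
                    log2fc = rnorm(200), t_stat = 0,
                    p_value = runif(200), fdr = runif(200),
                    auc = runif(200))
  full <- select_preliminary_tds(rnd)
  expect_true(all(full %in% select_preliminary_tds(rnd, lfc = 0)))
  expect_true(all(full %in% select_preliminary_tds(rnd, fdr = 1)))
  expect_true(all(full %in% select_preliminary_tds(rnd, auc = 0.5)))
})

test_that("cross-validation keeps consistent-direction, high-AUC genes", {
  mk <- function(gene, lfc, auc) data.frame(gene = gene, log2fc = lfc,
                                            t_stat = 0, p_value = 0.01,
                                            fdr = 0.01, auc = auc)
  t1 <- mk(c("keep", "flip", "weak"), c(0.5, 0.5, 0.4), c(0.75, 0.9, 0.65))
  t2 <- mk(c("keep", "flip", "weak"), c(0.3, -0.2, 0.5), c(0.65, 0.9, 0.66))
  v <- cross_validate_panel(t1, t2)
  expect_equal(v$gene, "keep")
  expect_warning(
    cross_validate_panel(t1, t2[1:2, ], candidates = c("keep", "weak")),
    "weak")
})

test_that("weights are 2 for double-high-AUC genes, else the best AUC", {
  v <- data.frame(gene = c("both_high", "one_high", "edge"),
                  log2fc1 = c(1, 0.8, -0.9), log2fc2 = c(1.2, 0.6, -0.7),
                  auc1 = c(0.85, 0.75, 0.85), auc2 = c(0.90, 0.68, 0.78))
  panel <- assign_weights(v)
  expect_equal(panel$weight, c(2, 0.75, 0.85))
  expect_equal(panel$ref_direction, c(1L, 1L, -1L))
  expect_equal(panel$ref_log2fc, c(1.1, 0.7, -0.8))
})

test_that("gene_stats computes the per-gene table on a labelled cohort", {
  sc <- scored_cohort(seed = 21, n_wt = 6, n_disease = 6)
  st <- gene_stats(sc$norm$table, sc$cohort$annotation, sc$cohort$sheet,
                   classes = "tds")
  expect_equal(nrow(st), 97)
  expect_true(all(st$fdr >= 0 & st$fdr <= 1))
  expect_true(all(st$auc >= 0 & st$auc <= 1))
  # strong fully-penetrant genes should separate in the disease direction
  g <- sc$cohort$truth$genes
  strong <- g$gene[g$penetrance > 0.95 & g$delta > 2]
  if (length(strong)) {
    i <- match(strong, st$gene)
    expect_true(all(sign(st$log2fc[i]) == g$direction[match(strong, g$gene)]))
  }
})

test_that("panel building recovers strong penetrant genes, not null genes", {
  hits <- 0L; total <- 0L
  for (seed in 1:5) {
    cfg1 <- sim_config(seed = seed * 100)
    co1 <- simulate_cohort(cfg1)
    cfg2 <- sim_config(seed = seed * 100 + 1, n_wt = 15, n_disease = 15)
    co2 <- simulate_cohort(cfg2, truth = co1$truth)
    n1 <- normalize_pipeline(co1$counts, co1$annotation)$table
    n2 <- normalize_pipeline(co2$counts, co2$annotation)$table
    built <- build_panel(n1, co1$sheet, n2, co2$sheet, co1$annotation)
    g <- co1$truth$genes
    strong <- g$gene[g$penetrance >= 0.9 & g$delta >= 1.5]
    hits <- hits + sum(strong %in% built$panel$gene)
    total <- total + length(strong)
    # weight-2 genes are enriched for high penetrance
    w2 <- built$panel$gene[built$panel$weight == 2]
    if (length(w2) >= 5) {
      pen <- g$penetrance[match(built$panel$gene, g$gene)]
      expect_gt(mean(pen[built$panel$weight == 2]),
                mean(pen))
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("an effect-free cohort yields only FDR-level selections", {
  cfg <- sim_config(seed = 31, effect_log2_range = c(0, 0))
  co <- simulate_cohort(cfg)
  norm <- normalize_pipeline(co$counts, co$annotation)$table
  st <- gene_stats(norm, co$annotation, co$sheet, classes = "tds")
  expect_lte(length(select_preliminary_tds(st)), ceiling(0.05 * 97))
})

test_that("spearman matrix is rank-invariant, symmetric, unit-diagonal", {
  m <- matrix(c(1, 2, 3, 4,
                10, 20, 30, 40,     # monotone transform of s1
                4, 3, 2, 1), nrow = 4,
              dimnames = list(paste0("p", 1:4), c("s1", "s2", "s3")))
  res <- spearman_matrix(count_table(m, stage = "hk_normalized"))
  cc <- res$correlation
  expect_equal(cc, t(cc))
  expect_equal(unname(diag(cc)), rep(1, 3))
  expect_equal(cc["s1", "s2"], 1)    # rank invariance
  expect_equal(cc["s1", "s3"], -1)   # reversed ranks
  expect_setequal(res$dendrogram_order, c("s1", "s2", "s3"))
  # constant sample: undefined correlation recorded as missing
  m2 <- m; m2[, 2] <- 7
  expect_warning(res2 <- spearman_matrix(count_table(m2, stage = "hk_normalized")),
                 "constant")
  expect_true(anyNA(res2$correlation["s2", ]))
})
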