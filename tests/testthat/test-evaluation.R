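test_that("balanced accuracy matches hand-derived values", {
  expect_equal(balanced_accuracy(c(0, 0, 0, 1), c(0, 0, 1, 1)),
               (2 / 3 + 1) / 2)
  expect_equal(balanced_accuracy(c(0, 0, 0, 1), c(0, 0, 1, 1)), 0.8333,
               tolerance = 1e-4)
  y <- rep(c("cancer", "control"), c(8, 2))
  expect_equal(balanced_accuracy(y, y), 1)
  expect_equal(balanced_accuracy(y, rep("cancer", 10)), 0.5)
  expect_error(balanced_accuracy(rep(1, 5), rep(1, 5)), "both classes")
})

test_that("balanced accuracy is invariant under a joint class swap", {
  withr::with_seed(3, {
    for (i in 1:20) {
      y <- rbinom(30, 1, 0.5); p <- rbinom(30, 1, 0.5)
      if (length(unique(y)) < 2) next
      expect_equal(balanced_accuracy(y, p), balanced_accuracy(1 - y, 1 - p))
    }
  })
})

test_that("AUC matches brute-force pair counting, ties included", {
  expect_equal(roc_auc(c(0, 1, 0, 1), c(0.1, 0.9, 0.4, 0.35))$auc, 0.75)
  withr::with_seed(42, {
    for (i in 1:200) {
      n <- sample(4:50, 1)
      y <- c(0, 1, rbinom(n - 2, 1, 0.5))
      s <- sample(round(runif(n), 2))     # coarse grid forces ties
      expect_identical(roc_auc(y, s)$auc, auc_pairs(y, s))
    }
  })
})

test_that("AUC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(7, {
    y <- rbinom(80, 1, 0.4)
    s <- rnorm(80) + y
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
    expect_equal(roc_auc(y, s)$auc, ref, tolerance = 1e-12)
  })
})

test_that("ROC points run monotonically from (0,0) to (1,1)", {
  withr::with_seed(9, {
    y <- rbinom(60, 1, 0.5); s <- round(rnorm(60), 1)
    r <- roc_auc(y, s)$roc
    expect_equal(unlist(r[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r[nrow(r), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(r$fpr) >= 0))
    expect_true(all(diff(r$tpr) >= 0))
  })
  expect_warning(a <- roc_auc(c(0, 1, 0, 1), rep(0.4, 4)), "constant")
  expect_equal(a$auc, 0.5)
})

test_that("stratified split honours the 30% / 5-fold arithmetic", {
  labels <- setNames(rep(c("cancer", "control"), each = 100),
                     paste0("S", 1:200))
  sp <- stratified_split(labels, seed = 2)
  test_lab <- labels[sp$test_ids]
  expect_identical(sum(test_lab == "cancer"), 30L)
  expect_identical(sum(test_lab == "control"), 30L)
  expect_length(sp$folds, 5L)
  for (f in sp$folds) {
    expect_identical(sum(labels[f] == "cancer"), 14L)
    expect_identical(sum(labels[f] == "control"), 14L)
  }
  # partitions are disjoint and exhaustive
  all_ids <- c(sp$test_ids, unlist(sp$folds))
  expect_setequal(all_ids, names(labels))
  expect_identical(anyDuplicated(all_ids), 0L)
})

test_that("test_frac = 0 puts everything in the folds", {
  labels <- setNames(rep(c("cancer", "control"), c(40, 30)), paste0("S", 1:70))
  sp <- stratified_split(labels, test_frac = 0, seed = 1)
  expect_length(sp$test_ids, 0L)
  expect_setequal(unlist(sp$folds), names(labels))
})

test_that("per-class test proportion is within one sample of the target", {
  withr::with_seed(10, {
    for (i in 1:10) {
      n1 <- sample(20:80, 1); n0 <- sample(20:80, 1)
      labels <- setNames(sample(rep(c("cancer", "control"), c(n1, n0))),
                         paste0("S", seq_len(n1 + n0)))
      sp <- stratified_split(labels, test_frac = 0.3, seed = i)
      t1 <- sum(labels[sp$test_ids] == "cancer")
      t0 <- sum(labels[sp$test_ids] == "control")
      expect_lte(abs(t1 - 0.3 * n1), 1)
      expect_lte(abs(t0 - 0.3 * n0), 1)
      for (f in sp$folds) {
        p_f <- mean(labels[f] == "cancer")
        p_g <- n1 / (n1 + n0)
        expect_lte(abs(p_f * length(f) - p_g * length(f)), 2)
      }
    }
  })
  expect_error(stratified_split(setNames(rep(c("cancer", "control"), c(5, 50)),
                                         paste0("S", 1:55))),
               ">= 10")
})

test_that("location split separates sites and reports exclusions", {
  meta <- data.frame(sample_id = paste0("S", 1:60),
                     label = rep(c("cancer", "control"), 30),
                     cohort = "c",
                     site = rep(c("A", "B", "C", "D"), each = 15))
  sp <- location_split(meta, c("A", "B"), "C")
  expect_length(intersect(sp$train_ids, sp$test_ids), 0L)
  expect_setequal(sp$test_ids, meta$sample_id[meta$site == "C"])
  expect_setequal(sp$excluded, meta$sample_id[meta$site == "D"])
  expect_error(location_split(meta, c("A", "B", "C", "D"), "E"),
               "test sites")
  expect_error(location_split(meta, "A", "A"), "disjoint")
  # per-site counts recoverable from the generator's assignment
  st <- small_study(seed = 33)
  sites <- sort(unique(st$prep$expr$meta$site))
  sp2 <- location_split(st$prep$expr$meta, sites[1:2], sites[3:4])
  truth_sites <- st$truth$site_assignment[sp2$test_ids]
  expect_true(all(truth_sites %in% sites[3:4]))
})

test_that("model comparison reports models x repeats x partitions", {
  st <- small_study(seed = 40)
  rep <- run_model_comparison(st$prep$expr, st$db, st$split,
                              models = "boosting", repeats = 2,
                              search = fast_search(n = 2))
  expect_identical(nrow(rep$results), 2L * 2L)
  expect_setequal(unique(rep$results$partition), c("cv_validation", "test"))
  expect_true(all(rep$results$auc >= 0 & rep$results$auc <= 1))
  expect_true(all(rep$results$bal_acc >= 0 & rep$results$bal_acc <= 1))
  # planted signal is strong: held-out AUC high for every repeat
  expect_true(all(rep$results$auc[rep$results$partition == "test"] > 0.9))
})

test_that("group ablation emits one report per group plus the baseline", {
  st <- small_study(seed = 41)
  rep <- suppressMessages(run_group_ablation(st$prep$expr, st$db, st$split,
                                             search = fast_search(n = 2)))
  expect_identical(nrow(rep$results), 9L)
  expect_identical(rep$results$group[1], "all_groups")
  expect_setequal(rep$results$group[-1], kegg_groups())
})

test_that("feature sweep truncates oversized budgets and keeps full-model AUC", {
  st <- small_study(seed = 42)
  n_feat <- length(preselect_features(st$db, st$prep$expr))
  expect_warning(
    rep <- run_feature_sweep(st$prep$expr, st$db, st$split,
                             counts = c(10, n_feat + 1000),
                             rounds_per_count = 3,
                             search = fast_search(n = 2)),
    "truncated")
  expect_identical(rep$results$k, c(10, n_feat))
  full_auc <- rep$results$test_auc[2]
  cmp <- run_model_comparison(st$prep$expr, st$db, st$split,
                              models = "boosting", repeats = 1,
                              search = fast_search(n = 2))
  base_auc <- cmp$results$auc[cmp$results$partition == "test"]
  expect_lte(abs(full_auc - base_auc), 0.02)
})

test_that("experiment runners never leak test samples into training", {
  st <- small_study(seed = 43)
  sp <- st$split
  sp$folds[[1]] <- c(sp$folds[[1]], sp$test_ids[1])   # corrupt on purpose
  sp$train_ids <- unlist(sp$folds)
  expect_error(run_model_comparison(st$prep$expr, st$db, sp,
                                    models = "boosting", repeats = 1,
                                    search = fast_search(n = 2)),
               "leakage")
})
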