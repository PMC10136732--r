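test_that("invalid configurations fail naming the offending field", {
  expect_error(synthetic_config(n_cancer = 0), "n_cancer")
  expect_error(synthetic_config(fold_change_range = c(0.5, 2)),
               "fold_change_range")
  expect_error(synthetic_config(n_informative = 50, n_variants = 10),
               "n_informative")
  expect_error(synthetic_config(dispersion = -1), "dispersion")
  expect_error(synthetic_config(pathway_size_range = c(5, 1e6)),
               "pathway_size_range")
})

test_that("identical config and seed give bit-identical output", {
  cfg <- synthetic_config(n_cancer = 30, n_control = 20, n_variants = 50,
                          n_informative = 5, seed = 42)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$counts$meta, b$counts$meta)
  expect_identical(a$truth, b$truth)
  d <- simulate_counts(synthetic_config(n_cancer = 30, n_control = 20,
                                        n_variants = 50, n_informative = 5,
                                        seed = 43))
  expect_false(identical(a$counts$counts, d$counts$counts))
})

test_that("generated label counts equal the configured counts exactly", {
  cfg <- synthetic_config(n_cancer = 37, n_control = 23, n_variants = 40,
                          n_informative = 4, seed = 5)
  sim <- simulate_counts(cfg)
  expect_identical(sum(sim$counts$meta$label == "cancer"), 37L)
  expect_identical(sum(sim$counts$meta$label == "control"), 23L)
})

test_that("without a planted effect the class means agree within sampling error", {
  cfg <- synthetic_config(n_cancer = 300, n_control = 300, n_variants = 200,
                          n_informative = 10, fold_change_range = c(1, 1),
                          dispersion = 0.1, library_size_log_sd = 0,
                          seed = 8)
  sim <- simulate_counts(cfg)
  k <- sim$counts$counts
  cancer <- sim$counts$meta$label == "cancer"
  lfc <- log2(rowMeans(k[, cancer]) + 0.5) - log2(rowMeans(k[, !cancer]) + 0.5)
  expect_lt(median(abs(lfc)), 0.1)
  expect_lt(max(abs(lfc)), 0.75)
})

test_that("zero dispersion yields Poisson counts (variance ~ mean)", {
  cfg <- synthetic_config(n_cancer = 500, n_control = 500, n_variants = 100,
                          n_informative = 0, fold_change_range = c(1, 1),
                          dispersion = 0, library_size_log_sd = 0, seed = 3)
  sim <- simulate_counts(cfg)
  k <- sim$counts$counts
  ratio <- apply(k, 1, var) / rowMeans(k)
  expect_lt(abs(median(ratio) - 1), 0.1)
})

test_that("moment-based fold-change estimates recover the planted truth", {
  cfg <- synthetic_config(n_cancer = 400, n_control = 400, n_variants = 2000,
                          n_informative = 100, fold_change_range = c(2, 3),
                          dispersion = 0.2, library_size_log_sd = 0, seed = 7)
  sim <- simulate_counts(cfg)
  k <- sim$counts$counts
  cancer <- sim$counts$meta$label == "cancer"
  info <- sim$truth$informative_variants
  est <- rowMeans(k[info, cancer]) / rowMeans(k[info, !cancer])
  rel_err <- abs(est - sim$truth$fold_change) / sim$truth$fold_change
  expect_lt(median(rel_err), 0.15)
  # magnitudes are in range, directions balanced by construction
  expect_true(all(sim$truth$fold_change_magnitude >= 2 &
                    sim$truth$fold_change_magnitude <= 3))
  expect_setequal(unique(sim$truth$direction), c(-1, 1))
})

test_that("method-of-moments dispersion recovery at the study scale", {
  errs <- vapply(1:3, function(s) {
    cfg <- synthetic_config(n_cancer = 200, n_control = 200, n_variants = 500,
                            n_informative = 0, fold_change_range = c(1, 1),
                            dispersion = 0.2, seed = s)
    sim <- simulate_counts(cfg)
    sf <- size_factors(sim$counts)
    abs(estimate_dispersion(sim$counts, sf) - 0.2) / 0.2
  }, numeric(1))
  expect_lt(median(errs), 0.2)
})

test_that("site and label are independent unless the confound flag is set", {
  ps <- vapply(1:8, function(s) {
    cfg <- synthetic_config(n_cancer = 150, n_control = 150, n_variants = 10,
                            n_informative = 0, fold_change_range = c(1, 1),
                            n_sites = 3, n_pathways = 8,
                            pathway_size_range = c(2, 3), seed = s)
    sim <- simulate_counts(cfg)
    suppressWarnings(
      chisq.test(table(sim$counts$meta$label, sim$counts$meta$site))$p.value)
  }, numeric(1))
  expect_gt(min(ps), 0.001)           # no systematic association
  expect_gt(mean(ps > 0.05), 0.5)     # p-values behave like a uniform draw
  cfg <- synthetic_config(n_cancer = 200, n_control = 200, n_variants = 10,
                          n_informative = 0, fold_change_range = c(1, 1),
                          n_sites = 4, confound_site_with_label = TRUE,
                          n_pathways = 8, pathway_size_range = c(2, 3),
                          seed = 1)
  sim <- simulate_counts(cfg)
  p <- suppressWarnings(
    chisq.test(table(sim$counts$meta$label, sim$counts$meta$site))$p.value)
  expect_lt(p, 1e-6)
})

test_that("annotation exercises both filters with exact duplicate counts", {
  cfg <- synthetic_config(n_variants = 1000, n_informative = 10, seed = 2)
  an <- generate_annotation(cfg, fraction_duplicates = 0.1,
                            fraction_non_known = 0.2)
  expect_identical(nrow(an), 1000L)
  expect_false(anyDuplicated(an$variant_id) > 0)
  dup_genes <- table(an$gene_name)
  expect_identical(sum(dup_genes == 2), 100L)
  expect_identical(sum(dup_genes > 2), 0L)
  expect_identical(sum(an$status != "known"), 200L)

  clean <- generate_annotation(cfg, fraction_duplicates = 0,
                               fraction_non_known = 0)
  expect_true(all(clean$status == "known"))
  expect_false(anyDuplicated(clean$gene_name) > 0)
  all_nk <- generate_annotation(cfg, fraction_non_known = 1)
  expect_identical(sum(all_nk$status == "known"), 0L)
})

test_that("pathway database honours the informative-membership guarantees", {
  cfg <- synthetic_config(n_cancer = 30, n_control = 30, n_variants = 300,
                          n_informative = 30, n_pathways = 16,
                          pathway_size_range = c(4, 8),
                          frac_informative_in_pathways = 1, seed = 4)
  sim <- simulate_counts(cfg)
  an <- generate_annotation(cfg, fraction_duplicates = 0,
                            fraction_non_known = 0)
  db <- generate_pathway_db(cfg, an, sim$truth)
  member_genes <- unique(unlist(db$members))
  info <- informative_genes(sim$truth, an)
  expect_true(all(info %in% member_genes))

  cfg0 <- synthetic_config(n_cancer = 30, n_control = 30, n_variants = 300,
                           n_informative = 30, n_pathways = 16,
                           pathway_size_range = c(4, 8),
                           frac_informative_in_pathways = 0, seed = 4)
  db0 <- generate_pathway_db(cfg0, an, sim$truth)
  expect_length(intersect(informative_genes(sim$truth, an),
                          unlist(db0$members)), 0)
})

test_that("group tags cycle so every group ablation arm is non-empty", {
  st <- small_study(seed = 9)
  expect_setequal(unique(st$db$group), kegg_groups())
  for (g in kegg_groups())
    expect_gt(length(subset_group(st$db, g)), 0)
})
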