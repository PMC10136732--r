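test_that("class weights equalize the weighted class masses", {
  w <- class_weights(rep(c("cancer", "control"), each = 25))
  expect_equal(unname(w), c(1, 1))
  # the real cohort's imbalance: 720 cancer / 422 control
  w2 <- class_weights(rep(c("cancer", "control"), c(720, 422)))
  expect_equal(w2[["cancer"]], 1142 / 1440, tolerance = 1e-12)
  expect_equal(w2[["control"]], 1142 / 844, tolerance = 1e-12)
  expect_equal(w2[["cancer"]], 0.7931, tolerance = 1e-4)
  expect_equal(w2[["control"]], 1.3531, tolerance = 1e-4)
  expect_equal(720 * w2[["cancer"]], 422 * w2[["control"]])
  expect_error(class_weights(rep("cancer", 10)), "both classes")
})

test_that("random search draws are reproducible and within ranges", {
  sc <- search_config(n_settings = 25, seed = 9)
  a <- draw_search_settings(sc)
  b <- draw_search_settings(sc)
  expect_identical(a, b)
  expect_true(all(a$learning_rate >= 0.01 & a$learning_rate <= 0.3))
  expect_true(all(a$max_depth %in% 2:8))
  expect_true(all(a$n_estimators >= 50 & a$n_estimators <= 1000))
  expect_true(all(a$feature_dropout >= 0.1 & a$feature_dropout <= 1))
  expect_false(identical(a, draw_search_settings(search_config(n_settings = 25,
                                                               seed = 10))))
})

make_separable <- function(n = 120, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c("cancer", "control"), length.out = n)
    x <- cbind(f1 = ifelse(y == "cancer", 1, 0) + rnorm(n, 0, 0.01),
               f2 = rnorm(n))
    rownames(x) <- paste0("S", seq_len(n))
    list(x = x, y = setNames(y, rownames(x)))
  })
}

test_that("boosting separates separable data and is seed-reproducible", {
  d <- make_separable()
  val <- rownames(d$x)[1:30]
  m1 <- train_boosting(d$x, d$y, val, fast_search(seed = 3))
  expect_equal(m1$val_auc, 1.0)
  m2 <- train_boosting(d$x, d$y, val, fast_search(seed = 3))
  expect_identical(m1$setting, m2$setting)
  expect_identical(predict_proba(m1, d$x), predict_proba(m2, d$x))
  # training-set self-prediction all correct at the 0.5 threshold
  p <- predict_proba(m1, d$x)
  expect_equal(balanced_accuracy(d$y, ifelse(p >= 0.5, "cancer", "control")), 1)
})

test_that("boosting on permuted labels hovers at chance", {
  aucs <- vapply(1:5, function(s) {
    withr::with_seed(s, {
      n <- 160
      x <- matrix(rnorm(n * 12), n, dimnames = list(paste0("S", 1:n),
                                                    paste0("f", 1:12)))
      y <- setNames(sample(rep(c("cancer", "control"), each = n / 2)),
                    rownames(x))
      test_ids <- rownames(x)[1:40]
      val_ids <- rownames(x)[41:80]
      m <- train_boosting(x[-(1:40), ], y, val_ids, fast_search(seed = s, n = 2))
      roc_auc(y[test_ids], predict_proba(m, x[test_ids, ]))$auc
    })
  }, numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("predict_proba is keyed by feature id, not position", {
  d <- make_separable()
  m <- train_boosting(d$x, d$y, rownames(d$x)[1:30], fast_search())
  p0 <- predict_proba(m, d$x)
  expect_identical(predict_proba(m, d$x[, c("f2", "f1")]), p0)
  expect_error(predict_proba(m, `colnames<-`(d$x, c("f1", "weird"))),
               "unknown feature")
  expect_error(predict_proba(m, d$x[, "f1", drop = FALSE]),
               "missing feature")
  dup <- d$x[c(1, 1, 2), ]
  rownames(dup) <- c("a", "b", "c")
  pd <- predict_proba(m, dup)
  expect_equal(unname(pd[1]), unname(pd[2]))
  expect_true(all(p0 >= 0 & p0 <= 1))
})

test_that("gain importance ranks a single informative feature first", {
  hits <- vapply(1:5, function(s) {
    withr::with_seed(s, {
      n <- 200
      x <- matrix(rnorm(n * 20), n, dimnames = list(paste0("S", 1:n),
                                                    paste0("f", 1:20)))
      y <- ifelse(x[, "f7"] + rnorm(n, 0, 0.3) > 0, "cancer", "control")
      names(y) <- rownames(x)
      m <- train_boosting(x, y, rownames(x)[1:50], fast_search(seed = s, n = 2))
      feature_importance(m)$feature[1] == "f7"
    })
  }, logical(1))
  expect_gte(sum(hits), 3)               # majority over seeds
})

test_that("importance scores are sorted, normalized and zero-padded", {
  d <- make_separable(n = 150, seed = 4)
  m <- train_boosting(d$x, d$y, rownames(d$x)[1:30], fast_search(seed = 2))
  imp <- feature_importance(m)
  expect_identical(sort(imp$feature), sort(m$feature_ids))
  expect_true(all(diff(imp$importance[imp$importance > 0]) <= 0))
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  # essentially all the gain sits on the separating feature
  expect_gt(imp$importance[imp$feature == "f1"], 0.9)
})

test_that("class weighting does not hurt minority recall on imbalanced data", {
  # 90/10 imbalance, separable with noise; paired comparison over seeds
  deltas <- vapply(1:5, function(s) {
    withr::with_seed(s, {
      n <- 200
      y <- rep(c("cancer", "control"), c(180, 20))
      x <- cbind(f1 = ifelse(y == "cancer", 0.6, -0.6) + rnorm(n, 0, 1),
                 f2 = rnorm(n))
      rownames(x) <- paste0("S", seq_len(n))
      names(y) <- rownames(x)
      test_ids <- c(paste0("S", 121:180), paste0("S", 191:200))
      train_ids <- setdiff(rownames(x), test_ids)
      val_ids <- train_ids[seq(1, length(train_ids), by = 4)]
      m <- train_boosting(x[train_ids, ], y, val_ids, fast_search(seed = s, n = 2))
      p <- predict_proba(m, x[test_ids, ])
      yb <- y[test_ids] == "control"
      rec_w <- mean(p[yb] < 0.5)
      # unweighted xgboost fit, same hyperparameters
      d <- xgboost::xgb.DMatrix(x[setdiff(train_ids, val_ids), ],
                                label = as.integer(y[setdiff(train_ids, val_ids)] == "cancer"),
                                nthread = 1)
      bst <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                              nthread = 1, seed = s),
                                data = d, nrounds = 60, verbose = 0)
      pu <- predict(bst, x[test_ids, ])
      rec_u <- mean(pu[yb] < 0.5)
      rec_w - rec_u
    })
  }, numeric(1))
  expect_gte(mean(deltas), 0)
})

make_images <- function(n = 80, H = 8, W = 6, signal = TRUE, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c("cancer", "control"), length.out = n)
    vals <- array(runif(H * W * n, 0, 0.4), c(H, W, n))
    if (signal)                           # planted bright block for cancer
      vals[2:4, 2:4, y == "cancer"] <- vals[2:4, 2:4, y == "cancer"] + 0.5
    ids <- paste0("S", seq_len(n))
    dimnames(vals) <- list(NULL, NULL, ids)
    cg <- matrix(paste0("g", seq_len(H * W)), H, W)
    structure(list(values = vals, cell_gene = cg,
                   pathway_id = paste0("P", seq_len(H)),
                   group = rep_len(kegg_groups(), H),
                   scale = c(min = 0, max = 1), sample_ids = ids,
                   meta = data.frame(sample_id = ids, label = y,
                                     cohort = "c", site = "s")),
              class = "tep_images")
  })
}

test_that("the CNN learns planted image signal within 50 epochs", {
  imgs <- make_images(n = 100, seed = 2)
  y <- setNames(imgs$meta$label, imgs$sample_ids)
  val <- imgs$sample_ids[seq(1, 100, by = 5)]
  m <- train_implatelet(imgs, y, val, epochs = 50, seed = 1)
  expect_gte(m$val_auc, 0.95)
  p <- predict_proba(m, imgs)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("the CNN is at chance on permuted labels", {
  aucs <- vapply(1:3, function(s) {
    imgs <- make_images(n = 60, signal = FALSE, seed = s)
    y <- withr::with_seed(s, setNames(sample(imgs$meta$label),
                                      imgs$sample_ids))
    val <- imgs$sample_ids[1:20]
    m <- train_implatelet(imgs, y, val, epochs = 10, seed = s)
    m$val_auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.25)
  expect_lt(mean(aucs), 0.75)
})

test_that("CNN training is deterministic for a fixed seed", {
  imgs <- make_images(n = 40, seed = 5)
  y <- setNames(imgs$meta$label, imgs$sample_ids)
  val <- imgs$sample_ids[1:10]
  m1 <- train_implatelet(imgs, y, val, epochs = 3, seed = 7)
  m2 <- train_implatelet(imgs, y, val, epochs = 3, seed = 7)
  expect_identical(m1$par, m2$par)
  expect_identical(predict_proba(m1, imgs), predict_proba(m2, imgs))
})

test_that("model contract errors are informative", {
  imgs <- make_images(n = 30)
  y <- setNames(imgs$meta$label, imgs$sample_ids)
  m <- train_implatelet(imgs, y, imgs$sample_ids[1:8], epochs = 2, seed = 1)
  bad <- make_images(n = 5, H = 10, W = 6)
  expect_error(predict_proba(m, bad), "shape")
  expect_error(feature_importance(m), "boosting")
  small <- make_images(n = 20, H = 4, W = 4)
  expect_error(train_implatelet(small, y[1:20], imgs$sample_ids[1:4],
                                epochs = 1, seed = 1), "5 x 5")
})

test_that("constant features trigger a warning but training proceeds", {
  n <- 60
  x <- matrix(1, n, 3, dimnames = list(paste0("S", 1:n), paste0("f", 1:3)))
  y <- setNames(rep(c("cancer", "control"), each = n / 2), rownames(x))
  val <- rownames(x)[c(1:8, 31:38)]
  w <- capture_warnings(m <- train_boosting(x, y, val, fast_search(n = 2)))
  expect_true(any(grepl("constant", w)))
  expect_s3_class(m, "tep_model")
})
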