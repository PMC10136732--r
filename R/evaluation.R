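# Internal: coerce labels to 0/1 with cancer (or 1) as the positive class.
as_binary <- function(y) {
  if (is.numeric(y)) {
    if (!all(y %in% c(0, 1))) stop("numeric labels must be 0/1", call. = FALSE)
    return(as.integer(y))
  }
  y <- as.character(y)
  if (!all(y %in% c("cancer", "control")))
    stop("labels must be 'cancer'/'control' or 0/1", call. = FALSE)
  as.integer(y == "cancer")
}

#' Balanced accuracy
#'
#' Mean of the per-class recalls; robust to class imbalance.
#'
#' @param y_true true labels (`cancer`/`control` or 0/1; both classes
#'   must be present).
#' @param y_pred predicted labels on the same coding.
#' @return number in \[0, 1\].
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  yt <- as_binary(y_true); yp <- as_binary(y_pred)
  if (length(yt) != length(yp)) stop("length mismatch", call. = FALSE)
  if (length(unique(yt)) < 2L)
    stop("balanced accuracy requires both classes in y_true", call. = FALSE)
  mean(c(mean(yp[yt == 1] == 1), mean(yp[yt == 0] == 0)))
}

#' ROC curve and AUC
#'
#' AUC is the probability that a randomly chosen positive outscores a
#' randomly chosen negative, ties counted one half (the rank /
#' Mann-Whitney formulation). ROC points come from a threshold sweep over
#' the unique scores, from (0, 0) to (1, 1).
#'
#' @param y_true true labels (both classes present).
#' @param scores numeric scores, higher = more cancer-like.
#' @return list with `auc` and `roc`, a data.frame of `fpr`, `tpr`.
#' @export
roc_auc <- function(y_true, scores) {
  yt <- as_binary(y_true)
  stopifnot(length(yt) == length(scores))
  if (length(unique(yt)) < 2L)
    stop("AUC requires both classes in y_true", call. = FALSE)
  n1 <- sum(yt == 1); n0 <- sum(yt == 0)
  if (length(unique(scores)) == 1L) {
    warning("constant scores: AUC = 0.5", call. = FALSE)
    auc <- 0.5
  } else {
    r <- rank(scores)                      # midranks handle ties at 1/2
    auc <- (sum(r[yt == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  ord <- order(scores, decreasing = TRUE)
  ys <- yt[ord]; ss <- scores[ord]
  grp <- cumsum(!duplicated(ss))           # group ties at one threshold
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  last <- !duplicated(grp, fromLast = TRUE)
  roc <- data.frame(fpr = c(0, fp[last] / n0), tpr = c(0, tp[last] / n1))
  list(auc = auc, roc = roc)
}

#' Stratified train/validation/test split
#'
#' Assigns `round(test_frac * n)` samples to the test set with per-class
#' largest-remainder rounding, then deals the remainder into `n_folds`
#' stratified cross-validation folds.
#'
#' @param labels named label vector (`cancer`/`control`).
#' @param test_frac test fraction (default 0.30).
#' @param n_folds number of CV folds (default 5).
#' @param seed split seed.
#' @return object of class `split_spec`: `train_ids`, `folds` (list of id
#'   vectors), `test_ids`, `seed`, `provenance = "random"`.
#' @export
stratified_split <- function(labels, test_frac = 0.30, n_folds = 5L, seed = 1L) {
  stopifnot(!is.null(names(labels)))
  test_frac <- check_real(test_frac, "test_frac", 0, 0.9)
  yt <- as_binary(labels)
  n_c <- table(yt)
  if (any(n_c < 10)) stop("each class needs >= 10 samples", call. = FALSE)
  target <- as.numeric(n_c) * test_frac
  base <- floor(target)
  extra <- round(test_frac * length(labels)) - sum(base)
  if (extra > 0) {
    give <- order(target - base, decreasing = TRUE)[seq_len(extra)]
    base[give] <- base[give] + 1
  }
  with_seed(seed, {
    test_ids <- character(0)
    folds <- vector("list", n_folds)
    for (k in seq_along(n_c)) {
      cls <- as.integer(names(n_c)[k])
      ids <- sample(names(labels)[yt == cls])
      test_k <- ids[seq_len(base[k])]
      test_ids <- c(test_ids, test_k)
      rest <- setdiff(ids, test_k)
      if (length(rest) < n_folds)
        stop("class ", names(n_c)[k], " too small for ", n_folds, " folds",
             call. = FALSE)
      fold_of <- rep_len(seq_len(n_folds), length(rest))
      for (f in seq_len(n_folds))
        folds[[f]] <- c(folds[[f]], rest[fold_of == f])
    }
    structure(list(train_ids = unlist(folds, use.names = FALSE),
                   folds = folds, test_ids = test_ids,
                   seed = as.integer(seed), provenance = "random",
                   excluded = character(0)),
              class = "split_spec")
  })
}

#' Split by collection site (hospital transfer design)
#'
#' Assigns samples to train or test purely by their collection site;
#' within-train validation folds remain stratified by label. Samples from
#' unlisted sites are excluded and reported.
#'
#' @param meta sample metadata data.frame (`sample_id`, `label`, `site`).
#' @param train_sites,test_sites disjoint site name vectors.
#' @param n_folds CV folds within the training partition.
#' @param seed fold seed.
#' @return a `split_spec` with `provenance = "location"`.
#' @export
location_split <- function(meta, train_sites, test_sites, n_folds = 5L,
                           seed = 1L) {
  if (length(intersect(train_sites, test_sites)))
    stop("train and test site lists must be disjoint", call. = FALSE)
  tr <- meta$sample_id[meta$site %in% train_sites]
  te <- meta$sample_id[meta$site %in% test_sites]
  if (!length(tr)) stop("no samples in the training sites", call. = FALSE)
  if (!length(te)) stop("no samples in the test sites", call. = FALSE)
  excluded <- setdiff(meta$sample_id, c(tr, te))
  labels <- setNames(meta$label, meta$sample_id)[tr]
  yt <- as_binary(labels)
  folds <- with_seed(seed, {
    folds <- vector("list", n_folds)
    for (cls in unique(yt)) {
      ids <- sample(names(labels)[yt == cls])
      fold_of <- rep_len(seq_len(n_folds), length(ids))
      for (f in seq_len(n_folds))
        folds[[f]] <- c(folds[[f]], ids[fold_of == f])
    }
    folds
  })
  structure(list(train_ids = unlist(folds, use.names = FALSE), folds = folds,
                 test_ids = te, seed = as.integer(seed),
                 provenance = "location", excluded = excluded,
                 train_sites = train_sites, test_sites = test_sites),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec:%s> %d train (%d folds), %d test, %d excluded\n",
              x$provenance, length(x$train_ids), length(x$folds),
              length(x$test_ids), length(x$excluded)))
  invisible(x)
}

# Internal: bal acc (threshold 0.5) and AUC from probabilities.
prob_metrics <- function(y, p) {
  list(bal_acc = balanced_accuracy(y, as.integer(p >= 0.5)),
       auc = roc_auc(y, p)$auc)
}

# Internal: assert that two id sets do not intersect (leakage guard).
assert_disjoint <- function(a, b, what) {
  if (length(intersect(a, b)))
    stop("leakage detected: ", what, " partitions share samples",
         call. = FALSE)
  invisible(TRUE)
}

new_report <- function(df, experiment, extra = list()) {
  structure(c(list(results = df, experiment = experiment), extra),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report:%s>\n", x$experiment))
  print(x$results, row.names = FALSE)
  invisible(x)
}

# Internal: fit one model kind and return val/test metrics.
fit_and_score <- function(kind, expr, db, labels, train_ids, val_ids,
                          test_ids, search, epochs, seed) {
  assert_disjoint(train_ids, test_ids, "train/test")
  assert_disjoint(val_ids, test_ids, "validation/test")
  if (kind == "boosting") {
    genes <- preselect_features(db, expr)
    xm <- feature_matrix(expr, genes)
    model <- train_boosting(xm[c(train_ids, val_ids), , drop = FALSE],
                            labels, val_ids, search)
    p_val <- predict_proba(model, xm[val_ids, , drop = FALSE])
    p_test <- predict_proba(model, xm[test_ids, , drop = FALSE])
  } else if (kind == "implatelet") {
    imgs <- build_images(expr, db, train_ids = c(train_ids, val_ids))
    model <- train_implatelet(sub_images(imgs, c(train_ids, val_ids)),
                              labels, val_ids, epochs = epochs, seed = seed)
    p_val <- predict_proba(model, sub_images(imgs, val_ids))
    p_test <- predict_proba(model, sub_images(imgs, test_ids))
  } else stop("unknown model kind: ", kind, call. = FALSE)
  list(model = model,
       val = prob_metrics(labels[val_ids], p_val),
       test = prob_metrics(labels[test_ids], p_test))
}

# Internal: subset a tep_images object by sample id.
sub_images <- function(imgs, ids) {
  j <- match(ids, imgs$sample_ids)
  if (anyNA(j)) stop("unknown sample ids in images", call. = FALSE)
  imgs$values <- imgs$values[, , j, drop = FALSE]
  imgs$sample_ids <- ids
  imgs$meta <- imgs$meta[match(ids, imgs$meta$sample_id), , drop = FALSE]
  imgs
}

#' Internal model comparison with cross-validation and held-out test
#'
#' For each model and repeat: 5-fold cross-validation metrics on the
#' training partition (each fold serving once as the early-stopping /
#' epoch-selection validation set), then final metrics on the held-out
#' test set from a model trained on the full training partition with the
#' first fold as validation. Repeats use distinct seeds; results report
#' the per-repeat values and their mean. Image scaling constants are fit
#' on the training partition only.
#'
#' @param expr a [tep_expr()].
#' @param db a [pathway_db()].
#' @param split a `split_spec`.
#' @param models subset of `c("boosting", "implatelet")`.
#' @param repeats repeats with distinct seeds (default 3).
#' @param search a [search_config()] for the boosting arm.
#' @param epochs CNN epoch budget.
#' @return an `eval_report`; `$results` has one row per model x repeat x
#'   partition (cv_validation / test) with `bal_acc` and `auc`.
#' @export
run_model_comparison <- function(expr, db, split,
                                 models = c("boosting", "implatelet"),
                                 repeats = 3L, search = search_config(),
                                 epochs = 30L) {
  labels <- sample_labels(expr)
  rows <- list()
  for (m in models) {
    for (r in seq_len(repeats)) {
      seed_r <- split$seed + 1000L * r
      search_r <- search; search_r$seed <- search$seed + r
      cv_bal <- cv_auc <- numeric(length(split$folds))
      for (f in seq_along(split$folds)) {
        val_ids <- split$folds[[f]]
        tr_ids <- setdiff(split$train_ids, val_ids)
        # CV fold metrics are measured on the fold used for early stopping
        sc <- fit_and_score(m, expr, db, labels, tr_ids, val_ids,
                            split$test_ids, search_r, epochs, seed_r + f)
        cv_bal[f] <- sc$val$bal_acc; cv_auc[f] <- sc$val$auc
        if (f == 1L) test <- sc$test
      }
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, rep = r, partition = "cv_validation",
        bal_acc = mean(cv_bal), auc = mean(cv_auc))
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, rep = r, partition = "test",
        bal_acc = test$bal_acc, auc = test$auc)
    }
  }
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(bal_acc, auc) ~ model + partition, df, mean)
  new_report(df, "model_comparison", list(summary = agg, repeats = repeats))
}

#' Image permutation experiment
#'
#' Trains the CNN on baseline, row-permuted and column-permuted
#' pathway-grid images (one seed-determined permutation shared by all
#' samples per arm) and reports the validation/test metric pairs. A
#' boosting arm consuming the order-canonicalized flat features is
#' included as a control: its metrics are identical across arms by
#' construction.
#'
#' @param expr a [tep_expr()].
#' @param db a [pathway_db()].
#' @param split a `split_spec`.
#' @param seed permutation seed.
#' @param epochs CNN epoch budget.
#' @param search boosting [search_config()].
#' @return an `eval_report` with one row per arm x model.
#' @export
run_permutation_experiment <- function(expr, db, split, seed = 1L,
                                       epochs = 30L,
                                       search = search_config()) {
  labels <- sample_labels(expr)
  val_ids <- split$folds[[1]]
  tr_ids <- setdiff(split$train_ids, val_ids)
  base <- build_images(expr, db, train_ids = split$train_ids)
  arms <- list(baseline = base,
               permuted_rows = permute_images(base, "rows", seed),
               permuted_columns = permute_images(base, "columns", seed))
  rows <- list()
  for (arm in names(arms)) {
    imgs <- arms[[arm]]
    cnn <- train_implatelet(sub_images(imgs, split$train_ids), labels,
                            val_ids, epochs = epochs, seed = split$seed)
    mv <- prob_metrics(labels[val_ids],
                       predict_proba(cnn, sub_images(imgs, val_ids)))
    mt <- prob_metrics(labels[split$test_ids],
                       predict_proba(cnn, sub_images(imgs, split$test_ids)))
    xm <- images_to_features(imgs)
    bst <- train_boosting(xm[split$train_ids, , drop = FALSE], labels,
                          val_ids, search)
    bv <- prob_metrics(labels[val_ids],
                       predict_proba(bst, xm[val_ids, , drop = FALSE]))
    bt <- prob_metrics(labels[split$test_ids],
                       predict_proba(bst, xm[split$test_ids, , drop = FALSE]))
    rows[[length(rows) + 1L]] <- data.frame(
      arm = arm, model = c("implatelet", "boosting"),
      val_auc = c(mv$auc, bv$auc), test_auc = c(mt$auc, bt$auc),
      val_bal_acc = c(mv$bal_acc, bv$bal_acc),
      test_bal_acc = c(mt$bal_acc, bt$bal_acc))
  }
  new_report(do.call(rbind, rows), "permutation")
}

#' Pathway preselection versus all features
#'
#' Trains the boosting classifier on (a) the pathway-preselected feature
#' set and (b) all features, and reports the paired metrics.
#'
#' @param expr a [tep_expr()].
#' @param db a [pathway_db()].
#' @param split a `split_spec`.
#' @param search boosting [search_config()].
#' @return an `eval_report` with rows `preselected` and `all_features`.
#' @export
run_preselection_experiment <- function(expr, db, split,
                                        search = search_config()) {
  labels <- sample_labels(expr)
  val_ids <- split$folds[[1]]
  genes <- preselect_features(db, expr)
  arms <- list(preselected = feature_matrix(expr, genes),
               all_features = feature_matrix(expr))
  rows <- lapply(names(arms), function(arm) {
    xm <- arms[[arm]]
    model <- train_boosting(xm[split$train_ids, , drop = FALSE], labels,
                            val_ids, search)
    mv <- prob_metrics(labels[val_ids],
                       predict_proba(model, xm[val_ids, , drop = FALSE]))
    mt <- prob_metrics(labels[split$test_ids],
                       predict_proba(model, xm[split$test_ids, , drop = FALSE]))
    data.frame(arm = arm, n_features = ncol(xm),
               val_auc = mv$auc, test_auc = mt$auc,
               val_bal_acc = mv$bal_acc, test_bal_acc = mt$bal_acc)
  })
  df <- do.call(rbind, rows)
  message(sprintf("preselected %d of %d features",
                  df$n_features[1], df$n_features[2]))
  new_report(df, "preselection")
}

#' Hospital-transfer robustness experiment
#'
#' Trains on the training-site samples and evaluates on held-out-site
#' samples without any adaptation or fine-tuning, reporting
#' internal-validation versus external-test metrics and their gap.
#'
#' @param expr a [tep_expr()].
#' @param db a [pathway_db()].
#' @param train_sites,test_sites disjoint site lists.
#' @param models subset of `c("boosting", "implatelet")`.
#' @param search boosting [search_config()].
#' @param epochs CNN epoch budget.
#' @param seed fold seed for the within-train validation split.
#' @return an `eval_report`; one row per model with internal/external
#'   metrics and `auc_gap = internal - external`.
#' @export
run_transfer_experiment <- function(expr, db, train_sites, test_sites,
                                    models = "boosting",
                                    search = search_config(),
                                    epochs = 30L, seed = 1L) {
  split <- location_split(expr$meta, train_sites, test_sites, seed = seed)
  labels <- sample_labels(expr)
  val_ids <- split$folds[[1]]
  tr_ids <- setdiff(split$train_ids, val_ids)
  expr_use <- if (length(split$excluded))
    subset_samples(expr, c(split$train_ids, split$test_ids)) else expr
  rows <- lapply(models, function(m) {
    sc <- fit_and_score(m, expr_use, db, labels, tr_ids, val_ids,
                        split$test_ids, search, epochs, seed)
    data.frame(model = m,
               internal_bal_acc = sc$val$bal_acc, internal_auc = sc$val$auc,
               external_bal_acc = sc$test$bal_acc, external_auc = sc$test$auc,
               auc_gap = sc$val$auc - sc$test$auc)
  })
  site_counts <- table(expr$meta$site[match(c(split$train_ids, split$test_ids),
                                            expr$meta$sample_id)])
  new_report(do.call(rbind, rows), "transfer",
             list(split = split, site_counts = site_counts))
}

#' Pathway-group ablation
#'
#' For each of the eight pathway groups, restricts the database to that
#' group alone, re-runs preselection and training, and reports the test
#' metrics next to the all-groups baseline. Groups absent from the
#' database are skipped with a warning.
#'
#' @param expr a [tep_expr()].
#' @param db a [pathway_db()].
#' @param split a `split_spec`.
#' @param search boosting [search_config()].
#' @return an `eval_report` with one row per group plus `all_groups`.
#' @export
run_group_ablation <- function(expr, db, split, search = search_config()) {
  labels <- sample_labels(expr)
  val_ids <- split$folds[[1]]
  tr_ids <- setdiff(split$train_ids, val_ids)
  score_db <- function(dbi, tag) {
    sc <- fit_and_score("boosting", expr, dbi, labels, tr_ids, val_ids,
                        split$test_ids, search, 0L, split$seed)
    data.frame(group = tag, n_pathways = length(dbi),
               test_bal_acc = sc$test$bal_acc, test_auc = sc$test$auc)
  }
  rows <- list(score_db(db, "all_groups"))
  for (g in kegg_groups()) {
    if (!g %in% db$group) {
      warning("group '", g, "' absent from database; skipped", call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- score_db(subset_group(db, g), g)
  }
  new_report(do.call(rbind, rows), "group_ablation")
}

#' Importance-limited feature sweep
#'
#' Extracts a gain-based importance ranking from a full-feature boosting
#' fit on the training partition, then, for each feature budget k,
#' restricts training to the top-k features, runs a fresh random
#' hyperparameter search, and reports the test AUC, giving an AUC-versus-k
#' curve.
#'
#' @param expr a [tep_expr()].
#' @param db a [pathway_db()] (features = preselected set).
#' @param split a `split_spec`.
#' @param counts feature budgets (default 10, 20, 50, 100, 200, 500).
#' @param rounds_per_count hyperparameter settings searched per budget
#'   (default 100).
#' @param search base [search_config()] (ranges and seed).
#' @return an `eval_report`; `$results` has the AUC-vs-k curve and
#'   `$ranking` the importance ranking used.
#' @export
run_feature_sweep <- function(expr, db, split,
                              counts = c(10, 20, 50, 100, 200, 500),
                              rounds_per_count = 100L,
                              search = search_config()) {
  labels <- sample_labels(expr)
  val_ids <- split$folds[[1]]
  genes <- preselect_features(db, expr)
  xm <- feature_matrix(expr, genes)
  full <- train_boosting(xm[split$train_ids, , drop = FALSE], labels,
                         val_ids, search)
  ranking <- feature_importance(full)
  rows <- list()
  for (k in counts) {
    kk <- min(k, nrow(ranking))
    if (kk < k)
      warning("feature budget ", k, " exceeds ", nrow(ranking),
              " available features; truncated", call. = FALSE)
    top <- ranking$feature[seq_len(kk)]
    sk <- search
    sk$n_settings <- as.integer(rounds_per_count)
    sk$repeats_per_setting <- 1L
    sk$seed <- search$seed + kk
    model <- train_boosting(xm[split$train_ids, top, drop = FALSE], labels,
                            val_ids, sk)
    mt <- prob_metrics(labels[split$test_ids],
                       predict_proba(model, xm[split$test_ids, top,
                                               drop = FALSE]))
    rows[[length(rows) + 1L]] <- data.frame(
      k = kk, test_auc = mt$auc, test_bal_acc = mt$bal_acc)
  }
  new_report(do.call(rbind, rows), "feature_sweep", list(ranking = ranking))
}
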