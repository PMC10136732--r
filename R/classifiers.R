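#' Inverse-frequency class weights
#'
#' Weight of class c is `n_total / (2 * n_c)`, so the two weighted class
#' masses are equal and accuracy under these weights is balanced
#' accuracy.
#'
#' @param labels character/factor vector with both classes present.
#' @return named numeric vector of per-class weights.
#' @export
class_weights <- function(labels) {
  tab <- table(as.character(labels))
  if (length(tab) < 2L)
    stop("class_weights requires both classes present", call. = FALSE)
  w <- sum(tab) / (2 * tab)
  setNames(as.numeric(w), names(tab))
}

#' Random hyperparameter search configuration for gradient boosting
#'
#' The searched hyperparameters are learning rate (log-uniform), maximal
#' tree depth, number of estimators, and the input-feature dropout rate
#' (column subsampling). Defaults: 150 settings, each tested three times,
#' with early stopping after 15 non-improving rounds.
#'
#' @param n_settings number of random settings to draw.
#' @param repeats_per_setting fits per setting (distinct seeds).
#' @param early_stopping_rounds early-stopping patience.
#' @param learning_rate (low, high) interval, sampled log-uniformly.
#' @param max_depth integer interval.
#' @param n_estimators integer interval (upper bound on boosting rounds).
#' @param feature_dropout (low, high) interval in (0, 1].
#' @param seed search seed.
#' @return validated list of class `search_config`.
#' @export
search_config <- function(n_settings = 150L, repeats_per_setting = 3L,
                          early_stopping_rounds = 15L,
                          learning_rate = c(0.01, 0.3),
                          max_depth = c(2L, 8L),
                          n_estimators = c(50L, 1000L),
                          feature_dropout = c(0.1, 1.0),
                          seed = 1L) {
  cfg <- list(
    n_settings = check_count(n_settings, "n_settings"),
    repeats_per_setting = check_count(repeats_per_setting, "repeats_per_setting"),
    early_stopping_rounds = check_count(early_stopping_rounds, "early_stopping_rounds"),
    learning_rate = check_pair(learning_rate, "learning_rate", min = 1e-6),
    max_depth = check_pair(max_depth, "max_depth", min = 1),
    n_estimators = check_pair(n_estimators, "n_estimators", min = 1),
    feature_dropout = check_pair(feature_dropout, "feature_dropout", min = 1e-6),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$feature_dropout[2] > 1)
    stop_field("feature_dropout", "upper bound cannot exceed 1")
  structure(cfg, class = "search_config")
}

#' Draw the hyperparameter settings of a random search
#'
#' Deterministic in `search$seed`.
#'
#' @param search a [search_config()].
#' @return data.frame with one row per setting: `learning_rate`,
#'   `max_depth`, `n_estimators`, `feature_dropout`.
#' @export
draw_search_settings <- function(search) {
  stopifnot(inherits(search, "search_config"))
  with_seed(search$seed, {
    n <- search$n_settings
    data.frame(
      learning_rate = exp(runif(n, log(search$learning_rate[1]),
                                log(search$learning_rate[2]))),
      max_depth = sample(seq(search$max_depth[1], search$max_depth[2]), n,
                         replace = TRUE),
      n_estimators = sample(seq(search$n_estimators[1], search$n_estimators[2]),
                            n, replace = TRUE),
      feature_dropout = runif(n, search$feature_dropout[1],
                              search$feature_dropout[2])
    )
  })
}

# Internal: one xgboost fit with early stopping; returns booster + val AUC.
xgb_fit <- function(x_tr, y_tr, x_va, y_va, setting, early, w_class, seed) {
  dtr <- xgboost::xgb.DMatrix(x_tr, label = y_tr,
                              weight = w_class[ifelse(y_tr == 1, "cancer", "control")],
                              nthread = 1)
  dva <- xgboost::xgb.DMatrix(x_va, label = y_va, nthread = 1)
  params <- list(objective = "binary:logistic", eval_metric = "logloss",
                 eta = setting$learning_rate,
                 max_depth = as.integer(setting$max_depth),
                 colsample_bytree = setting$feature_dropout,
                 nthread = 1, seed = as.integer(seed))
  bst <- xgboost::xgb.train(params = params, data = dtr,
                            nrounds = as.integer(setting$n_estimators),
                            evals = list(val = dva),
                            early_stopping_rounds = early, verbose = 0)
  best_iter <- as.integer(xgboost::xgb.attr(bst, "best_iteration"))
  if (is.na(best_iter)) best_iter <- as.integer(setting$n_estimators)
  p <- predict(bst, x_va, iterationrange = c(1L, best_iter))
  list(booster = bst, best_iter = best_iter,
       val_auc = roc_auc(y_va, p)$auc)
}

#' Train a class-weighted gradient-boosting classifier with random search
#'
#' Draws `search$n_settings` hyperparameter settings, fits each
#' `search$repeats_per_setting` times with distinct seeds (early-stopping
#' on validation loss), and returns the setting with the best mean
#' validation AUC, refit on the training partition. Ties fall to the
#' smaller number of estimators, then the smaller depth. Sample weights
#' are the inverse-frequency class weights.
#'
#' @param x numeric matrix, samples x features, rownames = sample ids,
#'   colnames = feature ids.
#' @param y named vector of labels (`cancer` / `control`) covering all
#'   rows of `x`.
#' @param val_ids sample ids forming the validation partition (disjoint
#'   from training rows by construction: the remaining rows train).
#' @param search a [search_config()].
#' @return object of class `tep_model` with `kind = "boosting"`.
#' @export
train_boosting <- function(x, y, val_ids, search = search_config()) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  y <- y[rownames(x)]
  if (anyNA(y)) stop("labels missing for some samples", call. = FALSE)
  if (!all(val_ids %in% rownames(x)))
    stop("val_ids must be rows of x", call. = FALSE)
  if (all(apply(x, 2L, function(col) all(col == col[1]))))
    warning("feature matrix is constant; model will not learn", call. = FALSE)
  tr_ids <- setdiff(rownames(x), val_ids)
  yb <- as.integer(y == "cancer")
  names(yb) <- names(y)
  w <- class_weights(y[tr_ids])
  settings <- draw_search_settings(search)
  fit_seeds <- with_seed(search$seed + 1L,
                         matrix(sample.int(.Machine$integer.max %/% 2,
                                           nrow(settings) * search$repeats_per_setting),
                                nrow = nrow(settings)))
  mean_auc <- numeric(nrow(settings))
  for (i in seq_len(nrow(settings))) {
    aucs <- vapply(seq_len(search$repeats_per_setting), function(r) {
      xgb_fit(x[tr_ids, , drop = FALSE], yb[tr_ids],
              x[val_ids, , drop = FALSE], yb[val_ids],
              settings[i, ], search$early_stopping_rounds, w,
              fit_seeds[i, r])$val_auc
    }, numeric(1))
    mean_auc[i] <- mean(aucs)
  }
  ord <- order(-mean_auc, settings$n_estimators, settings$max_depth)
  best <- ord[1]
  final <- xgb_fit(x[tr_ids, , drop = FALSE], yb[tr_ids],
                   x[val_ids, , drop = FALSE], yb[val_ids],
                   settings[best, ], search$early_stopping_rounds, w,
                   fit_seeds[best, 1])
  structure(list(kind = "boosting", booster = final$booster,
                 best_iter = final$best_iter,
                 setting = settings[best, ],
                 search_auc = mean_auc, settings = settings,
                 feature_ids = colnames(x), class_weights = w,
                 val_auc = final$val_auc, seed = search$seed),
            class = "tep_model")
}

#' @export
print.tep_model <- function(x, ...) {
  cat(sprintf("<tep_model:%s> %d features, validation AUC %.3f\n",
              x$kind, length(x$feature_ids), x$val_auc))
  invisible(x)
}

#' Predict cancer probabilities
#'
#' Inputs are matched to the training feature set by id, never by
#' position: a column-permuted matrix yields identical probabilities, and
#' unknown or missing feature ids raise an error listing them.
#'
#' @param model a `tep_model` (boosting or imPlatelet CNN).
#' @param x samples x features matrix with colnames (boosting) or a
#'   `tep_images` object (CNN).
#' @return named numeric vector of probabilities in \[0, 1\].
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "tep_model"))
  if (model$kind == "implatelet_cnn") return(cnn_predict(model, x))
  stopifnot(is.matrix(x))
  if (is.null(colnames(x))) stop("feature ids (colnames) required", call. = FALSE)
  unknown <- setdiff(colnames(x), model$feature_ids)
  if (length(unknown))
    stop("unknown feature ids: ", paste(head(unknown, 5), collapse = ", "),
         call. = FALSE)
  missing <- setdiff(model$feature_ids, colnames(x))
  if (length(missing))
    stop("missing feature ids: ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  x <- x[, model$feature_ids, drop = FALSE]
  p <- predict(model$booster, x, iterationrange = c(1L, model$best_iter))
  setNames(as.numeric(p), rownames(x))
}

#' Gain-based feature importance of a boosting model
#'
#' Features are ordered by decreasing total gain; features never used by
#' the ensemble score 0 and are appended in training-input order.
#'
#' @param model a `tep_model` of kind `boosting`.
#' @return data.frame with columns `feature`, `importance`
#'   (non-increasing; used features' scores sum to 1).
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "tep_model"))
  if (model$kind != "boosting")
    stop("feature importance is only defined for boosting models",
         call. = FALSE)
  imp <- xgboost::xgb.importance(model = model$booster)
  used <- data.frame(feature = imp$Feature, importance = imp$Gain,
                     stringsAsFactors = FALSE)
  rest <- setdiff(model$feature_ids, used$feature)
  out <- rbind(used, data.frame(feature = rest,
                                importance = rep(0, length(rest))))
  rownames(out) <- NULL
  out
}
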