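#' Pipeline run configuration
#'
#' A flat configuration for [run_pipeline()]: either a synthetic-study
#' block or paths to counts/metadata/annotation/GMT inputs, plus
#' preprocessing thresholds, search settings, the experiment selection
#' and one top-level seed. Unknown keys are rejected.
#'
#' @param out_dir output directory (created if missing).
#' @param synthetic `NULL`, or a list of [synthetic_config()] arguments.
#' @param counts,meta,annot,gmt input paths (ignored when `synthetic` is
#'   given; all four required otherwise).
#' @param min_total QC threshold.
#' @param search list of [search_config()] arguments.
#' @param experiments character subset of `c("compare", "permute",
#'   "preselect", "transfer", "ablation", "sweep")`.
#' @param repeats repeats for the comparison experiment.
#' @param epochs CNN epoch budget.
#' @param models models for the comparison experiment.
#' @param seed top-level seed.
#' @param config_file optionally, a YAML file whose keys replace the
#'   above arguments.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, synthetic = list(), counts = NULL,
                            meta = NULL, annot = NULL, gmt = NULL,
                            min_total = 100000, search = list(),
                            experiments = "compare", repeats = 1L,
                            epochs = 20L, models = "boosting", seed = 1L,
                            config_file = NULL) {
  if (!is.null(config_file)) {
    vals <- yaml::read_yaml(config_file)
    known <- setdiff(names(formals(pipeline_config)), "config_file")
    bad <- setdiff(names(vals), known)
    if (length(bad))
      stop_field("config_file", paste("unknown keys:", paste(bad, collapse = ", ")))
    return(do.call(pipeline_config, vals))
  }
  allowed <- c("compare", "permute", "preselect", "transfer", "ablation",
               "sweep")
  if (!all(experiments %in% allowed))
    stop_field("experiments", paste("must be a subset of",
                                    paste(allowed, collapse = ", ")))
  use_synth <- length(synthetic) > 0 || is.null(counts)
  if (!use_synth && (is.null(meta) || is.null(annot) || is.null(gmt)))
    stop_field("counts", "counts, meta, annot and gmt must all be given")
  if (!use_synth)
    for (p in c(counts, meta, annot, gmt))
      if (!file.exists(p)) stop_field("paths", paste("missing input:", p))
  structure(list(out_dir = out_dir, synthetic = synthetic, counts = counts,
                 meta = meta, annot = annot, gmt = gmt,
                 min_total = min_total, search = search,
                 experiments = experiments, repeats = check_count(repeats, "repeats"),
                 epochs = check_count(epochs, "epochs"), models = models,
                 seed = check_count(seed, "seed", min = 0L)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes the selected stages in fixed order — simulate (when a
#' synthetic block is configured) or load, preprocess, encode, train,
#' experiments — and writes a run manifest (config hash, seed, output
#' files with checksums). Re-running with the same config and seed
#' reproduces all outputs byte-identically (manifests differ only in the
#' timestamp).
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  outputs <- character(0)
  emit <- function(path) outputs <<- c(outputs, path)
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  use_synth <- is.null(config$counts)
  study <- stage("simulate", function() {
    if (use_synth) {
      args <- config$synthetic
      args$seed <- args$seed %||% config$seed
      st <- simulate_study(do.call(synthetic_config, args))
      write_counts_tsv(st$counts, out("counts.tsv"), out("metadata.tsv"))
      write_annotation_tsv(st$annot, out("annotation.tsv"))
      write_gmt(st$db, out("pathways.gmt"))
      for (f in c("counts.tsv", "metadata.tsv", "annotation.tsv",
                  "pathways.gmt")) emit(out(f))
      st
    } else {
      list(counts = read_counts_tsv(config$counts, config$meta),
           annot = read_annotation_tsv(config$annot),
           db = read_gmt(config$gmt), truth = NULL)
    }
  })

  prep <- stage("preprocess", function() {
    pr <- preprocess_counts(study$counts, study$annot, config$min_total)
    write_expr_tsv(pr$expr, out("expression.tsv"), out("expr_metadata.tsv"))
    emit(out("expression.tsv")); emit(out("expr_metadata.tsv"))
    pr
  })

  split <- stratified_split(sample_labels(prep$expr), seed = config$seed)
  search <- do.call(search_config, c(config$search,
                                     if (is.null(config$search$seed))
                                       list(seed = config$seed)))

  stage("encode", function() {
    imgs <- build_images(prep$expr, study$db, train_ids = split$train_ids)
    d <- dim(imgs$values)
    flat <- matrix(imgs$values, d[1] * d[2], d[3],
                   dimnames = list(NULL, imgs$sample_ids))
    write.table(data.frame(cell = seq_len(nrow(flat)), flat,
                           check.names = FALSE),
                out("images.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(
      list(shape = d[1:2], pathway_id = imgs$pathway_id,
           group = imgs$group, scale = as.list(imgs$scale),
           cell_gene = as.vector(imgs$cell_gene)),
      out("images_meta.json"), auto_unbox = TRUE, null = "null")
    emit(out("images.tsv")); emit(out("images_meta.json"))
  })

  model <- stage("train", function() {
    genes <- preselect_features(study$db, prep$expr)
    xm <- feature_matrix(prep$expr, genes)
    m <- train_boosting(xm[split$train_ids, , drop = FALSE],
                        sample_labels(prep$expr), split$folds[[1]], search)
    jsonlite::write_json(
      list(kind = m$kind, setting = as.list(m$setting),
           best_iter = m$best_iter, val_auc = m$val_auc,
           class_weights = as.list(m$class_weights),
           n_features = length(m$feature_ids)),
      out("model.json"), auto_unbox = TRUE, digits = NA)
    emit(out("model.json"))
    m
  })

  reports <- list()
  for (exp in config$experiments) {
    reports[[exp]] <- stage(exp, function() {
      rep <- switch(exp,
        compare = run_model_comparison(prep$expr, study$db, split,
                                       models = config$models,
                                       repeats = config$repeats,
                                       search = search,
                                       epochs = config$epochs),
        permute = run_permutation_experiment(prep$expr, study$db, split,
                                             seed = config$seed,
                                             epochs = config$epochs,
                                             search = search),
        preselect = run_preselection_experiment(prep$expr, study$db, split,
                                                search = search),
        transfer = {
          sites <- sort(unique(prep$expr$meta$site))
          half <- seq_len(ceiling(length(sites) / 2))
          run_transfer_experiment(prep$expr, study$db, sites[half],
                                  sites[-half], models = config$models[1],
                                  search = search, epochs = config$epochs,
                                  seed = config$seed)
        },
        ablation = run_group_ablation(prep$expr, study$db, split,
                                      search = search),
        sweep = run_feature_sweep(prep$expr, study$db, split,
                                  counts = c(10, 20, 50, 100),
                                  rounds_per_count = 20L, search = search))
      f <- out(paste0("report_", exp, ".tsv"))
      write.table(rep$results, f, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      emit(f)
      rep
    })
  }

  cfg_for_hash <- unclass(config)
  cfg_for_hash$out_dir <- NULL           # hash the science, not the location
  cfg_json <- jsonlite::toJSON(cfg_for_hash, auto_unbox = TRUE,
                               null = "null", digits = NA)
  manifest <- list(
    package = "teptools",
    version = as.character(utils::packageVersion("teptools")),
    config = jsonlite::fromJSON(cfg_json),
    config_hash = unname(tools::md5sum(textConnection_write(cfg_json))),
    seed = config$seed,
    stages = c("simulate", "preprocess", "encode", "train",
               config$experiments),
    outputs = data.frame(path = basename(outputs),
                         md5 = unname(tools::md5sum(outputs))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  emit(out("manifest.json"))
  invisible(c(manifest, list(reports = reports, model = model)))
}

# md5sum works on files only; hash a string via a temp file.
textConnection_write <- function(txt) {
  f <- tempfile()
  writeLines(as.character(txt), f)
  f
}
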